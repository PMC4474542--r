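## Matched random background sampling.
##
## Each positive regulatory region is anchored to a target gene and
## described by a relative coordinate: its genomic context (upstream
## window, exon, or intron of the target gene) and its relative distance
## to the context's landmark. Background regions of identical length are
## placed at the same relative coordinate in randomly chosen genes, so
## that positives and backgrounds share the distribution of positions
## along genes and differ only in regulatory status.

.UPSTREAM_BP <- 10000L

# midpoint used as a region's reference point throughout
.region_mid <- function(rs) (rs$start + rs$end) %/% 2L

# upstream window [w_start, w_end) of each gene, strand-aware
.upstream_windows <- function(genes) {
  data.table::data.table(
    gene_id = genes$gene_id, chrom = genes$chrom,
    w_start = ifelse(genes$strand == "+",
                     pmax(0L, genes$tx_start - .UPSTREAM_BP), genes$tx_end),
    w_end = ifelse(genes$strand == "+",
                   genes$tx_start, genes$tx_end + .UPSTREAM_BP),
    tss = genes$tss,
    norm_length = genes$coding_length + .UPSTREAM_BP)
}

# long tables of exons and introns: gene_id, chrom, s, e, len
.exon_table <- function(genes) {
  n <- vapply(genes$exon_starts, length, 1L)
  data.table::data.table(
    gene_id = rep(genes$gene_id, n), chrom = rep(genes$chrom, n),
    s = unlist(genes$exon_starts), e = unlist(genes$exon_ends))[
      , len := e - s][]
}

.intron_table <- function(genes) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) < 2L) return(NULL)
    data.table::data.table(gene_id = genes$gene_id[i],
                           chrom = genes$chrom[i],
                           s = ee[-length(ee)], e = es[-1L])
  })
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L) {
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  s = integer(), e = integer(),
                                  len = integer()))
  }
  out[, len := e - s][]
}

#' Assign a target gene to each region
#'
#' A region whose midpoint falls inside a gene body is assigned that gene;
#' a region whose midpoint falls in the 10 kb window upstream of one or
#' more TSSs is assigned the immediately downstream gene (the one with
#' the smallest upstream distance). Regions in neither context get `NA`
#' and are reported.
#'
#' @param regions a `region_set`.
#' @param genes a `gene_annotation`.
#' @return character vector of gene ids aligned with `regions` (`NA`
#'   where no target exists).
#' @export
assign_target_gene <- function(regions, genes) {
  stopifnot(inherits(genes, "gene_annotation"))
  lv <- union(unique(regions$chrom), unique(genes$chrom))
  mids <- .region_mid(regions)
  mid_gr <- GenomicRanges::GRanges(factor(regions$chrom, levels = lv),
                                   IRanges::IRanges(mids + 1L, width = 1L))
  body_gr <- GenomicRanges::GRanges(factor(genes$chrom, levels = lv),
                                    IRanges::IRanges(genes$tx_start + 1L,
                                                     genes$tx_end))
  res <- rep(NA_character_, nrow(regions))
  hit <- GenomicRanges::findOverlaps(mid_gr, body_gr, select = "first")
  res[!is.na(hit)] <- genes$gene_id[hit[!is.na(hit)]]

  up <- .upstream_windows(genes)
  up_gr <- GenomicRanges::GRanges(factor(up$chrom, levels = lv),
                                  IRanges::IRanges(up$w_start + 1L, up$w_end))
  todo <- which(is.na(res))
  if (length(todo)) {
    ov <- GenomicRanges::findOverlaps(mid_gr[todo], up_gr)
    if (length(ov)) {
      cand <- data.table::data.table(
        idx = todo[S4Vectors::queryHits(ov)],
        gene_id = up$gene_id[S4Vectors::subjectHits(ov)],
        d = abs(mids[todo[S4Vectors::queryHits(ov)]] -
                  up$tss[S4Vectors::subjectHits(ov)]))
      best <- cand[order(d), .SD[1L], by = "idx"]
      res[best$idx] <- best$gene_id
    }
  }
  n_miss <- sum(is.na(res))
  if (n_miss > 0L) {
    message(n_miss, " region(s) without a target gene ",
            "(outside gene bodies and 10 kb upstream windows)")
  }
  res
}

#' Relative genomic coordinate of regions within their target genes
#'
#' The region midpoint determines the context: `upstream` when it lies in
#' the 10 kb window upstream of the target TSS, `exon` or `intron` when
#' it lies in the gene body. The relative distance is the distance to the
#' context landmark normalized by the context length: for the upstream
#' context the distance to the TSS over `coding_length + 10000`, for
#' exons/introns the distance to the nearest boundary of the containing
#' element over the element length.
#'
#' @param regions a `region_set`; `target_gene` must be set (it is
#'   assigned with [assign_target_gene()] when entirely missing).
#' @param genes a `gene_annotation`.
#' @return `data.table` with columns `region_id`, `gene_id`, `context`,
#'   `dist`, `norm_length`, `rel_dist`.
#' @export
relative_position <- function(regions, genes) {
  stopifnot(inherits(genes, "gene_annotation"))
  regions <- data.table::as.data.table(regions)
  if (all(is.na(regions$target_gene))) {
    regions$target_gene <- assign_target_gene(
      structure(regions, class = c("region_set", "data.table", "data.frame")),
      genes)
  }
  if (anyNA(regions$target_gene)) {
    stop("regions without target gene; run assign_target_gene() and drop ",
         "unassignable regions first")
  }
  gmap <- genes[, .(gene_id, strand, tx_start, tx_end, tss, coding_length)]
  q <- data.table::data.table(region_id = regions$region_id,
                              gene_id = regions$target_gene,
                              mid = .region_mid(regions))
  q <- gmap[q, on = "gene_id"]
  if (anyNA(q$tss)) {
    stop("unknown target gene: ", q$region_id[which(is.na(q$tss))[1L]])
  }

  res <- data.table::data.table(region_id = q$region_id, gene_id = q$gene_id,
                                context = NA_character_, dist = NA_integer_,
                                norm_length = NA_integer_)
  in_body <- q$mid >= q$tx_start & q$mid < q$tx_end
  upstream <- (!in_body) &
    ((q$strand == "+" & q$mid < q$tx_start &
        q$mid >= q$tx_start - .UPSTREAM_BP) |
       (q$strand == "-" & q$mid >= q$tx_end &
          q$mid < q$tx_end + .UPSTREAM_BP))
  res$context[upstream] <- "upstream"
  res$dist[upstream] <- abs(q$mid[upstream] - q$tss[upstream])
  res$norm_length[upstream] <- q$coding_length[upstream] + .UPSTREAM_BP

  if (any(in_body)) {
    ex <- .exon_table(genes)
    intr <- .intron_table(genes)
    qb <- data.table::data.table(region_id = q$region_id[in_body],
                                 gene_id = q$gene_id[in_body],
                                 m1 = q$mid[in_body], m2 = q$mid[in_body])
    hit_ex <- ex[qb, on = .(gene_id, s <= m1, e > m2), nomatch = NULL,
                 .(region_id = i.region_id, elem_s = x.s, elem_e = x.e,
                   context = "exon")]
    hit_in <- intr[qb, on = .(gene_id, s <= m1, e > m2), nomatch = NULL,
                   .(region_id = i.region_id, elem_s = x.s, elem_e = x.e,
                     context = "intron")]
    hits <- data.table::rbindlist(list(hit_ex, hit_in))
    if (nrow(hits)) {
      ix <- match(hits$region_id, res$region_id)
      res$context[ix] <- hits$context
      midv <- q$mid[match(hits$region_id, q$region_id)]
      res$dist[ix] <- pmin(midv - hits$elem_s, hits$elem_e - midv)
      res$norm_length[ix] <- hits$elem_e - hits$elem_s
    }
  }
  if (anyNA(res$context)) {
    stop("region midpoint outside upstream/exon/intron contexts: ",
         res$region_id[which(is.na(res$context))[1L]])
  }
  res[, rel_dist := dist / norm_length]
  res[]
}

#' Sample random background regions matched by relative genomic position
#'
#' For every positive region, `n_per_region` background regions of
#' identical length are drawn: a host gene (or one of its exons/introns,
#' depending on the source context) is chosen uniformly at random, the
#' source's relative distance is mapped onto the host's normalizing
#' length, and the placement is accepted if it reproduces the source
#' context and relative distance (within `tol`), does not overlap any
#' positive region, and (optionally) contains at least one covered mCpG.
#' Placement uses rejection sampling with at most `max_attempts` rounds.
#'
#' @param positives a `region_set` of positive regions (target genes are
#'   assigned on the fly when missing; regions without a target are
#'   dropped with a warning).
#' @param genes a `gene_annotation` providing the candidate host genes.
#' @param n_per_region backgrounds per positive (default 1000).
#' @param seed integer seed; the output is fully determined by it.
#' @param methylome optional `methylome`; when supplied, candidate
#'   backgrounds must contain at least one covered site.
#' @param genome optional named `DNAStringSet` used to keep candidates
#'   within chromosome bounds.
#' @param max_attempts rejection-sampling rounds per placement (default 50).
#' @param tol accepted absolute deviation in relative distance after
#'   integer rounding of coordinates (default 0.01).
#' @return a `region_set` of background regions carrying `source_id` and
#'   `replicate`.
#' @export
sample_matched_regions <- function(positives, genes, n_per_region = 1000,
                                   seed = NULL, methylome = NULL,
                                   genome = NULL, max_attempts = 50,
                                   tol = 0.01) {
  stopifnot(inherits(positives, "region_set"),
            inherits(genes, "gene_annotation"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (all(is.na(positives$target_gene))) {
    positives <- data.table::copy(positives)
    positives$target_gene <- assign_target_gene(positives, genes)
  }
  keep <- !is.na(positives$target_gene)
  if (!all(keep)) {
    warning(sum(!keep), " positive region(s) without target gene dropped")
    positives <- positives[keep]
  }
  rc <- relative_position(positives, genes)
  rc <- rc[match(positives$region_id, rc$region_id)]

  up <- .upstream_windows(genes)
  up[, strand := genes$strand[match(gene_id, genes$gene_id)]]
  ex <- .exon_table(genes)[len >= 50L]
  intr <- .intron_table(genes)[len >= 50L]
  chrom_len <- if (!is.null(genome)) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else NULL
  lv <- unique(c(positives$chrom, genes$chrom))
  avoid_gr <- .as_granges(positives, lv)

  tasks <- data.table::data.table(
    source_id = rep(positives$region_id, each = n_per_region),
    region_class = rep(positives$region_class, each = n_per_region),
    replicate = rep(seq_len(n_per_region), times = nrow(positives)),
    context = rep(rc$context, each = n_per_region),
    rel_dist = rep(rc$rel_dist, each = n_per_region),
    len = rep(positives$end - positives$start, each = n_per_region))

  accepted <- vector("list", max_attempts)
  for (attempt in seq_len(max_attempts)) {
    if (nrow(tasks) == 0L) break
    n <- nrow(tasks)
    cand <- data.table::data.table(
      chrom = rep(NA_character_, n), mid = rep(NA_integer_, n),
      host = rep(NA_character_, n))
    is_up <- tasks$context == "upstream"
    if (any(is_up)) {
      gi <- sample.int(nrow(up), sum(is_up), replace = TRUE)
      d <- as.integer(round(tasks$rel_dist[is_up] * up$norm_length[gi]))
      m <- ifelse(up$strand[gi] == "+", up$tss[gi] - d, up$tss[gi] + d)
      cand$chrom[is_up] <- up$chrom[gi]
      cand$mid[is_up] <- as.integer(m)
      cand$host[is_up] <- up$gene_id[gi]
    }
    for (ctx in c("exon", "intron")) {
      sel <- tasks$context == ctx
      if (!any(sel)) next
      pool <- if (ctx == "exon") ex else intr
      if (nrow(pool) == 0L) next
      pi <- sample.int(nrow(pool), sum(sel), replace = TRUE)
      d <- as.integer(round(tasks$rel_dist[sel] * pool$len[pi]))
      side <- sample(c(TRUE, FALSE), sum(sel), replace = TRUE)
      m <- ifelse(side, pool$s[pi] + d, pool$e[pi] - 1L - d)
      cand$chrom[sel] <- pool$chrom[pi]
      cand$mid[sel] <- as.integer(m)
      cand$host[sel] <- pool$gene_id[pi]
    }
    cand[, `:=`(start = mid - tasks$len %/% 2L)]
    cand[, end := start + tasks$len]
    ok <- !is.na(cand$mid) & cand$start >= 0L
    if (!is.null(chrom_len)) {
      ok <- ok & !is.na(chrom_len[cand$chrom]) &
        cand$end <= chrom_len[cand$chrom]
    }
    if (any(ok)) {
      cgr <- GenomicRanges::GRanges(
        factor(cand$chrom[ok], levels = lv),
        IRanges::IRanges(cand$start[ok] + 1L, cand$end[ok]))
      ok[ok] <- GenomicRanges::countOverlaps(cgr, avoid_gr) == 0L
    }
    if (any(ok) && !is.null(methylome)) {
      sgr <- .sites_granges(methylome, lv)
      cgr <- GenomicRanges::GRanges(
        factor(cand$chrom[ok], levels = lv),
        IRanges::IRanges(cand$start[ok] + 1L, cand$end[ok]))
      ok[ok] <- GenomicRanges::countOverlaps(cgr, sgr) > 0L
    }
    # faithfulness check: recompute the relative coordinate of survivors
    if (any(ok)) {
      idx <- which(ok)
      probe <- region_set(cand$chrom[idx], cand$start[idx], cand$end[idx],
                          label = "background",
                          region_class = tasks$region_class[idx],
                          region_id = paste0("cand_", idx),
                          target_gene = cand$host[idx])
      tg <- suppressMessages(assign_target_gene(probe, genes))
      good <- !is.na(tg) & tg == cand$host[idx]
      if (any(good)) {
        rp <- relative_position(probe[good], genes)
        rp <- rp[match(probe$region_id[good], rp$region_id)]
        good[good] <- rp$context == tasks$context[idx[good]] &
          abs(rp$rel_dist - tasks$rel_dist[idx[good]]) <= tol
      }
      ok[idx] <- good
    }
    if (any(ok)) {
      accepted[[attempt]] <- data.table::data.table(
        chrom = cand$chrom[ok], start = cand$start[ok], end = cand$end[ok],
        source_id = tasks$source_id[ok], replicate = tasks$replicate[ok],
        region_class = tasks$region_class[ok], target_gene = cand$host[ok])
    }
    tasks <- tasks[!ok]
  }
  if (nrow(tasks) > 0L) {
    warning(nrow(tasks), " background placement(s) skipped after ",
            max_attempts, " attempts (",
            length(unique(tasks$source_id)), " source region(s) affected)")
  }
  acc <- data.table::rbindlist(accepted)
  if (nrow(acc) == 0L) stop("no background region could be placed")
  data.table::setorder(acc, source_id, replicate)
  region_set(acc$chrom, acc$start, acc$end, label = "background",
             region_class = acc$region_class,
             region_id = paste0(acc$source_id, ":", acc$replicate),
             source_id = acc$source_id, replicate = acc$replicate,
             target_gene = acc$target_gene)
}
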