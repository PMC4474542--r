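## Per-region methylation features and the global autocorrelation /
## expression-correlation analyses.

#' Mean methylation level of each region
#'
#' Unweighted mean of the levels of the covered mCpG sites falling in
#' `[start, end)`. Regions without any site get `NA` (they are dropped,
#' with a message, by [build_feature_table()]).
#'
#' @param regions a `region_set`.
#' @param methylome a `methylome`.
#' @return numeric vector aligned with `regions`.
#' @export
mean_methylation <- function(regions, methylome) {
  st <- .sites_in_regions(regions, methylome)
  agg <- st[, .(mm = mean(level)), by = "region_id"]
  res <- agg$mm[match(regions$region_id, agg$region_id)]
  n_miss <- sum(is.na(res))
  if (n_miss > 0L) {
    message(n_miss, " region(s) without covered mCpG sites (NA)")
  }
  res
}

# sequence of each region; errors if a region exceeds its chromosome
.region_seqs <- function(regions, genome) {
  unknown <- setdiff(unique(regions$chrom), names(genome))
  if (length(unknown)) {
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "))
  }
  w <- Biostrings::width(genome)[match(regions$chrom, names(genome))]
  bad <- which(regions$end > w | regions$start < 0L)
  if (length(bad)) {
    stop("region beyond chromosome end: ", regions$region_id[bad[1L]])
  }
  out <- vector("list", nrow(regions))
  for (ch in unique(regions$chrom)) {
    ix <- which(regions$chrom == ch)
    out[ix] <- as.list(Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(regions$start[ix] + 1L, regions$end[ix])))
  }
  do.call(c, lapply(out, Biostrings::DNAStringSet))
}

#' CpG density of each region
#'
#' Number of `CG` dinucleotides in the region sequence divided by the
#' region length in bp. `CG` cannot overlap itself, so a plain substring
#' count is exact.
#'
#' @param regions a `region_set`.
#' @param genome named `DNAStringSet`.
#' @return numeric vector in `[0, 0.5]` aligned with `regions`.
#' @export
cpg_density <- function(regions, genome) {
  seqs <- .region_seqs(regions, genome)
  Biostrings::vcountPattern("CG", seqs) / (regions$end - regions$start)
}

#' CG (G+C) content of each region
#'
#' Fraction of bases that are C or G.
#' @inheritParams cpg_density
#' @return numeric vector in `[0, 1]`.
#' @export
cg_content <- function(regions, genome) {
  seqs <- .region_seqs(regions, genome)
  as.numeric(Biostrings::letterFrequency(seqs, "CG")) /
    (regions$end - regions$start)
}

#' Cross-cell-line methylation variance of each region
#'
#' For every site observed (after coverage filtering) in at least two of
#' the supplied methylomes, the population variance (divisor n) of its
#' levels across cell lines is computed; the region value is the mean of
#' these per-site variances. Sites seen in a single cell line are
#' excluded, not zero-filled. Regions without any qualifying site get
#' `NA`.
#'
#' @param regions a `region_set`.
#' @param methylomes list of `methylome` objects (>= 2).
#' @return numeric vector aligned with `regions`.
#' @export
methylation_variance <- function(regions, methylomes) {
  if (length(methylomes) < 2L) stop("need >= 2 methylomes")
  st <- data.table::rbindlist(lapply(methylomes, function(m) {
    .sites_in_regions(regions, m)
  }))
  if (nrow(st) == 0L) return(rep(NA_real_, nrow(regions)))
  sv <- st[, .(n_cells = .N, v = mean((level - mean(level))^2)),
           by = .(region_id, pos)]
  agg <- sv[n_cells >= 2L, .(mv = mean(v)), by = "region_id"]
  agg$mv[match(regions$region_id, agg$region_id)]
}

#' Methylation autocorrelation as a function of genomic distance
#'
#' For all within-region pairs of mCpG sites, the autocorrelation at
#' distance bin `k` is the sum of `(x_i - xbar)(x_j - xbar)` over pairs
#' whose genomic distance falls in the bin, divided by the total sum of
#' squares `sum((x_i - xbar)^2)` over all sites, where `xbar` is the
#' grand mean level over all sites of all supplied regions. Pair
#' distances are binned by `bin_width`: bin label `L > 0` covers
#' distances `(L - bin_width, L]`, and bin 0 holds the self-pairs, so the
#' lag-0 value is exactly 1. Bins with fewer than `min_pairs` pairs are
#' suppressed.
#'
#' @param regions a `region_set`.
#' @param methylome a `methylome`.
#' @param max_lag largest pair distance considered, bp (default 2000).
#' @param bin_width distance bin width, bp (default 10).
#' @param min_pairs minimum pairs per reported bin (default 30).
#' @return an `autocorr_profile`: `data.table(lag, r, n_pairs)` with
#'   attributes `max_lag`, `bin_width`, `min_pairs`, `n_sites`,
#'   `grand_mean`.
#' @export
autocorrelation_profile <- function(regions, methylome, max_lag = 2000,
                                    bin_width = 10, min_pairs = 30) {
  stopifnot(nrow(regions) > 0L)
  st <- .sites_in_regions(regions, methylome)
  if (nrow(st) == 0L) stop("no covered sites in the supplied regions")
  xbar <- mean(st$level)
  denom <- sum((st$level - xbar)^2)
  if (denom == 0) {
    stop("degenerate methylation profile: all site levels are identical")
  }
  acc <- st[, {
    n <- .N
    if (n >= 2L) {
      x <- level - xbar
      i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
      j <- sequence(rev(seq_len(n - 1L))) + i
      dd <- pos[j] - pos[i]
      keep <- dd <= max_lag
      list(bin = as.integer(ceiling(dd[keep] / bin_width) * bin_width),
           pr = x[i[keep]] * x[j[keep]])
    } else list(bin = integer(), pr = numeric())
  }, by = "region_id"]
  sums <- acc[, .(num = sum(pr), n_pairs = .N), by = "bin"]
  sums <- data.table::rbindlist(list(
    data.table::data.table(bin = 0L, num = denom, n_pairs = nrow(st)),
    sums))
  prof <- sums[n_pairs >= min_pairs & bin <= max_lag,
               .(lag = bin, r = num / denom, n_pairs)]
  data.table::setorder(prof, lag)
  data.table::setattr(prof, "class",
                      c("autocorr_profile", "data.table", "data.frame"))
  data.table::setattr(prof, "max_lag", max_lag)
  data.table::setattr(prof, "bin_width", bin_width)
  data.table::setattr(prof, "min_pairs", min_pairs)
  data.table::setattr(prof, "n_sites", nrow(st))
  data.table::setattr(prof, "grand_mean", xbar)
  prof[]
}

#' Distance at which the autocorrelation disappears
#'
#' Smallest reported positive lag at which the profile value drops to
#' `threshold` or below. When the profile never reaches the threshold the
#' profile's `max_lag` is returned with attribute `censored = TRUE`.
#'
#' @param profile an `autocorr_profile`.
#' @param threshold autocorrelation value regarded as vanished
#'   (default 0.05).
#' @return distance in bp, with attribute `censored`.
#' @export
autocorrelation_extent <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "autocorr_profile"))
  if (nrow(profile) == 0L) stop("empty autocorrelation profile")
  pos <- profile[lag > 0L]
  hit <- which(pos$r <= threshold)
  if (length(hit)) {
    structure(as.numeric(pos$lag[hit[1L]]), censored = FALSE)
  } else {
    structure(as.numeric(attr(profile, "max_lag")), censored = TRUE)
  }
}

#' Per-region methylation autocorrelation feature
#'
#' Region-level reduction of the autocorrelation estimator: the mean
#' over all within-region site pairs (distance at most `max_lag`) of
#' `(x_i - xbar_r)(x_j - xbar_r) / s2_r`, where `xbar_r` and `s2_r` are
#' the mean and population variance of the region's own sites. The
#' estimator centers on the mean of the regions being profiled, so its
#' single-region reduction centers on that region: the feature then
#' measures how coherently neighbouring mCpG levels fluctuate together,
#' independent of the region's overall methylation offset (which the
#' mean-methylation feature already carries). Regions with fewer than
#' two qualifying pairs, or with zero level variance, are imputed 0 and
#' flagged.
#'
#' @param regions a `region_set`.
#' @param methylome a `methylome`.
#' @param max_lag largest pair distance considered, bp (default 2000).
#' @return `data.table(region_id, autocorr, n_pairs, imputed)` aligned
#'   with `regions`.
#' @export
region_autocorrelation <- function(regions, methylome, max_lag = 2000) {
  st <- .sites_in_regions(regions, methylome)
  out <- data.table::data.table(region_id = regions$region_id,
                                autocorr = 0, n_pairs = 0L, imputed = TRUE)
  if (nrow(st) == 0L) return(out[])
  agg <- st[, {
    n <- .N
    s2 <- mean((level - mean(level))^2)
    if (n >= 2L && s2 > 0) {
      x <- level - mean(level)
      i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
      j <- sequence(rev(seq_len(n - 1L))) + i
      keep <- (pos[j] - pos[i]) <= max_lag
      list(val = if (sum(keep) > 0L) mean(x[i[keep]] * x[j[keep]]) / s2
           else NA_real_,
           np = sum(keep))
    } else list(val = NA_real_, np = 0L)
  }, by = "region_id"]
  ix <- match(agg$region_id, out$region_id)
  out$n_pairs[ix] <- agg$np
  good <- agg$np >= 2L & !is.na(agg$val)
  out$autocorr[ix[good]] <- agg$val[good]
  out$imputed[ix[good]] <- FALSE
  out[]
}

#' Correlation between region methylation and target-gene expression
#'
#' For each region with an assigned target gene, the mean methylation
#' level of the region is computed in every cell line where it has at
#' least one covered site and correlated with the target gene's RPKM
#' across cell lines. Cell lines are matched by name between the
#' methylomes and the expression matrix columns. Regions with fewer than
#' 3 complete (methylation, expression) pairs, or with constant values in
#' either variable, get `NA`.
#'
#' @param regions a `region_set` with `target_gene` set.
#' @param methylomes list of `methylome` objects (>= 3 cell lines).
#' @param expr expression matrix from [read_expression()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return numeric vector of correlations aligned with `regions`.
#' @export
expression_correlation <- function(regions, methylomes, expr,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(methylomes) < 3L) stop("need >= 3 methylomes")
  cells <- vapply(methylomes, function(m) attr(m, "cell_line"), "")
  if (anyDuplicated(cells)) stop("duplicate cell-line names in methylomes")
  meth <- matrix(NA_real_, nrow(regions), length(cells),
                 dimnames = list(regions$region_id, cells))
  for (k in seq_along(methylomes)) {
    meth[, k] <- mean_methylation(regions, methylomes[[k]])
  }
  common <- intersect(cells, colnames(expr))
  if (length(common) < 3L) {
    stop("fewer than 3 cell lines shared between methylomes and expression")
  }
  res <- rep(NA_real_, nrow(regions))
  n_degenerate <- 0L
  for (i in seq_len(nrow(regions))) {
    g <- regions$target_gene[i]
    if (is.na(g) || !(g %in% rownames(expr))) next
    x <- meth[i, common]
    y <- expr[g, common]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3L) next
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    res[i] <- stats::cor(x[keep], y[keep], method = method)
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate,
            " region(s) with constant methylation or expression (NA)")
  }
  res
}

#' Assemble the five-feature table for a region set
#'
#' Computes, for every region, the five classifier features: mean
#' methylation (in the reference cell line), cross-cell-line methylation
#' variance, per-region methylation autocorrelation, CpG density, and
#' (when a motif table is supplied) the centered-CpG 8-mer motif score.
#' Regions without any covered mCpG in the reference methylome are
#' dropped with a message; degenerate variance/autocorrelation/motif
#' values are imputed 0 and flagged.
#'
#' @param regions a `region_set` (typically positives plus matched
#'   backgrounds).
#' @param methylomes list of `methylome` objects.
#' @param genome named `DNAStringSet`.
#' @param motif_table optional `motif_table` ([classify_motifs()]); when
#'   `NULL` the `motif_score` column is `NA` (the cross-validation path
#'   rebuilds it per training fold).
#' @param reference index or cell-line name of the reference methylome
#'   used for mean methylation, autocorrelation, and motif anchoring
#'   (default the first).
#' @param max_lag pair-distance cap for the autocorrelation feature, bp.
#' @return a `feature_table` `data.table`; attribute `n_dropped` counts
#'   regions removed for lack of sites.
#' @export
build_feature_table <- function(regions, methylomes, genome,
                                motif_table = NULL, reference = 1L,
                                max_lag = 2000) {
  stopifnot(inherits(regions, "region_set"))
  if (inherits(methylomes, "methylome")) methylomes <- list(methylomes)
  if (is.character(reference)) {
    reference <- match(reference,
                       vapply(methylomes, attr, "", which = "cell_line"))
  }
  ref <- methylomes[[reference]]
  mm <- suppressMessages(mean_methylation(regions, ref))
  drop <- is.na(mm)
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " region(s) without covered mCpG sites")
    regions <- regions[!drop]
    mm <- mm[!drop]
  }
  if (nrow(regions) == 0L) stop("no region with covered mCpG sites")
  st <- .sites_in_regions(regions, ref)
  ns <- st[, .N, by = "region_id"]
  n_sites <- ns$N[match(regions$region_id, ns$region_id)]
  if (length(methylomes) >= 2L) {
    mv <- methylation_variance(regions, methylomes)
  } else {
    mv <- rep(NA_real_, nrow(regions))
  }
  variance_imputed <- is.na(mv)
  mv[variance_imputed] <- 0
  ac <- region_autocorrelation(regions, ref, max_lag = max_lag)
  dens <- cpg_density(regions, genome)
  if (!is.null(motif_table)) {
    ms <- motif_score_feature(regions, genome, ref, motif_table)
    motif_score <- ms$motif_score
    motif_imputed <- ms$imputed
  } else {
    motif_score <- rep(NA_real_, nrow(regions))
    motif_imputed <- rep(NA, nrow(regions))
  }
  ft <- data.table::data.table(
    region_id = regions$region_id, chrom = regions$chrom,
    start = regions$start, end = regions$end,
    region_class = regions$region_class, label = regions$label,
    n_sites = n_sites,
    mean_meth = mm, meth_variance = mv, autocorr = ac$autocorr,
    cpg_density = dens, motif_score = motif_score,
    autocorr_imputed = ac$imputed, variance_imputed = variance_imputed,
    motif_imputed = motif_imputed)
  data.table::setattr(ft, "class",
                      c("feature_table", "data.table", "data.frame"))
  data.table::setattr(ft, "n_dropped", n_dropped)
  ft[]
}
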