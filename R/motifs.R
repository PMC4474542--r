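## Centered-CpG k-mer motif enrichment.
##
## Motifs are k-mers (k = 8 by default) carrying the CG dinucleotide at
## the two central positions. A k-mer and its reverse complement are the
## same double-stranded word, so every k-mer is reduced to a canonical
## form before counting. Enrichment of each motif around the mCpGs of
## positive regions, relative to its occurrence probability in matched
## background regions, is tested with a binomial upper tail and
## Bonferroni-corrected over the enumerated motif universe.

.validate_kmers <- function(kmers, k = NULL) {
  if (!length(kmers)) stop("empty k-mer input")
  n <- unique(nchar(kmers))
  if (length(n) != 1L) stop("k-mers of differing lengths")
  if (!is.null(k) && n != k) stop("expected ", k, "-mers")
  if (n < 2L || n %% 2L != 0L) stop("k must be even and >= 2")
  if (any(grepl("[^ACGT]", kmers))) {
    stop("k-mers must use the ACGT alphabet: ",
         kmers[grepl("[^ACGT]", kmers)][1L])
  }
  ctr <- substr(kmers, n / 2L, n / 2L + 1L)
  if (any(ctr != "CG")) {
    stop("k-mer without central CG: ", kmers[ctr != "CG"][1L])
  }
  as.integer(n)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of centered-CpG k-mers
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement. The reverse complement of a centered-CG k-mer is
#' itself centered-CG, so canonicalization stays within the motif
#' universe.
#'
#' @param kmers character vector of even-length ACGT k-mers with CG at
#'   the two central positions.
#' @return character vector of canonical k-mers.
#' @export
canonicalize <- function(kmers) {
  .validate_kmers(kmers)
  rc <- .revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Enumerate all canonical centered-CpG k-mers
#'
#' There are `4^(k-2)` raw k-mers with CG fixed at the center; collapsing
#' reverse complements leaves `(4^(k-2) + 4^((k-2)/2)) / 2` canonical
#' motifs (2080 for k = 8).
#'
#' @param k even motif length >= 2 (default 8).
#' @return sorted character vector of canonical motifs.
#' @export
canonical_kmers <- function(k = 8) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k %% 2L != 0L) stop("k must be even and >= 2")
  if (k == 2L) return("CG")
  b <- c("A", "C", "G", "T")
  m <- k - 2L
  idx <- 0:(4^m - 1)
  flanks <- vapply(seq_len(m), function(j) b[(idx %/% 4^(m - j)) %% 4 + 1],
                   character(length(idx)))
  half <- m %/% 2L
  left <- do.call(paste0, as.data.frame(flanks[, seq_len(half), drop = FALSE]))
  right <- do.call(paste0,
                   as.data.frame(flanks[, half + seq_len(half), drop = FALSE]))
  sort(unique(canonicalize(paste0(left, "CG", right))))
}

# windows of width k centered on each covered mCpG of each region:
# data.table(region_id, pos, motif). Windows may extend past the region
# boundary (motifs *surround* the mCpG) but not past the chromosome;
# windows with non-ACGT bases or without a central CG are skipped.
.mcpg_windows <- function(regions, genome, methylome, k = 8L) {
  st <- .sites_in_regions(regions, methylome)
  if (nrow(st) == 0L) {
    return(data.table::data.table(region_id = character(), pos = integer(),
                                  motif = character()))
  }
  half <- k %/% 2L
  st[, `:=`(ws = pos - (half - 1L), we = pos - (half - 1L) + k)]
  w <- Biostrings::width(genome)[match(st$chrom, names(genome))]
  st <- st[!is.na(w) & st$ws >= 0L & st$we <= w]
  if (nrow(st) == 0L) {
    return(data.table::data.table(region_id = character(), pos = integer(),
                                  motif = character()))
  }
  seqs <- character(nrow(st))
  for (ch in unique(st$chrom)) {
    ix <- which(st$chrom == ch)
    seqs[ix] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(st$ws[ix] + 1L, st$we[ix])))
  }
  valid <- !grepl("[^ACGT]", seqs) &
    substr(seqs, half, half + 1L) == "CG"
  n_skip <- sum(!valid)
  if (n_skip > 0L) {
    message(n_skip, " mCpG window(s) skipped (ambiguous bases or ",
            "mismatched reference)")
  }
  out <- data.table::data.table(region_id = st$region_id[valid],
                                pos = st$pos[valid],
                                motif = canonicalize(seqs[valid]))
  out[]
}

#' Count canonical motif occurrences around the mCpGs of a region set
#'
#' At each covered mCpG a window of width `k` is extracted with the CpG
#' at the central positions and reduced to canonical form.
#'
#' @param regions a `region_set`.
#' @param genome named `DNAStringSet`.
#' @param methylome a `methylome`; its covered sites anchor the windows.
#' @param k motif length (default 8).
#' @return named integer vector over all canonical k-mers (zeros
#'   included) with attribute `n_total`, the number of counted windows.
#' @export
count_motifs <- function(regions, genome, methylome, k = 8) {
  w <- .mcpg_windows(regions, genome, methylome, k = as.integer(k))
  if (nrow(w) == 0L) stop("no mCpG-anchored windows in the supplied regions")
  universe <- canonical_kmers(k)
  cnt <- table(factor(w$motif, levels = universe))
  out <- stats::setNames(as.integer(cnt), universe)
  attr(out, "n_total") <- nrow(w)
  out
}

#' Binomial enrichment p-value (upper tail)
#'
#' Probability of observing strictly more than `k_obs` successes in
#' `n_total` draws with success probability `p_bg`:
#' `P(X > k_obs) = 1 - sum_{i=0}^{k} C(n,i) p^i (1-p)^(n-i)`. Evaluated
#' through the binomial survival function, which is numerically stable up
#' to very large `n`. Note the inequality is strict: the observed count
#' itself is not included in the tail.
#'
#' @param k_obs observed count(s).
#' @param n_total number of draws.
#' @param p_bg background success probability.
#' @return p-value(s); vectorized over the arguments.
#' @export
motif_pvalue <- function(k_obs, n_total, p_bg) {
  if (any(k_obs < 0 | k_obs > n_total)) {
    stop("k_obs must be within [0, n_total]")
  }
  if (any(p_bg < 0 | p_bg > 1)) stop("p_bg must be within [0, 1]")
  stats::pbinom(k_obs, n_total, p_bg, lower.tail = FALSE)
}

# mirrored lower tail: P(X <= k_obs). The inclusive tail is used (not
# the strict P(X < k)): a strict lower tail is identically zero at
# k = 0, which would flag every motif absent from the foreground as
# significantly depleted regardless of its expected count.
.motif_pvalue_under <- function(k_obs, n_total, p_bg) {
  stats::pbinom(k_obs, n_total, p_bg, lower.tail = TRUE)
}

#' Test all motifs for over- and under-representation
#'
#' Per-motif background probability is its frequency among the background
#' windows; over-representation uses the strict upper binomial tail
#' ([motif_pvalue()]), under-representation the inclusive lower tail
#' `P(X <= k)`, and both are Bonferroni-corrected over the enumerated canonical motif
#' universe (`n_tests` = 2080 for 8-mers), not over the observed motifs.
#' Motifs absent from the background pool are assigned the pseudo
#' probability `0.5 / bg_total` so that a zero background frequency never
#' produces a degenerate test.
#'
#' @param fg_counts named counts from [count_motifs()] on the positive
#'   regions (attribute `n_total` required).
#' @param bg_counts named counts from [count_motifs()] on the background
#'   regions.
#' @param alpha significance threshold (default 1e-5), applied to the
#'   Bonferroni-corrected p-value unless `correct = FALSE`.
#' @param n_tests number of tests for the Bonferroni correction; defaults
#'   to the size of the canonical motif universe.
#' @param correct apply the threshold to corrected (`TRUE`, default) or
#'   raw p-values.
#' @return a `motif_table`: `data.table(motif, count_fg, count_bg, p_bg,
#'   pvalue_raw, pvalue_bonferroni, pvalue_under,
#'   pvalue_under_bonferroni, status)` with status in
#'   `{over, under, ns}`; attributes `n_fg_total`, `n_bg_total`,
#'   `alpha`, `n_tests`.
#' @export
classify_motifs <- function(fg_counts, bg_counts, alpha = 1e-5,
                            n_tests = NULL, correct = TRUE) {
  motifs <- union(names(fg_counts), names(bg_counts))
  if (is.null(motifs)) stop("counts must be named by motif")
  if (is.null(n_tests)) n_tests <- length(motifs)
  n_fg <- attr(fg_counts, "n_total")
  n_bg <- attr(bg_counts, "n_total")
  if (is.null(n_fg)) n_fg <- sum(fg_counts)
  if (is.null(n_bg)) n_bg <- sum(bg_counts)
  if (n_bg == 0) stop("empty background window pool")
  fg <- ifelse(is.na(fg_counts[motifs]), 0L, fg_counts[motifs])
  bg <- ifelse(is.na(bg_counts[motifs]), 0L, bg_counts[motifs])
  p_bg <- bg / n_bg
  p_bg[bg == 0L] <- 0.5 / n_bg
  p_over <- motif_pvalue(fg, n_fg, p_bg)
  p_under <- .motif_pvalue_under(fg, n_fg, p_bg)
  tab <- data.table::data.table(
    motif = motifs, count_fg = as.integer(fg), count_bg = as.integer(bg),
    p_bg = p_bg,
    pvalue_raw = p_over,
    pvalue_bonferroni = pmin(1, p_over * n_tests),
    pvalue_under = p_under,
    pvalue_under_bonferroni = pmin(1, p_under * n_tests))
  po <- if (correct) tab$pvalue_bonferroni else tab$pvalue_raw
  pu <- if (correct) tab$pvalue_under_bonferroni else tab$pvalue_under
  tab[, status := "ns"]
  tab$status[po < alpha] <- "over"
  tab$status[pu < alpha] <- "under"
  data.table::setorder(tab, pvalue_raw)
  data.table::setattr(tab, "class",
                      c("motif_table", "data.table", "data.frame"))
  data.table::setattr(tab, "n_fg_total", n_fg)
  data.table::setattr(tab, "n_bg_total", n_bg)
  data.table::setattr(tab, "alpha", alpha)
  data.table::setattr(tab, "n_tests", n_tests)
  tab[]
}

#' Nucleotide composition summary of a motif list
#'
#' Mean GC content of the motifs, the fraction with a C or G immediately
#' flanking the central CpG on either side, and the fraction with C or G
#' on both sides simultaneously.
#'
#' @param motifs character vector of centered-CpG k-mers.
#' @return list with `gc_content`, `either_neighbor_cg`,
#'   `both_neighbors_cg`, `n`.
#' @export
motif_composition_summary <- function(motifs) {
  k <- .validate_kmers(motifs)
  gc <- vapply(strsplit(motifs, ""), function(ch) {
    mean(ch %in% c("C", "G"))
  }, 0)
  left <- substr(motifs, k / 2L - 1L, k / 2L - 1L)
  right <- substr(motifs, k / 2L + 2L, k / 2L + 2L)
  l_cg <- left %in% c("C", "G")
  r_cg <- right %in% c("C", "G")
  list(gc_content = mean(gc),
       either_neighbor_cg = mean(l_cg | r_cg),
       both_neighbors_cg = mean(l_cg & r_cg),
       n = length(motifs))
}

#' Motif significance score of each region
#'
#' Mean over the region's mCpG-anchored windows of `-log10` of the
#' window motif's raw over-representation p-value (from `motif_table`),
#' with p-values floored at 1e-300. Motifs absent from the table score 0;
#' regions without windows are imputed 0 and flagged.
#'
#' @param regions a `region_set`.
#' @param genome named `DNAStringSet`.
#' @param methylome a `methylome` anchoring the windows.
#' @param motif_table a `motif_table` from [classify_motifs()]. To avoid
#'   circularity in cross-validation, supply a table built on training
#'   regions only.
#' @return `data.table(region_id, motif_score, n_windows, imputed)`
#'   aligned with `regions`.
#' @export
motif_score_feature <- function(regions, genome, methylome, motif_table) {
  stopifnot(inherits(motif_table, "motif_table"))
  k <- unique(nchar(motif_table$motif))[1L]
  w <- .mcpg_windows(regions, genome, methylome, k = as.integer(k))
  .score_windows(w, regions$region_id, motif_table)
}

# shared scorer: windows -> per-region mean -log10 p
.score_windows <- function(w, region_ids, motif_table) {
  out <- data.table::data.table(region_id = region_ids, motif_score = 0,
                                n_windows = 0L, imputed = TRUE)
  if (nrow(w) == 0L) return(out[])
  p <- motif_table$pvalue_raw[match(w$motif, motif_table$motif)]
  p[is.na(p)] <- 1
  w2 <- data.table::data.table(region_id = w$region_id,
                               score = -log10(pmax(p, 1e-300)))
  agg <- w2[, .(ms = mean(score), nw = .N), by = "region_id"]
  ix <- match(agg$region_id, out$region_id)
  out$motif_score[ix] <- agg$ms
  out$n_windows[ix] <- agg$nw
  out$imputed[ix] <- FALSE
  out[]
}
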