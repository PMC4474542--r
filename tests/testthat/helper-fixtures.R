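## Shared fixtures: tiny hand-built objects plus cached synthetic
## datasets (generated once per session; every dataset is a pure
## function of its seed).

make_methylome <- function(chrom, pos, level, depth = 10L,
                           cell_line = "cell", min_coverage = 5L) {
  methylome(data.frame(chrom = chrom, pos = as.integer(pos),
                       meth_count = as.integer(round(level * depth)),
                       total_count = depth),
            cell_line = cell_line, min_coverage = min_coverage)
}

tiny_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# three-gene annotation on one chromosome used by the background tests:
#   gA: + strand, body 20000-26000, exons 400/400/1000 bp
#   gB: - strand, body 40000-45000 (upstream window on the right)
#   gC: + strand, body 60000-66000
#   gD: + strand, body 80000-85000 (coding length 5000)
tiny_genes <- function() {
  gene_annotation(data.table::data.table(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = "chrT",
    strand = c("+", "-", "+", "+"),
    tx_start = c(20000L, 40000L, 60000L, 80000L),
    tx_end = c(26000L, 45000L, 66000L, 85000L),
    exon_starts = list(c(20000L, 21600L, 25000L),
                       c(40000L, 43000L),
                       c(60000L, 64000L),
                       c(80000L, 84000L)),
    exon_ends = list(c(20400L, 22000L, 26000L),
                     c(41000L, 45000L),
                     c(61000L, 66000L),
                     c(81000L, 85000L))))
}

## session-level cache for generated datasets
.sim_env <- new.env(parent = emptyenv())

sim_cached <- function(key, fn) {
  if (is.null(.sim_env[[key]])) .sim_env[[key]] <- fn()
  .sim_env[[key]]
}

# small promoter-scenario dataset with matched backgrounds
sim_small <- function() {
  sim_cached("small", function() {
    cfg <- generator_config("promoter", n_regions = 60L,
                            n_cell_lines = 5L, seed = 301L)
    sim <- simulate_dataset(cfg)
    sim$background <- suppressWarnings(suppressMessages(
      sample_matched_regions(sim$regions, sim$genes, n_per_region = 5L,
                             seed = 302L, methylome = sim$methylomes[[1L]],
                             genome = sim$genome)))
    sim
  })
}

# promoter preset at the generator's default study conditions
# (200 regions, 15 cell lines), with a matched background pool
sim_promoter200 <- function() {
  sim_cached("promoter200", function() {
    cfg <- generator_config("promoter", seed = 401L)
    sim <- simulate_dataset(cfg)
    sim$background <- suppressWarnings(suppressMessages(
      sample_matched_regions(sim$regions, sim$genes, n_per_region = 20L,
                             seed = 402L, methylome = sim$methylomes[[1L]],
                             genome = sim$genome)))
    sim
  })
}

# one-background-per-positive subsample of a background pool
pick_one_per_source <- function(pool, seed) {
  set.seed(seed)
  ids <- pool[, .(region_id = region_id[sample.int(.N, 1L)]),
              by = "source_id"]$region_id
  out <- pool[pool$region_id %in% ids]
  data.table::setattr(out, "class",
                      c("region_set", "data.table", "data.frame"))
  out
}

# feature table + fold-refit closure for a simulated dataset; mirrors
# the pipeline's classification path
prepare_classification <- function(sim, seed) {
  m <- sim$methylomes[[1L]]
  neg <- pick_one_per_source(sim$background, seed)
  regions <- data.table::rbindlist(list(sim$regions, neg))
  data.table::setattr(regions, "class",
                      c("region_set", "data.table", "data.frame"))
  ft <- suppressMessages(
    build_feature_table(regions, sim$methylomes, sim$genome))
  win <- suppressMessages(methylreg:::.mcpg_windows(ft, sim$genome, m))
  pool_win <- suppressMessages(
    methylreg:::.mcpg_windows(sim$background, sim$genome, m))
  pool_src <- sim$background$source_id[
    match(pool_win$region_id, sim$background$region_id)]
  refit <- function(train_idx) {
    train_pos <- ft$region_id[train_idx][ft$label[train_idx] == "positive"]
    fg_w <- win$motif[win$region_id %in% train_pos]
    bg_w <- pool_win$motif[pool_src %in% train_pos]
    fg <- table(fg_w); bg <- table(bg_w)
    fgc <- stats::setNames(as.integer(fg), names(fg))
    attr(fgc, "n_total") <- length(fg_w)
    bgc <- stats::setNames(as.integer(bg), names(bg))
    attr(bgc, "n_total") <- length(bg_w)
    mt <- classify_motifs(fgc, bgc, n_tests = 2080L)
    methylreg:::.score_windows(win, ft$region_id, mt)$motif_score
  }
  list(ft = ft, refit = refit)
}
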