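## End-to-end orchestration: simulate or load inputs, sample matched
## backgrounds, build the feature table, run the motif analysis, the
## cross-validated SVM and the information-gain ranking, and write all
## result files plus a run manifest.

#' Run the complete prediction pipeline
#'
#' Stages: (1) obtain inputs, either from a simulation preset or from
#' files; (2) sample position-matched background regions
#' (`n_per_region` per positive); (3) subsample one background per
#' positive as the classifier's negative set (the full pool is kept for
#' motif background probabilities); (4) build the exploratory motif
#' table over all data; (5) build the five-feature table; (6)
#' cross-validate the SVM with the motif feature rebuilt inside every
#' training fold, plus the methylation-level-only comparator; (7) rank
#' features by information gain; (8) write results and a manifest.
#'
#' @param config a named list. For simulated runs: `preset`
#'   (`"promoter"`/`"enhancer"`) plus optional [generator_config()]
#'   overrides (e.g. `n_regions`, `n_cell_lines`). For file runs:
#'   `methylomes` (paths, reference first), `genome`, `annotation`,
#'   `positives` (BED), `region_class`, optionally `expression`.
#'   Common options: `seed`, `n_per_region` (default 20), `folds` (10),
#'   `cost` (10), `degree` (2), `alpha` (1e-5), `min_coverage` (5).
#' @param out_dir output directory; created when missing. Written files:
#'   `feature_table.tsv`, `motif_table.tsv`, `feature_ig.tsv`,
#'   `roc.tsv`, `auc.txt`, `background.bed`, `manifest.json`.
#' @return a `run_manifest` list (invisibly): configuration echo,
#'   per-stage record counts, AUCs, and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(seed = 1L, n_per_region = 20L, folds = 10L,
                   cost = 10, degree = 2L, alpha = 1e-5,
                   min_coverage = 5L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  seed <- as.integer(config$seed)

  if (!is.null(config$preset)) {
    gc_fields <- setdiff(names(config),
                         c("preset", "n_per_region", "folds", "cost",
                           "degree", "alpha"))
    gcfg <- do.call(generator_config,
                    c(list(preset = config$preset),
                      config[intersect(gc_fields,
                                       names(generator_config(config$preset)))]))
    sim <- simulate_dataset(gcfg)
    genome <- sim$genome
    genes <- sim$genes
    positives <- sim$regions
    methylomes <- sim$methylomes
  } else {
    for (nm in c("methylomes", "genome", "annotation", "positives",
                 "region_class")) {
      if (is.null(config[[nm]])) {
        stop("pipeline config is missing required field: ", nm)
      }
    }
    genome <- read_genome(config$genome)
    genes <- read_gene_annotation(config$annotation)
    positives <- read_regions(config$positives, label = "positive",
                              region_class = config$region_class,
                              genome = genome)
    methylomes <- lapply(config$methylomes, read_methylome,
                         min_coverage = config$min_coverage)
  }
  ref <- methylomes[[1L]]
  n_pos_in <- nrow(positives)

  pool <- sample_matched_regions(positives, genes,
                                 n_per_region = config$n_per_region,
                                 seed = seed + 1L, methylome = ref,
                                 genome = genome)
  # one background per positive as the training negative set
  set.seed(seed + 2L)
  neg_ids <- pool[, .(region_id = region_id[sample.int(.N, 1L)]),
                  by = "source_id"]$region_id
  negatives <- pool[pool$region_id %in% neg_ids]
  regions <- data.table::rbindlist(list(positives, negatives))
  data.table::setattr(regions, "class",
                      c("region_set", "data.table", "data.frame"))

  # exploratory motif table over all data (reported, not used in CV)
  fg_counts <- count_motifs(positives, genome, ref)
  bg_counts <- count_motifs(pool, genome, ref)
  motif_table <- classify_motifs(fg_counts, bg_counts,
                                 alpha = config$alpha)

  ft <- build_feature_table(regions, methylomes, genome,
                            motif_table = motif_table, reference = 1L)
  n_dropped <- attr(ft, "n_dropped")

  # per-fold motif refit: counts restricted to training-fold rows
  win <- .mcpg_windows(ft, genome, ref)
  pool_win <- .mcpg_windows(pool, genome, ref)
  pool_src <- pool$source_id[match(pool_win$region_id, pool$region_id)]
  refit <- function(train_idx) {
    train_ids <- ft$region_id[train_idx]
    train_pos <- train_ids[ft$label[train_idx] == "positive"]
    fg_w <- win$motif[win$region_id %in% train_pos]
    bg_w <- pool_win$motif[pool_src %in% train_pos]
    fg <- table(fg_w); bg <- table(bg_w)
    fgc <- stats::setNames(as.integer(fg), names(fg))
    attr(fgc, "n_total") <- length(fg_w)
    bgc <- stats::setNames(as.integer(bg), names(bg))
    attr(bgc, "n_total") <- length(bg_w)
    mt <- classify_motifs(fgc, bgc, alpha = config$alpha,
                          n_tests = length(canonical_kmers(8)))
    .score_windows(win, ft$region_id, mt)$motif_score
  }

  cv_all <- cross_validate(ft, folds = config$folds, seed = seed + 3L,
                           kernel_degree = config$degree,
                           cost = config$cost, refit_motif = refit)
  cv_meth <- cross_validate(ft, folds = config$folds, seed = seed + 3L,
                            kernel_degree = config$degree,
                            cost = config$cost,
                            feature_subset = "mean_meth")
  # rank with out-of-fold motif scores: a full-data motif table inflates
  # the motif feature through each window's own contribution to its count
  ft_ig <- data.table::copy(ft)
  ft_ig$motif_score <- cv_all$motif_score_oof
  ig <- rank_features(ft_ig)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    feature_table = file.path(out_dir, "feature_table.tsv"),
    motif_table = file.path(out_dir, "motif_table.tsv"),
    feature_ig = file.path(out_dir, "feature_ig.tsv"),
    roc = file.path(out_dir, "roc.tsv"),
    auc = file.path(out_dir, "auc.txt"),
    background = file.path(out_dir, "background.bed"),
    manifest = file.path(out_dir, "manifest.json"))
  write_feature_table(ft, paths$feature_table)
  data.table::fwrite(motif_table, paths$motif_table, sep = "\t")
  data.table::fwrite(ig, paths$feature_ig, sep = "\t")
  data.table::fwrite(cv_all$roc, paths$roc, sep = "\t")
  writeLines(c(
    sprintf("auc_all_features\t%.6f", cv_all$auc),
    sprintf("auc_all_features_fold_mean\t%.6f", mean(cv_all$fold_auc)),
    sprintf("auc_mean_meth_only\t%.6f", cv_meth$auc)), paths$auc)
  write_regions(pool, paths$background)

  manifest <- list(
    config = config[setdiff(names(config), "preset_obj")],
    seed = seed,
    counts = list(
      positives_in = n_pos_in,
      background_pool = nrow(pool),
      negatives_selected = nrow(negatives),
      regions_featurized_in = nrow(regions),
      regions_dropped_no_sites = n_dropped,
      regions_featurized_out = nrow(ft),
      motifs_tested = nrow(motif_table),
      motifs_over = sum(motif_table$status == "over"),
      motifs_under = sum(motif_table$status == "under")),
    auc = list(all_features = cv_all$auc,
               all_features_fold_mean = mean(cv_all$fold_auc),
               mean_meth_only = cv_meth$auc),
    information_gain = stats::setNames(as.list(ig$info_gain), ig$feature),
    outputs = paths)
  stopifnot(manifest$counts$regions_featurized_out ==
              manifest$counts$regions_featurized_in -
              manifest$counts$regions_dropped_no_sites)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("methylreg pipeline run\n")
  cat("  positives:", x$counts$positives_in,
      "| background pool:", x$counts$background_pool,
      "| featurized:", x$counts$regions_featurized_out, "\n")
  cat(sprintf("  AUC all features: %.4f | mean methylation only: %.4f\n",
              x$auc$all_features, x$auc$mean_meth_only))
  cat("  outputs in:", dirname(x$outputs$auc), "\n")
  invisible(x)
}
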