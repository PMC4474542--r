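## Synthetic data generator.
##
## Emits a genome, gene annotation, regulatory regions with per-cell-line
## activity states, multi-cell-line methylomes, and an expression table
## reproducing the statistical signatures of regulatory methylation:
## regions are hypomethylated through a long-range Gaussian-shaped dip,
## neighbouring mCpG levels are spatially correlated with a longer
## correlation length inside regulatory regions, CpG density is elevated
## in regions, regions switch activity across cell lines with inactive
## copies hypermethylated above background, GC-rich motifs are planted
## around a fraction of regulatory CpGs, and expression of target genes
## is repressively coupled to region methylation.

#' Configuration for the synthetic data generator
#'
#' Two presets encode the promoter-like and enhancer-like scenarios:
#' background methylation 0.72 with a dip to 0.34 for promoters, 0.84
#' with a dip to 0.69 for enhancers; promoter regions sit in the 10 kb
#' upstream windows of their host genes, enhancer regions in introns and
#' exons. All values can be overridden through `...`.
#'
#' @param preset `"promoter"` or `"enhancer"`.
#' @param ... named overrides of any configuration field.
#' @return a `generator_config` list. Fields: `n_chromosomes`, `n_genes`
#'   (defaults to 3x `n_regions` + 20, so that position-matched random
#'   regions mostly fall in regulatory-free genes, as in a real
#'   genome), `n_regions`,
#'   `region_length` (min/max, bp), `background_meth`, `dip_mean`
#'   (target mean level at active region centers), `dip_sd` (per-region
#'   spread), `dip_halfwidth` (Gaussian sigma of the hypomethylation
#'   dip, bp; the dip fades into background around 2 sigma, ~1500 bp),
#'   `corr_length_fg`/`corr_length_bg` (spatial noise correlation
#'   lengths, bp), `noise_sd`, `cpg_density_fg`/`cpg_density_bg`,
#'   `density_jitter_sd` (log-normal per-region density spread),
#'   `n_cell_lines`, `activity_switch_prob` (probability that a region
#'   is active in a non-reference cell line), `inactive_hypermeth_delta`
#'   (methylation added inside inactive regions), `planted_motifs`,
#'   `motif_plant_rate`, `read_depth_lambda` (depth = min_coverage +
#'   Poisson(lambda)), `min_coverage`, `context_probs`,
#'   `expr_intercept`, `expr_slope`, `expr_noise_sd`, `seed`.
#' @export
generator_config <- function(preset = c("promoter", "enhancer"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_chromosomes = 2L,
    n_genes = NULL,
    n_regions = 200L,
    region_length = c(400L, 800L),
    background_meth = 0.72,
    dip_mean = 0.34,
    dip_sd = 0.10,
    dip_halfwidth = 750,
    corr_length_fg = 250,
    corr_length_bg = 40,
    noise_sd = 0.08,
    cpg_density_fg = 0.05,
    cpg_density_bg = 0.01,
    density_jitter_sd = 0.3,
    n_cell_lines = 15L,
    activity_switch_prob = 0.5,
    inactive_hypermeth_delta = 0.08,
    planted_motifs = c("GGCCGGCC", "CCACGTGG", "GGGCGCCC"),
    motif_plant_rate = 0.03,
    read_depth_lambda = 20,
    min_coverage = 5L,
    context_probs = c(upstream = 1, exon = 0, intron = 0),
    region_class = "promoter",
    expr_intercept = 10,
    expr_slope = 8,
    expr_noise_sd = 1.5,
    seed = 1L)
  if (preset == "enhancer") {
    cfg$background_meth <- 0.84
    cfg$dip_mean <- 0.69
    cfg$dip_sd <- 0.12
    cfg$cpg_density_fg <- 0.03
    cfg$context_probs <- c(upstream = 0, exon = 0.25, intron = 0.75)
    cfg$region_class <- "enhancer"
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown generator_config field(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  if (is.null(cfg$n_genes)) {
    cfg$n_genes <- as.integer(cfg$n_regions * 3L + 20L)
  }
  if (cfg$n_genes < cfg$n_regions) stop("n_genes must be >= n_regions")
  if (cfg$cpg_density_fg > 0.5 || cfg$cpg_density_bg > 0.5) {
    stop("infeasible CpG density request (> 0.5)")
  }
  probs <- c(cfg$activity_switch_prob, cfg$motif_plant_rate,
             cfg$context_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$inactive_hypermeth_delta <= 0) {
    stop("inactive_hypermeth_delta must be > 0")
  }
  if (length(cfg$planted_motifs)) .validate_kmers(cfg$planted_motifs)
  class(cfg) <- "generator_config"
  cfg
}

# gene models laid out sequentially with strand-aware gaps so that
# 10 kb upstream windows never overlap a neighbouring gene or window
.make_genes <- function(config) {
  n <- config$n_genes
  strand <- sample(c("+", "-"), n, replace = TRUE)
  per_chrom <- rep_len(seq_len(config$n_chromosomes), n)
  per_chrom <- sort(per_chrom)
  rows <- vector("list", n)
  for (ci in seq_len(config$n_chromosomes)) {
    ix <- which(per_chrom == ci)
    cursor <- 0L
    prev_strand <- "+"
    for (g in ix) {
      n_ex <- sample(3:5, 1L)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(1200:2500, n_ex - 1L, replace = TRUE)
      gap <- as.integer(round(stats::runif(1, 500, 1500))) +
        .UPSTREAM_BP * (strand[g] == "+") +
        .UPSTREAM_BP * (prev_strand == "-")
      tx_start <- cursor + gap
      es <- integer(n_ex); ee <- integer(n_ex)
      p <- tx_start
      for (k in seq_len(n_ex)) {
        es[k] <- p
        ee[k] <- p + ex_len[k]
        p <- ee[k] + if (k < n_ex) in_len[k] else 0L
      }
      rows[[g]] <- data.table::data.table(
        gene_id = sprintf("gene_%04d", g),
        chrom = sprintf("chr%d", ci),
        strand = strand[g], tx_start = tx_start, tx_end = p,
        exon_starts = list(es), exon_ends = list(ee))
      cursor <- p
      prev_strand <- strand[g]
    }
  }
  gene_annotation(data.table::rbindlist(rows))
}

# pick host genes and place one regulatory region per host
.place_regions <- function(config, genes) {
  n <- config$n_regions
  hosts <- sort(sample.int(nrow(genes), n))
  ctx <- sample(names(config$context_probs), n, replace = TRUE,
                prob = config$context_probs)
  L <- 2L * sample(seq(config$region_length[1] %/% 2L,
                       config$region_length[2] %/% 2L), n, replace = TRUE)
  chrom <- genes$chrom[hosts]
  mid <- integer(n)
  for (i in seq_len(n)) {
    g <- hosts[i]
    if (ctx[i] == "upstream") {
      d <- as.integer(round(stats::runif(1, L[i] / 2 + 100, 3000)))
      mid[i] <- if (genes$strand[g] == "+") genes$tss[g] - d
                else genes$tss[g] + d
    } else {
      es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
      if (ctx[i] == "exon") {
        j <- sample.int(length(es), 1L)
        s <- es[j]; e <- ee[j]
      } else {
        j <- sample.int(length(es) - 1L, 1L)
        s <- ee[j]; e <- es[j + 1L]
      }
      rel <- stats::runif(1, 0.08, 0.45)
      d <- as.integer(round(rel * (e - s)))
      mid[i] <- if (stats::runif(1) < 0.5) s + d else e - 1L - d
    }
  }
  region_set(chrom, mid - L %/% 2L, mid - L %/% 2L + L,
             label = "positive", region_class = config$region_class,
             region_id = sprintf("%s_%04d", config$region_class,
                                 seq_len(n)),
             target_gene = genes$gene_id[hosts])
}

# positions are 1-based character indices of the C of each planted CpG
.build_chrom_seq <- function(len, fg, config) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  is_cg <- which(ch[-len] == "C" & ch[-1L] == "G")
  if (length(is_cg)) {
    ch[is_cg + 1L] <- sample(c("A", "T"), length(is_cg), replace = TRUE)
  }
  pick <- function(from, to, n_target) {
    if (to < from || n_target < 1L) return(integer())
    cand <- sort(sample.int(to - from + 1L, min(n_target, to - from + 1L)) +
                   from - 1L)
    cand[c(TRUE, diff(cand) >= 2L)]
  }
  n_bg <- as.integer(round(len * config$cpg_density_bg))
  bg_pos <- pick(2L, len - 2L, n_bg)
  if (nrow(fg)) {
    infg <- rep(FALSE, length(bg_pos))
    for (i in seq_len(nrow(fg))) {
      infg <- infg | (bg_pos > fg$start[i] & bg_pos <= fg$end[i])
    }
    bg_pos <- bg_pos[!infg]
  }
  fg_pos <- integer()
  fg_region <- integer()
  if (nrow(fg)) {
    for (i in seq_len(nrow(fg))) {
      dens <- config$cpg_density_fg *
        exp(stats::rnorm(1, 0, config$density_jitter_sd))
      n_i <- max(2L, as.integer(round((fg$end[i] - fg$start[i]) * dens)))
      p <- pick(fg$start[i] + 1L, fg$end[i] - 1L, n_i)
      fg_pos <- c(fg_pos, p)
      fg_region <- c(fg_region, rep(fg$idx[i], length(p)))
    }
  }
  all_pos <- c(bg_pos, fg_pos)
  ch[all_pos] <- "C"
  ch[all_pos + 1L] <- "G"
  # plant motifs around a fraction of regulatory CpGs
  if (length(fg_pos) && length(config$planted_motifs) &&
      config$motif_plant_rate > 0) {
    take <- stats::runif(length(fg_pos)) < config$motif_plant_rate
    for (i in which(take)) {
      p <- fg_pos[i]
      if (p - 3L < 1L || p + 4L > len) next
      m <- config$planted_motifs[
        sample.int(length(config$planted_motifs), 1L)]
      ch[(p - 3L):(p + 4L)] <- strsplit(m, "")[[1L]]
    }
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic genome, gene annotation, and regulatory regions
#'
#' Genes are laid out sequentially with strand-aware intergenic gaps so
#' upstream windows stay unambiguous; one regulatory region is placed
#' per host gene in the preset's contexts. Sequence is random with all
#' CpGs removed and then re-planted: at the background density genome
#' wide and at the (log-normally jittered) foreground density inside
#' regulatory regions, with GC-rich motifs written around a fraction of
#' regulatory CpGs. Fully deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `genome` (`DNAStringSet`), `genes`
#'   (`gene_annotation`), `regions` (`region_set` of positives),
#'   `activity` (logical regions x cell lines matrix; column 1 is the
#'   reference cell line, always active), `dip_levels` (per-region
#'   target methylation at the dip center), `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(config$seed))
  genes <- .make_genes(config)
  if (config$n_regions > 0L) {
    regions <- .place_regions(config, genes)
  } else {
    regions <- NULL
  }
  chrom_ids <- unique(genes$chrom)
  seqs <- character(length(chrom_ids))
  for (ci in seq_along(chrom_ids)) {
    ch <- chrom_ids[ci]
    len <- max(genes$tx_end[genes$chrom == ch]) + 12000L
    fg <- if (is.null(regions)) {
      data.table::data.table(start = integer(), end = integer(),
                             idx = integer())
    } else {
      ix <- which(regions$chrom == ch)
      data.table::data.table(start = regions$start[ix],
                             end = regions$end[ix], idx = ix)
    }
    seqs[ci] <- .build_chrom_seq(len, fg, config)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrom_ids
  n_reg <- if (is.null(regions)) 0L else nrow(regions)
  activity <- matrix(FALSE, n_reg, config$n_cell_lines)
  dip_levels <- numeric(0)
  if (n_reg > 0L) {
    activity[, 1L] <- TRUE
    if (config$n_cell_lines > 1L) {
      activity[, -1L] <- stats::runif(n_reg * (config$n_cell_lines - 1L)) <
        config$activity_switch_prob
    }
    dip_levels <- pmin(0.98, pmax(0.02, stats::rnorm(
      n_reg, config$dip_mean, config$dip_sd)))
  }
  colnames(activity) <- sprintf("cell_%02d", seq_len(config$n_cell_lines))
  list(genome = genome, genes = genes, regions = regions,
       activity = activity, dip_levels = dip_levels, config = config)
}

# 0-based positions of all CG dinucleotides per chromosome
.scan_cpgs <- function(genome) {
  lapply(stats::setNames(names(genome), names(genome)), function(ch) {
    Biostrings::start(Biostrings::matchPattern("CG", genome[[ch]])) - 1L
  })
}

# distance-decaying autoregressive noise over irregularly spaced sites
.ar_noise <- function(pos, corr_len, sd) {
  n <- length(pos)
  eps <- stats::rnorm(n, 0, sd)
  if (n < 2L) return(eps)
  phi <- exp(-diff(pos) / corr_len[-1L])
  z <- numeric(n)
  z[1L] <- eps[1L]
  w <- sqrt(1 - phi^2)
  for (i in 2:n) z[i] <- phi[i - 1L] * z[i - 1L] + w[i - 1L] * eps[i]
  z
}

#' Generate per-cell-line methylomes for a synthetic genome
#'
#' For every CpG and cell line a latent methylation level is built as
#' background + spatially correlated noise (autoregressive over genomic
#' distance, with the foreground correlation length inside regulatory
#' regions and the background length elsewhere) + a Gaussian-shaped
#' hypomethylation dip centered on each region active in that cell line
#' + a hypermethylation offset inside regions inactive in that cell line
#' (but active in another). Observed counts are binomial draws at a
#' shifted-Poisson read depth, so the coverage filter of the readers is
#' exercised without removing sites.
#'
#' @param config a [generator_config()].
#' @param gen output of [generate_genome()].
#' @return list of `methylome` objects, one per cell line.
#' @export
generate_methylomes <- function(config, gen) {
  set.seed(as.integer(config$seed) + 1L)
  cpgs <- .scan_cpgs(gen$genome)
  n_reg <- if (is.null(gen$regions)) 0L else nrow(gen$regions)
  sigma <- config$dip_halfwidth
  per_chrom <- lapply(names(cpgs), function(ch) {
    pos <- cpgs[[ch]]
    corr <- rep(config$corr_length_bg, length(pos))
    dipw <- vector("list", n_reg)   # list(site index range, weights)
    inreg <- vector("list", n_reg)
    if (n_reg > 0L) {
      ix <- which(gen$regions$chrom == ch)
      for (i in ix) {
        s <- gen$regions$start[i]; e <- gen$regions$end[i]
        corr[pos >= s & pos < e] <- config$corr_length_fg
        ctr <- (s + e) %/% 2L
        zone <- which(pos >= ctr - 3 * sigma & pos < ctr + 3 * sigma)
        if (length(zone)) {
          dipw[[i]] <- list(idx = zone,
                            w = exp(-(pos[zone] - ctr)^2 / (2 * sigma^2)))
        }
        inreg[[i]] <- which(pos >= s & pos < e)
      }
    }
    list(chrom = ch, pos = pos, corr = corr, dipw = dipw, inreg = inreg)
  })
  lapply(seq_len(config$n_cell_lines), function(cell) {
    parts <- lapply(per_chrom, function(pc) {
      n <- length(pc$pos)
      if (n == 0L) return(NULL)
      latent <- config$background_meth +
        .ar_noise(pc$pos, pc$corr, config$noise_sd)
      if (n_reg > 0L) {
        for (i in seq_len(n_reg)) {
          dw <- pc$dipw[[i]]
          if (gen$activity[i, cell]) {
            if (!is.null(dw)) {
              latent[dw$idx] <- latent[dw$idx] +
                (gen$dip_levels[i] - config$background_meth) * dw$w
            }
          } else if (length(pc$inreg[[i]])) {
            latent[pc$inreg[[i]]] <- latent[pc$inreg[[i]]] +
              config$inactive_hypermeth_delta
          }
        }
      }
      latent <- pmin(0.999, pmax(0.001, latent))
      depth <- config$min_coverage +
        stats::rpois(n, config$read_depth_lambda)
      data.table::data.table(chrom = pc$chrom, pos = pc$pos,
                             meth_count = stats::rbinom(n, depth, latent),
                             total_count = depth)
    })
    methylome(data.table::rbindlist(parts),
              cell_line = sprintf("cell_%02d", cell),
              min_coverage = config$min_coverage)
  })
}

#' Generate an expression table coupled to region methylation
#'
#' Target genes of regulatory regions are repressively coupled:
#' `RPKM = max(0, a - b * region mean methylation + noise)` per cell
#' line, so switching regions drive anticorrelated expression. All other
#' genes get expression unrelated to methylation at a comparable scale.
#'
#' @param config a [generator_config()].
#' @param gen output of [generate_genome()].
#' @param methylomes output of [generate_methylomes()].
#' @return numeric matrix gene x cell line (RPKM).
#' @export
generate_expression <- function(config, gen, methylomes) {
  set.seed(as.integer(config$seed) + 2L)
  cells <- vapply(methylomes, attr, "", which = "cell_line")
  genes <- gen$genes$gene_id
  expr <- matrix(NA_real_, length(genes), length(cells),
                 dimnames = list(genes, cells))
  meth <- if (!is.null(gen$regions)) {
    vapply(methylomes, function(m) {
      suppressMessages(mean_methylation(gen$regions, m))
    }, numeric(nrow(gen$regions)))
  } else NULL
  a <- config$expr_intercept; b <- config$expr_slope
  coupled <- if (!is.null(gen$regions)) gen$regions$target_gene else
    character()
  for (j in seq_along(cells)) {
    base <- pmax(0, a - b * config$background_meth +
                   stats::rnorm(length(genes), 0, 2))
    expr[, j] <- base
  }
  if (length(coupled)) {
    for (j in seq_along(cells)) {
      v <- pmax(0, a - b * meth[, j] +
                  stats::rnorm(length(coupled), 0, config$expr_noise_sd))
      v[is.na(meth[, j])] <- NA_real_
      expr[coupled, j] <- v
    }
  }
  expr
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_genome()], [generate_methylomes()] and
#' [generate_expression()], and optionally writes all outputs as plain
#' text (FASTA genome, gene table, truth BED + activity table, one
#' methylome TSV per cell line, expression TSV, and the configuration as
#' JSON). Two runs with the same configuration produce identical files.
#'
#' @param config a [generator_config()].
#' @param out_dir optional output directory.
#' @return list with `genome`, `genes`, `regions`, `activity`,
#'   `dip_levels`, `methylomes`, `expression`, `config` (invisibly when
#'   writing to `out_dir`).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  gen <- generate_genome(config)
  methylomes <- generate_methylomes(config, gen)
  expression <- generate_expression(config, gen, methylomes)
  res <- list(genome = gen$genome, genes = gen$genes,
              regions = gen$regions, activity = gen$activity,
              dip_levels = gen$dip_levels, methylomes = methylomes,
              expression = expression, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(res$genome,
                                file.path(out_dir, "genome.fa"))
    write_gene_annotation(res$genes, file.path(out_dir, "genes.tsv"))
    if (!is.null(res$regions)) {
      write_regions(res$regions, file.path(out_dir, "regions.bed"))
      act <- data.table::data.table(region_id = res$regions$region_id)
      for (cn in colnames(res$activity)) act[[cn]] <- res$activity[, cn]
      data.table::fwrite(act, file.path(out_dir, "activity.tsv"),
                         sep = "\t")
    }
    for (m in methylomes) {
      write_methylome(m, file.path(out_dir,
                                   paste0(attr(m, "cell_line"), ".tsv")))
    }
    write_expression(expression, file.path(out_dir, "expression.tsv"))
    cfg <- res$config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
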