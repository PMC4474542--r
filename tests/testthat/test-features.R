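test_that("mean methylation is the unweighted site mean", {
  m <- make_methylome("c", c(100L, 200L, 500L), c(0.2, 0.4, 0.9))
  rs <- region_set("c", c(50L, 450L, 900L), c(250L, 550L, 950L),
                   region_id = c("two", "one", "none"))
  mm <- suppressMessages(mean_methylation(rs, m))
  expect_equal(mm[1L], 0.3)
  expect_equal(mm[2L], 0.9)
  expect_true(is.na(mm[3L]))
})

test_that("CpG density and CG content count what they claim", {
  g <- tiny_genome(c1 = "ACGT", c2 = "AAAA", c3 = "CGCGCG", c4 = "GGGG",
                   c5 = "ATAT")
  one <- function(chrom, len) region_set(chrom, 0L, len)
  expect_equal(cpg_density(one("c1", 4L), g), 0.25)
  expect_equal(cpg_density(one("c2", 4L), g), 0)
  expect_equal(cpg_density(one("c3", 6L), g), 0.5)
  expect_equal(cg_content(one("c1", 4L), g), 0.5)
  expect_equal(cg_content(one("c4", 4L), g), 1)
  expect_equal(cg_content(one("c5", 4L), g), 0)
  expect_error(cpg_density(region_set("c1", 0L, 10L), g), "beyond")
})

test_that("cross-cell-line variance uses the population convention", {
  # site 10: constant 0.5 in all three cell lines
  # site 50: levels 0, 0.5, 1 across the cell lines
  # site 90: covered in cell lines 1-2 only, equal levels
  ms <- list(
    make_methylome("c", c(10L, 50L, 90L), c(0.5, 0, 0.3),
                   cell_line = "cl1"),
    make_methylome("c", c(10L, 50L, 90L), c(0.5, 0.5, 0.3),
                   cell_line = "cl2"),
    make_methylome("c", c(10L, 50L), c(0.5, 1), cell_line = "cl3"))
  rs <- region_set("c", c(0L, 40L, 80L), c(20L, 60L, 100L),
                   region_id = c("const", "varying", "pair"))
  v <- methylation_variance(rs, ms)
  expect_equal(v[1L], 0)
  expect_equal(v[2L], mean((c(0, 0.5, 1) - 0.5)^2))  # population variance
  expect_equal(v[3L], 0)                              # two equal values
  # a two-cell-line 0/1 site has variance 0.25 (the maximum)
  m2 <- list(make_methylome("c", 5L, 0, cell_line = "a"),
             make_methylome("c", 5L, 1, cell_line = "b"))
  expect_equal(methylation_variance(region_set("c", 0L, 10L), m2), 0.25)
  # sites seen in a single cell line are excluded, not zero-filled
  m3 <- list(make_methylome("c", 5L, 0.4, cell_line = "a"),
             make_methylome("c", 99L, 0.8, cell_line = "b"))
  expect_true(is.na(methylation_variance(
    region_set("c", c(0L, 90L), c(10L, 100L)), m3)[1L]))
})

test_that("autocorrelation profile has unit lag-0 and tracks alternation", {
  # alternating 0.1/0.9 levels at exact 10 bp spacing
  n <- 200L
  m <- make_methylome("c", seq(0L, by = 10L, length.out = n),
                      rep(c(0.1, 0.9), n / 2))
  rs <- region_set("c", 0L, 10L * n)
  pr <- autocorrelation_profile(rs, m, max_lag = 100, bin_width = 10,
                                min_pairs = 10)
  expect_equal(pr[lag == 0L, r], 1)
  expect_lte(pr[lag == 10L, r], -0.8)
  expect_gte(pr[lag == 20L, r], 0.8)
  expect_true(all(abs(pr$r) <= 1 + 1e-6))
})

test_that("autocorrelation of i.i.d. levels vanishes at positive lags", {
  set.seed(21)
  n <- 10000L
  m <- make_methylome("c", sort(sample.int(300000L, n)),
                      round(runif(n), 3), depth = 1000L)
  rs <- region_set("c", 0L, 300000L)
  pr <- autocorrelation_profile(rs, m, max_lag = 2000, bin_width = 10,
                                min_pairs = 30)
  expect_equal(pr[lag == 0L, r], 1)
  expect_true(all(abs(pr[lag > 0L, r]) <= 0.05))
})

test_that("profile matches a naive pairwise oracle and is scale invariant", {
  set.seed(8)
  pos <- sort(sample.int(5000L, 300L))
  lev <- round(runif(300L, 0.1, 0.7), 2)
  m <- make_methylome("c", pos, lev, depth = 1000L)
  rs <- region_set("c", c(0L, 2500L), c(2500L, 5000L))
  pr <- autocorrelation_profile(rs, m, max_lag = 500, bin_width = 10,
                                min_pairs = 1)
  # naive double-loop oracle over within-region pairs
  st <- methylreg:::.sites_in_regions(rs, m)
  xbar <- mean(st$level)
  denom <- sum((st$level - xbar)^2)
  num <- numeric(0); cnt <- numeric(0)
  for (rid in unique(st$region_id)) {
    p <- st$pos[st$region_id == rid]; x <- st$level[st$region_id == rid]
    for (i in seq_along(p)) {
      for (j in seq_along(p)) {
        if (j <= i) next
        d <- p[j] - p[i]
        if (d > 500) next
        b <- as.character(ceiling(d / 10) * 10)
        num[b] <- (if (is.na(num[b])) 0 else num[b]) +
          (x[i] - xbar) * (x[j] - xbar)
        cnt[b] <- (if (is.na(cnt[b])) 0 else cnt[b]) + 1
      }
    }
  }
  for (b in names(num)) {
    expect_equal(pr[lag == as.integer(b), r], unname(num[b] / denom),
                 tolerance = 1e-9)
    expect_equal(pr[lag == as.integer(b), n_pairs], unname(as.integer(cnt[b])))
  }
  # shifting all levels by a constant leaves r unchanged
  m_shift <- make_methylome("c", pos, lev / 2 + 0.2, depth = 1000L)
  pr2 <- autocorrelation_profile(rs, m_shift, max_lag = 500,
                                 bin_width = 10, min_pairs = 1)
  expect_equal(pr2$r, pr$r, tolerance = 1e-9)
  # degenerate constant profile errors
  m_const <- make_methylome("c", pos, rep(0.4, 300L))
  expect_error(autocorrelation_profile(rs, m_const), "degenerate")
})

test_that("autocorrelation extent finds the first threshold crossing", {
  mk_prof <- function(lag, r) {
    pr <- data.table::data.table(lag = lag, r = r,
                                 n_pairs = rep(100L, length(lag)))
    data.table::setattr(pr, "class", c("autocorr_profile", "data.table",
                                       "data.frame"))
    data.table::setattr(pr, "max_lag", max(lag))
    pr
  }
  e <- autocorrelation_extent(mk_prof(c(0L, 10L, 20L), c(1, 0.04, 0.3)))
  expect_equal(as.numeric(e), 10)
  expect_false(attr(e, "censored"))
  e2 <- autocorrelation_extent(mk_prof(c(0L, 10L, 20L), c(1, 0.5, 0.2)))
  expect_equal(as.numeric(e2), 20)
  expect_true(attr(e2, "censored"))
})

test_that("per-region autocorrelation feature carries the right sign", {
  # neighbouring sites fluctuating together (two coherent blocks):
  # adjacent-pair products are positive
  mA <- make_methylome("c", seq(10L, 100L, by = 10L),
                       c(rep(0.2, 5), rep(0.8, 5)))
  rs <- region_set("c", 0L, 150L, region_id = "smooth")
  ac <- region_autocorrelation(rs, mA, max_lag = 10)
  expect_gt(ac$autocorr[1L], 0)
  expect_false(ac$imputed[1L])
  # alternating levels: neighbouring deviations oppose, feature < 0
  mB <- make_methylome("c", c(10L, 20L, 30L, 40L), c(0.9, 0.1, 0.9, 0.1))
  ac2 <- region_autocorrelation(region_set("c", 0L, 50L), mB)
  expect_lt(ac2$autocorr[1L], 0)
  expect_false(ac2$imputed[1L])
  # constant levels carry no fluctuation signal: imputed 0
  mC <- make_methylome("c", c(10L, 20L, 30L), rep(0.6, 3))
  ac3 <- region_autocorrelation(region_set("c", 0L, 50L), mC)
  expect_identical(ac3$autocorr[1L], 0)
  expect_true(ac3$imputed[1L])
})

test_that("regions lacking pairs are imputed 0 with a flag", {
  m <- make_methylome("c", c(10L, 5000L), c(0.2, 0.9))
  rs <- region_set("c", c(0L, 4990L), c(20L, 5010L))
  ac <- region_autocorrelation(rs, m)
  expect_identical(ac$autocorr, c(0, 0))
  expect_true(all(ac$imputed))
})

test_that("region feature agrees with the set-level profile estimator", {
  # regions of evenly spaced sites with a common mean and AR(1)
  # fluctuations: restricted to adjacent pairs, the mean region feature
  # estimates the same quantity as the set-level profile at lag = 10
  set.seed(33)
  n_reg <- 60L; n_site <- 100L
  rows <- lapply(seq_len(n_reg), function(i) {
    z <- as.numeric(stats::arima.sim(list(ar = 0.5), n_site, sd = 0.1))
    data.frame(chrom = sprintf("r%02d", i),
               pos = seq(0L, by = 10L, length.out = n_site),
               level = pmin(0.95, pmax(0.05, 0.5 + z)))
  })
  st <- do.call(rbind, rows)
  m <- make_methylome(st$chrom, st$pos, round(st$level, 3), depth = 1000L)
  rs <- region_set(sprintf("r%02d", seq_len(n_reg)), 0L, 10L * n_site)
  ac <- region_autocorrelation(rs, m, max_lag = 10)
  pr <- autocorrelation_profile(rs, m, max_lag = 10, bin_width = 10,
                                min_pairs = 30)
  expect_lt(abs(mean(ac$autocorr) - pr[lag == 10L, r]), 0.1)
})

test_that("expression correlation recovers exact coupling", {
  ms <- lapply(1:3, function(i) {
    make_methylome("c", 50L, c(0, 0.5, 1)[i], cell_line = paste0("cl", i))
  })
  expr <- matrix(c(10, 5, 0, 0, 5, 10, 3, 3, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gNeg", "gPos", "gFlat"),
                                 c("cl1", "cl2", "cl3")))
  rs <- region_set("c", rep(0L, 3), rep(100L, 3),
                   region_id = c("a", "b", "d"),
                   target_gene = c("gNeg", "gPos", "gFlat"))
  r <- suppressWarnings(
    expression_correlation(rs, ms, expr, method = "pearson"))
  expect_equal(r[1L], -1)
  expect_equal(r[2L], 1)
  expect_true(is.na(r[3L]))   # constant expression: undefined
  r2 <- suppressWarnings(
    expression_correlation(rs, ms, expr, method = "spearman"))
  expect_equal(r2[1L], -1)
})

test_that("feature tables are complete after the drop/impute policy", {
  sim <- sim_small()
  neg <- pick_one_per_source(sim$background, 7L)
  regions <- data.table::rbindlist(list(sim$regions, neg))
  data.table::setattr(regions, "class",
                      c("region_set", "data.table", "data.frame"))
  fg <- suppressMessages(count_motifs(sim$regions, sim$genome,
                                      sim$methylomes[[1L]]))
  bg <- suppressMessages(count_motifs(sim$background, sim$genome,
                                      sim$methylomes[[1L]]))
  mt <- classify_motifs(fg, bg)
  ft <- suppressMessages(build_feature_table(
    regions, sim$methylomes, sim$genome, motif_table = mt))
  feats <- c("mean_meth", "meth_variance", "autocorr", "cpg_density",
             "motif_score")
  expect_false(anyNA(ft[, feats, with = FALSE]))
  expect_true(all(is.finite(as.matrix(ft[, feats, with = FALSE]))))
  # bounds
  expect_true(all(ft$mean_meth >= 0 & ft$mean_meth <= 1))
  expect_true(all(ft$cpg_density >= 0 & ft$cpg_density <= 1))
  expect_true(all(ft$meth_variance >= 0 & ft$meth_variance <= 0.25))
  expect_true(all(abs(ft$autocorr[!ft$autocorr_imputed]) <=
                    max(1, max(abs(ft$autocorr)))))
  # separations carry the expected signs on promoter-like data
  pos <- ft$label == "positive"
  expect_lt(mean(ft$mean_meth[pos]), mean(ft$mean_meth[!pos]))
  expect_gt(mean(ft$cpg_density[pos]), mean(ft$cpg_density[!pos]))
  expect_gt(mean(ft$meth_variance[pos]), mean(ft$meth_variance[!pos]))
  expect_gt(mean(ft$autocorr[pos]), mean(ft$autocorr[!pos]))
  expect_gt(mean(ft$motif_score[pos]), mean(ft$motif_score[!pos]))
})
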