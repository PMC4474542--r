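test_that("entropy covers the textbook cases", {
  expect_equal(entropy(c("a", "a", "b", "b")), 1)
  expect_equal(entropy(rep("a", 7)), 0)
  expect_equal(entropy(c(rep("a", 1), rep("b", 3))),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-12)
  expect_error(entropy(character()), "empty")
})

test_that("equal-frequency discretization balances bins and ignores scale", {
  set.seed(2)
  x <- sample(seq_len(100))
  b <- discretize(x, 10)
  expect_equal(unname(table(b)), rep(10L, 10L), ignore_attr = TRUE)
  # strictly increasing transforms give identical assignments
  expect_identical(discretize(exp(x / 20), 10), b)
  expect_identical(discretize(rank(x), 10), b)
  # constant input collapses to one bin
  expect_equal(unique(discretize(rep(3.3, 40), 10)), 1L)
  # boundary values go to the lower bin
  expect_identical(discretize(c(1, 1, 2, 2), 2), c(1L, 1L, 2L, 2L))
})

test_that("information gain matches hand-computed cases", {
  lab <- rep(c("pos", "neg"), each = 4)
  # perfect predictor recovers the full entropy
  expect_equal(information_gain(lab, lab), entropy(lab))
  # constant feature carries nothing
  expect_equal(information_gain(rep(1, 8), lab), 0)
  # one disagreement per half: 1 - 2 * (4/8) * H(3/4, 1/4)
  f <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(information_gain(f, lab), 0.1887219, tolerance = 1e-6)
  expect_error(information_gain(1:3, lab), "length")
})

test_that("information gain is bounded by H(S) and log2(n_bins)", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(40:200, 1)
    lab <- sample(c("p", "n"), n, replace = TRUE, prob = c(runif(1), 1))
    if (length(unique(lab)) < 2) next
    x <- switch(sample(3, 1),
                rnorm(n), rexp(n), as.numeric(lab == "p") + rnorm(n))
    nb <- sample(2:10, 1)
    ig <- information_gain(x, lab, n_bins = nb)
    expect_gte(ig, 0)
    expect_lte(ig, entropy(lab) + 1e-12)
    expect_lte(ig, log2(nb) + 1e-12)
  }
})

test_that("feature ranking: noise scores ~0, duplicates score equal", {
  set.seed(4)
  n <- 1000L
  ft <- data.table::data.table(
    label = rep(c("positive", "background"), each = n / 2),
    mean_meth = c(rnorm(n / 2, 0.3, 0.1), rnorm(n / 2, 0.7, 0.1)),
    noise = runif(n))
  ft$dup <- ft$mean_meth
  ig <- rank_features(ft, features = c("mean_meth", "noise", "dup"))
  expect_lte(ig[feature == "noise", info_gain], 0.05)
  expect_equal(ig[feature == "mean_meth", info_gain],
               ig[feature == "dup", info_gain])
  expect_gt(ig[feature == "mean_meth", info_gain], 0.5)
})

test_that("AUC equals the pairwise ordering probability", {
  lab <- c("positive", "background", "positive", "background")
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), lab)$auc, 0.75)
  expect_equal(roc_auc(c(5, 1, 4, 2), lab)$auc, 1)
  expect_equal(roc_auc(c(1, 5, 2, 4), lab)$auc, 0)
  # ties count one half
  expect_equal(roc_auc(c(1, 1), c("positive", "background"))$auc, 0.5)
  # invariance under strictly monotone transforms
  set.seed(9)
  sc <- rnorm(200)
  lb <- sample(c("positive", "background"), 200, TRUE)
  a1 <- roc_auc(sc, lb)$auc
  expect_equal(roc_auc(exp(sc), lb)$auc, a1)
  expect_equal(roc_auc(rank(sc), lb)$auc, a1)
  # agreement with an independent implementation
  skip_if_not_installed("pROC")
  a2 <- as.numeric(pROC::auc(pROC::roc(
    response = lb, predictor = sc, levels = c("background", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")
})

test_that("ROC points trace the cumulative classification rates", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3),
               c("positive", "background", "positive", "background"))$roc
  expect_equal(r$fpr[1L], 0)
  expect_equal(r$tpr[1L], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("cross-validation is deterministic, stratified, exhaustive", {
  set.seed(12)
  n <- 120L
  ft <- data.table::data.table(
    label = rep(c("positive", "background"), each = n / 2),
    mean_meth = c(rnorm(n / 2, 0.35, 0.12), rnorm(n / 2, 0.7, 0.12)),
    meth_variance = c(rnorm(n / 2, 0.06, 0.02), rnorm(n / 2, 0.02, 0.01)),
    autocorr = rnorm(n, 0.2, 0.2),
    cpg_density = c(rnorm(n / 2, 0.05, 0.01), rnorm(n / 2, 0.01, 0.005)),
    motif_score = rexp(n))
  cv1 <- cross_validate(ft, folds = 5, seed = 31)
  cv2 <- cross_validate(ft, folds = 5, seed = 31)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$scores, cv2$scores)
  expect_equal(cv1$auc, cv2$auc)
  # every region in exactly one test fold; both classes in every fold
  expect_setequal(unique(cv1$fold), 1:5)
  for (f in 1:5) {
    expect_setequal(unique(ft$label[cv1$fold == f]),
                    c("positive", "background"))
  }
  # the single-feature comparator runs on mean methylation alone
  cvm <- cross_validate(ft, folds = 5, seed = 31,
                        feature_subset = "mean_meth")
  expect_identical(cvm$config$features, "mean_meth")
  expect_gt(cvm$auc, 0.9)
  expect_error(cross_validate(ft[1:12], folds = 10), "folds")
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(42)
  n <- 1000L
  ft <- data.table::data.table(
    label = sample(rep(c("positive", "background"), each = n / 2)),
    mean_meth = runif(n), meth_variance = runif(n, 0, 0.25),
    autocorr = runif(n, -1, 1), cpg_density = runif(n, 0, 0.1),
    motif_score = rexp(n))
  cv <- cross_validate(ft, folds = 10, seed = 7)
  expect_gte(cv$auc, 0.45)
  expect_lte(cv$auc, 0.55)
})
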