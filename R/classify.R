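## SVM classification under stratified cross-validation, ROC/AUC, and
## information-gain feature ranking.

.FEATURES <- c("mean_meth", "meth_variance", "autocorr", "cpg_density",
               "motif_score")

#' Shannon entropy of a label vector, in bits
#' @param labels non-empty vector of class assignments.
#' @return entropy in bits (`0 * log2(0)` taken as 0).
#' @export
entropy <- function(labels) {
  if (length(labels) == 0L) stop("empty label vector")
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Equal-frequency discretization of a continuous feature
#'
#' Cut points are the type-1 (inverse empirical CDF) quantiles of the
#' input, so bin assignments are invariant under strictly increasing
#' transforms; values tied with a cut point go to the lower bin. Constant
#' input collapses to a single bin.
#'
#' @param values numeric vector.
#' @param n_bins target number of bins (default 10).
#' @return integer bin assignments.
#' @export
discretize <- function(values, n_bins = 10) {
  stopifnot(n_bins >= 1)
  if (anyNA(values)) stop("missing values cannot be discretized")
  qs <- unique(stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                               type = 1, names = FALSE))
  as.integer(cut(values, breaks = c(-Inf, qs, Inf), labels = FALSE,
                 right = TRUE))
}

#' Information gain of a feature with respect to class labels
#'
#' `IG(S, F) = H(S) - sum_v |S_v|/|S| H(S_v)`, the entropy reduction of
#' the label set given the feature. Numeric features are discretized
#' first with [discretize()].
#'
#' @param feature_values feature vector (numeric features are
#'   discretized; discrete vectors are used as-is).
#' @param labels class labels, same length.
#' @param n_bins bins for discretization (default 10).
#' @return information gain in bits.
#' @export
information_gain <- function(feature_values, labels, n_bins = 10) {
  if (length(feature_values) != length(labels)) {
    stop("feature and label vectors differ in length")
  }
  f <- if (is.numeric(feature_values) && !is.integer(feature_values)) {
    discretize(feature_values, n_bins)
  } else feature_values
  h <- entropy(labels)
  n <- length(labels)
  cond <- 0
  for (v in unique(f)) {
    sel <- f == v
    cond <- cond + sum(sel) / n * entropy(labels[sel])
  }
  h - cond
}

#' Rank features by information gain
#'
#' @param ft a `feature_table` (or any data frame with a `label` column
#'   and feature columns).
#' @param features feature columns to rank; defaults to the five
#'   classifier features present in `ft`.
#' @param n_bins bins for discretization (default 10).
#' @return a `data.table(feature, info_gain)` sorted by decreasing gain,
#'   with attribute `n_bins`.
#' @export
rank_features <- function(ft, features = NULL, n_bins = 10) {
  ft <- data.table::as.data.table(ft)
  if (is.null(features)) features <- intersect(.FEATURES, names(ft))
  features <- features[vapply(features, function(f) {
    !anyNA(ft[[f]])
  }, TRUE)]
  if (length(features) < 2L) stop("need >= 2 complete features to rank")
  ig <- vapply(features, function(f) {
    information_gain(ft[[f]], ft$label, n_bins = n_bins)
  }, 0)
  out <- data.table::data.table(feature = features, info_gain = ig)
  data.table::setorder(out, -info_gain)
  data.table::setattr(out, "n_bins", n_bins)
  out[]
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, ties counted 1/2; it is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels class labels; `positive` marks the positive class.
#' @param positive value of `labels` identifying positives.
#' @return list with `auc` and `roc`, a `data.table(threshold, fpr, tpr)`.
#' @export
roc_auc <- function(scores, labels, positive = "positive") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)
  roc <- data.table::data.table(
    threshold = c(Inf, sc[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1))
  list(auc = auc, roc = roc)
}

# standardize columns with training statistics; zero-variance -> untouched
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = scale(train, center = mu, scale = sdv),
       test = scale(test, center = mu, scale = sdv))
}

#' Cross-validated SVM classification of regulatory regions
#'
#' Trains a polynomial-kernel support vector machine (degree 2, cost 10
#' by default) under stratified k-fold cross-validation and returns the
#' held-out decision scores of every region together with the pooled and
#' per-fold AUC. Features are standardized with training-fold statistics
#' only. When `refit_motif` is supplied, the `motif_score` column is
#' recomputed for each fold from a motif table built on the training
#' rows only, which keeps the motif feature free of test-fold
#' information.
#'
#' @param ft a `feature_table` with a `label` column
#'   (`positive`/`background`).
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param kernel_degree polynomial degree (default 2).
#' @param cost soft-margin misclassification cost C (default 10).
#' @param coef0 polynomial kernel offset (default 1, the inhomogeneous
#'   kernel).
#' @param feature_subset optional subset of feature columns (e.g.
#'   `"mean_meth"` for the methylation-level-only comparator).
#' @param refit_motif optional `function(train_idx)` returning a
#'   numeric vector of motif scores for all rows, computed from the
#'   training rows only.
#' @return a `cv_result`: list with `scores`, `labels`, `fold`, `auc`
#'   (pooled), `fold_auc`, `roc`, `motif_score_oof` (out-of-fold motif
#'   scores when `refit_motif` is used; the leakage-free feature values
#'   appropriate for information-gain ranking), `config`.
#' @export
cross_validate <- function(ft, folds = 10, seed = NULL, kernel_degree = 2,
                           cost = 10, coef0 = 1, feature_subset = NULL,
                           refit_motif = NULL) {
  ft <- data.table::as.data.table(ft)
  feats <- if (is.null(feature_subset)) {
    intersect(.FEATURES, names(ft))
  } else feature_subset
  if (is.null(refit_motif)) {
    feats <- feats[vapply(feats, function(f) !anyNA(ft[[f]]), TRUE)]
  }
  if (length(feats) == 0L) stop("no usable feature columns")
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- factor(ft$label, levels = c("background", "positive"))
  if (any(table(y) < folds)) {
    stop("need at least `folds` regions per class")
  }
  fold <- integer(nrow(ft))
  for (cl in levels(y)) {
    ix <- which(y == cl)
    fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  X0 <- as.matrix(ft[, feats, with = FALSE])
  scores <- numeric(nrow(ft))
  fold_auc <- numeric(folds)
  motif_oof <- if (!is.null(refit_motif) && "motif_score" %in% feats) {
    numeric(nrow(ft))
  } else NULL
  for (f in seq_len(folds)) {
    test <- fold == f
    X <- X0
    if (!is.null(motif_oof)) {
      X[, "motif_score"] <- refit_motif(which(!test))
      motif_oof[test] <- X[test, "motif_score"]
    }
    std <- .standardize(X[!test, , drop = FALSE], X[test, , drop = FALSE])
    fit <- e1071::svm(std$train, y[!test], kernel = "polynomial",
                      degree = kernel_degree, cost = cost, coef0 = coef0,
                      scale = FALSE)
    pred <- stats::predict(fit, std$test, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    s <- dv[, 1L]
    if (colnames(dv)[1L] == "background/positive") s <- -s
    scores[test] <- s
    fold_auc[f] <- roc_auc(s, y[test])$auc
  }
  pooled <- roc_auc(scores, y)
  res <- list(scores = scores, labels = as.character(y), fold = fold,
              auc = pooled$auc, fold_auc = fold_auc, roc = pooled$roc,
              motif_score_oof = motif_oof,
              config = list(folds = folds, kernel_degree = kernel_degree,
                            cost = cost, coef0 = coef0, seed = seed,
                            features = feats))
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated SVM (polynomial kernel, degree ",
      x$config$kernel_degree, ", cost ", x$config$cost, ")\n", sep = "")
  cat("  features: ", paste(x$config$features, collapse = ", "), "\n",
      sep = "")
  cat("  regions:  ", length(x$scores), " in ", x$config$folds,
      " folds\n", sep = "")
  cat(sprintf("  AUC:      %.4f pooled (fold mean %.4f, sd %.4f)\n",
              x$auc, mean(x$fold_auc), stats::sd(x$fold_auc)))
  invisible(x)
}
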