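# Splitting, metrics (rank AUC, accuracy, precision, recall), ROC and
# confusion-matrix utilities, and the survey sample-size calculation.

#' Stratified train/test split with stratified 5-fold assignments
#'
#' Class proportions in the test set are within one sample per class of the
#' global proportions; the fold labels partition the training set, also
#' stratified by class.
#'
#' @param y Binary label vector.
#' @param test_fraction Proportion held out as the independent test set.
#' @param n_folds Number of cross-validation folds over the training set.
#' @param seed Integer seed.
#' @return List of class `split_plan`: `train`, `test` (index vectors) and
#'   `folds` (fold id per training index, aligned with `train`).
#' @export
stratified_split <- function(y, test_fraction = 0.15, n_folds = 5L,
                             seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  with_seed(as.integer(seed), {
    # largest-remainder allocation: per-class test counts floor the exact
    # quota and the remaining slots go to the largest fractional parts, so
    # the total matches round(n * test_fraction) and every class is within
    # one sample of its exact share
    classes <- sort(unique(y))
    quota <- vapply(classes, function(cl) sum(y == cl) * test_fraction,
                    numeric(1))
    n_per <- floor(quota)
    rem <- round(length(y) * test_fraction) - sum(n_per)
    if (rem > 0) {
      ord <- order(quota - n_per, decreasing = TRUE)
      n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1
    }
    test <- integer(0)
    for (i in seq_along(classes)) {
      idx <- which(y == classes[i])
      test <- c(test, sample(idx, n_per[i]))
    }
    test <- sort(test)
    train <- setdiff(seq_along(y), test)
    folds <- integer(length(train))
    for (cl in sort(unique(y))) {
      pos <- which(y[train] == cl)
      folds[sample(pos)] <- rep_len(seq_len(n_folds), length(pos))
    }
    structure(list(train = train, test = test, folds = folds,
                   n_folds = as.integer(n_folds), seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; 1 is the positive (at-risk) class.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a threshold
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary labels.
#' @param threshold Scores >= threshold predict the positive class.
#' @return Named vector TP, FP, TN, FN.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  c(TP = sum(pred == 1 & labels == 1),
    FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0),
    FN = sum(pred == 0 & labels == 1))
}

#' Classification metrics report
#'
#' AUC by the rank statistic; accuracy, precision and recall at the given
#' threshold (precision defined as 0 when nothing is predicted positive).
#'
#' @inheritParams confusion_counts
#' @return List of class `metrics_report`: auc, acc, precision, recall,
#'   confusion (TP/FP/TN/FN), roc (data frame of ROC points), threshold.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  cc <- confusion_counts(scores, labels, threshold)
  precision <- if (cc["TP"] + cc["FP"] > 0) {
    unname(cc["TP"] / (cc["TP"] + cc["FP"]))
  } else 0
  recall <- if (cc["TP"] + cc["FN"] > 0) {
    unname(cc["TP"] / (cc["TP"] + cc["FN"]))
  } else 0
  structure(list(auc = rank_auc(scores, labels),
                 acc = unname((cc["TP"] + cc["TN"]) / length(labels)),
                 precision = precision, recall = recall,
                 confusion = cc,
                 roc = roc_points(scores, labels),
                 threshold = threshold),
            class = "metrics_report")
}

#' ROC curve points at all distinct thresholds
#'
#' The curve starts at (0, 0), ends at (1, 1), and its trapezoidal area
#' equals the rank AUC.
#'
#' @inheritParams rank_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC undefined with a single class")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Required sample size for estimating a proportion
#'
#' `ceiling(z^2 * p * (1 - p) / d^2)` with `z` the two-sided normal quantile
#' of `conf_level` and `d` the half-width of the confidence interval. With
#' p = 0.5, a 95% confidence level and a total interval width of 10%
#' (half-width 0.05) this gives 385.
#'
#' @param prevalence Assumed proportion p in (0, 1).
#' @param conf_level Confidence level in (0, 1).
#' @param half_width Confidence-interval half-width d in (0, 1).
#' @return Integer sample size.
#' @export
required_sample_size <- function(prevalence = 0.5, conf_level = 0.95,
                                 half_width = 0.05) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must be in (0,1)")
  if (half_width <= 0 || half_width >= 1) stop("half_width must be in (0,1)")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  as.integer(ceiling(z^2 * prevalence * (1 - prevalence) / half_width^2))
}
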