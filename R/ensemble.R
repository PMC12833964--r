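# Branch A stacking classifier (SVM, random forest, KNN, gradient boosting
# under a ridge-logistic meta-learner fed with out-of-fold predictions) and
# the final two-branch logistic fusion.

base_learner_names <- c("svm", "rf", "knn", "xgb")

# fit one base learner on (X, y); returns a closure predicting P(class 1).
# SVM probabilities come from a deterministic logistic (Platt) calibration of
# the decision values, fitted on the same training rows.
fit_base_learner <- function(name, X, y, seed) {
  y <- as.integer(y)
  with_seed(seed, switch(
    name,
    svm = {
      fit <- e1071::svm(X, factor(y), kernel = "radial", scale = TRUE)
      dvm <- attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      sgn <- if (colnames(dvm)[1] == "1/0") 1 else -1
      cal <- suppressWarnings(
        stats::glm(y ~ d, family = stats::binomial(),
                   data = data.frame(y = y, d = sgn * dv)))
      function(Xn) {
        d <- sgn * attr(stats::predict(fit, Xn, decision.values = TRUE),
                        "decision.values")[, 1]
        as.vector(stats::predict(cal, data.frame(d = d), type = "response"))
      }
    },
    rf = {
      fit <- randomForest::randomForest(X, factor(y), ntree = 200L)
      function(Xn) stats::predict(fit, Xn, type = "prob")[, "1"]
    },
    knn = {
      k <- 5L
      function(Xn) {
        pred <- class::knn(X, Xn, factor(y), k = k, prob = TRUE)
        p_win <- attr(pred, "prob")
        ifelse(pred == "1", p_win, 1 - p_win)
      }
    },
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3L,
                      eta = 0.3, nthread = 1L),
        data = dtrain, nrounds = 50L, verbose = 0)
      function(Xn) {
        stats::predict(fit, xgboost::xgb.DMatrix(Xn, nthread = 1L))
      }
    }))
}

#' Fit the stacking classifier
#'
#' The four base learners (RBF-kernel SVM, random forest, 5-NN, gradient
#' boosted trees) produce out-of-fold probability predictions via an
#' internal stratified 5-fold split; a ridge-penalized logistic regression
#' is fitted on the resulting n x 4 meta-feature matrix, and the base
#' learners are then refitted on the full data for inference.
#'
#' @param X n x F numeric feature matrix (n >= 20).
#' @param y Binary labels (0/1), both classes present.
#' @param seed Integer seed (controls folds and the stochastic learners).
#' @return Object of class `stacking_model` with `base` (fitted predictors),
#'   `meta` (glmnet ridge-logistic fit), `oof` (the out-of-fold meta-feature
#'   matrix) and `folds` (fold id per row).
#' @export
fit_stacking <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (nrow(X) < 20) stop("need at least 20 samples for stacking")
  plan <- stratified_split(y, test_fraction = 0, n_folds = 5L, seed = seed)
  folds <- integer(length(y))
  folds[plan$train] <- plan$folds
  oof <- matrix(NA_real_, nrow(X), length(base_learner_names),
                dimnames = list(NULL, base_learner_names))
  for (f in seq_len(5L)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    for (b in base_learner_names) {
      pred <- fit_base_learner(b, X[tr, , drop = FALSE], y[tr],
                               seed + 97L * f)
      oof[te, b] <- pred(X[te, , drop = FALSE])
    }
  }
  meta <- with_seed(seed, glmnet::glmnet(oof, y, family = "binomial",
                                         alpha = 0, lambda = 1 / nrow(X)))
  base <- lapply(stats::setNames(base_learner_names, base_learner_names),
                 function(b) fit_base_learner(b, X, y, seed))
  structure(list(base = base, meta = meta, oof = oof, folds = folds,
                 n_features = ncol(X)),
            class = "stacking_model")
}

#' Predict at-risk probabilities with a stacking model
#'
#' @param model A `stacking_model`.
#' @param X n x F matrix with the same feature count used in fitting.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_stacking <- function(model, X) {
  stopifnot(inherits(model, "stacking_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) stop("feature dimension mismatch")
  meta_X <- vapply(base_learner_names, function(b) model$base[[b]](X),
                   numeric(nrow(X)))
  if (nrow(X) == 1L) meta_X <- matrix(meta_X, 1L)
  as.vector(stats::predict(model$meta, meta_X, type = "response"))
}

#' Fuse the two branch scores with logistic regression
#'
#' Fits an intercept + L2-penalized logistic model on the two-column matrix
#' `[score_a, score_b]`. The scores must come from data not used to fit
#' either branch (held out or out-of-fold).
#'
#' @param score_a Branch A (manual features) probabilities.
#' @param score_b Branch B (CNN) probabilities.
#' @param y Binary labels aligned with the scores.
#' @return Object of class `fusion_model` with `coef` (intercept and two
#'   coefficients) and `fitted` (fused probabilities for the input scores).
#' @export
fuse_branches <- function(score_a, score_b, y) {
  stopifnot(length(score_a) == length(score_b),
            length(score_a) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  Xs <- cbind(score_a = score_a, score_b = score_b)
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                        lambda = 1 / length(y))
  structure(list(coef = as.vector(stats::coef(fit)),
                 model = fit,
                 fitted = as.vector(stats::predict(fit, Xs,
                                                   type = "response"))),
            class = "fusion_model")
}

#' Apply a fitted fusion model to new branch scores
#'
#' @param model A `fusion_model`.
#' @inheritParams fuse_branches
#' @return Fused probabilities.
#' @export
predict_fusion <- function(model, score_a, score_b) {
  stopifnot(inherits(model, "fusion_model"))
  Xs <- cbind(score_a = score_a, score_b = score_b)
  as.vector(stats::predict(model$model, Xs, type = "response"))
}
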