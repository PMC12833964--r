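# End-to-end orchestration: images -> masked manual features -> train-fitted
# normalization -> imbalance handling (training data only) -> SelectNet +
# stacking (branch A) -> shuttle-attention CNN (branch B) -> held-out
# logistic fusion -> metrics on the untouched test set.

#' Pipeline configuration
#'
#' @param n Number of synthetic images (ignored when `data_dir` is given).
#' @param image_params [synthetic_image_params()] for the fixture generator.
#' @param data_dir Optional directory in the [write_image_dataset()] layout;
#'   when given, images are read instead of generated.
#' @param test_fraction Fraction held out as the final test set.
#' @param fusion_fraction Fraction of the training set held out to fit the
#'   two-branch fusion model (branches never see these samples).
#' @param top_k Number of SelectNet-ranked features kept for stacking.
#' @param cles A [cles_config()] or NULL to disable imbalance handling.
#' @param selectnet_epochs,selectnet_lr SelectNet training parameters.
#' @param cnn A [shuttle_config()] for branch B.
#' @param run_cv If TRUE, also report branch-A 5-fold cross-validation
#'   metrics over the training set.
#' @param seed Master seed for the split and both branches.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 300L,
                            image_params = synthetic_image_params(
                              height = 64L, width = 64L, pos_fraction = 0.3),
                            data_dir = NULL,
                            test_fraction = 0.15,
                            fusion_fraction = 0.15,
                            top_k = 30L,
                            cles = cles_config(),
                            selectnet_epochs = 40L,
                            selectnet_lr = 0.02,
                            cnn = shuttle_config(),
                            run_cv = FALSE,
                            seed = 1L) {
  structure(list(n = as.integer(n), image_params = image_params,
                 data_dir = data_dir, test_fraction = test_fraction,
                 fusion_fraction = fusion_fraction, top_k = as.integer(top_k),
                 cles = cles, selectnet_epochs = as.integer(selectnet_epochs),
                 selectnet_lr = selectnet_lr, cnn = cnn, run_cv = run_cv,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# branch A fit on given rows of a normalized table; returns predictors
fit_branch_a <- function(X_norm, y, config, seed) {
  if (!is.null(config$cles)) {
    cl <- config$cles
    cl$seed <- seed
    res <- apply_cles(X_norm, y, cl)
    X_fit <- res$X; y_fit <- res$y; y_soft <- res$y_soft
  } else {
    X_fit <- X_norm; y_fit <- y
    y_soft <- smooth_labels(y, 0, 2L)
  }
  sn_cfg <- selectnet_config(feature_dim = ncol(X_fit),
                             epochs = config$selectnet_epochs,
                             learning_rate = config$selectnet_lr,
                             seed = seed)
  sn <- train_selectnet(X_fit, y_soft, sn_cfg)
  sel <- select_top_k(sn, X_fit, min(config$top_k, ncol(X_fit)))
  stack <- fit_stacking(sel$table, y_fit, seed = seed)
  list(selectnet = sn, indices = sel$indices, stacking = stack,
       predict = function(Xn) {
     predict_stacking(stack, Xn[, sel$indices, drop = FALSE])
   })
}

# imbalance handling at the image-index level for branch B: boundary
# undersampling in manual-feature space, then duplication (not
# interpolation) of minority indices up to the target ratio
cles_image_indices <- function(X_norm, y, idx, cles, seed) {
  if (is.null(cles)) return(idx)
  kept_local <- boundary_undersample(X_norm[idx, , drop = FALSE], y[idx],
                                     cles$m_neighbors)
  kept <- idx[kept_local]
  yk <- y[kept]
  minority <- if (sum(yk == 1) <= sum(yk == 0)) 1L else 0L
  n_min <- sum(yk == minority); n_maj <- sum(yk != minority)
  n_new <- max(0L, as.integer(round(cles$target_ratio * n_maj)) - n_min)
  dup <- with_seed(seed, sample(kept[yk == minority], n_new, replace = TRUE))
  c(kept, dup)
}

#' Run the full dual-branch pipeline
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress to stderr.
#' @return List of class `pipeline_report` with test-set metrics for the
#'   fused model and both branches, fusion coefficients, an audit block
#'   recording which indices each fitted component saw, and the split plan.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  seed <- config$seed

  say("generating/loading images")
  dataset <- if (!is.null(config$data_dir)) {
    read_image_dataset(config$data_dir)
  } else {
    p <- config$image_params; p$seed <- seed
    make_image_dataset(config$n, p)
  }
  y <- dataset$labels
  plan <- stratified_split(y, config$test_fraction, 5L, seed)
  train <- plan$train; test <- plan$test

  say("extracting manual features")
  feats <- extract_feature_table(dataset)

  # normalization fitted on training rows only
  mm <- fit_minmax(feats[train, , drop = FALSE])
  X_norm <- apply_minmax(feats, mm)

  # carve a fusion holdout out of the training set
  inner_plan <- stratified_split(y[train], config$fusion_fraction, 2L,
                                 seed + 1L)
  inner_train <- train[inner_plan$train]
  fusion_hold <- train[inner_plan$test]

  say("branch A: selectnet + stacking")
  branch_a <- fit_branch_a(X_norm[inner_train, , drop = FALSE],
                           y[inner_train], config, seed)
  score_a_hold <- branch_a$predict(X_norm[fusion_hold, , drop = FALSE])
  score_a_test <- branch_a$predict(X_norm[test, , drop = FALSE])

  say("branch B: shuttle-attention CNN")
  cnn_cfg <- config$cnn
  cnn_cfg$seed <- seed
  cnn_train_idx <- cles_image_indices(X_norm, y, inner_train, config$cles,
                                      seed + 2L)
  soft <- if (!is.null(config$cles)) {
    smooth_labels(y, config$cles$epsilon, 2L)
  } else NULL
  branch_b <- train_cnn_branch(dataset, cnn_cfg,
                               train_idx = cnn_train_idx,
                               score_idx = c(fusion_hold, test),
                               soft_targets = soft)
  score_b_hold <- branch_b$scores[seq_along(fusion_hold)]
  score_b_test <- branch_b$scores[length(fusion_hold) + seq_along(test)]

  say("fusing branches")
  fusion <- fuse_branches(score_a_hold, score_b_hold, y[fusion_hold])
  fused_test <- predict_fusion(fusion, score_a_test, score_b_test)

  metrics <- list(
    fused = compute_metrics(fused_test, y[test]),
    branch_a = compute_metrics(score_a_test, y[test]),
    branch_b = compute_metrics(score_b_test, y[test]))

  cv <- NULL
  if (config$run_cv) {
    say("branch A cross-validation")
    cv_scores <- rep(NA_real_, length(train))
    for (f in seq_len(plan$n_folds)) {
      tr <- train[plan$folds != f]
      te_local <- which(plan$folds == f)
      te <- train[te_local]
      mm_f <- fit_minmax(feats[tr, , drop = FALSE])
      Xf <- apply_minmax(feats, mm_f)
      ba <- fit_branch_a(Xf[tr, , drop = FALSE], y[tr], config, seed + 10L + f)
      cv_scores[te_local] <- ba$predict(Xf[te, , drop = FALSE])
    }
    cv <- compute_metrics(cv_scores, y[train])
  }

  structure(list(
    metrics = metrics,
    cv_branch_a = cv,
    fusion_coef = fusion$coef,
    importance = branch_a$selectnet$importance,
    selected_features = branch_a$indices,
    loss_log_cnn = branch_b$loss_log,
    split = plan,
    audit = list(minmax_fit_idx = train,
                 branch_fit_idx = inner_train,
                 cnn_fit_idx = unique(cnn_train_idx),
                 fusion_fit_idx = fusion_hold,
                 test_idx = test),
    seed = seed),
    class = "pipeline_report")
}

#' Write a pipeline report to JSON (metrics) and CSV (ROC, confusion)
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- lapply(report$metrics, function(m) {
    list(auc = m$auc, acc = m$acc, precision = m$precision,
         recall = m$recall, confusion = as.list(m$confusion))
  })
  jsonlite::write_json(list(metrics = flat, fusion_coef = report$fusion_coef,
                            seed = report$seed),
                       file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(report$metrics$fused$roc, file.path(dir, "roc_fused.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(count = report$metrics$fused$confusion),
                   file.path(dir, "confusion_fused.csv"))
  invisible(dir)
}
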