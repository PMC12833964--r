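# Imbalance strategy: interpolation oversampling, boundary undersampling,
# label smoothing and the combined pipeline.

test_that("interpolation formula returns endpoints and midpoints", {
  xi <- c(0, 0); xn <- c(1, 1)
  tn <- asNamespace("tonguenrs")
  expect_equal(tn$interpolate_minority(xi, xn, 0.5), c(0.5, 0.5))
  expect_equal(tn$interpolate_minority(xi, xn, 0), xi)
  expect_equal(tn$interpolate_minority(xi, xn, 1), xn)
})

test_that("synthetic points lie on segments between minority neighbors", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2)
  syn <- smooth_oversample(X, k = 3, n_new = 50, seed = 4)
  expect_equal(dim(syn), c(50, 2))
  # brute force: distance from each synthetic point to the nearest segment
  # between any pair of minority points is ~0
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (s in seq_len(nrow(syn))) {
    dmin <- Inf
    for (i in 1:19) for (j in (i + 1):20) {
      dmin <- min(dmin, seg_dist(syn[s, ], X[i, ], X[j, ]))
    }
    expect_lt(dmin, 1e-10)
  }
  # convexity: synthetic samples stay in the coordinate-wise envelope
  expect_true(all(syn[, 1] >= min(X[, 1]) & syn[, 1] <= max(X[, 1])))
  expect_true(all(syn[, 2] >= min(X[, 2]) & syn[, 2] <= max(X[, 2])))
  expect_identical(smooth_oversample(X, 3, 50, seed = 4), syn)
  expect_error(smooth_oversample(X[1, , drop = FALSE], 1, 5), "at least 2")
})

test_that("boundary undersampling removes only ambiguous majority points", {
  set.seed(13)
  # two well-separated clusters: nothing removed
  X <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(20) + 50, 10, 2))
  y <- c(rep(0, 30), rep(1, 10))
  expect_equal(boundary_undersample(X, y, 5), 1:40)
  # a majority point at the centroid of a minority cluster is removed
  minority <- matrix(rnorm(20, sd = 0.2), 10, 2)
  intruder <- matrix(colMeans(minority), 1, 2)
  far_majority <- matrix(rnorm(40) + 30, 20, 2)
  X2 <- rbind(minority, intruder, far_majority)
  y2 <- c(rep(1, 10), 0, rep(0, 20))
  kept <- boundary_undersample(X2, y2, 5)
  expect_false(11 %in% kept)
  expect_true(all(1:10 %in% kept))  # minority always kept
  expect_error(boundary_undersample(X2, rep(1, 31), 5), "both classes")
})

test_that("label smoothing matches the standard formula", {
  s <- smooth_labels(c(0, 1), 0.1, 2)
  expect_equal(s[2, ], c(class0 = 0.05, class1 = 0.95))
  expect_equal(s[1, ], c(class0 = 0.95, class1 = 0.05))
  expect_equal(smooth_labels(c(0, 1), 0, 2),
               matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("class0", "class1"))))
  expect_equal(rowSums(smooth_labels(sample(0:2, 20, TRUE), 0.3, 3)),
               rep(1, 20))
  expect_error(smooth_labels(0:1, 1, 2), "epsilon")
})

test_that("apply_cles balances classes, keeps minority rows and is deterministic", {
  fs <- make_feature_dataset(200, 4, 2, 1.5, pos_fraction = 0.1, seed = 14)
  cfg <- cles_config(seed = 14)
  out <- apply_cles(fs$features, fs$labels, cfg)
  counts <- table(out$y)
  expect_lte(abs(counts[1] - counts[2]), 1)
  expect_equal(rowSums(out$y_soft), rep(1, nrow(out$X)))
  expect_identical(apply_cles(fs$features, fs$labels, cfg), out)
  # with no smoothing and separable clusters, all original minority rows
  # survive into the output
  X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(8) + 20, 4, 2))
  y <- c(rep(0, 20), rep(1, 4))
  res <- apply_cles(X, y, cles_config(epsilon = 0, k_neighbors = 1, seed = 2))
  min_rows <- X[y == 1, ]
  for (i in seq_len(nrow(min_rows))) {
    expect_true(any(apply(res$X, 1, function(r) all(r == min_rows[i, ]))))
  }
})

test_that("synthetic minority samples respect the minority envelope after CLES", {
  fs <- make_feature_dataset(150, 3, 1, 1, pos_fraction = 0.15, seed = 15)
  out <- apply_cles(fs$features, fs$labels, cles_config(seed = 15))
  Xmin <- fs$features[fs$labels == 1, ]
  syn <- out$X[is.na(out$kept_idx), , drop = FALSE]
  for (j in seq_len(ncol(syn))) {
    expect_true(all(syn[, j] >= min(Xmin[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(Xmin[, j]) + 1e-12))
  }
})
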