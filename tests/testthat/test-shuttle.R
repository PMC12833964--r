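# Grouped channel/spatial attention with channel shuffle, and the residual
# backbone built around it.

test_that("group_split partitions channels and round-trips exactly", {
  set.seed(1)
  x <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  gs <- group_split(x, 2)
  expect_length(gs, 2)
  expect_equal(dim(gs[[1]]$k1), c(2, 4, 4))
  recon <- abind_channels <- do.call(
    function(...) {
      parts <- list(...)
      out <- array(0, dim(x))
      i <- 0
      for (p in parts) for (c_ in seq_len(dim(p)[1])) {
        i <- i + 1
        out[i, , ] <- p[c_, , ]
      }
      out
    },
    unlist(gs, recursive = FALSE))
  expect_identical(recon, x)
  expect_error(group_split(array(0, c(6, 2, 2)), 4), "divisible")
})

test_that("channel shuffle is the reshape-transpose permutation", {
  x <- array(0, c(4, 1, 1))
  x[, 1, 1] <- c(10, 11, 12, 13)   # channels 0..3 in 0-based terms
  out <- channel_shuffle(x, 2)
  expect_equal(as.vector(out[, 1, 1]), c(10, 12, 11, 13))  # [0,2,1,3]
  y <- array(rnorm(12 * 2 * 2), c(12, 2, 2))
  expect_identical(channel_shuffle(y, 1), y)
  expect_identical(channel_shuffle(channel_shuffle(y, 3), 4), y)
  # agreement with an explicit reshape-transpose oracle for all C <= 24
  for (C in 2:24) for (g in seq_len(C)) {
    if (C %% g != 0) next
    # reshape to g x C/g (groups as rows), transpose, flatten row-major
    oracle <- as.vector(matrix(seq_len(C), nrow = g, byrow = TRUE))
    expect_equal(channel_shuffle_perm(C, g), oracle,
                 info = sprintf("C=%d g=%d", C, g))
  }
})

test_that("channel attention scales by sigmoid weights", {
  set.seed(2)
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  # zero linear map: sigmoid(0) = 0.5 everywhere
  expect_equal(channel_attention(x), 0.5 * x)
  # constant map with identity linear: output sigma(c) * c
  cmap <- array(2, c(3, 5, 5))
  got <- channel_attention(cmap, W = diag(3))
  expect_equal(got, cmap * (1 / (1 + exp(-2))))
  expect_equal(dim(channel_attention(x, W = matrix(rnorm(16), 4))), dim(x))
})

test_that("spatial attention normalizes, squashes to (0,1) and keeps shape", {
  # spatially constant input: group-norm gives 0, weights sigmoid(bias)
  cmap <- array(7, c(2, 4, 4))
  expect_equal(spatial_attention(cmap, b = 0), 0.5 * cmap)
  expect_equal(spatial_attention(cmap, b = 3), cmap / (1 + exp(-3)))
  set.seed(3)
  x <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  out <- spatial_attention(x, w = rnorm(4), b = 0.2)
  expect_equal(dim(out), dim(x))
  ratio <- out / x
  expect_true(all(ratio > 0 & ratio < 1))
})

test_that("shuttle_block preserves shape and reduces to a permutation when clamped", {
  set.seed(4)
  for (C in c(8, 16)) {
    x <- array(rnorm(C * 4 * 4), c(C, 4, 4))
    params <- shuttle_params_new(C, 4)
    out <- shuttle_block(x, params, g = 4)
    expect_equal(dim(out), dim(x))
    clamped <- shuttle_block(x, params, g = 4, clamp_unit = TRUE)
    expect_equal(clamped, x[channel_shuffle_perm(C, 4), , , drop = FALSE])
  }
  # both-halves-channel-attention variant also preserves shape
  x <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  out2 <- shuttle_block(x, shuttle_params_new(8, 2), g = 2,
                        pair = "channel_channel")
  expect_equal(dim(out2), dim(x))
})

test_that("shuttle block passes gradient to every input channel", {
  tn <- asNamespace("tonguenrs")
  set.seed(5)
  C <- 8L; HW <- 9L
  X <- tn$ad_param(matrix(rnorm(HW * C), HW, C))
  params <- tn$ad_lift(shuttle_params_new(C, 2L))
  out <- tn$shuttle_forward_nodes(X, function(nm) params[[nm]], 2L, 1L, HW)
  tn$ad_backward(tn$ad_mean(tn$ad_square(out)))
  expect_true(all(colSums(abs(X$grad)) > 0))
})

test_that("built models classify with softmax outputs and seeded determinism", {
  cfg <- shuttle_config(backbone = "resnet-mini", input_size = 32,
                        seed = 11)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$values, m2$values)
  ds <- make_image_dataset(4, tiny_image_params())
  probs <- predict_cnn(m1, ds)
  expect_equal(dim(probs), c(4L, 2L))
  expect_equal(rowSums(probs), rep(1, 4))
  expect_true(all(probs > 0))
})

test_that("shuttle blocks add exactly the attention parameters", {
  cfg <- shuttle_config(backbone = "resnet-mini", input_size = 32, seed = 1)
  m <- build_model(cfg)
  sh <- grep("_sh_", names(m$values), value = TRUE)
  expect_gt(length(sh), 0)
  # per insertion point with C channels and g groups, the block owns
  # 2 channel-attention linears, the group-norm affine pair and the 1x1
  # spatial map per group
  g <- cfg$groups
  for (C in c(16, 32, 64)) {
    h <- C / (2 * g)
    expected <- g * (2 * (h * h + h) + 2 * h + h + 1)
    unit <- paste0("u", match(C, c(16, 32, 64)))
    got <- sum(lengths(m$values[grep(paste0("^", unit, "_sh_"), names(m$values))]))
    expect_equal(got, expected)
  }
})

test_that("resnet50 backbone builds and runs a forward pass", {
  cfg <- shuttle_config(backbone = "resnet50", input_size = 64, seed = 3)
  m <- build_model(cfg)
  ds <- make_image_dataset(2, synthetic_image_params(height = 64, width = 64,
                                                     seed = 1))
  probs <- predict_cnn(m, ds)
  expect_equal(rowSums(probs), rep(1, 2))
})

test_that("CNN training is seed-reproducible and learns a separable fixture", {
  p <- synthetic_image_params(height = 32, width = 32, color_effect = 60,
                              noise_sd = 4, seed = 31)
  ds <- make_image_dataset(60, p)
  plan <- stratified_split(ds$labels, 0.25, 2L, 31)
  cfg <- shuttle_config(backbone = "resnet-mini", input_size = 32,
                        epochs = 3, seed = 31)
  r1 <- train_cnn_branch(ds, cfg, train_idx = plan$train,
                         score_idx = plan$test)
  r2 <- train_cnn_branch(ds, cfg, train_idx = plan$train,
                         score_idx = plan$test)
  expect_identical(r1$scores, r2$scores)
  expect_lt(tail(r1$loss_log, 1), r1$loss_log[1])
  expect_gt(rank_auc(r1$scores, ds$labels[plan$test]), 0.8)
})
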