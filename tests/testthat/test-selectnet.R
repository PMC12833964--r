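# Stepwise attention feature selection: block-level identities, forward
# contracts, training determinism and loss behavior.

test_that("res_block_1d is the identity at zero weights and preserves shape", {
  x <- c(1.5, -2, 0.3, 4)
  expect_equal(res_block_1d(x), x)
  for (F in c(1, 3, 10)) {
    expect_length(res_block_1d(rnorm(F), w1 = rnorm(3), b1 = 0.2,
                               w2 = rnorm(3), b2 = -0.1), F)
  }
})

test_that("res_block_1d matches a hand-rolled two-layer convolution oracle", {
  set.seed(8)
  x <- rnorm(3)
  w1 <- rnorm(3); b1 <- rnorm(1); w2 <- rnorm(3); b2 <- rnorm(1)
  conv3 <- function(v, w, b) {
    vp <- c(0, v, 0)
    vapply(seq_along(v), function(i) {
      sum(w * vp[i:(i + 2)]) + b
    }, numeric(1))
  }
  manual <- pmax(conv3(pmax(conv3(x, w1, b1), 0), w2, b2), 0) + x
  expect_equal(res_block_1d(x, w1, b1, w2, b2), manual)
})

test_that("choice_block obeys the softmax-product contracts", {
  set.seed(3)
  x <- matrix(runif(20), 4, 5)
  xs <- matrix(runif(20), 4, 5)
  # zero stage-1 weights: uniform softmax over features
  cb <- choice_block(x, xs)
  expect_equal(cb$S1, rep(1 / 5, 5))
  expect_equal(sum(cb$S1), 1)
  expect_true(all(cb$M >= 0))
  # random weights keep the normalizations
  W <- matrix(rnorm(50), 5, 10)
  cb2 <- choice_block(x, xs, W = W, b = rnorm(10),
                      rb = list(w1 = rnorm(3), b1 = 0.1,
                                w2 = rnorm(3), b2 = 0))
  expect_equal(sum(cb2$S1), 1)
  expect_equal(sum(cb2$S2), 1)
  expect_true(all(cb2$M >= 0))
  # multiplicative gating: zero input stays zero
  cb3 <- choice_block(matrix(0, 4, 5), xs, W = W)
  expect_true(all(cb3$weighted == 0))
})

test_that("attention_block weights are a feature softmax and zero values give BN(x)", {
  set.seed(4)
  x <- matrix(rnorm(12), 3, 4)
  xs <- matrix(rnorm(12), 3, 4)
  params <- list(Wq = matrix(rnorm(16), 4), Wk = matrix(rnorm(16), 4),
                 Wv = matrix(rnorm(16), 4), Wl = matrix(rnorm(16), 4))
  ab <- attention_block(x, xs, params)
  expect_equal(rowSums(ab$weights), rep(1, 3))
  # with zero value projection v_decision = 0, so x_decision = BN(x)
  ab0 <- attention_block(x, xs, params[c("Wq", "Wk")])
  bn_manual <- x / sqrt(1 + 1e-5)  # running stats mean 0, var 1, gamma 1
  expect_equal(ab0$x_decision, bn_manual)
  # a single feature always gets attention weight exactly 1
  ab1 <- attention_block(matrix(1:3, 3, 1), matrix(0, 3, 1))
  expect_equal(as.vector(ab1$weights), rep(1, 3))
})

test_that("forward pass satisfies probability and importance contracts", {
  set.seed(5)
  fs <- make_feature_dataset(60, 8, 2, 2, seed = 2)
  Xn <- apply_minmax(fs$features, fit_minmax(fs$features))
  cfg <- selectnet_config(8, epochs = 2, seed = 2)
  m <- train_selectnet(Xn, fs$labels, cfg)
  fw <- selectnet_forward(Xn, m)
  expect_true(all(fw$probs >= 0))
  expect_equal(rowSums(fw$probs), rep(1, 60))
  expect_equal(sum(fw$importance), 1)
  expect_true(all(fw$importance >= 0))
  expect_identical(selectnet_forward(Xn, m)$probs, fw$probs)
  # per-step selection vectors are softmax-normalized factors
  for (S in fw$record$S1) expect_equal(sum(S), 1)
  for (S in fw$record$S2) expect_equal(sum(S), 1)
  expect_error(selectnet_forward(Xn * NA, m), "finite")
})

test_that("training is deterministic and reduces the loss on separable data", {
  fs <- make_feature_dataset(200, 10, 3, 3, seed = 6)
  Xn <- apply_minmax(fs$features, fit_minmax(fs$features))
  cfg <- selectnet_config(10, epochs = 8, seed = 6)
  m1 <- train_selectnet(Xn, fs$labels, cfg)
  m2 <- train_selectnet(Xn, fs$labels, cfg)
  expect_identical(m1$values, m2$values)
  expect_lt(tail(m1$loss_log, 1), m1$loss_log[1])
  expect_error(train_selectnet(Xn, rep(1, 200), cfg), "single class")
})

test_that("select_top_k orders by importance with index tie-breaks", {
  fs <- make_feature_dataset(80, 6, 2, 2.5, seed = 9)
  Xn <- apply_minmax(fs$features, fit_minmax(fs$features))
  m <- train_selectnet(Xn, fs$labels, selectnet_config(6, epochs = 3, seed = 9))
  full <- select_top_k(m, Xn, 6)
  expect_setequal(full$indices, 1:6)
  expect_equal(order(-m$importance, 1:6), full$indices)
  one <- select_top_k(m, Xn, 1)
  expect_equal(one$indices, unname(which.max(m$importance)))
  expect_equal(one$table[, 1], Xn[, one$indices])
  expect_error(select_top_k(m, Xn, 7), "exceed")
  # explicit tie: equal importance prefers the lower index
  m$importance <- rep(1 / 6, 6)
  expect_equal(select_top_k(m, Xn, 2)$indices, c(1L, 2L))
})
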