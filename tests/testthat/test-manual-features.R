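# Color conversions, masked statistics, GLCM texture block, the default
# 107-feature inventory and min-max normalization.

test_that("color conversions hit the standard reference points", {
  img <- array(128, dim = c(2, 2, 3))
  ti <- tongue_image(img, matrix(1, 2, 2))
  ch <- convert_color_spaces(ti)
  expect_equal(ch$Cr[1, 1], 128)
  expect_equal(ch$Cb[1, 1], 128)
  expect_equal(ch$a[1, 1], 0, tolerance = 1e-6)
  expect_equal(ch$b[1, 1], 0, tolerance = 1e-6)
  expect_identical(ch$R, img[, , 1])
  expect_identical(ch$G, img[, , 2])
  expect_identical(ch$B, img[, , 3])
  black <- tongue_image(array(0, dim = c(2, 2, 3)), matrix(1, 2, 2))
  chb <- convert_color_spaces(black)
  expect_equal(chb$Y[1, 1], 0)
  expect_equal(chb$L[1, 1], 0, tolerance = 1e-6)
})

test_that("masked first-order statistics follow the degenerate-moment conventions", {
  m <- matrix(1, 2, 4)
  expect_equal(masked_first_order_stats(matrix(7, 2, 4), m),
               c(mean = 7, std = 0, skewness = 0, kurtosis = 0,
                 median = 7, min = 7, max = 7))
  two_point <- matrix(c(0, 255, 0, 255, 0, 255, 0, 255), 2, 4)
  s <- masked_first_order_stats(two_point, m)
  expect_equal(unname(s["mean"]), 127.5)
  expect_equal(unname(s["std"]), 127.5)
  expect_equal(unname(s["skewness"]), 0)
  expect_error(masked_first_order_stats(two_point, matrix(0, 2, 4)), "empty")
})

test_that("statistics are invariant to everything outside the mask", {
  set.seed(1)
  ch <- matrix(runif(64, 0, 255), 8, 8)
  mask <- matrix(0, 8, 8); mask[3:6, 3:6] <- 1
  base <- masked_first_order_stats(ch, mask)
  for (i in 1:5) {
    ch2 <- ch
    ch2[mask == 0] <- runif(sum(mask == 0), 0, 255)
    expect_identical(masked_first_order_stats(ch2, mask), base)
  }
})

test_that("GLCM matches hand-derived cases and normalization contracts", {
  const <- compute_glcm(matrix(100, 4, 4), matrix(1, 4, 4), 1, 0, 8)
  q <- floor(100 / (256 / 8)) + 1
  expect_equal(const$matrix[q, q], 1)
  expect_equal(sum(const$matrix), 1)
  checker <- matrix(c(0, 255, 255, 0), 2, 2)
  g <- compute_glcm(checker, matrix(1, 2, 2), 1, 0, 2)
  expect_equal(g$matrix, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  set.seed(3)
  gray <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
  gg <- compute_glcm(gray, matrix(1, 6, 6), 1, 45, 4)
  expect_equal(sum(gg$matrix), 1)
  expect_equal(gg$matrix, t(gg$matrix))
  expect_error(compute_glcm(checker, matrix(0, 2, 2), 1, 0, 2), "pairs")
})

test_that("GLCM agrees with brute-force pair counting on random masked images", {
  set.seed(11)
  for (rep in 1:8) {
    gray <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    mask <- matrix(rbinom(64, 1, 0.8), 8, 8)
    mask[4:5, 4:5] <- 1  # keep enough pairs
    for (ang in c(0, 45, 90, 135)) {
      got <- compute_glcm(gray, mask, 1, ang, 8)$matrix
      expect_equal(got, brute_glcm(gray, mask, 1L, ang, 8L),
                   ignore_attr = TRUE)
    }
  }
})

test_that("GLCM descriptors are exact on point-mass and checkerboard matrices", {
  const <- compute_glcm(matrix(100, 4, 4), matrix(1, 4, 4), 1, 0, 8)
  d <- glcm_descriptors(const)
  expect_equal(unname(d[c("ASM", "energy", "entropy", "contrast", "max_prob",
                          "correlation")]),
               c(1, 1, 0, 0, 1, 1))
  checker <- compute_glcm(matrix(c(0, 255, 255, 0), 2, 2),
                          matrix(1, 2, 2), 1, 0, 2)
  dc <- glcm_descriptors(checker)
  expect_equal(unname(dc["contrast"]), 1)
  expect_equal(unname(dc["entropy"]), log(2))
  set.seed(5)
  gray <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  dr <- glcm_descriptors(compute_glcm(gray, matrix(1, 7, 7), 1, 90, 16))
  expect_equal(unname(dr["ASM"]), unname(dr["energy"])^2)
  expect_true(dr["energy"] > 0 && dr["energy"] <= 1)
})

test_that("the default inventory is 107 uniquely named deterministic features", {
  ti <- tiny_tongue()
  fv <- extract_features(ti)
  expect_length(fv, 107)
  expect_equal(anyDuplicated(names(fv)), 0)
  expect_identical(extract_features(ti), fv)
  # background-only edits leave the vector unchanged
  img2 <- ti$rgb
  bg <- ti$mask == 0
  for (ch in 1:3) {
    plane <- img2[, , ch]
    plane[bg] <- 255 - plane[bg]
    img2[, , ch] <- plane
  }
  expect_identical(extract_features(tongue_image(img2, ti$mask)), fv)
})

test_that("min-max normalization follows the fitted-range conventions", {
  tab <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  mm <- fit_minmax(tab)
  norm <- apply_minmax(tab, mm)
  expect_equal(unname(norm[, 1]), c(0, 0.5, 1))
  expect_equal(unname(norm[, 2]), c(0, 0, 0))
  # out-of-range test values clip to [0, 1]
  expect_equal(unname(apply_minmax(cbind(a = 8, b = 5), mm)[1, 1]), 1)
  expect_equal(unname(apply_minmax(cbind(a = -1, b = 5), mm)[1, 1]), 0)
  expect_error(apply_minmax(tab[, 1, drop = FALSE], mm), "dimension")
  # idempotence: renormalizing a normalized table with refit params
  set.seed(2)
  X <- matrix(runif(40), 10, 4)
  n1 <- apply_minmax(X, fit_minmax(X))
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_equal(apply_minmax(n1, fit_minmax(n1)), n1)
})
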