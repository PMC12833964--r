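# Synthetic tongue-image and feature-table generators: determinism,
# class-conditional effects and mask geometry.

test_that("image generation is a pure function of (label, params, seed)", {
  p <- tiny_image_params()
  a <- make_tongue_image(1, p, 42)
  b <- make_tongue_image(1, p, 42)
  expect_identical(a, b)
  expect_false(identical(a, make_tongue_image(1, p, 43)))
  expect_error(make_tongue_image(2, p, 1), "label")
})

test_that("masks are nonempty single 4-connected components", {
  p <- tiny_image_params()
  for (s in 1:5) {
    m <- make_tongue_image(s %% 2, p, s)$mask
    expect_gt(sum(m), 0)
    # flood fill from one masked pixel must reach every masked pixel
    start <- which(m == 1, arr.ind = TRUE)[1, ]
    seen <- matrix(FALSE, nrow(m), ncol(m))
    queue <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        y <- cur[1] + d[1]; x <- cur[2] + d[2]
        if (y >= 1 && y <= nrow(m) && x >= 1 && x <= ncol(m) &&
            m[y, x] == 1 && !seen[y, x]) {
          seen[y, x] <- TRUE
          queue[[length(queue) + 1]] <- c(y, x)
        }
      }
    }
    expect_equal(sum(seen), sum(m))
  }
})

test_that("null effects give no class difference; color_effect shifts red by its value", {
  p0 <- synthetic_image_params(height = 32, width = 32, color_effect = 0,
                               texture_effect = 0, noise_sd = 4, seed = 5)
  mean_red <- function(label, params, n = 200) {
    vals <- vapply(seq_len(n), function(i) {
      im <- make_tongue_image(label, params, i)
      mean(im$image[, , 1][im$mask == 1])
    }, numeric(1))
    mean(vals)
  }
  expect_lt(abs(mean_red(1, p0) - mean_red(0, p0)), 1)
  p30 <- synthetic_image_params(height = 32, width = 32, color_effect = 30,
                                texture_effect = 0, noise_sd = 4, seed = 5)
  expect_equal(mean_red(1, p30) - mean_red(0, p30), 30, tolerance = 0.05)
})

test_that("class separation is monotone in color_effect", {
  seps <- vapply(c(0, 15, 30), function(ce) {
    p <- synthetic_image_params(height = 32, width = 32, color_effect = ce,
                                texture_effect = 0, noise_sd = 4, seed = 9)
    m <- function(lab) mean(vapply(1:60, function(i) {
      im <- make_tongue_image(lab, p, i)
      mean(im$image[, , 1][im$mask == 1])
    }, numeric(1)))
    m(1) - m(0)
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})

test_that("dataset has exact positive counts and is seed-reproducible", {
  p <- tiny_image_params(pos_fraction = 0.3)
  d <- make_image_dataset(100, p)
  expect_equal(sum(d$labels), 30)
  expect_identical(make_image_dataset(100, p)$labels, d$labels)
  expect_identical(make_image_dataset(100, p)$images[[7]], d$images[[7]])
  p0 <- tiny_image_params(pos_fraction = 0)
  expect_equal(sum(make_image_dataset(10, p0)$labels), 0)
  expect_error(make_image_dataset(1, p), "at least 2")
})

test_that("feature dataset plants recoverable informative columns", {
  # delta = 0: single-column AUC is chance
  f0 <- make_feature_dataset(2000, 4, 2, 0, seed = 3)
  expect_equal(rank_auc(f0$features[, f0$informative_idx[1]], f0$labels),
               0.5, tolerance = 0.05)
  # delta = 3: single-column AUC approx pnorm(3 / sqrt(2)) = 0.983
  f3 <- make_feature_dataset(500, 10, 3, 3, seed = 3)
  expect_gt(rank_auc(f3$features[, f3$informative_idx[1]], f3$labels), 0.95)
  expect_identical(make_feature_dataset(500, 10, 3, 3, seed = 3), f3)
  expect_error(make_feature_dataset(10, 5, 6, 1), "n_informative")
})

test_that("image sets round-trip through the PNG/CSV layout", {
  dir <- withr::local_tempdir()
  d <- make_image_dataset(4, tiny_image_params())
  write_image_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_image_dataset(dir)
  expect_equal(back$labels, d$labels)
  expect_equal(back$images[[2]], d$images[[2]])
  expect_equal(back$masks[[3]], d$masks[[3]])
})
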