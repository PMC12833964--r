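# Synthetic tongue images and tabular feature sets with controllable
# class-conditional structure. Everything here is a pure function of its
# seed, so the rest of the package is testable without clinical data.

#' Parameters for the synthetic tongue-image generator
#'
#' The generator draws an ellipse-like "tongue" on a dark background. For
#' at-risk images (label 1) the red channel mean is shifted by `color_effect`
#' and a band-limited coating texture of amplitude `texture_effect` is added
#' inside the mask; both classes receive i.i.d. Gaussian pixel noise.
#'
#' @param height,width Image dimensions in pixels (at least 32).
#' @param pos_fraction Proportion of at-risk (label 1) images in a dataset.
#' @param color_effect Mean red-channel shift for the positive class, in
#'   8-bit intensity units.
#' @param texture_effect Amplitude of the band-limited coating noise for the
#'   positive class, in intensity units.
#' @param noise_sd Per-pixel Gaussian noise standard deviation (both classes).
#' @param seed Integer master seed; per-image seeds are derived from it.
#' @return An object of class `synthetic_image_params`.
#' @export
synthetic_image_params <- function(height = 128L, width = 128L,
                                   pos_fraction = 0.5, color_effect = 30,
                                   texture_effect = 20, noise_sd = 8,
                                   seed = 1L) {
  stopifnot(height >= 32L, width >= 32L,
            pos_fraction >= 0, pos_fraction <= 1,
            color_effect >= 0, texture_effect >= 0, noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 pos_fraction = pos_fraction, color_effect = color_effect,
                 texture_effect = texture_effect, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_image_params")
}

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# documented per-instance seed scheme: seed_i = master * 10007 + index,
# wrapped into the 32-bit integer range
instance_seed <- function(master, index) {
  as.integer((as.double(master) * 10007 + index) %% .Machine$integer.max)
}

# bilinear upsampling of a coarse grid to H x W (band-limited noise source)
bilinear_upsample <- function(grid, H, W) {
  gh <- nrow(grid); gw <- ncol(grid)
  y <- seq(1, gh, length.out = H)
  x <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(y), gh - 1L); x0 <- pmin(floor(x), gw - 1L)
  fy <- y - y0; fx <- x - x0
  a <- grid[y0, x0, drop = FALSE]; b <- grid[y0, x0 + 1L, drop = FALSE]
  c_ <- grid[y0 + 1L, x0, drop = FALSE]; d <- grid[y0 + 1L, x0 + 1L, drop = FALSE]
  top <- a * outer(rep(1, H), 1 - fx) + b * outer(rep(1, H), fx)
  bot <- c_ * outer(rep(1, H), 1 - fx) + d * outer(rep(1, H), fx)
  top * (1 - fy) + bot * fy
}

#' Generate one synthetic tongue image and its mask
#'
#' @param label 0 (not at risk) or 1 (at risk).
#' @param params A [synthetic_image_params()] object.
#' @param instance_seed Integer seed for this image; generation is a pure
#'   function of `(label, params, instance_seed)`.
#' @return A list with `image` (height x width x 3 array, integer-valued
#'   0-255) and `mask` (height x width binary matrix, 1 inside the tongue).
#' @export
make_tongue_image <- function(label, params, instance_seed) {
  stopifnot(inherits(params, "synthetic_image_params"))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  H <- params$height; W <- params$width
  with_seed(as.integer(instance_seed), {
    cy <- (H + 1) / 2 + stats::runif(1, -0.02, 0.02) * H
    cx <- (W + 1) / 2 + stats::runif(1, -0.02, 0.02) * W
    ry <- 0.36 * H * (1 + stats::runif(1, -0.08, 0.08))
    rx <- 0.40 * W * (1 + stats::runif(1, -0.08, 0.08))
    ry <- min(ry, cy - 2, H - cy - 1)
    rx <- min(rx, cx - 2, W - cx - 1)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    mask <- 1 * (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1)

    base <- c(165, 85, 90)   # reddish tongue body
    img <- array(20, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(20, H, W)
      plane[mask == 1] <- base[ch]
      img[, , ch] <- plane
    }
    if (label == 1) {
      img[, , 1] <- img[, , 1] + params$color_effect * mask
      coarse <- matrix(stats::rnorm((H %/% 8 + 2) * (W %/% 8 + 2)),
                       H %/% 8 + 2, W %/% 8 + 2)
      tex <- bilinear_upsample(coarse, H, W) * params$texture_effect
      for (ch in 1:3) img[, , ch] <- img[, , ch] + tex * mask
    }
    if (params$noise_sd > 0) {
      img <- img + array(stats::rnorm(H * W * 3, sd = params$noise_sd),
                         dim = c(H, W, 3L))
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, mask = mask)
  })
}

#' Generate a labeled set of synthetic tongue images
#'
#' Exactly `round(n * pos_fraction)` images are positive. Per-image seeds are
#' `params$seed * 10007 + i` (mod 2^31 - 1); the label order is a
#' deterministic permutation drawn from `params$seed`.
#'
#' @param n Number of images (at least 2).
#' @param params A [synthetic_image_params()] object.
#' @return A list of class `labeled_image_set` with `images`, `masks`,
#'   `labels`, and the generating `params`.
#' @export
make_image_dataset <- function(n, params) {
  stopifnot(inherits(params, "synthetic_image_params"))
  if (n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  n_pos <- as.integer(round(n * params$pos_fraction))
  labels <- with_seed(params$seed,
                      sample(c(rep(1L, n_pos), rep(0L, n - n_pos))))
  out <- lapply(seq_len(n), function(i) {
    make_tongue_image(labels[i], params, instance_seed(params$seed, i))
  })
  structure(list(images = lapply(out, `[[`, "image"),
                 masks = lapply(out, `[[`, "mask"),
                 labels = labels, params = params),
            class = "labeled_image_set")
}

#' Generate a labeled feature table with planted informative columns
#'
#' Columns are standard normal noise; in the `n_informative` informative
#' columns the class-1 mean is shifted by `delta`. The informative column
#' indices are returned so feature-selection methods can be scored against
#' ground truth.
#'
#' @param n Number of rows.
#' @param dim Number of feature columns.
#' @param n_informative Number of class-informative columns (at most `dim`).
#' @param delta Mean shift of class 1 in informative columns (in SD units).
#' @param pos_fraction Proportion of class-1 rows.
#' @param seed Integer seed.
#' @return A list of class `labeled_feature_set` with `features` (n x dim
#'   matrix with column names), `labels` (0/1 vector) and `informative_idx`.
#' @export
make_feature_dataset <- function(n, dim, n_informative, delta,
                                 pos_fraction = 0.5, seed = 1L) {
  if (n_informative > dim) stop("n_informative must not exceed dim")
  n <- as.integer(n); dim <- as.integer(dim)
  with_seed(as.integer(seed), {
    n_pos <- as.integer(round(n * pos_fraction))
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    X <- matrix(stats::rnorm(n * dim), n, dim)
    idx <- sort(sample(dim, n_informative))
    X[labels == 1L, idx] <- X[labels == 1L, idx] + delta
    colnames(X) <- sprintf("f%03d", seq_len(dim))
    structure(list(features = X, labels = labels, informative_idx = idx),
              class = "labeled_feature_set")
  })
}

#' Write a labeled image set to disk as PNGs plus labels and manifest
#'
#' Images go to `img_NNNN.png`, masks to `mask_NNNN.png`, labels to a
#' two-column `labels.csv` (filename, label) and the generator parameters to
#' `manifest.json`.
#'
#' @param dataset A `labeled_image_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  fnames <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[[i]] / 255, file.path(dir, fnames[i]))
    png::writePNG(dataset$masks[[i]], file.path(dir, sprintf("mask_%04d.png", i)))
  }
  utils::write.csv(data.frame(filename = fnames, label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(dataset$params),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a labeled image set written by [write_image_dataset()]
#'
#' @param dir Directory containing `img_*.png`, `mask_*.png` and `labels.csv`.
#' @return A `labeled_image_set`.
#' @export
read_image_dataset <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  n <- nrow(lab)
  images <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, lab$filename[i]))
    images[[i]] <- round(img * 255)
    m <- png::readPNG(file.path(dir, sprintf("mask_%04d.png", i)))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    masks[[i]] <- 1 * (m > 0.5)
  }
  structure(list(images = images, masks = masks, labels = lab$label,
                 params = NULL),
            class = "labeled_image_set")
}
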