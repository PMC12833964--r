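# Branch A hand-crafted features: first-order statistics over nine color
# channels (RGB, YCrCb, CIE L*a*b*) restricted to the tongue mask, plus
# gray-level co-occurrence (GLCM) texture descriptors of the Y channel.
# Default inventory: 9 channels x 7 statistics + 4 GLCM angles x 11
# descriptors = 107 features.

#' Construct a tongue image (RGB raster plus binary mask)
#'
#' @param rgb Height x width x 3 array of 8-bit intensities (0-255).
#' @param mask Height x width binary matrix; 1 marks the tongue region.
#' @return An object of class `tongue_image`.
#' @export
tongue_image <- function(rgb, mask) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("rgb must be a height x width x 3 array")
  }
  if (!all(dim(mask) == dim(rgb)[1:2])) stop("mask dimensions must match rgb")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (sum(mask) == 0) stop("mask must be nonempty")
  structure(list(rgb = rgb, mask = mask), class = "tongue_image")
}

#' Map an RGB tongue image into the nine-channel color stack
#'
#' YCrCb follows full-range ITU-R BT.601 (JPEG/JFIF convention, +128 chroma
#' offset); L*a*b* is CIE Lab under D65 from sRGB, via
#' [grDevices::convertColor()]. R, G and B are passed through unchanged.
#'
#' @param image A [tongue_image()].
#' @return Named list of nine height x width matrices:
#'   R, G, B, Y, Cr, Cb, L, a, b.
#' @export
convert_color_spaces <- function(image) {
  stopifnot(inherits(image, "tongue_image"))
  R <- image$rgb[, , 1]; G <- image$rgb[, , 2]; B <- image$rgb[, , 3]
  Y <- 0.299 * R + 0.587 * G + 0.114 * B
  Cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B
  Cr <- 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
  lab <- grDevices::convertColor(cbind(as.vector(R), as.vector(G),
                                       as.vector(B)) / 255,
                                 from = "sRGB", to = "Lab")
  dims <- dim(R)
  list(R = R, G = G, B = B, Y = Y, Cr = Cr, Cb = Cb,
       L = matrix(lab[, 1], dims[1], dims[2]),
       a = matrix(lab[, 2], dims[1], dims[2]),
       b = matrix(lab[, 3], dims[1], dims[2]))
}

#' First-order statistics of a channel restricted to a mask
#'
#' Moments use the population (n) denominator. Skewness and excess kurtosis
#' are defined as 0 when the masked standard deviation is 0.
#'
#' @param channel Real-valued matrix.
#' @param mask Binary matrix of the same dimensions; must be nonempty.
#' @return Named vector: mean, std, skewness, kurtosis, median, min, max.
#' @export
masked_first_order_stats <- function(channel, mask) {
  stopifnot(all(dim(channel) == dim(mask)))
  v <- channel[mask == 1]
  if (length(v) == 0) stop("mask is empty")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s > 0) {
    skew <- mean((v - m)^3) / s^3
    kurt <- mean((v - m)^4) / s^4 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  c(mean = m, std = s, skewness = skew, kurtosis = kurt,
    median = stats::median(v), min = min(v), max = max(v))
}

#' Gray-level co-occurrence matrix over a masked region
#'
#' Gray values in \[0, 255\] are quantized uniformly into `levels` bins. Ordered
#' pixel pairs at the given offset are counted only when both pixels lie
#' inside the mask; counts are symmetrized and normalized to sum to 1.
#' Angles follow the usual convention: 0 degrees pairs each pixel with the one
#' `distance` columns to its right, 90 degrees with the one `distance` rows
#' above, 45/135 the diagonals.
#'
#' @param gray Real matrix of gray values in \[0, 255\].
#' @param mask Binary matrix, same dimensions.
#' @param distance Pair offset in pixels.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param levels Number of quantization levels (at least 2).
#' @return An object of class `glcm`: list with `matrix` (levels x levels,
#'   symmetric, sums to 1), `levels`, `distance`, `angle`.
#' @export
compute_glcm <- function(gray, mask, distance = 1L, angle = 0,
                         levels = 32L) {
  stopifnot(all(dim(gray) == dim(mask)), levels >= 2L)
  if (!angle %in% c(0, 45, 90, 135)) stop("angle must be 0, 45, 90 or 135")
  H <- nrow(gray); W <- ncol(gray); d <- as.integer(distance)
  q <- matrix(pmin(floor(gray / (256 / levels)) + 1L, levels), H, W)
  # (dy, dx) with image row 1 at the top; 90 degrees points upward
  off <- switch(as.character(angle),
                "0"   = c(0L, d),
                "45"  = c(-d, d),
                "90"  = c(-d, 0L),
                "135" = c(-d, -d))
  dy <- off[1]; dx <- off[2]
  ys <- seq_len(H); xs <- seq_len(W)
  y1 <- ys[ys + dy >= 1L & ys + dy <= H]
  x1 <- xs[xs + dx >= 1L & xs + dx <= W]
  if (length(y1) == 0 || length(x1) == 0) stop("no valid pixel pairs")
  a <- q[y1, x1, drop = FALSE]
  b <- q[y1 + dy, x1 + dx, drop = FALSE]
  ok <- mask[y1, x1, drop = FALSE] == 1 & mask[y1 + dy, x1 + dx, drop = FALSE] == 1
  if (!any(ok)) stop("no valid pixel pairs inside the mask")
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a[ok], levels = seq_len(levels)),
               factor(b[ok], levels = seq_len(levels)))
  counts <- counts + tab
  counts <- counts + t(counts)            # symmetrize
  P <- matrix(as.numeric(counts / sum(counts)), levels, levels)
  structure(list(matrix = P, levels = levels,
                 distance = d, angle = angle),
            class = "glcm")
}

#' Haralick-style descriptors of a GLCM
#'
#' Entropy uses the natural logarithm with the 0*log(0) = 0 convention;
#' correlation is defined as 1 when either marginal variance is 0. Gray-level
#' indices run 1..levels.
#'
#' @param P A `glcm` object (or a levels x levels probability matrix).
#' @return Named vector of 11 descriptors: contrast, dissimilarity,
#'   homogeneity, ASM, energy, correlation, entropy, max_prob,
#'   cluster_shade, cluster_prominence, sum_average.
#' @export
glcm_descriptors <- function(P) {
  M <- if (inherits(P, "glcm")) P$matrix else P
  L <- nrow(M)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_i <- sum(i * M); mu_j <- sum(j * M)
  var_i <- sum((i - mu_i)^2 * M); var_j <- sum((j - mu_j)^2 * M)
  corr <- if (var_i > 0 && var_j > 0) {
    sum((i - mu_i) * (j - mu_j) * M) / sqrt(var_i * var_j)
  } else 1
  nz <- M > 0
  c(contrast = sum((i - j)^2 * M),
    dissimilarity = sum(abs(i - j) * M),
    homogeneity = sum(M / (1 + (i - j)^2)),
    ASM = sum(M^2),
    energy = sqrt(sum(M^2)),
    correlation = corr,
    entropy = -sum(M[nz] * log(M[nz])),
    max_prob = max(M),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * M),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * M),
    sum_average = sum((i + j) * M))
}

glcm_angles <- c(0, 45, 90, 135)

#' Extract the default 107-dimensional manual feature vector
#'
#' 9 color channels x 7 first-order statistics (63 features) plus GLCMs of
#' the Y channel at distance 1 for angles 0/45/90/135 x 11 descriptors
#' (44 features), in a fixed documented order with unique names.
#'
#' @param image A [tongue_image()].
#' @param glcm_levels Gray quantization levels for the texture block.
#' @param glcm_distance Pair offset in pixels.
#' @return Named numeric vector of length 107.
#' @export
extract_features <- function(image, glcm_levels = 32L, glcm_distance = 1L) {
  stopifnot(inherits(image, "tongue_image"))
  ch <- convert_color_spaces(image)
  firsts <- unlist(lapply(names(ch), function(nm) {
    s <- masked_first_order_stats(ch[[nm]], image$mask)
    names(s) <- paste(nm, names(s), sep = "_")
    s
  }))
  texture <- unlist(lapply(glcm_angles, function(ang) {
    g <- compute_glcm(ch$Y, image$mask, distance = glcm_distance,
                      angle = ang, levels = glcm_levels)
    d <- glcm_descriptors(g)
    names(d) <- sprintf("glcm_a%d_%s", ang, names(d))
    d
  }))
  c(firsts, texture)
}

#' Extract a feature table from a labeled image set
#'
#' @param dataset A `labeled_image_set`.
#' @param ... Passed to [extract_features()].
#' @return n x 107 matrix with feature names as column names.
#' @export
extract_feature_table <- function(dataset, ...) {
  stopifnot(inherits(dataset, "labeled_image_set"))
  rows <- lapply(seq_along(dataset$images), function(i) {
    extract_features(tongue_image(dataset$images[[i]], dataset$masks[[i]]), ...)
  })
  do.call(rbind, rows)
}

#' Fit min-max normalization parameters on a training table
#'
#' @param table n x F numeric matrix (training data only).
#' @return Object of class `minmax_params` with per-feature `k_min`, `k_max`.
#' @export
fit_minmax <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 1)
  structure(list(k_min = apply(table, 2, min), k_max = apply(table, 2, max),
                 names = colnames(table)),
            class = "minmax_params")
}

#' Apply min-max normalization, mapping features to \[0, 1\]
#'
#' `k' = (k - k_min) / (k_max - k_min)`. Constant features map to 0; values
#' outside the fitted range are clipped to \[0, 1\].
#'
#' @param table n x F numeric matrix.
#' @param params A `minmax_params` fitted with [fit_minmax()].
#' @return Normalized matrix of the same shape.
#' @export
apply_minmax <- function(table, params) {
  table <- as.matrix(table)
  stopifnot(inherits(params, "minmax_params"))
  if (ncol(table) != length(params$k_min)) {
    stop("feature dimension does not match fitted parameters")
  }
  rng <- params$k_max - params$k_min
  out <- sweep(table, 2, params$k_min, "-")
  safe <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2, safe, "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}
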