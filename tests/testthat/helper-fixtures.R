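# shared helpers: tiny deterministic inputs built in code

tiny_image_params <- function(...) {
  synthetic_image_params(height = 32L, width = 32L, seed = 7L, ...)
}

tiny_tongue <- function(label = 1, seed = 42L, ...) {
  p <- tiny_image_params(...)
  out <- make_tongue_image(label, p, seed)
  tongue_image(out$image, out$mask)
}

# numerical gradient by central differences
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force AUC over all positive-negative pairs, ties counted 0.5
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force GLCM by explicit pair enumeration
brute_glcm <- function(gray, mask, distance, angle, levels) {
  q <- pmin(floor(gray / (256 / levels)) + 1L, levels)
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (y in seq_len(nrow(gray))) {
    for (x in seq_len(ncol(gray))) {
      y2 <- y + off[1]; x2 <- x + off[2]
      if (y2 < 1 || y2 > nrow(gray) || x2 < 1 || x2 > ncol(gray)) next
      if (mask[y, x] == 1 && mask[y2, x2] == 1) {
        counts[q[y, x], q[y2, x2]] <- counts[q[y, x], q[y2, x2]] + 1
      }
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}
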