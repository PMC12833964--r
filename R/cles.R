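# Comprehensive imbalance handling: boundary undersampling of the majority
# class, smooth (interpolation) oversampling of the minority class and label
# smoothing of the training targets.

#' Configuration for the imbalance strategy
#'
#' @param k_neighbors Neighborhood size for interpolation oversampling.
#' @param m_neighbors Neighborhood size for the boundary test.
#' @param target_ratio Desired minority:majority count ratio after
#'   resampling (1 = balanced).
#' @param epsilon Label-smoothing strength in \[0, 1).
#' @param n_classes Number of classes K for the smoothed targets.
#' @param seed Integer seed for all sampling.
#' @return An object of class `cles_config`.
#' @export
cles_config <- function(k_neighbors = 5L, m_neighbors = 5L,
                        target_ratio = 1, epsilon = 0.1,
                        n_classes = 2L, seed = 1L) {
  stopifnot(k_neighbors >= 1, m_neighbors >= 1, target_ratio > 0,
            epsilon >= 0, epsilon < 1, n_classes >= 2)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 m_neighbors = as.integer(m_neighbors),
                 target_ratio = target_ratio, epsilon = epsilon,
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "cles_config")
}

euclidean_dist <- function(X) {
  as.matrix(stats::dist(X))
}

# the interpolation rule: x_new = x_i + lambda * (x_neighbor - x_i)
interpolate_minority <- function(xi, x_neighbor, lambda) {
  xi + lambda * (x_neighbor - xi)
}

#' Interpolation ("smooth") oversampling of the minority class
#'
#' Each synthetic sample is `x_i + lambda * (x_neighbor - x_i)` where `x_i`
#' is drawn uniformly from the minority points, `x_neighbor` uniformly from
#' its `k` nearest Euclidean neighbors and `lambda ~ Uniform(0, 1)`.
#'
#' @param X_minority n x F matrix of minority-class samples (n >= 2).
#' @param k Neighborhood size (at most n - 1).
#' @param n_new Number of synthetic samples to generate.
#' @param seed Integer seed.
#' @return n_new x F matrix of synthetic samples.
#' @export
smooth_oversample <- function(X_minority, k, n_new, seed = 1L) {
  X_minority <- as.matrix(X_minority)
  n <- nrow(X_minority)
  if (n < 2) stop("need at least 2 minority samples")
  k <- min(as.integer(k), n - 1L)
  if (n_new == 0) {
    return(matrix(numeric(0), 0L, ncol(X_minority),
                  dimnames = list(NULL, colnames(X_minority))))
  }
  D <- euclidean_dist(X_minority)
  diag(D) <- Inf
  nn <- t(matrix(apply(D, 1, function(d) order(d)[seq_len(k)]), nrow = k))
  with_seed(as.integer(seed), {
    i <- sample.int(n, n_new, replace = TRUE)
    j <- nn[cbind(i, sample.int(k, n_new, replace = TRUE))]
    lam <- stats::runif(n_new)
    interpolate_minority(X_minority[i, , drop = FALSE],
                         X_minority[j, , drop = FALSE], lam)
  })
}

#' Boundary undersampling of the majority class
#'
#' A majority sample is removed iff strictly more than m/2 of its m nearest
#' Euclidean neighbors (excluding itself) belong to the minority class; all
#' minority samples are kept.
#'
#' @param X n x F feature matrix.
#' @param y Binary labels (0/1); the rarer value is the minority class.
#' @param m Neighborhood size.
#' @return Integer vector of kept row indices.
#' @export
boundary_undersample <- function(X, y, m = 5L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  minority <- if (sum(y == 1) <= sum(y == 0)) 1L else 0L
  m <- min(as.integer(m), nrow(X) - 1L)
  D <- euclidean_dist(X)
  diag(D) <- Inf
  keep <- rep(TRUE, nrow(X))
  maj_idx <- which(y != minority)
  for (i in maj_idx) {
    nb <- order(D[i, ])[seq_len(m)]
    if (sum(y[nb] == minority) > m / 2) keep[i] <- FALSE
  }
  which(keep | y == minority)
}

#' Smooth one-hot labels
#'
#' Each target row is `(1 - epsilon) * onehot + epsilon / K`.
#'
#' @param y Integer labels in 0..K-1.
#' @param epsilon Smoothing strength in \[0, 1).
#' @param K Number of classes.
#' @return n x K matrix of soft labels; every row sums to 1.
#' @export
smooth_labels <- function(y, epsilon = 0.1, K = 2L) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  y <- as.integer(y)
  if (any(y < 0 | y >= K)) stop("labels must be in 0..K-1")
  out <- matrix(epsilon / K, length(y), K)
  out[cbind(seq_along(y), y + 1L)] <- (1 - epsilon) + epsilon / K
  colnames(out) <- paste0("class", seq_len(K) - 1L)
  out
}

#' Apply the full imbalance strategy
#'
#' Order of operations: boundary undersampling of the majority class, then
#' interpolation oversampling of the minority class up to `target_ratio`,
#' then label smoothing. The output rows are shuffled deterministically by
#' the config seed.
#'
#' @param X n x F feature matrix.
#' @param y Binary labels (0/1).
#' @param config A [cles_config()].
#' @return List with `X` (resampled features), `y` (hard labels),
#'   `y_soft` (smoothed targets), and `kept_idx` (original-row indices of
#'   the retained real samples; synthetic rows are NA).
#' @export
apply_cles <- function(X, y, config = cles_config()) {
  stopifnot(inherits(config, "cles_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  kept <- boundary_undersample(X, y, config$m_neighbors)
  Xk <- X[kept, , drop = FALSE]
  yk <- y[kept]
  minority <- if (sum(yk == 1) <= sum(yk == 0)) 1L else 0L
  n_min <- sum(yk == minority)
  n_maj <- sum(yk != minority)
  n_new <- max(0L, as.integer(round(config$target_ratio * n_maj)) - n_min)
  Xmin <- Xk[yk == minority, , drop = FALSE]
  Xs <- smooth_oversample(Xmin, config$k_neighbors, n_new,
                          seed = config$seed)
  X_all <- rbind(Xk, Xs)
  y_all <- c(yk, rep(minority, n_new))
  src <- c(kept, rep(NA_integer_, n_new))
  perm <- with_seed(config$seed + 1L, sample.int(nrow(X_all)))
  list(X = X_all[perm, , drop = FALSE],
       y = y_all[perm],
       y_soft = smooth_labels(y_all[perm], config$epsilon, config$n_classes),
       kept_idx = src[perm])
}
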