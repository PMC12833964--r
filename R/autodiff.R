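# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value in the graph is a plain numeric matrix. Nodes are environments
# carrying the value, an id (creation order), the parent nodes and a backward
# closure returning one gradient per parent. ad_backward() walks reachable
# nodes in reverse creation order, so any forward expression built from the
# ops below differentiates correctly, including reused (diamond) nodes.
#
# This engine exists to train the two neural branches (the feature-selection
# network and the shuttle-attention CNN); it is deliberately small and
# single-threaded-deterministic. Gradients are verified against central
# finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$n <- 0L

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(value, parents = list(), backward = NULL, rg = NULL) {
  # force args before taking an id: nested node creation inside a lazily
  # evaluated argument must receive a smaller id than this node
  force(value); force(parents); force(backward)
  .ad$n <- .ad$n + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .ad$n
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  node$rg <- if (is.null(rg)) {
    any(vapply(parents, function(p) p$rg, logical(1)))
  } else rg
  class(node) <- "ad_node"
  node
}

ad_const <- function(x) ad_node(as_mat(x), rg = FALSE)
ad_param <- function(x) ad_node(as_mat(x), rg = TRUE)

is_ad <- function(x) inherits(x, "ad_node")

#' @noRd
ad_value <- function(x) if (is_ad(x)) x$value else x

# ---- core ops ---------------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g, node) {
    list(g %*% t(node$parents[[2]]$value), t(node$parents[[1]]$value) %*% g)
  })
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g, node) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g, node) list(g, -g))
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(g, node) {
    list(g * node$parents[[2]]$value, g * node$parents[[1]]$value)
  })
}

# scalar ad node (1x1) times matrix
ad_mul_scalar <- function(a, s) {
  ad_node(a$value * s$value[1L], list(a, s), function(g, node) {
    list(g * node$parents[[2]]$value[1L],
         matrix(sum(g * node$parents[[1]]$value), 1L, 1L))
  })
}

ad_scale_const <- function(a, c) {
  ad_node(a$value * c, list(a), function(g, node) list(g * c))
}

ad_add_const <- function(a, c) {
  ad_node(a$value + c, list(a), function(g, node) list(g))
}

# broadcast a 1 x C row vector over the rows of X
ad_add_rowvec <- function(X, v) {
  ad_node(cpp_add_rowvec(X$value, as.vector(v$value)), list(X, v),
          function(g, node) list(g, matrix(colSums(g), 1L)))
}

ad_mul_rowvec <- function(X, v) {
  ad_node(cpp_mul_rowvec(X$value, as.vector(v$value)), list(X, v),
          function(g, node) {
            p1 <- node$parents[[1]]$value
            list(cpp_mul_rowvec(g, as.vector(node$parents[[2]]$value)),
                 matrix(colSums(g * p1), 1L))
          })
}

# broadcast an n x 1 column vector over the columns of X
ad_add_colvec <- function(X, v) {
  ad_node(X$value + as.vector(v$value), list(X, v),
          function(g, node) list(g, matrix(rowSums(g), ncol = 1L)))
}

ad_mul_colvec <- function(X, v) {
  ad_node(X$value * as.vector(v$value), list(X, v),
          function(g, node) {
            vv <- as.vector(node$parents[[2]]$value)
            list(g * vv,
                 matrix(rowSums(g * node$parents[[1]]$value), ncol = 1L))
          })
}

ad_relu <- function(a) {
  ad_node(pmax(a$value, 0), list(a), function(g, node) {
    list(g * (node$parents[[1]]$value > 0))
  })
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g, node) list(g * node$value * (1 - node$value)))
}

ad_square <- function(a) {
  ad_node(a$value^2, list(a), function(g, node) {
    list(2 * g * node$parents[[1]]$value)
  })
}

ad_sqrt_eps <- function(a, eps = 1e-5) {
  ad_node(sqrt(a$value + eps), list(a), function(g, node) {
    list(g / (2 * node$value))
  })
}

ad_reciprocal <- function(a) {
  ad_node(1 / a$value, list(a), function(g, node) list(-g * node$value^2))
}

# row-wise softmax (numerically shifted)
ad_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ad_node(p, list(a), function(g, node) {
    p <- node$value
    list(p * (g - rowSums(g * p)))
  })
}

ad_rowsums <- function(X) {
  ad_node(matrix(rowSums(X$value), ncol = 1L), list(X), function(g, node) {
    matrix_g <- matrix(as.vector(g), nrow(node$parents[[1]]$value),
                       ncol(node$parents[[1]]$value))
    list(matrix_g)
  })
}

ad_rowmeans <- function(X) {
  C <- ncol(X$value)
  ad_node(matrix(rowMeans(X$value), ncol = 1L), list(X), function(g, node) {
    p <- node$parents[[1]]$value
    list(matrix(as.vector(g) / ncol(p), nrow(p), ncol(p)))
  })
}

ad_colmeans <- function(X) {
  ad_node(matrix(colMeans(X$value), 1L), list(X), function(g, node) {
    p <- node$parents[[1]]$value
    list(matrix(rep(as.vector(g) / nrow(p), each = nrow(p)), nrow(p), ncol(p)))
  })
}

ad_sum <- function(X) {
  ad_node(matrix(sum(X$value), 1L, 1L), list(X), function(g, node) {
    p <- node$parents[[1]]$value
    list(matrix(g[1L], nrow(p), ncol(p)))
  })
}

ad_mean <- function(X) {
  ad_node(matrix(mean(X$value), 1L, 1L), list(X), function(g, node) {
    p <- node$parents[[1]]$value
    list(matrix(g[1L] / length(p), nrow(p), ncol(p)))
  })
}

# gather rows by (possibly repeated) index; backward scatter-adds
ad_gather_rows <- function(X, idx) {
  idx <- as.integer(idx)
  ad_node(X$value[idx, , drop = FALSE], list(X), function(g, node) {
    p <- node$parents[[1]]$value
    out <- matrix(0, nrow(p), ncol(p))
    rs <- rowsum(g, idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

ad_gather_cols <- function(X, cols) {
  cols <- as.integer(cols)
  ad_node(X$value[, cols, drop = FALSE], list(X), function(g, node) {
    p <- node$parents[[1]]$value
    out <- matrix(0, nrow(p), ncol(p))
    for (j in seq_along(cols)) {
      out[, cols[j]] <- out[, cols[j]] + g[, j]
    }
    list(out)
  })
}

# prepend one all-zero row (index 1); used as the padding row for im2col
ad_pad_row0 <- function(X) {
  ad_node(rbind(0, X$value), list(X), function(g, node) {
    list(g[-1L, , drop = FALSE])
  })
}

# sum rows of X within consecutive integer groups 1..G
ad_rowsum_groups <- function(X, group, ngroups) {
  group <- as.integer(group)
  val <- rowsum(X$value, group)
  stopifnot(nrow(val) == ngroups)
  ad_node(val, list(X), function(g, node) {
    list(g[group, , drop = FALSE])
  })
}

ad_cbind_list <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, vals), nodes, function(g, node) {
    lapply(seq_along(node$parents), function(i) {
      g[, starts[i]:ends[i], drop = FALSE]
    })
  })
}

ad_cbind <- function(a, b) ad_cbind_list(list(a, b))

# mean soft-target cross-entropy with an in-op softmax (stable); the
# backward formula (p - t)/n requires target rows that sum to 1
ad_softmax_xent <- function(logits, targets) {
  t <- as_mat(targets)
  stopifnot(all(abs(rowSums(t) - 1) < 1e-8))
  z <- logits$value - apply(logits$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  loss <- -sum(t * log(pmax(p, 1e-12))) / n
  node <- ad_node(matrix(loss, 1L, 1L), list(logits), function(g, node) {
    list(g[1L] * (node$probs - node$targets) / nrow(node$probs))
  })
  node$probs <- p
  node$targets <- t
  node
}

# fused 2-D convolution: one tape node; the per-image im2col blocks are
# built in C++ and rebuilt (not stored) during backward, so peak memory
# stays at one feature map per layer.
# X: (N*H*W) x Cin; W: (k*k*Cin) x Cout with row index j + (c-1)*k*k;
# b: 1 x Cout or NULL; idxinfo: from im2col_idx().
ad_conv2d <- function(X, W, b, idxinfo) {
  out <- cpp_conv2d_fwd(X$value, W$value, idxinfo$idx, idxinfo$N,
                        idxinfo$HWout,
                        if (is.null(b)) numeric(0) else as.vector(b$value))
  parents <- if (is.null(b)) list(X, W) else list(X, W, b)
  node <- ad_node(out, parents, function(g, node) {
    bw <- cpp_conv2d_bwd(node$parents[[1]]$value, node$parents[[2]]$value,
                         g, idxinfo$idx, idxinfo$N, idxinfo$HWout,
                         node$parents[[1]]$rg)
    out <- list(if (node$parents[[1]]$rg) bw$gX else NULL, bw$gW)
    if (length(node$parents) == 3L) out <- c(out, list(matrix(colSums(g), 1L)))
    out
  })
  node
}

# fused training-mode batch normalization (population batch statistics)
ad_batchnorm <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X$value)
  xc <- cpp_add_rowvec(X$value, -mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- cpp_mul_rowvec(xc, inv)
  out <- cpp_add_rowvec(cpp_mul_rowvec(xhat, as.vector(gamma$value)),
                        as.vector(beta$value))
  node <- ad_node(out, list(X, gamma, beta), function(g, node) {
    n <- nrow(g)
    xhat <- node$xhat
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- cpp_mul_rowvec(g, as.vector(node$parents[[2]]$value))
    dx <- cpp_mul_rowvec(
      n * dxhat - cpp_add_rowvec(cpp_mul_rowvec(xhat, colSums(dxhat * xhat)),
                                 colSums(dxhat)),
      node$inv / n)
    list(dx, matrix(dgamma, 1L), matrix(dbeta, 1L))
  })
  node$xhat <- xhat
  node$inv <- inv
  node$batch_mean <- mu
  node$batch_var <- v
  node
}

ad_log <- function(a) {
  ad_node(log(pmax(a$value, 1e-12)), list(a), function(g, node) {
    list(g / pmax(node$parents[[1]]$value, 1e-12))
  })
}

# elementwise maximum; ties route the gradient to the first argument
ad_pmax <- function(a, b) {
  ad_node(pmax(a$value, b$value), list(a, b), function(g, node) {
    take_a <- node$parents[[1]]$value >= node$parents[[2]]$value
    list(g * take_a, g * !take_a)
  })
}

ad_reshape <- function(X, nr, nc) {
  v <- X$value
  dim(v) <- c(nr, nc)
  ad_node(v, list(X), function(g, node) {
    p <- node$parents[[1]]$value
    dim(g) <- dim(p)
    list(g)
  })
}

# add a 1x1 scalar node to every entry of X
ad_add_scalar <- function(X, s) {
  ad_node(X$value + s$value[1L], list(X, s), function(g, node) {
    list(g, matrix(sum(g), 1L, 1L))
  })
}

# ---- backward pass ----------------------------------------------------------

ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  # collect reachable grad-requiring nodes
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  count <- 0L
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]]) || !nd$rg) next
    seen[[key]] <- TRUE
    count <- count + 1L
    if (count > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[count]] <- nd
    for (p in nd$parents) if (p$rg) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(count)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  nodes <- nodes[ord]
  for (nd in nodes) nd$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (nd in nodes) {
    if (!is.null(nd$grad) && !is.null(nd$backward)) {
      gs <- nd$backward(nd$grad, nd)
      for (i in seq_along(nd$parents)) {
        p <- nd$parents[[i]]
        if (!p$rg || is.null(gs[[i]])) next
        p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
      }
    }
    # this node's value and gradient are no longer needed (its consumers
    # were processed earlier); drop them so the live set shrinks as the
    # sweep proceeds. Leaf parameters keep both for the optimizer; the loss
    # node keeps its value so callers can log it after the backward pass.
    if (!is.null(nd$backward) && !identical(nd, loss)) {
      nd$value <- NULL
      nd$grad <- NULL
      nd$xhat <- NULL
    }
  }
  invisible(loss)
}

# ---- parameter store and optimizer ------------------------------------------

# lift a named list of plain matrices into parameter nodes
ad_lift <- function(values) lapply(values, ad_param)

# extract accumulated gradients (zero where a parameter was unused)
ad_grads <- function(nodes) {
  lapply(nodes, function(n) {
    if (is.null(n$grad)) matrix(0, nrow(n$value), ncol(n$value)) else n$grad
  })
}

adam_init <- function(values) {
  list(m = lapply(values, function(v) v * 0),
       v = lapply(values, function(v) v * 0),
       t = 0L)
}

adam_step <- function(state, values, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(values)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    if (weight_decay > 0) upd <- upd + lr * weight_decay * values[[k]]
    values[[k]] <- values[[k]] - upd
  }
  list(state = state, values = values)
}
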