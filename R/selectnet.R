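# Stepwise attention-based feature selection. Each of T steps applies a 1-D
# residual block to the (normalized) input, a choice block that builds a
# per-feature selection weight from two softmax-normalized stages, and an
# attention block that fuses the current representation with the carried
# step state. Per-feature selection weights aggregated over steps give the
# feature importance used for top-k selection.

#' SelectNet configuration
#'
#' @param feature_dim Number of input features F.
#' @param n_steps Number of selection steps T.
#' @param attn_dim Attention scale d: the per-feature attention logits are
#'   divided by sqrt(d) before the softmax.
#' @param n_classes Number of output classes K.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (batches of size 1 are dropped, as batch
#'   normalization is undefined there).
#' @param sparsity_weight Strength of the selection-entropy penalty that
#'   pushes each step's selection weights toward a sparse profile; 0
#'   disables it (the aggregated importance then stays near-uniform).
#' @param weight_decay Decoupled L2 weight decay applied by the optimizer.
#' @param seed Integer seed for initialization and batching.
#' @return An object of class `selectnet_config`.
#' @export
selectnet_config <- function(feature_dim, n_steps = 3L, attn_dim = 32L,
                             n_classes = 2L, learning_rate = 0.02,
                             epochs = 20L, batch_size = 128L,
                             sparsity_weight = 0.02, weight_decay = 1e-3,
                             seed = 1L) {
  stopifnot(feature_dim >= 1, n_steps >= 1, attn_dim >= 1, n_classes >= 1,
            sparsity_weight >= 0, weight_decay >= 0)
  structure(list(feature_dim = as.integer(feature_dim),
                 n_steps = as.integer(n_steps),
                 attn_dim = as.integer(attn_dim),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 sparsity_weight = sparsity_weight,
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "selectnet_config")
}

# parameter initialisation for one step
selectnet_init_values <- function(config) {
  F <- config$feature_dim; d <- config$attn_dim; K <- config$n_classes
  vals <- list()
  for (t in seq_len(config$n_steps)) {
    p <- function(nm) paste0("s", t, "_", nm)
    # residual conv branches start at zero so each block begins as the
    # identity; the convolutions only deviate if the loss asks them to
    vals[[p("rb1_w1")]] <- matrix(0, 1, 3); vals[[p("rb1_b1")]] <- matrix(0, 1, 1)
    vals[[p("rb1_w2")]] <- matrix(0, 1, 3); vals[[p("rb1_b2")]] <- matrix(0, 1, 1)
    vals[[p("rb2_w1")]] <- matrix(0, 1, 3); vals[[p("rb2_b1")]] <- matrix(0, 1, 1)
    vals[[p("rb2_w2")]] <- matrix(0, 1, 3); vals[[p("rb2_b2")]] <- matrix(0, 1, 1)
    # stage-1 selection map starts at zero: a uniform prior over features.
    # A randomly initialized stage-1 biases the early selection race toward
    # arbitrary features and measurably harms recovery of informative ones.
    vals[[p("Wch")]] <- matrix(0, F, 2L * F); vals[[p("bch")]] <- matrix(0, 1, 2L * F)
    vals[[p("Wq")]] <- nn_init(F, F); vals[[p("bq")]] <- matrix(0, 1, F)
    vals[[p("Wk")]] <- nn_init(F, F); vals[[p("bk")]] <- matrix(0, 1, F)
    vals[[p("Wv")]] <- nn_init(F, F); vals[[p("bv")]] <- matrix(0, 1, F)
    vals[[p("Wl")]] <- nn_init(F, F); vals[[p("bl")]] <- matrix(0, 1, F)
    vals[[p("bn1")]] <- bn_new(F)$gamma; vals[[p("bn1b")]] <- bn_new(F)$beta
    vals[[p("bn2")]] <- bn_new(F)$gamma; vals[[p("bn2b")]] <- bn_new(F)$beta
  }
  vals[["Wc"]] <- nn_init(F, K); vals[["bc"]] <- matrix(0, 1, K)
  vals
}

selectnet_init_state <- function(config) {
  F <- config$feature_dim
  run <- list()
  for (t in seq_len(config$n_steps)) {
    run[[paste0("s", t, "_bn1")]] <- bn_state_new(F)
    run[[paste0("s", t, "_bn2")]] <- bn_state_new(F)
  }
  run
}

# residual block on ad nodes
selectnet_resblock_nodes <- function(X, w1, b1, w2, b2) {
  h <- ad_relu(conv1d3_forward(X, w1, b1))
  h <- ad_relu(conv1d3_forward(h, w2, b2))
  ad_add(h, X)
}

# full forward on ad nodes. ps: lifted parameter nodes; run: running stats
# (mutated copies returned). Returns logits node plus per-step records.
selectnet_forward_nodes <- function(ps, Xn, config, run, training) {
  F <- config$feature_dim; d <- config$attn_dim
  x_step <- Xn
  Ms <- list(); S1s_rec <- list(); S2s_rec <- list(); M_nodes <- list()
  x_decision <- NULL
  for (t in seq_len(config$n_steps)) {
    p <- function(nm) ps[[paste0("s", t, "_", nm)]]
    h <- selectnet_resblock_nodes(Xn, p("rb1_w1"), p("rb1_b1"),
                                  p("rb1_w2"), p("rb1_b2"))
    # selection vectors are one F-vector per step, shared across the batch:
    # per-sample logits are averaged before the feature softmax. A
    # per-sample mask lets the network smuggle class information through the
    # mask values themselves, which destroys the importance signal.
    # Stage-1 logits come from the original input features; the
    # residual-transformed h feeds the decision stream below.
    z <- ad_relu(linear_forward(Xn, p("Wch"), p("bch")))
    S1 <- ad_colmeans(ad_gather_cols(z, seq_len(F)))  # first half: logits
    S1s <- ad_softmax_rows(S1)
    S2 <- selectnet_resblock_nodes(x_step, p("rb2_w1"), p("rb2_b1"),
                                   p("rb2_w2"), p("rb2_b2"))
    S2s <- ad_softmax_rows(ad_colmeans(S2))
    M <- ad_mul(S1s, S2s)
    # gate with the sum-normalized selection weights so selected features
    # keep O(1) magnitude (a raw two-softmax product is O(1/F^2), which
    # would starve the selected stream)
    Mn <- ad_mul_colvec(M, ad_reciprocal(ad_rowsums(M)))
    u <- ad_mul_rowvec(h, Mn)
    # per-feature attention on the selected stream: every decision path
    # passes through the selection mask; the step state steers the next
    # selection (S2 above) and evolves through the value-projection carry
    q <- linear_forward(u, p("Wq"), p("bq"))
    k <- linear_forward(u, p("Wk"), p("bk"))
    v <- linear_forward(u, p("Wv"), p("bv"))
    a <- ad_softmax_rows(ad_scale_const(ad_mul(q, k), 1 / sqrt(d)))
    vdec <- ad_mul(a, v)
    v_step <- linear_forward(x_step, p("Wv"), p("bv"))
    b1 <- bn_forward(ad_add(u, vdec), p("bn1"), p("bn1b"),
                     run[[paste0("s", t, "_bn1")]], training)
    run[[paste0("s", t, "_bn1")]] <- b1$run
    x_decision <- b1$out
    b2 <- bn_forward(ad_add(x_step, linear_forward(v_step, p("Wl"), p("bl"))),
                     p("bn2"), p("bn2b"),
                     run[[paste0("s", t, "_bn2")]], training)
    run[[paste0("s", t, "_bn2")]] <- b2$run
    x_step <- b2$out
    Ms[[t]] <- M$value; S1s_rec[[t]] <- S1s$value; S2s_rec[[t]] <- S2s$value
    M_nodes[[t]] <- M
  }
  logits <- linear_forward(x_decision, ps$Wc, ps$bc)
  list(logits = logits, run = run, M_nodes = M_nodes,
       record = list(S1 = S1s_rec, S2 = S2s_rec, M = Ms))
}

#' 1-D residual block (kernel-3 convolutions with identity skip)
#'
#' `out = ReLU(Conv(ReLU(Conv(x)))) + x`, with single-channel kernel-3
#' convolutions, padding 1. With all weights and biases zero the block is
#' the identity.
#'
#' @param x Numeric vector (or n x F matrix of row vectors).
#' @param w1,w2 Length-3 convolution kernels.
#' @param b1,b2 Scalar biases.
#' @return Same shape as `x`.
#' @export
res_block_1d <- function(x, w1 = c(0, 0, 0), b1 = 0, w2 = c(0, 0, 0),
                         b2 = 0) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  out <- selectnet_resblock_nodes(ad_const(X),
                                  ad_const(matrix(w1, 1L)), ad_const(b1),
                                  ad_const(matrix(w2, 1L)), ad_const(b2))$value
  if (is.matrix(x)) out else as.vector(out)
}

#' Choice block: two-stage softmax feature selection
#'
#' Stage 1 maps the input through a linear layer F -> 2F with ReLU and keeps
#' the first half as selection logits S1; Stage 2 passes the step state
#' through a residual block to give S2. Logits of both stages are averaged
#' over the batch, so the selection weights form one F-vector per step:
#' `M = softmax(S1) * softmax(S2)` (softmax over features). The output is
#' the input gated feature-wise by M.
#'
#' @param x Input row vector or n x F matrix.
#' @param x_step Step state, same shape.
#' @param W F x 2F stage-1 weight matrix (default zero: uniform selection).
#' @param b Length-2F stage-1 bias.
#' @param rb Stage-2 residual-block parameters:
#'   list(w1, b1, w2, b2) as in [res_block_1d()].
#' @param normalize Gate with M scaled to sum 1 (the training convention);
#'   set FALSE for the raw product of the two softmaxes.
#' @return List with `weighted` (same shape as `x`), the selection vector
#'   `M` (length F), and its two softmax factors `S1`, `S2`.
#' @export
choice_block <- function(x, x_step, W = NULL, b = NULL,
                         rb = list(w1 = c(0, 0, 0), b1 = 0,
                                   w2 = c(0, 0, 0), b2 = 0),
                         normalize = TRUE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  Xs <- if (is.matrix(x_step)) x_step else matrix(x_step, nrow = 1L)
  F <- ncol(X)
  if (is.null(W)) W <- matrix(0, F, 2L * F)
  if (is.null(b)) b <- rep(0, 2L * F)
  z <- ad_relu(linear_forward(ad_const(X), ad_const(W),
                              ad_const(matrix(b, 1L))))
  S1s <- ad_softmax_rows(ad_colmeans(ad_gather_cols(z, seq_len(F))))
  S2 <- selectnet_resblock_nodes(ad_const(Xs),
                                 ad_const(matrix(rb$w1, 1L)), ad_const(rb$b1),
                                 ad_const(matrix(rb$w2, 1L)), ad_const(rb$b2))
  S2s <- ad_softmax_rows(ad_colmeans(S2))
  M <- as.vector(S1s$value * S2s$value)
  gate <- if (normalize) M / sum(M) else M
  weighted <- sweep(X, 2L, gate, "*")
  if (!is.matrix(x)) weighted <- as.vector(weighted)
  list(weighted = weighted, M = M,
       S1 = as.vector(S1s$value), S2 = as.vector(S2s$value))
}

#' Attention block fusing the representation with the step state
#'
#' Per-feature attention: the query is a linear map of `x`, the key a linear
#' map of the step state, the value a linear map of `x`. The attention
#' weights are a softmax over features of the scaled elementwise product
#' `q * k`, and `v_decision = weights * v`, so the importance of each
#' feature is modulated by the carried step context. The decision output is
#' `BN(x + v_decision)` and the next step state is
#' `BN(x_step + Linear(v_step))` with `v_step` the value projection of
#' `x_step`. In evaluation mode (the default here) batch normalization uses
#' the provided running statistics.
#'
#' @param x Input n x F matrix (rows are samples).
#' @param x_step Step state, same shape.
#' @param params Named list: Wq, bq, Wk, bk, Wv, bv, Wl, bl, bn1, bn1b,
#'   bn2, bn2b (all F-shaped). Missing entries default to zero weights
#'   (bn scales to 1).
#' @param run Running statistics, as from `bn_state_new`; defaults to mean 0,
#'   variance 1.
#' @param attn_scale Softmax temperature divisor (default sqrt(F)).
#' @return List with `x_decision`, `x_step_next`, and the n x F attention
#'   weight matrix `weights` (rows sum to 1; with a single feature the
#'   weight is exactly 1).
#' @export
attention_block <- function(x, x_step, params = list(), run = NULL,
                            attn_scale = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  Xs <- if (is.matrix(x_step)) x_step else matrix(x_step, nrow = 1L)
  F <- ncol(X)
  if (is.null(attn_scale)) attn_scale <- sqrt(F)
  dft <- list(Wq = matrix(0, F, F), bq = matrix(0, 1, F),
              Wk = matrix(0, F, F), bk = matrix(0, 1, F),
              Wv = matrix(0, F, F), bv = matrix(0, 1, F),
              Wl = matrix(0, F, F), bl = matrix(0, 1, F),
              bn1 = matrix(1, 1, F), bn1b = matrix(0, 1, F),
              bn2 = matrix(1, 1, F), bn2b = matrix(0, 1, F))
  for (nm in names(params)) dft[[nm]] <- as_mat(params[[nm]])
  if (is.null(run)) run <- list(bn1 = bn_state_new(F), bn2 = bn_state_new(F))
  ps <- lapply(dft, ad_const)
  q <- linear_forward(ad_const(X), ps$Wq, ps$bq)
  k <- linear_forward(ad_const(Xs), ps$Wk, ps$bk)
  v <- linear_forward(ad_const(X), ps$Wv, ps$bv)
  a <- ad_softmax_rows(ad_scale_const(ad_mul(q, k), 1 / attn_scale))
  vdec <- ad_mul(a, v)
  v_step <- linear_forward(ad_const(Xs), ps$Wv, ps$bv)
  xd <- bn_forward(ad_add(ad_const(X), vdec), ps$bn1, ps$bn1b,
                   run$bn1, training = FALSE)$out
  xs <- bn_forward(ad_add(ad_const(Xs), linear_forward(v_step, ps$Wl, ps$bl)),
                   ps$bn2, ps$bn2b, run$bn2, training = FALSE)$out
  list(x_decision = xd$value, x_step_next = xs$value, weights = a$value)
}

#' Forward pass of a trained SelectNet (evaluation mode)
#'
#' @param X n x F matrix of normalized features (rows in \[0, 1\]).
#' @param model A `selectnet_model` from [train_selectnet()].
#' @return List with `probs` (n x K, rows sum to 1), `record` (per-step S1,
#'   S2 and M matrices) and `importance` (F-vector summing to 1).
#' @export
selectnet_forward <- function(X, model) {
  stopifnot(inherits(model, "selectnet_model"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("input contains non-finite values")
  ps <- lapply(model$values, ad_const)
  fw <- selectnet_forward_nodes(ps, ad_const(X), model$config, model$run,
                                training = FALSE)
  z <- fw$logits$value
  z <- z - apply(z, 1, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  Msum <- Reduce(`+`, lapply(fw$record$M, colMeans))
  importance <- Msum / sum(Msum)
  names(importance) <- colnames(X)
  list(probs = probs, record = fw$record, importance = importance)
}

#' Train SelectNet on a normalized feature table
#'
#' Minimizes soft-target cross-entropy with Adam. Fully deterministic given
#' the config seed.
#'
#' @param table n x F matrix of normalized features.
#' @param labels Binary vector, or an n x K matrix of soft targets (for
#'   example from [smooth_labels()]).
#' @param config A [selectnet_config()].
#' @return Object of class `selectnet_model` with fields `values`
#'   (parameters), `run` (batch-norm running statistics), `config`,
#'   `loss_log` (per-epoch mean loss) and `importance`.
#' @export
train_selectnet <- function(table, labels, config) {
  stopifnot(inherits(config, "selectnet_config"))
  X <- as.matrix(table)
  K <- config$n_classes
  targets <- if (is.matrix(labels)) labels else smooth_labels(labels, 0, K)
  if (is.null(dim(labels)) && length(unique(labels)) < 2) {
    stop("training labels contain a single class")
  }
  n <- nrow(X)
  with_seed(config$seed, {
    values <- selectnet_init_values(config)
    run <- selectnet_init_state(config)
    opt <- adam_init(values)
    loss_log <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        ps <- ad_lift(values)
        fw <- selectnet_forward_nodes(ps, ad_const(X[idx, , drop = FALSE]),
                                      config, run, training = TRUE)
        run <- fw$run
        loss <- ad_softmax_xent(fw$logits, targets[idx, , drop = FALSE])
        if (config$sparsity_weight > 0) {
          # mean entropy of the row-normalized selection weights
          for (M in fw$M_nodes) {
            Mn <- ad_mul_colvec(M, ad_reciprocal(ad_rowsums(M)))
            ent <- ad_scale_const(ad_mean(ad_mul(Mn, ad_log(Mn))),
                                  -ncol(X))
            loss <- ad_add(loss, ad_scale_const(
              ent, config$sparsity_weight / config$n_steps))
          }
        }
        ad_backward(loss)
        st <- adam_step(opt, values, ad_grads(ps), lr = config$learning_rate,
                        weight_decay = config$weight_decay)
        opt <- st$state; values <- st$values
        losses <- c(losses, loss$value[1])
      }
      loss_log[epoch] <- mean(losses)
    }
    model <- structure(list(values = values, run = run, config = config,
                            loss_log = loss_log),
                       class = "selectnet_model")
    model$importance <- selectnet_forward(X, model)$importance
    model
  })
}

#' Keep the k features with highest aggregated importance
#'
#' Ties are broken in favor of the lower column index.
#'
#' @param model A trained `selectnet_model`.
#' @param table n x F feature matrix (same column order as training).
#' @param k Number of features to keep (at most F).
#' @return List with `table` (n x k, columns ordered by decreasing
#'   importance) and `indices` (original column indices).
#' @export
select_top_k <- function(model, table, k) {
  stopifnot(inherits(model, "selectnet_model"))
  table <- as.matrix(table)
  F <- length(model$importance)
  if (k > F) stop("k must not exceed the number of features")
  ord <- order(-model$importance, seq_len(F))
  idx <- ord[seq_len(k)]
  list(table = table[, idx, drop = FALSE], indices = idx)
}
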