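# Branch B: residual CNN image classifier with a grouped channel/spatial
# ("shuttle") attention block inside every residual unit. The block splits
# the channels into g groups, halves each group, runs channel attention on
# one half and spatial attention on the other, concatenates everything back
# and applies a channel shuffle so information crosses group boundaries.
#
# Feature maps on the public surface are C x H x W arrays; internally they
# are (N*H*W) x C matrices (see nn-layers.R).

#' Configuration for the shuttle-attention CNN branch
#'
#' @param groups Number of channel groups g in each shuttle block. Channel
#'   counts at every insertion point must be divisible by 2g.
#' @param backbone `"resnet-mini"` (3 stages of 16/32/64 channels, one basic
#'   unit each; desk-scale) or `"resnet50"` (bottleneck units 3/4/6/3).
#' @param input_size Square input side in pixels.
#' @param n_classes Number of output classes.
#' @param learning_rate Initial Adam learning rate (cosine-annealed to 0
#'   over training).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param attention_pair `"channel_spatial"` (channel attention on one half,
#'   spatial attention on the other) or `"channel_channel"` (channel
#'   attention on both halves).
#' @param seed Integer seed.
#' @return An object of class `shuttle_config`.
#' @export
shuttle_config <- function(groups = 4L, backbone = "resnet-mini",
                           input_size = if (backbone == "resnet50") 224L else 64L,
                           n_classes = 2L,
                           learning_rate = if (backbone == "resnet50") 1e-4 else 1e-3,
                           epochs = 5L, batch_size = 32L,
                           attention_pair = "channel_spatial", seed = 1L) {
  backbone <- match.arg(backbone, c("resnet-mini", "resnet50"))
  attention_pair <- match.arg(attention_pair,
                              c("channel_spatial", "channel_channel"))
  stopifnot(groups >= 1, input_size >= 8, n_classes >= 2)
  structure(list(groups = as.integer(groups), backbone = backbone,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 attention_pair = attention_pair, seed = as.integer(seed)),
            class = "shuttle_config")
}

# ---- public array-level operations ------------------------------------------

fmap_to_mat <- function(x) {
  d <- dim(x)  # C, H, W
  matrix(aperm(x, c(3, 2, 1)), d[2] * d[3], d[1])
}

mat_to_fmap <- function(m, C, H, W) {
  aperm(array(m, c(W, H, C)), c(3, 2, 1))
}

#' Split a feature map into g channel groups, each halved
#'
#' Channel-contiguous partition; concatenating the halves back in order
#' reproduces the input exactly.
#'
#' @param x C x H x W array with C divisible by 2g.
#' @param g Number of groups.
#' @return List of g elements, each `list(k1, k2)` of (C/2g) x H x W arrays.
#' @export
group_split <- function(x, g) {
  C <- dim(x)[1]
  if (C %% (2L * g) != 0L) stop("channel count must be divisible by 2*groups")
  h <- C %/% (2L * g)
  lapply(seq_len(g), function(j) {
    base <- (j - 1L) * 2L * h
    list(k1 = x[base + seq_len(h), , , drop = FALSE],
         k2 = x[base + h + seq_len(h), , , drop = FALSE])
  })
}

#' Channel-shuffle permutation of channel indices
#'
#' Reshape the C channels to g x C/g, transpose, flatten. Returns the source
#' index for each output position, so `x[perm]` applies the shuffle.
#'
#' @param C Number of channels (divisible by g).
#' @param g Number of groups.
#' @return Integer vector of length C.
#' @export
channel_shuffle_perm <- function(C, g) {
  if (C %% g != 0L) stop("channel count must be divisible by groups")
  j <- seq_len(C) - 1L
  (j %% g) * (C %/% g) + j %/% g + 1L   # source channel of output slot j
}

#' Channel shuffle of a feature map
#'
#' Pure channel permutation (values untouched); `g = 1` is the identity, and
#' shuffling with g followed by C/g restores the original order.
#'
#' @param x C x H x W array.
#' @param g Number of groups (divides C).
#' @return Array of the same shape with permuted channels.
#' @export
channel_shuffle <- function(x, g) {
  perm <- channel_shuffle_perm(dim(x)[1], g)
  x[perm, , , drop = FALSE]
}

#' Channel attention on a sub-feature
#'
#' Per-channel weights `sigmoid(Linear(GAP(x)))` (single linear layer),
#' broadcast over the spatial grid.
#'
#' @param x h x H x W array.
#' @param W h x h linear weight (default zero, giving weights sigmoid(0) = 0.5).
#' @param b Length-h bias.
#' @return Array of the same shape.
#' @export
channel_attention <- function(x, W = NULL, b = NULL) {
  h <- dim(x)[1]
  if (is.null(W)) W <- matrix(0, h, h)
  if (is.null(b)) b <- rep(0, h)
  gapv <- apply(x, 1, mean)
  w <- 1 / (1 + exp(-(as.vector(gapv %*% W) + b)))
  x * w
}

#' Spatial attention on a sub-feature
#'
#' Group-normalize the sub-map (one group spanning all its channels), map to
#' a single channel with a 1x1 convolution, squash with a sigmoid and
#' multiply the per-position weights back, broadcast over channels.
#'
#' @param x h x H x W array.
#' @param gamma,beta Per-channel affine parameters of the normalization.
#' @param w Length-h 1x1-convolution weights (default zero: uniform weights
#'   sigmoid(b)).
#' @param b Scalar bias.
#' @return Array of the same shape.
#' @export
spatial_attention <- function(x, gamma = NULL, beta = NULL, w = NULL, b = 0) {
  h <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  if (is.null(gamma)) gamma <- rep(1, h)
  if (is.null(beta)) beta <- rep(0, h)
  if (is.null(w)) w <- rep(0, h)
  m <- mean(x)
  v <- mean((x - m)^2)
  xn <- (x - m) / sqrt(v + 1e-5)
  xn <- xn * gamma + beta     # gamma/beta recycle over the channel dim
  logit <- apply(xn * w, c(2, 3), sum) + b
  wt <- 1 / (1 + exp(-logit))
  out <- x
  for (c_ in seq_len(h)) out[c_, , ] <- x[c_, , ] * wt
  out
}

#' Parameters for one shuttle block
#'
#' @param C Channel count at the insertion point.
#' @param g Number of groups.
#' @return Named list of per-group parameter matrices (channel-attention
#'   linear weights for both halves, group-norm affine, 1x1 spatial weights),
#'   zero-initialized biases and Glorot-uniform weights drawn from the
#'   current RNG stream.
#' @export
shuttle_params_new <- function(C, g) {
  if (C %% (2L * g) != 0L) stop("channel count must be divisible by 2*groups")
  h <- C %/% (2L * g)
  vals <- list()
  for (j in seq_len(g)) {
    p <- function(nm) paste0("g", j, "_", nm)
    vals[[p("cw")]] <- nn_init(h, h); vals[[p("cb")]] <- matrix(0, 1, h)
    vals[[p("cw2")]] <- nn_init(h, h); vals[[p("cb2")]] <- matrix(0, 1, h)
    vals[[p("gng")]] <- matrix(1, 1, h); vals[[p("gnb")]] <- matrix(0, 1, h)
    vals[[p("sw")]] <- nn_init(h, 1L); vals[[p("sb")]] <- matrix(0, 1, 1)
  }
  vals
}

# shuttle block on ad nodes. X: (N*HW) x C node; ps: accessor returning the
# node for a given local name; group: row-group vector; clamp_unit replaces
# both attention maps by 1 (used to check the pure-permutation property).
shuttle_forward_nodes <- function(X, ps, g, N, HW, clamp_unit = FALSE,
                                  pair = "channel_spatial") {
  C <- ncol(X$value)
  h <- C %/% (2L * g)
  group <- row_group(N, HW)
  parts <- vector("list", 2L * g)
  for (j in seq_len(g)) {
    p <- function(nm) ps(paste0("g", j, "_", nm))
    base <- (j - 1L) * 2L * h
    Xk1 <- ad_gather_cols(X, base + seq_len(h))
    Xk2 <- ad_gather_cols(X, base + h + seq_len(h))
    if (clamp_unit) {
      a1 <- Xk1
      a2 <- Xk2
    } else {
      gapv <- gap_forward(Xk1, group, N, HW)
      wch <- ad_sigmoid(linear_forward(gapv, p("cw"), p("cb")))
      a1 <- ad_mul(Xk1, ad_gather_rows(wch, group))
      if (pair == "channel_channel") {
        gapv2 <- gap_forward(Xk2, group, N, HW)
        wch2 <- ad_sigmoid(linear_forward(gapv2, p("cw2"), p("cb2")))
        a2 <- ad_mul(Xk2, ad_gather_rows(wch2, group))
      } else {
        xn <- gn_forward(Xk2, group, N, HW, p("gng"), p("gnb"))
        wsp <- ad_sigmoid(ad_add_scalar(ad_matmul(xn, p("sw")), p("sb")))
        a2 <- ad_mul_colvec(Xk2, wsp)
      }
    }
    parts[[2L * j - 1L]] <- a1
    parts[[2L * j]] <- a2
  }
  ad_gather_cols(ad_cbind_list(parts), channel_shuffle_perm(C, g))
}

#' Apply one shuttle block to a feature map
#'
#' Per group: channel attention on the first half, spatial attention on the
#' second (or channel attention on both, see `pair`), concatenation, then a
#' channel shuffle with the same g.
#'
#' @param x C x H x W array, C divisible by 2g.
#' @param params Parameters from [shuttle_params_new()].
#' @param g Number of groups.
#' @param clamp_unit If TRUE, both attention maps are forced to 1, reducing
#'   the block to a pure channel permutation.
#' @param pair `"channel_spatial"` or `"channel_channel"`.
#' @return Array of the same shape.
#' @export
shuttle_block <- function(x, params = NULL, g = 4L, clamp_unit = FALSE,
                          pair = "channel_spatial") {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  if (C %% (2L * g) != 0L) stop("channel count must be divisible by 2*groups")
  if (is.null(params)) params <- with_seed(1L, shuttle_params_new(C, g))
  nodes <- lapply(params, ad_const)
  out <- shuttle_forward_nodes(ad_const(fmap_to_mat(x)),
                               function(nm) nodes[[nm]],
                               g, 1L, H * W, clamp_unit, pair)
  mat_to_fmap(out$value, C, H, W)
}

# ---- backbone construction --------------------------------------------------

backbone_spec <- function(config) {
  if (config$backbone == "resnet-mini") {
    # stride-2 stem: stage 1 runs at half the input resolution, the usual
    # economy for small-input residual networks
    list(stem = list(k = 3L, stride = 2L, C = 16L, pool = FALSE),
         stages = list(list(C = 16L, n = 1L, stride = 1L),
                       list(C = 32L, n = 1L, stride = 2L),
                       list(C = 64L, n = 1L, stride = 2L)),
         bottleneck = FALSE)
  } else {
    list(stem = list(k = 7L, stride = 2L, C = 64L, pool = TRUE),
         stages = list(list(C = 64L, n = 3L, stride = 1L),
                       list(C = 128L, n = 4L, stride = 2L),
                       list(C = 256L, n = 6L, stride = 2L),
                       list(C = 512L, n = 3L, stride = 2L)),
         bottleneck = TRUE)
  }
}

# enumerate residual units with channel/stride bookkeeping
backbone_units <- function(config) {
  spec <- backbone_spec(config)
  expand <- if (spec$bottleneck) 4L else 1L
  Cin <- spec$stem$C
  units <- list()
  u <- 0L
  for (s in spec$stages) {
    Cout <- s$C * expand
    for (i in seq_len(s$n)) {
      u <- u + 1L
      units[[u]] <- list(name = paste0("u", u), Cin = Cin, Cmid = s$C,
                         Cout = Cout, stride = if (i == 1L) s$stride else 1L)
      Cin <- Cout
    }
  }
  list(spec = spec, units = units, C_final = Cin)
}

#' Build the shuttle-attention image classifier
#'
#' A residual CNN with a shuttle block appended inside every residual unit
#' (after the last convolution of the unit, before the skip addition) and a
#' linear + softmax head.
#'
#' @param config A [shuttle_config()].
#' @return Object of class `cnn_model` with `values` (parameters), `run`
#'   (batch-norm running statistics) and `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "shuttle_config"))
  bb <- backbone_units(config)
  g <- config$groups
  with_seed(config$seed, {
    vals <- list(); run <- list()
    st <- bb$spec$stem
    vals$stem_w <- conv_w_init(st$k, 3L, st$C)
    vals$stem_b <- matrix(0, 1, st$C)
    vals$stem_bng <- matrix(1, 1, st$C); vals$stem_bnb <- matrix(0, 1, st$C)
    run$stem_bn <- bn_state_new(st$C)
    for (un in bb$units) {
      nm <- un$name
      if (bb$spec$bottleneck) {
        vals[[paste0(nm, "_c1_w")]] <- conv_w_init(1L, un$Cin, un$Cmid)
        vals[[paste0(nm, "_c2_w")]] <- conv_w_init(3L, un$Cmid, un$Cmid)
        vals[[paste0(nm, "_c3_w")]] <- conv_w_init(1L, un$Cmid, un$Cout)
        for (cc in c("c1", "c2", "c3")) {
          Cb <- if (cc == "c3") un$Cout else un$Cmid
          vals[[paste0(nm, "_", cc, "_b")]] <- matrix(0, 1, Cb)
          vals[[paste0(nm, "_", cc, "_bng")]] <- matrix(1, 1, Cb)
          vals[[paste0(nm, "_", cc, "_bnb")]] <- matrix(0, 1, Cb)
          run[[paste0(nm, "_", cc, "_bn")]] <- bn_state_new(Cb)
        }
      } else {
        vals[[paste0(nm, "_c1_w")]] <- conv_w_init(3L, un$Cin, un$Cout)
        vals[[paste0(nm, "_c2_w")]] <- conv_w_init(3L, un$Cout, un$Cout)
        for (cc in c("c1", "c2")) {
          vals[[paste0(nm, "_", cc, "_b")]] <- matrix(0, 1, un$Cout)
          vals[[paste0(nm, "_", cc, "_bng")]] <- matrix(1, 1, un$Cout)
          vals[[paste0(nm, "_", cc, "_bnb")]] <- matrix(0, 1, un$Cout)
          run[[paste0(nm, "_", cc, "_bn")]] <- bn_state_new(un$Cout)
        }
      }
      if (un$Cin != un$Cout || un$stride != 1L) {
        vals[[paste0(nm, "_sk_w")]] <- conv_w_init(1L, un$Cin, un$Cout)
        vals[[paste0(nm, "_sk_b")]] <- matrix(0, 1, un$Cout)
        vals[[paste0(nm, "_sk_bng")]] <- matrix(1, 1, un$Cout)
        vals[[paste0(nm, "_sk_bnb")]] <- matrix(0, 1, un$Cout)
        run[[paste0(nm, "_sk_bn")]] <- bn_state_new(un$Cout)
      }
      sp <- shuttle_params_new(un$Cout, g)
      for (k in names(sp)) vals[[paste0(nm, "_sh_", k)]] <- sp[[k]]
    }
    vals$head_w <- nn_init(bb$C_final, config$n_classes)
    vals$head_b <- matrix(0, 1, config$n_classes)
    structure(list(values = vals, run = run, config = config, units = bb),
              class = "cnn_model")
  })
}

# cached im2col index tables, keyed by geometry
idx_cache_get <- function(cache, N, H, W, k, stride) {
  key <- paste(N, H, W, k, stride, sep = "_")
  if (is.null(cache[[key]])) {
    cache[[key]] <- im2col_idx(N, H, W, k, stride)
  }
  cache[[key]]
}

# 3x3 stride-2 max pooling via kk pairwise maxima (padding excluded by
# using a very negative pad value)
pool3s2_forward <- function(X, idxinfo) {
  kk <- idxinfo$k^2
  Xp <- ad_pad_row0(X)
  # make the padding row strongly negative so it never wins the max
  Xp$value[1L, ] <- -1e30
  out <- NULL
  for (j in seq_len(kk)) {
    slice <- ad_gather_rows(Xp, idxinfo$idx[, j] + 1L)
    out <- if (is.null(out)) slice else ad_pmax(out, slice)
  }
  out
}

# full forward: Xn node (N*S*S) x 3, returns logits node and updated run
cnn_forward_nodes <- function(ps, Xn, model, N, run, training, cache) {
  cfg <- model$config
  bb <- model$units
  g <- cfg$groups
  S <- cfg$input_size
  pget <- function(nm) ps[[nm]]
  st <- bb$spec$stem
  ii <- idx_cache_get(cache, N, S, S, st$k, st$stride)
  h <- conv2d_forward(Xn, ii, ps$stem_w, ps$stem_b)
  bnres <- bn_forward(h, ps$stem_bng, ps$stem_bnb, run$stem_bn, training)
  run$stem_bn <- bnres$run
  h <- ad_relu(bnres$out)
  H <- ii$Ho
  if (st$pool) {
    ip <- idx_cache_get(cache, N, H, H, 3L, 2L)
    h <- pool3s2_forward(h, ip)
    H <- ip$Ho
  }
  for (un in bb$units) {
    nm <- un$name
    Hin <- H
    conv_bn_relu <- function(x, cc, k, stride, Hcur, relu = TRUE) {
      ii <- idx_cache_get(cache, N, Hcur, Hcur, k, stride)
      y <- conv2d_forward(x, ii, ps[[paste0(nm, "_", cc, "_w")]],
                          ps[[paste0(nm, "_", cc, "_b")]])
      key <- paste0(nm, "_", cc, "_bn")
      br <- bn_forward(y, ps[[paste0(nm, "_", cc, "_bng")]],
                       ps[[paste0(nm, "_", cc, "_bnb")]],
                       run[[key]], training)
      run[[key]] <<- br$run
      list(out = if (relu) ad_relu(br$out) else br$out, Ho = ii$Ho)
    }
    if (bb$spec$bottleneck) {
      r1 <- conv_bn_relu(h, "c1", 1L, 1L, Hin)
      r2 <- conv_bn_relu(r1$out, "c2", 3L, un$stride, Hin)
      r3 <- conv_bn_relu(r2$out, "c3", 1L, 1L, r2$Ho, relu = FALSE)
      body <- r3$out; Hout <- r2$Ho
    } else {
      r1 <- conv_bn_relu(h, "c1", 3L, un$stride, Hin)
      r2 <- conv_bn_relu(r1$out, "c2", 3L, 1L, r1$Ho, relu = FALSE)
      body <- r2$out; Hout <- r1$Ho
    }
    body <- shuttle_forward_nodes(body, function(k2) ps[[paste0(nm, "_sh_", k2)]],
                                  g, N, Hout * Hout,
                                  pair = cfg$attention_pair)
    if (!is.null(ps[[paste0(nm, "_sk_w")]])) {
      ii <- idx_cache_get(cache, N, Hin, Hin, 1L, un$stride)
      sk <- conv2d_forward(h, ii, ps[[paste0(nm, "_sk_w")]],
                           ps[[paste0(nm, "_sk_b")]])
      key <- paste0(nm, "_sk_bn")
      br <- bn_forward(sk, ps[[paste0(nm, "_sk_bng")]],
                       ps[[paste0(nm, "_sk_bnb")]], run[[key]], training)
      run[[key]] <- br$run
      sk <- br$out
    } else {
      sk <- h
    }
    h <- ad_relu(ad_add(body, sk))
    H <- Hout
  }
  pooled <- gap_forward(h, row_group(N, H * H), N, H * H)
  logits <- linear_forward(pooled, ps$head_w, ps$head_b)
  list(logits = logits, run = run)
}

# mask, resize and scale one image to the model input: returns (S*S) x 3
prep_image <- function(image, mask, input_size) {
  img <- image
  for (ch in 1:3) img[, , ch] <- img[, , ch] * mask
  if (nrow(mask) != input_size || ncol(mask) != input_size) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("EBImage is required to resize images to the model input size")
    }
    img <- as.array(EBImage::resize(img, w = input_size, h = input_size))
  }
  img <- img / 255 - 0.5
  fmap_to_mat(aperm(img, c(3, 1, 2)))
}

#' Predict class probabilities with a trained CNN model
#'
#' @param model A `cnn_model`.
#' @param dataset A `labeled_image_set` (masks are applied before scoring).
#' @param indices Which images to score (default all).
#' @return Matrix n x K of class probabilities (rows sum to 1).
#' @export
predict_cnn <- function(model, dataset, indices = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.null(indices)) indices <- seq_along(dataset$images)
  S <- model$config$input_size
  cache <- new.env(parent = emptyenv())
  out <- matrix(NA_real_, length(indices), model$config$n_classes)
  bs <- model$config$batch_size
  for (start in seq(1L, length(indices), by = bs)) {
    sel <- indices[start:min(start + bs - 1L, length(indices))]
    Xb <- do.call(rbind, lapply(sel, function(i) {
      prep_image(dataset$images[[i]], dataset$masks[[i]], S)
    }))
    ps <- lapply(model$values, ad_const)
    fw <- cnn_forward_nodes(ps, ad_const(Xb), model, length(sel),
                            model$run, training = FALSE, cache)
    z <- fw$logits$value
    z <- z - apply(z, 1, max)
    e <- exp(z)
    out[start:(start + length(sel) - 1L), ] <- e / rowSums(e)
  }
  out
}

#' Train the CNN branch and score held-out images
#'
#' Cross-entropy training (soft targets allowed) with Adam and a
#' cosine-annealed learning rate. The background outside each mask is zeroed
#' before training. Fully deterministic given the config seed.
#'
#' @param dataset A `labeled_image_set`.
#' @param config A [shuttle_config()].
#' @param train_idx Indices used for training (default all).
#' @param score_idx Indices to score after training (default `train_idx`'s
#'   complement, or all images when no complement exists).
#' @param soft_targets Optional n x K soft-label matrix aligned with
#'   `dataset` rows; defaults to one-hot labels.
#' @return List with `model` (a `cnn_model`), `scores` (probability of the
#'   at-risk class for `score_idx`), `score_idx` and `loss_log`.
#' @export
train_cnn_branch <- function(dataset, config, train_idx = NULL,
                             score_idx = NULL, soft_targets = NULL) {
  stopifnot(inherits(dataset, "labeled_image_set"),
            inherits(config, "shuttle_config"))
  n <- length(dataset$images)
  if (is.null(train_idx)) train_idx <- seq_len(n)
  if (is.null(score_idx)) {
    score_idx <- setdiff(seq_len(n), train_idx)
    if (length(score_idx) == 0L) score_idx <- seq_len(n)
  }
  y <- dataset$labels
  if (length(unique(y[train_idx])) < 2) {
    stop("training labels contain a single class")
  }
  K <- config$n_classes
  targets <- if (is.null(soft_targets)) smooth_labels(y, 0, K) else soft_targets
  S <- config$input_size
  prepped <- lapply(train_idx, function(i) {
    prep_image(dataset$images[[i]], dataset$masks[[i]], S)
  })
  model <- build_model(config)
  cache <- new.env(parent = emptyenv())
  nt <- length(train_idx)
  steps_total <- config$epochs * ceiling(nt / config$batch_size)
  loss_log <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    opt <- adam_init(model$values)
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(nt)
      losses <- c()
      for (start in seq(1L, nt, by = config$batch_size)) {
        sel <- perm[start:min(start + config$batch_size - 1L, nt)]
        if (length(sel) < 2L) next
        step <- step + 1L
        lr <- config$learning_rate * 0.5 *
          (1 + cos(pi * (step - 1L) / steps_total))
        Xb <- do.call(rbind, prepped[sel])
        ps <- ad_lift(model$values)
        fw <- cnn_forward_nodes(ps, ad_const(Xb), model, length(sel),
                                model$run, training = TRUE, cache)
        model$run <- fw$run
        loss <- ad_softmax_xent(fw$logits,
                                targets[train_idx[sel], , drop = FALSE])
        ad_backward(loss)
        st <- adam_step(opt, model$values, ad_grads(ps), lr = lr)
        opt <- st$state
        model$values <- st$values
        losses <- c(losses, loss$value[1])
      }
      loss_log[epoch] <- mean(losses)
    }
  })
  probs <- predict_cnn(model, dataset, score_idx)
  list(model = model, scores = probs[, 2], score_idx = score_idx,
       loss_log = loss_log)
}
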