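#' Model configuration
#'
#' Collects every architectural hyperparameter of the network. The published
#' per-dataset values (see [load_model_profile()]) fix the input geometry,
#' filter count, stem kernel, the dilated kernel pair, dilation rates and
#' residual/GRU depths; `fc_width` and `se_width` are not published and the
#' shipped profiles resolve them so that the per-layer ledger reproduces the
#' published parameter totals exactly (the derivation is recorded in each
#' profile file).
#'
#' @param n_channels,window_length input geometry (channels x timesteps).
#' @param n_classes number of activity classes.
#' @param filters feature channels used throughout the trunk.
#' @param n_residual_blocks depth of the plain convolutional branch.
#' @param n_gru_layers depth of the temporal branch (currently 2 supported).
#' @param stem_kernel kernel length of the stem convolution.
#' @param dilated_kernels length-2 integer vector; the four dilated layers use
#'   kernels `(k1, k1, k2, k2)`.
#' @param dilation_rates dilation of each dilated layer.
#' @param paddings documented padding values carried alongside
#'   `dilation_rates`; convolutions are built length-preserving, so these are
#'   informational and the constructor only checks the lengths agree.
#' @param se_width bottleneck width of the squeeze-excitation sub-network.
#' @param fc_width width of the classifier's hidden fully connected layer.
#' @param dropout_rate dropout applied to the hidden FC layer during training.
#' @param attention_scale `"n"` rescales attention-weighted sequences by their
#'   length (keeping feature magnitude stable), `"none"` leaves the softmax
#'   weighting as is.
#' @param fusion `"sum"` (default) adds the three branch outputs; `"concat"`
#'   is intentionally not offered because it would change the published
#'   channel counts.
#' @param enable_casb,enable_tfeb,enable_msfeb ablation switches; a disabled
#'   block is bypassed with the identity. Disabling all three leaves the
#'   stem + residual branch baseline.
#' @return A `model_config` list.
#' @export
model_config <- function(n_channels, window_length, n_classes,
                         filters = 16L, n_residual_blocks = 2L, n_gru_layers = 2L,
                         stem_kernel = 5L, dilated_kernels = c(3L, 2L),
                         dilation_rates = c(1L, 2L, 4L, 6L),
                         paddings = c(2L, 4L, 8L, 10L),
                         se_width = max(1L, filters %/% 4L),
                         fc_width = 64L, dropout_rate = 0.5,
                         attention_scale = c("n", "none"),
                         enable_casb = TRUE, enable_tfeb = TRUE, enable_msfeb = TRUE) {
  attention_scale <- match.arg(attention_scale)
  stop_if_not(length(dilated_kernels) == 2L, "dilated_kernels must be a pair")
  stop_if_not(length(paddings) == length(dilation_rates),
              "paddings and dilation_rates must have equal length")
  stop_if_not(filters >= 1L, "filters must be positive")
  stop_if_not(n_gru_layers == 2L, "the temporal branch is defined with 2 GRU layers")
  stop_if_not(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must lie in [0,1)")
  structure(list(n_channels = as.integer(n_channels),
                 window_length = as.integer(window_length),
                 n_classes = as.integer(n_classes), filters = as.integer(filters),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 n_gru_layers = as.integer(n_gru_layers),
                 stem_kernel = as.integer(stem_kernel),
                 dilated_kernels = as.integer(dilated_kernels),
                 dilation_rates = as.integer(dilation_rates),
                 paddings = as.integer(paddings),
                 se_width = as.integer(se_width), fc_width = as.integer(fc_width),
                 dropout_rate = dropout_rate, attention_scale = attention_scale,
                 enable_casb = isTRUE(enable_casb), enable_tfeb = isTRUE(enable_tfeb),
                 enable_msfeb = isTRUE(enable_msfeb)),
            class = "model_config")
}

msfeb_kernels <- function(config) {
  k <- config$dilated_kernels
  rep(k, each = ceiling(length(config$dilation_rates) / 2))[
    seq_along(config$dilation_rates)]
}

uinit <- function(..., fan_in, scale = 1) {
  array(scale * stats::runif(prod(...), -1, 1) / sqrt(fan_in), dim = c(...))
}

#' Initialize model parameters
#'
#' Uniform fan-in initialization of every trainable array of the network, in a
#' fixed traversal order so a given seed yields identical parameters across
#' platforms. Batch-norm scale/shift start at 1/0; running statistics live in
#' the separate `state` list returned alongside (they are buffers, not
#' trainable parameters).
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return `list(params =, state =)`.
#' @export
init_model <- function(config, seed = 1L) {
  set.seed(seed)
  f <- config$filters
  p <- list()
  p$stem <- list(W = uinit(f, config$n_channels, config$stem_kernel,
                           fan_in = config$n_channels * config$stem_kernel))
  if (config$enable_tfeb) {
    gru_init <- function(fin) list(
      W_ih = uinit(3L * f, fin, fan_in = f),
      W_hh = uinit(3L * f, f, fan_in = f),
      b_ih = as.vector(uinit(3L * f, 1L, fan_in = f)),
      b_hh = as.vector(uinit(3L * f, 1L, fan_in = f)))
    p$gru1 <- gru_init(f)
    p$gru2 <- gru_init(f)
    p$attn <- list(w = uinit(1L, f, fan_in = f), b = 0)
  }
  if (config$enable_msfeb) {
    ks <- msfeb_kernels(config)
    p$msfeb <- lapply(ks, function(k) list(
      W = uinit(f, f, k, fan_in = f * k), gamma = rep(1, f), beta = rep(0, f)))
  }
  p$res <- lapply(seq_len(config$n_residual_blocks), function(i) list(
    W1 = uinit(f, f, 1L, fan_in = f), gamma1 = rep(1, f), beta1 = rep(0, f),
    W2 = uinit(f, f, 1L, fan_in = f), gamma2 = rep(1, f), beta2 = rep(0, f)))
  if (config$enable_casb) {
    h <- config$se_width
    p$casb <- list(W1 = uinit(h, f, fan_in = f),
                   b1 = as.vector(uinit(h, 1L, fan_in = f)),
                   W2 = uinit(f, h, fan_in = h),
                   b2 = as.vector(uinit(f, 1L, fan_in = h)))
  }
  # the output layer starts an order of magnitude smaller, so an untrained
  # network predicts near-uniform class probabilities (initial cross-entropy
  # close to log(n_classes))
  p$head <- list(W_fc1 = uinit(config$fc_width, 2L * f, fan_in = 2L * f),
                 b_fc1 = as.vector(uinit(config$fc_width, 1L, fan_in = 2L * f)),
                 W_fc2 = uinit(config$n_classes, config$fc_width,
                               fan_in = config$fc_width, scale = 0.1),
                 b_fc2 = as.vector(uinit(config$n_classes, 1L,
                                         fan_in = config$fc_width, scale = 0.1)))
  state <- init_bn_state(config)
  list(params = p, state = state)
}

init_bn_state <- function(config) {
  f <- config$filters
  st <- list()
  if (config$enable_msfeb)
    st$msfeb <- lapply(msfeb_kernels(config),
                       function(k) list(rmean = rep(0, f), rvar = rep(1, f)))
  st$res <- lapply(seq_len(config$n_residual_blocks), function(i)
    list(rmean1 = rep(0, f), rvar1 = rep(1, f),
         rmean2 = rep(0, f), rvar2 = rep(1, f)))
  st
}

# ---- full forward pass ------------------------------------------------------

# x: (C, T, B). Returns probs (K, B), cache for backward, updated state.
model_forward <- function(x, params, config, state, training = FALSE) {
  cache <- list()
  stem <- conv1d_forward(x, params$stem$W, 1L)
  s <- stem$y
  cache$stem <- stem$cache

  if (config$enable_tfeb) {
    g1 <- gru_layer_forward(s, params$gru1)
    g2 <- gru_layer_forward(g1$y, params$gru2)
    scale <- if (config$attention_scale == "n") config$window_length else 1
    at <- attention_forward(g2$y, params$attn$w, params$attn$b, scale)
    tfeb <- at$y
    cache$tfeb <- list(g1 = g1$cache, g2 = g2$cache, at = at$cache)
  } else tfeb <- s

  if (config$enable_msfeb) {
    m <- s + tfeb
    mcache <- vector("list", length(params$msfeb))
    for (i in seq_along(params$msfeb)) {
      cv <- conv1d_forward(m, params$msfeb[[i]]$W, config$dilation_rates[i])
      bn <- bn_forward(cv$y, params$msfeb[[i]]$gamma, params$msfeb[[i]]$beta,
                       state$msfeb[[i]]$rmean, state$msfeb[[i]]$rvar, training)
      state$msfeb[[i]]$rmean <- bn$rmean; state$msfeb[[i]]$rvar <- bn$rvar
      pre <- bn$y
      m2 <- relu(pre)
      mcache[[i]] <- list(cv = cv$cache, bn = bn$cache, pre = pre)
      m <- m2
    }
    msfeb <- m
    cache$msfeb <- mcache
  } else msfeb <- s + tfeb  # identity bypass on the block's input

  r <- s
  rcache <- vector("list", config$n_residual_blocks)
  for (i in seq_len(config$n_residual_blocks)) {
    pb <- params$res[[i]]; sb <- state$res[[i]]
    c1 <- conv1d_forward(r, pb$W1, 1L)
    b1 <- bn_forward(c1$y, pb$gamma1, pb$beta1, sb$rmean1, sb$rvar1, training)
    a1 <- relu(b1$y)
    c2 <- conv1d_forward(a1, pb$W2, 1L)
    b2 <- bn_forward(c2$y, pb$gamma2, pb$beta2, sb$rmean2, sb$rvar2, training)
    pre <- r + b2$y
    out <- relu(pre)
    state$res[[i]] <- list(rmean1 = b1$rmean, rvar1 = b1$rvar,
                           rmean2 = b2$rmean, rvar2 = b2$rvar)
    rcache[[i]] <- list(c1 = c1$cache, b1 = b1$cache, pre1 = b1$y,
                        c2 = c2$cache, b2 = b2$cache, pre = pre)
    r <- out
  }
  cache$res <- rcache

  fused <- tfeb + msfeb + r
  if (config$enable_casb) {
    cb <- casb_forward(fused, params$casb)
    shrunk <- cb$y
    cache$casb <- cb$cache
    cache$casb_out <- list(z = cb$z, alpha = cb$alpha, tau = cb$tau, mask = cb$mask)
  } else shrunk <- fused

  hd <- head_forward(shrunk, params$head, training, config$dropout_rate)
  cache$head <- hd$cache
  list(probs = hd$probs, cache = cache, state = state)
}

model_backward <- function(dlogits, params, config, cache) {
  g <- list()
  hb <- head_backward(dlogits, params$head, cache$head)
  g$head <- hb$grads
  dshrunk <- hb$dx

  if (config$enable_casb) {
    cbb <- casb_backward(dshrunk, params$casb, cache$casb)
    g$casb <- cbb$grads
    dfused <- cbb$dx
  } else dfused <- dshrunk

  dtfeb <- dfused; dmsfeb <- dfused; dr <- dfused

  for (i in rev(seq_len(config$n_residual_blocks))) {
    rc <- cache$res[[i]]; pb <- params$res[[i]]
    dpre <- dr * (rc$pre > 0)
    db2 <- bn_backward(dpre, rc$b2)
    dc2 <- conv1d_backward(db2$dx, pb$W2, rc$c2)
    da1 <- dc2$dx * (rc$pre1 > 0)
    db1 <- bn_backward(da1, rc$b1)
    dc1 <- conv1d_backward(db1$dx, pb$W1, rc$c1)
    g$res[[i]] <- list(W1 = dc1$dw, gamma1 = db1$dgamma, beta1 = db1$dbeta,
                       W2 = dc2$dw, gamma2 = db2$dgamma, beta2 = db2$dbeta)
    dr <- dpre + dc1$dx
  }
  ds <- dr  # gradient into the stem features via the residual branch

  if (config$enable_msfeb) {
    dm <- dmsfeb
    for (i in rev(seq_along(params$msfeb))) {
      mc <- cache$msfeb[[i]]
      dpre <- dm * (mc$pre > 0)
      dbn <- bn_backward(dpre, mc$bn)
      dcv <- conv1d_backward(dbn$dx, params$msfeb[[i]]$W, mc$cv)
      g$msfeb[[i]] <- list(W = dcv$dw, gamma = dbn$dgamma, beta = dbn$dbeta)
      dm <- dcv$dx
    }
    ds <- ds + dm
    dtfeb <- dtfeb + dm
  } else {
    ds <- ds + dmsfeb
    dtfeb <- dtfeb + dmsfeb
  }

  if (config$enable_tfeb) {
    ab <- attention_backward(dtfeb, cache$tfeb$at)
    g$attn <- list(w = ab$dw, b = ab$db)
    g2b <- gru_layer_backward(ab$dx, params$gru2, cache$tfeb$g2)
    g$gru2 <- g2b$grads
    g1b <- gru_layer_backward(g2b$dx, params$gru1, cache$tfeb$g1)
    g$gru1 <- g1b$grads
    ds <- ds + g1b$dx
  } else ds <- ds + dtfeb

  sb <- conv1d_backward(ds, params$stem$W, cache$stem)
  g$stem <- list(W = sb$dw)
  g
}

#' Forward pass of the assembled network
#'
#' Runs the stem convolution, the three feature branches (temporal GRU +
#' attention; dilated multi-scale stack fed with the sum of stem and temporal
#' features; pointwise residual blocks), sums the branch outputs, applies the
#' channel-attention shrinkage and the pooled classifier head.
#'
#' @param window a channels x window_length matrix, an `n x C x T` array, or a
#'   [windowed_dataset()].
#' @param params,state from [init_model()].
#' @param config a [model_config()].
#' @return Class-probability matrix (windows x classes); rows sum to 1.
#' @export
rmfsn_forward <- function(window, params, config, state = init_bn_state(config)) {
  x <- as_batch(window, config)
  out <- model_forward(x, params, config, state, training = FALSE)
  t(out$probs)
}

as_batch <- function(window, config) {
  if (inherits(window, "windowed_dataset")) window <- window$data
  if (is.matrix(window)) window <- array(window, c(1L, dim(window)))
  stop_if_not(length(dim(window)) == 3L &&
                dim(window)[2L] == config$n_channels &&
                dim(window)[3L] == config$window_length,
              "window shape (%s) does not match the model config (%d x %d)",
              paste(dim(window), collapse = "x"),
              config$n_channels, config$window_length)
  aperm(window, c(2L, 3L, 1L))
}

# ---- parameter accounting ---------------------------------------------------

#' Per-layer parameter ledger and total count
#'
#' `parameter_ledger` enumerates every trainable array of the assembled model
#' (weights and biases; batch-norm running statistics are buffers and
#' excluded) with its shape and size; `count_parameters` is its column sum.
#' The ledger is the single source of truth used by the command-line
#' `describe` subcommand, and it is what reproduces the published totals for
#' the shipped dataset profiles.
#'
#' @param config a [model_config()].
#' @return `parameter_ledger`: a data.frame with columns `layer`, `parameter`,
#'   `shape`, `count`. `count_parameters`: a single integer.
#' @export
parameter_ledger <- function(config) {
  p <- init_model(config, seed = 1L)$params
  rows <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      nms <- names(x) %||% as.character(seq_along(x))
      if (is.null(names(x))) nms <- paste0("[", nms, "]")
      for (i in seq_along(x)) walk(x[[i]], c(path, nms[i]))
    } else {
      shape <- paste(if (is.null(dim(x))) length(x) else dim(x), collapse = "x")
      rows[[length(rows) + 1L]] <<-
        data.frame(layer = paste(path[-length(path)], collapse = "."),
                   parameter = path[length(path)],
                   shape = shape, count = length(x))
    }
  }
  walk(p, character())
  do.call(rbind, rows)
}

#' @rdname parameter_ledger
#' @export
count_parameters <- function(config) {
  sum(parameter_ledger(config)$count)
}

# ---- single-sample op wrappers (the block equations, exposed) ---------------

#' One GRU step
#'
#' The gated-recurrent-unit update in its textbook single-bias form:
#' \deqn{r = \sigma(W_r [x, h] + b_r),\quad z = \sigma(W_z [x, h] + b_z),}
#' \deqn{n = \tanh(W_n [x, r \odot h] + b_n),\quad
#'       h' = (1 - z) \odot n + z \odot h.}
#' The weight matrices act on the concatenation `[x, h]`; the reset gate
#' multiplies the previous hidden state before the candidate matmul.
#'
#' @param x_t input vector at the current step.
#' @param h_prev hidden state vector.
#' @param params list with `W_r`, `W_z`, `W_n` (each `hidden x (input+hidden)`)
#'   and `b_r`, `b_z`, `b_n`.
#' @return The new hidden state vector.
#' @export
gru_step <- function(x_t, h_prev, params) {
  hsz <- length(h_prev)
  isz <- length(x_t)
  for (w in c("W_r", "W_z", "W_n"))
    stop_if_not(all(dim(params[[w]]) == c(hsz, isz + hsz)),
                "%s must be %d x %d", w, hsz, isz + hsz)
  xh <- c(x_t, h_prev)
  r <- sigmoid(as.vector(params$W_r %*% xh) + params$b_r)
  z <- sigmoid(as.vector(params$W_z %*% xh) + params$b_z)
  n <- tanh(as.vector(params$W_n %*% c(x_t, r * h_prev)) + params$b_n)
  (1 - z) * n + z * h_prev
}

#' Lightweight temporal attention over a sequence
#'
#' A kernel-1 convolution maps all channels of each timestep to one score
#' `c_i = w . x_i + b`; the scores are softmax-normalised over time into
#' weights `a` (non-negative, summing to 1), and timestep `i` of the sequence
#' is scaled by `a_i` (times the sequence length when `scale = "n"`, restoring
#' overall magnitude).
#'
#' @param seq channels x timesteps feature matrix.
#' @param kernel_weights list with `w` (length-channels vector) and optional `b`.
#' @param scale `"n"` or `"none"`.
#' @return `list(reweighted =, weights = list(a =, c =))`.
#' @export
temporal_attention <- function(seq, kernel_weights, scale = c("n", "none")) {
  scale <- match.arg(scale)
  seq <- as.matrix(seq)
  w <- matrix(kernel_weights$w, 1L)
  b <- kernel_weights$b %||% 0
  sc <- if (scale == "n") ncol(seq) else 1
  out <- attention_forward(array(seq, c(dim(seq), 1L)), w, b, sc)
  stop_if_not(all(is.finite(out$c)), "non-finite attention scores")
  rw <- matrix(out$y[, , 1L], nrow(seq), ncol(seq))
  list(reweighted = rw,
       weights = list(a = as.vector(out$a), c = as.vector(out$c)))
}

#' Receptive field of a dilated convolution stack
#'
#' Iterates \eqn{r_i = r_{i-1} + d_i (k - 1) \prod_{n=1}^{i} s_{n-1}} with
#' \eqn{r_0 = 1} and \eqn{s_0 = 1}: each layer widens the field by its
#' dilated kernel span scaled by the stride product of the preceding layers.
#'
#' @param kernel kernel size (shared by all layers).
#' @param dilations per-layer dilation rates.
#' @param strides per-layer strides (defaults to all 1).
#' @return The receptive field in input samples (integer).
#' @export
receptive_field <- function(kernel, dilations, strides = rep(1L, length(dilations))) {
  stop_if_not(length(dilations) == length(strides),
              "dilations and strides must have equal length")
  stop_if_not(kernel >= 1L, "kernel must be >= 1")
  r <- 1
  prod_prev <- 1  # product of strides of layers before the current one
  for (i in seq_along(dilations)) {
    r <- r + dilations[i] * (kernel - 1L) * prod_prev
    prod_prev <- prod_prev * strides[i]
  }
  as.integer(r)
}

#' Multi-scale dilated convolution stack (single map)
#'
#' Applies the configured stack of length-preserving dilated 1-D convolutions
#' (kernels `(k1, k1, k2, k2)`, dilations `dilation_rates`), each followed by
#' batch normalisation and ReLU, to one feature map.
#'
#' @param x filters x timesteps feature map (the block's input after fusion
#'   with the temporal branch).
#' @param config a [model_config()].
#' @param params the `msfeb` component of [init_model()] parameters.
#' @param linear skip BN and ReLU (used to verify identity-kernel and
#'   impulse-response properties of the raw convolution stack).
#' @return A filters x timesteps feature map.
#' @export
msfeb_forward <- function(x, config, params, linear = FALSE) {
  m <- array(as.matrix(x), c(nrow(x), ncol(x), 1L))
  st <- init_bn_state(config)
  for (i in seq_along(params)) {
    cv <- conv1d_forward(m, params[[i]]$W, config$dilation_rates[i])
    if (linear) { m <- cv$y; next }
    bn <- bn_forward(cv$y, params[[i]]$gamma, params[[i]]$beta,
                     st$msfeb[[i]]$rmean, st$msfeb[[i]]$rvar, training = TRUE)
    m <- relu(bn$y)
  }
  m[, , 1L]
}

#' Squeeze-and-excitation over a feature map
#'
#' The squeeze step pools each channel over time,
#' \eqn{Z_k = \frac{1}{L}\sum_i x_{k,i}}; the excitation step maps the pooled
#' vector through a bottleneck FC-ReLU-FC-sigmoid network to per-channel
#' weights \eqn{\alpha \in (0,1)}.
#'
#' @param x channels x timesteps feature map.
#' @param excitation_params list with `W1`, `b1`, `W2`, `b2`.
#' @return A `shrinkage_state` list with `Z` and `alpha`.
#' @export
casb_squeeze_excite <- function(x, excitation_params) {
  x <- as.matrix(x)
  stop_if_not(ncol(x) > 0L, "empty feature map (L = 0)")
  z <- rowMeans(x)
  a1 <- as.vector(excitation_params$W1 %*% z) + excitation_params$b1
  alpha <- sigmoid(as.vector(excitation_params$W2 %*% relu(a1)) +
                     excitation_params$b2)
  structure(list(Z = z, alpha = alpha), class = "shrinkage_state")
}

#' Thresholds from a shrinkage state
#'
#' \eqn{\tau_k = \overline{|Z|} \cdot \alpha_k}: the scalar mean absolute
#' pooled value scales the per-channel excitation weights, so
#' \eqn{0 \le \tau_k \le \overline{|Z|}} always holds.
#'
#' @param state a `shrinkage_state` from [casb_squeeze_excite()].
#' @return Numeric vector of per-channel thresholds.
#' @export
casb_thresholds <- function(state) {
  mean(abs(state$Z)) * state$alpha
}

#' Soft thresholding
#'
#' Elementwise \eqn{S(x, \tau) = \mathrm{sign}(x)\,\max(|x| - \tau, 0)}:
#' magnitudes at or below the threshold become zero, larger magnitudes shrink
#' toward zero by \eqn{\tau}. Odd in `x`, non-expansive, and sparsifying
#' monotonically in \eqn{\tau}.
#'
#' @param x numeric vector or channels x timesteps matrix.
#' @param tau non-negative threshold; scalar or one value per channel (row).
#' @return Same shape as `x`.
#' @export
soft_threshold <- function(x, tau) {
  stop_if_not(all(tau >= 0), "thresholds must be non-negative")
  if (is.matrix(x) && length(tau) > 1L) {
    stop_if_not(length(tau) == nrow(x), "need one threshold per channel")
    tau <- matrix(tau, nrow(x), ncol(x))
  }
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Pooled classifier head (single map)
#'
#' Global average and global max pooling over time per channel, concatenated
#' into a `2 * channels` vector, then FC + ReLU (+ dropout during training),
#' a final FC to the classes, and softmax.
#'
#' @param x filters x timesteps feature map (the shrinkage block's output).
#' @param params the `head` component of [init_model()] parameters.
#' @param config a [model_config()].
#' @return Probability vector over classes (sums to 1).
#' @export
classifier_head <- function(x, params, config) {
  out <- head_forward(array(as.matrix(x), c(nrow(x), ncol(x), 1L)), params,
                      training = FALSE, dropout_rate = config$dropout_rate)
  as.vector(out$probs)
}
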