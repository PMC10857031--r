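# Batched network primitives with hand-derived backward passes.
#
# Convention: a batch of feature maps is a 3-d array (channels, timesteps,
# batch). Parameters are plain numeric arrays; each *_forward returns the
# output plus the cache its *_backward needs. All forward passes are pure;
# batch-norm running statistics are threaded explicitly.

# ---- dilated 1-D convolution (no bias; 'same' length) -----------------------

# W: (C_out, C_in, k). Length-preserving centred padding: total d*(k-1),
# split floor/ceil left/right.
conv1d_forward <- function(x, w, dilation = 1L) {
  d <- dim(x); cin <- d[1L]; ti <- d[2L]; b <- d[3L]
  k <- dim(w)[3L]
  pad <- dilation * (k - 1L)
  left <- dilation * ((k - 1L) %/% 2L)  # tap (k+1)%/%2 sits on the output sample
  xp <- array(0, c(cin, ti + pad, b))
  xp[, left + seq_len(ti), ] <- x
  cout <- dim(w)[1L]
  y <- matrix(0, cout, ti * b)
  for (j in seq_len(k)) {
    off <- (j - 1L) * dilation
    xs <- xp[, off + seq_len(ti), , drop = FALSE]
    y <- y + w[, , j] %*% mat3(xs)
  }
  list(y = arr3(y, ti, b), cache = list(x = x, dilation = dilation, k = k))
}

conv1d_backward <- function(dy, w, cache) {
  x <- cache$x; dilation <- cache$dilation; k <- cache$k
  d <- dim(x); cin <- d[1L]; ti <- d[2L]; b <- d[3L]
  pad <- dilation * (k - 1L)
  left <- dilation * ((k - 1L) %/% 2L)
  xp <- array(0, c(cin, ti + pad, b))
  xp[, left + seq_len(ti), ] <- x
  dxp <- array(0, dim(xp))
  dw <- array(0, dim(w))
  dym <- mat3(dy)
  for (j in seq_len(k)) {
    off <- (j - 1L) * dilation
    idx <- off + seq_len(ti)
    xs <- mat3(xp[, idx, , drop = FALSE])
    dw[, , j] <- dym %*% t(xs)
    dxp[, idx, ] <- dxp[, idx, ] + arr3(t(w[, , j]) %*% dym, ti, b)
  }
  list(dx = dxp[, left + seq_len(ti), , drop = FALSE], dw = dw)
}

# ---- batch normalisation over (time, batch) per channel ---------------------

bn_forward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x); ti <- d[2L]; b <- d[3L]
  xm <- mat3(x)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * va * (ti * b) / max(ti * b - 1L, 1L)
  } else {
    mu <- rmean; va <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  y <- arr3(gamma * xhat + beta, ti, b)
  list(y = y, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, ti = ti, b = b,
                    training = training))
}

bn_backward <- function(dy, cache) {
  ti <- cache$ti; b <- cache$b; m <- ti * b
  dym <- mat3(dy)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    dxhat <- dym * cache$gamma
    dx <- cache$istd * (dxhat - rowMeans(dxhat) -
                          cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx <- dym * cache$gamma * cache$istd
  }
  list(dx = arr3(dx, ti, b), dgamma = dgamma, dbeta = dbeta)
}

relu <- function(x) (x > 0) * x

# ---- GRU layer --------------------------------------------------------------
#
# Gate equations (reset gate applied before the candidate matmul):
#   r_t = sigmoid(W_ir x_t + b_ir + W_hr h_{t-1} + b_hr)
#   z_t = sigmoid(W_iz x_t + b_iz + W_hz h_{t-1} + b_hz)
#   n_t = tanh(  W_in x_t + b_in + W_hn (r_t * h_{t-1}) + b_hn)
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}
# Two bias vectors per gate are stored (input-side and hidden-side); the cell
# only ever sees their sum. Gate rows are stacked r, z, n.

gru_layer_forward <- function(x, p) {
  d <- dim(x); ti <- d[2L]; b <- d[3L]
  hsz <- ncol(p$W_hh)
  gx <- arr3(p$W_ih %*% mat3(x) + p$b_ih, ti, b)   # (3H, T, B)
  h <- matrix(0, hsz, b)
  y <- array(0, c(hsz, ti, b))
  ir <- seq_len(hsz); iz <- hsz + ir; inn <- 2L * hsz + ir
  Whr <- p$W_hh[ir, , drop = FALSE]; Whz <- p$W_hh[iz, , drop = FALSE]
  Whn <- p$W_hh[inn, , drop = FALSE]
  bhr <- p$b_hh[ir]; bhz <- p$b_hh[iz]; bhn <- p$b_hh[inn]
  steps <- vector("list", ti)
  for (t in seq_len(ti)) {
    gxt <- gx[, t, , drop = TRUE]
    if (b == 1L) gxt <- matrix(gxt, ncol = 1L)
    r <- sigmoid(gxt[ir, , drop = FALSE] + Whr %*% h + bhr)
    z <- sigmoid(gxt[iz, , drop = FALSE] + Whz %*% h + bhz)
    rh <- r * h
    n <- tanh(gxt[inn, , drop = FALSE] + Whn %*% rh + bhn)
    hn <- (1 - z) * n + z * h
    steps[[t]] <- list(r = r, z = z, n = n, h_prev = h, rh = rh)
    h <- hn
    y[, t, ] <- h
  }
  list(y = y, cache = list(x = x, steps = steps, hsz = hsz, ti = ti, b = b))
}

gru_layer_backward <- function(dy, p, cache) {
  ti <- cache$ti; b <- cache$b; hsz <- cache$hsz
  ir <- seq_len(hsz); iz <- hsz + ir; inn <- 2L * hsz + ir
  Whr <- p$W_hh[ir, , drop = FALSE]; Whz <- p$W_hh[iz, , drop = FALSE]
  Whn <- p$W_hh[inn, , drop = FALSE]
  dW_hh <- array(0, dim(p$W_hh)); db_hh <- numeric(3L * hsz)
  dgx <- array(0, c(3L * hsz, ti, b))
  dh <- matrix(0, hsz, b)
  for (t in rev(seq_len(ti))) {
    st <- cache$steps[[t]]
    dht <- dh + matrix(dy[, t, ], hsz, b)
    dz <- dht * (st$h_prev - st$n)
    dn <- dht * (1 - st$z)
    dh_prev <- dht * st$z
    dn_pre <- dn * (1 - st$n^2)
    dgx[inn, t, ] <- dn_pre
    dW_hh[inn, ] <- dW_hh[inn, ] + dn_pre %*% t(st$rh)
    db_hh[inn] <- db_hh[inn] + rowSums(dn_pre)
    drh <- t(Whn) %*% dn_pre
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    dgx[iz, t, ] <- dz_pre
    dgx[ir, t, ] <- dr_pre
    dW_hh[iz, ] <- dW_hh[iz, ] + dz_pre %*% t(st$h_prev)
    dW_hh[ir, ] <- dW_hh[ir, ] + dr_pre %*% t(st$h_prev)
    db_hh[iz] <- db_hh[iz] + rowSums(dz_pre)
    db_hh[ir] <- db_hh[ir] + rowSums(dr_pre)
    dh_prev <- dh_prev + t(Whz) %*% dz_pre + t(Whr) %*% dr_pre
    dh <- dh_prev
  }
  dgxm <- mat3(dgx)
  xm <- mat3(cache$x)
  list(dx = arr3(t(p$W_ih) %*% dgxm, ti, b),
       grads = list(W_ih = dgxm %*% t(xm), W_hh = dW_hh,
                    b_ih = rowSums(dgxm), b_hh = db_hh))
}

# ---- lightweight temporal attention (kernel-1 conv + softmax over time) -----
#
# One score per timestep: c_t = w . x_t + b; a = softmax_t(c); output scales
# timestep t of the sequence by a_t, then by `scale` (the sequence length by
# default, restoring the overall magnitude).

attention_forward <- function(x, w, b, scale) {
  d <- dim(x); ti <- d[2L]; bb <- d[3L]
  cc <- matrix(w %*% mat3(x) + b, ti, bb)          # (T, B)
  cmx <- apply(cc, 2L, max)
  e <- exp(sweep(cc, 2L, cmx))
  a <- sweep(e, 2L, colSums(e), "/")
  as <- a * scale
  y <- x * rep(as, each = d[1L])
  list(y = y, a = a, c = cc,
       cache = list(x = x, a = a, as = as, w = w, scale = scale, ti = ti, b = bb))
}

attention_backward <- function(dy, cache) {
  d <- dim(cache$x); f <- d[1L]; ti <- d[2L]; bb <- d[3L]
  dx <- dy * rep(cache$as, each = f)
  das <- matrix(colSums(matrix(dy * cache$x, f)), ti, bb)   # sum over channels
  da <- das * cache$scale
  a <- cache$a
  dc <- a * sweep(da, 2L, colSums(a * da))
  dcm <- matrix(as.vector(dc), 1L)                 # (1, T*B), matching mat3 order
  dx <- dx + arr3(t(cache$w) %*% dcm, ti, bb)
  dw <- dcm %*% t(mat3(cache$x))
  list(dx = dx, dw = dw, db = sum(dc))
}

# ---- channel-attention shrinkage (squeeze/excite -> thresholds -> soft) -----

casb_forward <- function(x, p) {
  d <- dim(x); f <- d[1L]; ti <- d[2L]; b <- d[3L]
  z <- matrix(colMeans(aperm(x, c(2L, 1L, 3L))), f, b)  # GAP over time: (F, B)
  a1 <- p$W1 %*% z + p$b1
  r1 <- relu(a1)
  alpha <- sigmoid(p$W2 %*% r1 + p$b2)                  # (F, B)
  mabs <- colMeans(abs(z))                              # scalar per batch item
  tau <- sweep(alpha, 2L, mabs, "*")                    # (F, B)
  # broadcast tau over time
  taux <- aperm(array(tau, c(f, b, ti)), c(1L, 3L, 2L))
  mask <- abs(x) > taux
  y <- sign(x) * (abs(x) - taux) * mask
  list(y = y, z = z, alpha = alpha, tau = tau, mask = mask,
       cache = list(x = x, z = z, a1 = a1, r1 = r1, alpha = alpha,
                    mabs = mabs, taux = taux, mask = mask, f = f, ti = ti, b = b))
}

casb_backward <- function(dy, p, cache) {
  f <- cache$f; ti <- cache$ti; b <- cache$b
  x <- cache$x
  dx <- dy * cache$mask
  # d tau (broadcast over time): dS/dtau = -sign(x) where |x| > tau
  dtau3 <- -sign(x) * cache$mask * dy
  dtau <- matrix(colSums(aperm(dtau3, c(2L, 1L, 3L))), f, b)  # sum over time
  dalpha <- sweep(dtau, 2L, cache$mabs, "*")
  dmabs <- colSums(dtau * cache$alpha)
  dz <- sweep(sign(cache$z), 2L, dmabs / f, "*")
  dpre2 <- dalpha * cache$alpha * (1 - cache$alpha)
  dW2 <- dpre2 %*% t(cache$r1)
  db2 <- rowSums(dpre2)
  dr1 <- t(p$W2) %*% dpre2
  dpre1 <- dr1 * (cache$a1 > 0)
  dW1 <- dpre1 %*% t(cache$z)
  db1 <- rowSums(dpre1)
  dz <- dz + t(p$W1) %*% dpre1
  dx <- dx + aperm(array(dz / ti, c(f, b, ti)), c(1L, 3L, 2L))
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- pooled classifier head -------------------------------------------------
#
# GAP and GMP over time per channel, concatenated, FC + ReLU + dropout,
# FC to classes, softmax.

head_forward <- function(x, p, training = FALSE, dropout_rate = 0) {
  d <- dim(x); f <- d[1L]; ti <- d[2L]; b <- d[3L]
  xm <- matrix(aperm(x, c(2L, 1L, 3L)), ti)        # (T, F*B)
  gap <- matrix(colMeans(xm), f, b)
  amax <- max.col(t(xm), ties.method = "first")    # argmax over time per (f,b)
  gmp <- matrix(xm[cbind(amax, seq_len(f * b))], f, b)
  v <- rbind(gap, gmp)                             # (2F, B)
  h1 <- p$W_fc1 %*% v + p$b_fc1
  r1 <- relu(h1)
  if (training && dropout_rate > 0) {
    dmask <- matrix(stats::runif(length(r1)) >= dropout_rate,
                    nrow(r1), ncol(r1)) / (1 - dropout_rate)
  } else dmask <- 1
  dr <- r1 * dmask
  logits <- p$W_fc2 %*% dr + p$b_fc2
  lmx <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, lmx))
  probs <- sweep(e, 2L, colSums(e), "/")
  list(probs = probs,
       cache = list(v = v, h1 = h1, dr = dr, dmask = dmask, amax = amax,
                    probs = probs, f = f, ti = ti, b = b))
}

# dlogits is (K, B): typically probs - onehot, already scaled by 1/B.
head_backward <- function(dlogits, p, cache) {
  f <- cache$f; ti <- cache$ti; b <- cache$b
  dW_fc2 <- dlogits %*% t(cache$dr)
  db_fc2 <- rowSums(dlogits)
  ddr <- t(p$W_fc2) %*% dlogits
  dr1 <- ddr * cache$dmask * (cache$h1 > 0)
  dW_fc1 <- dr1 %*% t(cache$v)
  db_fc1 <- rowSums(dr1)
  dv <- t(p$W_fc1) %*% dr1
  dgap <- dv[seq_len(f), , drop = FALSE]
  dgmp <- dv[f + seq_len(f), , drop = FALSE]
  dxm <- matrix(0, ti, f * b)
  dxm <- dxm + matrix(rep(as.vector(dgap) / ti, each = ti), ti)
  dxm[cbind(cache$amax, seq_len(f * b))] <-
    dxm[cbind(cache$amax, seq_len(f * b))] + as.vector(dgmp)
  dx <- aperm(array(dxm, c(ti, f, b)), c(2L, 1L, 3L))
  list(dx = dx, grads = list(W_fc1 = dW_fc1, b_fc1 = db_fc1,
                             W_fc2 = dW_fc2, b_fc2 = db_fc2))
}
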