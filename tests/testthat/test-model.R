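test_that("gru_step reproduces hand-computed gate values", {
  # scalar case: x = 1, h = 0, all weights 1, biases 0
  p1 <- list(W_r = matrix(1, 1, 2), W_z = matrix(1, 1, 2), W_n = matrix(1, 1, 2),
             b_r = 0, b_z = 0, b_n = 0)
  h <- gru_step(1, 0, p1)
  r <- 1 / (1 + exp(-1))
  expect_equal(h, (1 - r) * tanh(1), tolerance = 1e-6)
  expect_equal(round(h, 4), 0.2048)

  # all weights and biases zero: r = z = 0.5, n = 0, so h' = h/2
  h0 <- c(0.4, -1.2)
  p0 <- list(W_r = matrix(0, 2, 4), W_z = matrix(0, 2, 4), W_n = matrix(0, 2, 4),
             b_r = c(0, 0), b_z = c(0, 0), b_n = c(0, 0))
  expect_equal(gru_step(c(1, 1), h0, p0), 0.5 * h0)

  # saturated update gate copies the previous hidden state
  psat <- p0; psat$b_z <- c(50, 50)
  expect_equal(gru_step(c(1, 1), h0, psat), h0, tolerance = 1e-12)
})

test_that("gru_step matches an independent scalar reference on random shapes", {
  set.seed(31)
  for (rep in 1:10) {
    isz <- sample(1:5, 1); hsz <- sample(1:5, 1)
    p <- list(W_r = matrix(rnorm(hsz * (isz + hsz)), hsz),
              W_z = matrix(rnorm(hsz * (isz + hsz)), hsz),
              W_n = matrix(rnorm(hsz * (isz + hsz)), hsz),
              b_r = rnorm(hsz), b_z = rnorm(hsz), b_n = rnorm(hsz))
    x <- rnorm(isz); h <- rnorm(hsz)
    # scalar-loop reference, written against the gate equations directly
    ref <- numeric(hsz)
    r <- z <- n <- numeric(hsz)
    for (j in 1:hsz) {
      r[j] <- 1 / (1 + exp(-(sum(p$W_r[j, ] * c(x, h)) + p$b_r[j])))
      z[j] <- 1 / (1 + exp(-(sum(p$W_z[j, ] * c(x, h)) + p$b_z[j])))
    }
    for (j in 1:hsz)
      n[j] <- tanh(sum(p$W_n[j, ] * c(x, r * h)) + p$b_n[j])
    for (j in 1:hsz) ref[j] <- (1 - z[j]) * n[j] + z[j] * h[j]
    expect_lt(max(abs(gru_step(x, h, p) - ref)), 1e-6)
  }
})

test_that("the batched GRU layer agrees with iterated gru_step", {
  set.seed(12)
  f <- 4L; ti <- 7L
  cfg <- tiny_config(filters = f)
  prm <- init_model(cfg, seed = 5)$params$gru1
  x <- array(rnorm(f * ti), c(f, ti, 1L))
  y <- rmfsn:::gru_layer_forward(x, prm)$y
  # single-bias equivalent: W_* = [W_ih | W_hh], b = b_ih + b_hh per gate
  gate <- function(g) {
    rows <- (g - 1L) * f + seq_len(f)
    list(W = cbind(prm$W_ih[rows, ], prm$W_hh[rows, ]),
         b = prm$b_ih[rows] + prm$b_hh[rows])
  }
  gr <- gate(1); gz <- gate(2); gn <- gate(3)
  p <- list(W_r = gr$W, W_z = gz$W, W_n = gn$W, b_r = gr$b, b_z = gz$b, b_n = gn$b)
  h <- rep(0, f)
  for (t in seq_len(ti)) {
    h <- gru_step(x[, t, 1], h, p)
    expect_equal(as.vector(y[, t, 1]), h, tolerance = 1e-12)
  }
})

test_that("attention weights form the expected softmax distributions", {
  seqm <- matrix(rnorm(3 * 5), 3, 5)
  kw <- list(w = rep(0, 3), b = 1)          # constant scores -> uniform
  at <- temporal_attention(seqm, kw, scale = "none")
  expect_equal(at$weights$a, rep(1 / 5, 5))
  expect_equal(sum(at$weights$a), 1, tolerance = 1e-6)

  # two steps with scores (0, ln 2) -> weights (1/3, 2/3)
  s2 <- matrix(c(0, log(2)), 1, 2)
  at2 <- temporal_attention(s2, list(w = 1, b = 0), scale = "none")
  expect_equal(at2$weights$a, c(1 / 3, 2 / 3), tolerance = 1e-9)

  # shift invariance: adding a constant to all scores leaves weights unchanged
  at3 <- temporal_attention(s2, list(w = 1, b = 7.5), scale = "none")
  expect_equal(at3$weights$a, at2$weights$a, tolerance = 1e-9)
})

test_that("attention reweighting scales each timestep by its weight", {
  set.seed(3)
  seqm <- matrix(rnorm(4 * 6), 4, 6)
  kw <- list(w = rnorm(4), b = 0.3)
  at <- temporal_attention(seqm, kw, scale = "n")
  for (t in 1:6)
    expect_equal(at$reweighted[, t], seqm[, t] * at$weights$a[t] * 6)
})

test_that("receptive fields follow the dilation recursion", {
  expect_identical(receptive_field(3, c(2, 4)), 13L)
  expect_identical(receptive_field(1, c(1, 2, 4, 6)), 1L)
  expect_identical(receptive_field(3, c(1, 2, 4, 6)), 27L)
  # strides multiply the reach of later layers
  expect_identical(receptive_field(3, c(1, 1), strides = c(2, 1)), 1L + 2L + 4L)
})

test_that("impulse response support of a dilated stack equals the formula", {
  rates <- c(1L, 2L, 4L, 6L)
  for (k in c(2L, 3L, 4L, 5L)) {
    cfg <- model_config(n_channels = 1, window_length = 201, n_classes = 2,
                        filters = 2, stem_kernel = 3, dilated_kernels = c(k, k),
                        dilation_rates = rates, paddings = rates * (k - 1L),
                        se_width = 1, fc_width = 4)
    prm <- init_model(cfg, seed = 2)$params$msfeb
    # positive kernels guarantee no accidental cancellation
    for (i in seq_along(prm)) prm[[i]]$W <- abs(prm[[i]]$W) + 0.1
    x <- matrix(0, 2, 201)
    x[, 101] <- 1
    y <- msfeb_forward(x, cfg, prm, linear = TRUE)
    support <- range(which(abs(y[1, ]) > 0))
    expect_identical(diff(support) + 1L, receptive_field(k, rates))
  }
})

test_that("identity-initialized dilated kernels reproduce the input map", {
  cfg <- tiny_config(window_length = 80L)
  prm <- init_model(cfg, seed = 1)$params$msfeb
  ks <- rmfsn:::msfeb_kernels(cfg)
  for (i in seq_along(prm)) {
    w <- array(0, dim(prm[[i]]$W))
    centre <- (ks[i] + 1L) %/% 2L  # centre tap under floor-left padding
    for (c in seq_len(cfg$filters)) w[c, c, centre] <- 1
    prm[[i]]$W <- w
  }
  x <- matrix(rnorm(cfg$filters * cfg$window_length), cfg$filters)
  y <- msfeb_forward(x, cfg, prm, linear = TRUE)
  # interior timesteps are exact; padding clips the borders
  r <- receptive_field(max(ks), cfg$dilation_rates)
  inner <- (r + 1):(cfg$window_length - r)
  expect_equal(y[, inner], x[, inner], tolerance = 1e-12)
})

test_that("MSFEB output is length-preserving for the shipped configurations", {
  for (p in c("uci_har", "wisdm", "opportunity")) {
    cfg <- load_model_profile(p)$model
    cfg$filters <- 4L  # keep the check light; geometry is what matters
    cfg$se_width <- 2L; cfg$fc_width <- 4L
    prm <- init_model(cfg, seed = 1)$params$msfeb
    x <- matrix(rnorm(4 * cfg$window_length), 4)
    expect_equal(dim(msfeb_forward(x, cfg, prm)), dim(x))
  }
})

test_that("squeeze-excitation pools and bounds its weights", {
  x <- rbind(c(1, -1, 3, 1), c(2, 2, 2, 2))
  p <- list(W1 = matrix(rnorm(2 * 2), 2), b1 = rnorm(2),
            W2 = matrix(rnorm(2 * 2), 2), b2 = rnorm(2))
  st <- casb_squeeze_excite(x, p)
  expect_equal(st$Z, c(1, 2))               # channel means
  expect_true(all(st$alpha > 0 & st$alpha < 1))

  # constant map: every pooled value equals the constant
  xc <- matrix(1.7, 3, 5)
  pc <- list(W1 = matrix(rnorm(6), 2), b1 = rnorm(2),
             W2 = matrix(rnorm(6), 3), b2 = rnorm(3))
  expect_equal(casb_squeeze_excite(xc, pc)$Z, rep(1.7, 3))
  expect_error(casb_squeeze_excite(matrix(0, 2, 0), p), "L = 0")
})

test_that("thresholds are the mean absolute pooled value times the weights", {
  st <- structure(list(Z = c(2, -4), alpha = c(0.5, 1.0)),
                  class = "shrinkage_state")
  expect_equal(casb_thresholds(st), c(1.5, 3.0))
  st$alpha <- c(1e-9, 1e-9)
  expect_lt(max(casb_thresholds(st)), 1e-8)
  # bound: tau never exceeds mean |Z|
  set.seed(6)
  for (rep in 1:20) {
    st$Z <- rnorm(5); st$alpha <- runif(5)
    tau <- casb_thresholds(st)
    expect_true(all(tau >= 0 & tau <= mean(abs(st$Z)) + 1e-12))
  }
})

test_that("soft thresholding shrinks, zeroes, and stays non-expansive", {
  expect_equal(soft_threshold(0, 3), 0)
  expect_equal(soft_threshold(c(-2, 0.5, 4), 0), c(-2, 0.5, 4))
  expect_equal(soft_threshold(5, 2), 3)
  expect_equal(soft_threshold(-5, 2), -3)
  expect_equal(soft_threshold(1, 2), 0)
  expect_error(soft_threshold(1, -0.1), "non-negative")

  set.seed(8)
  x <- rnorm(100); y <- rnorm(100); tau <- 0.7
  # independent elementwise reference
  ref <- ifelse(abs(x) > tau, sign(x) * (abs(x) - tau), 0)
  expect_equal(soft_threshold(x, tau), ref)
  expect_equal(soft_threshold(-x, tau), -soft_threshold(x, tau))      # odd
  expect_true(all(abs(soft_threshold(x, tau) - soft_threshold(y, tau)) <=
                    abs(x - y) + 1e-12))                               # 1-Lipschitz
  taus <- c(0, 0.2, 0.5, 1, 2)
  sparsity <- vapply(taus, function(tt) mean(soft_threshold(x, tt) == 0), 0)
  expect_true(all(diff(sparsity) >= 0))                                # monotone

  # per-channel thresholds on a matrix
  xm <- rbind(c(3, -3), c(3, -3))
  expect_equal(soft_threshold(xm, c(1, 2)), rbind(c(2, -2), c(1, -1)))
})

test_that("classifier head pools, normalizes, and is deterministic", {
  cfg <- tiny_config()
  prm <- init_model(cfg, seed = 3)$params$head
  x <- matrix(rnorm(cfg$filters * cfg$window_length), cfg$filters)
  p1 <- classifier_head(x, prm, cfg)
  expect_length(p1, cfg$n_classes)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, classifier_head(x, prm, cfg))  # no dropout at inference

  # constant map: GAP equals GMP, so both pooled halves agree
  xc <- matrix(2, cfg$filters, cfg$window_length)
  out <- rmfsn:::head_forward(array(xc, c(dim(xc), 1)), prm)
  v <- out$cache$v
  expect_equal(v[seq_len(cfg$filters), 1], v[cfg$filters + seq_len(cfg$filters), 1])
})

test_that("full forward emits probability vectors and honours ablations", {
  set.seed(9)
  cfg <- tiny_config()
  mdl <- init_model(cfg, seed = 4)
  w <- matrix(rnorm(cfg$n_channels * cfg$window_length), cfg$n_channels)
  pr <- rmfsn_forward(w, mdl$params, cfg, mdl$state)
  expect_equal(dim(pr), c(1L, cfg$n_classes))
  expect_equal(sum(pr), 1, tolerance = 1e-6)

  # with the shrinkage block disabled the stage is the identity on the fused
  # features, which matches forcing alpha -> 0 (tau -> 0) in the full model
  cfg_off <- tiny_config(enable_casb = FALSE)
  params_off <- mdl$params
  params_off$casb <- NULL
  pr_off <- rmfsn_forward(w, params_off, cfg_off, init_model(cfg_off, 1)$state)
  mdl_zero <- mdl
  mdl_zero$params$casb$b2 <- rep(-1e3, cfg$filters)  # alpha -> 0 => tau -> 0
  pr_zero <- rmfsn_forward(w, mdl_zero$params, cfg, mdl$state)
  expect_equal(pr_off, pr_zero, tolerance = 1e-6)

  expect_error(rmfsn_forward(matrix(0, 5, 7), mdl$params, cfg), "shape")
})

test_that("parameter counts follow closed forms and the published totals", {
  # one linear map: i*o + o
  cfg <- tiny_config()
  led <- parameter_ledger(cfg)
  fc2 <- led[led$layer == "head" & led$parameter %in% c("W_fc2", "b_fc2"), ]
  expect_equal(sum(fc2$count), cfg$fc_width * cfg$n_classes + cfg$n_classes)

  # independent closed-form ledger for the whole assembly
  closed_form <- function(cf) {
    f <- cf$filters; ks <- rmfsn:::msfeb_kernels(cf)
    f * cf$n_channels * cf$stem_kernel +                        # stem conv
      2 * (3 * (f * f + f * f) + 6 * f) +                       # two GRU layers
      f + 1 +                                                   # attention
      sum(f * f * ks + 2 * f) +                                 # dilated convs + BN
      cf$n_residual_blocks * 2 * (f * f + 2 * f) +              # pointwise res + BN
      2 * f * cf$se_width + cf$se_width + f +                   # excitation MLP
      2 * f * cf$fc_width + cf$fc_width +                       # hidden FC
      cf$fc_width * cf$n_classes + cf$n_classes                 # output FC
  }
  expect_equal(count_parameters(cfg), closed_form(cfg))

  # doubling fc_width changes the count by exactly the two FC layers' delta
  cfg2 <- tiny_config(fc_width = 16L)
  delta <- (2 * cfg$filters + 1 + cfg$n_classes) * 8L
  expect_equal(count_parameters(cfg2) - count_parameters(cfg), delta)

  # removing blocks strictly reduces the count
  expect_lt(count_parameters(tiny_config(enable_casb = FALSE,
                                         enable_tfeb = FALSE,
                                         enable_msfeb = FALSE)),
            count_parameters(cfg))
})

test_that("disabling every branch flag is still a usable baseline model", {
  cfg <- tiny_config(enable_casb = FALSE, enable_tfeb = FALSE,
                     enable_msfeb = FALSE)
  mdl <- init_model(cfg, seed = 2)
  w <- matrix(rnorm(cfg$n_channels * cfg$window_length), cfg$n_channels)
  pr <- rmfsn_forward(w, mdl$params, cfg, mdl$state)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
})
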