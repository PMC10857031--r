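#' Default activity signal profiles
#'
#' Builds the six default pseudo-IMU activity signatures, ordered walking,
#' jogging, upstairs, downstairs, sitting, standing. The dynamic activities are
#' oscillatory with distinct dominant frequencies and amplitudes — jogging is
#' strictly stronger than walking on every axis, mirroring the amplitude
#' separation visible in real accelerometer traces. Sitting and standing are
#' static profiles distinguished only by opposite per-channel offsets, which
#' makes them intentionally confusable, as they are in real data.
#'
#' @param n_channels number of sensor channels.
#' @return A list of `activity_profile` objects (name, base_freq_hz, amplitude
#'   per channel, duty_pattern, harmonic_weights, offset per channel).
#' @export
make_profiles <- function(n_channels) {
  stop_if_not(is_count(n_channels), "n_channels must be a positive integer")
  ch <- seq_len(n_channels)
  axis_shape <- 1 + 0.25 * cos(2 * pi * ch / max(n_channels, 2L)) # mild per-axis variety
  prof <- function(name, f, amp, duty, harm, offset = rep(0, n_channels)) {
    structure(list(name = name, base_freq_hz = f, amplitude = amp,
                   duty_pattern = duty, harmonic_weights = harm, offset = offset),
              class = "activity_profile")
  }
  list(
    prof("walking",    2.0, 1.0 * axis_shape, "oscillatory", c(1, 0.30, 0.10)),
    prof("jogging",    2.8, 2.2 * axis_shape, "oscillatory", c(1, 0.45, 0.15)),
    prof("upstairs",   1.4, 1.2 * axis_shape, "oscillatory", c(1, 0.25, 0.05)),
    prof("downstairs", 1.7, 1.6 * axis_shape, "oscillatory", c(1, 0.35, 0.08)),
    prof("sitting",    0.0, 0 * axis_shape, "static", 1,
         offset = 0.5 * (-1)^ch),
    prof("standing",   0.0, 0 * axis_shape, "static", 1,
         offset = 0.5 * (-1)^(ch + 1L))
  )
}

#' Synthetic dataset configuration
#'
#' Study conditions for the generator. The default geometry mirrors the
#' smallest real configuration handled by the model family (3 channels,
#' 100-sample windows at 20 Hz). `subject_jitter` is the log-normal standard
#' deviation of the per-subject multiplicative spread applied to amplitude and
#' frequency, the mechanism that makes leave-one-subject-out evaluation
#' non-trivial.
#'
#' @param n_subjects,n_classes,windows_per_class_per_subject dataset size.
#' @param n_channels,window_length,sample_rate_hz window geometry.
#' @param noise_sd additive Gaussian noise standard deviation (sensor units).
#' @param subject_jitter log-normal sd of per-subject amplitude/frequency scaling.
#' @param missing_rate Bernoulli probability that a sample is masked missing.
#' @param seed integer seed; the stream is consumed in a fixed documented order
#'   (subjects, then classes, then windows), so output is reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 4L, n_classes = 6L,
                         windows_per_class_per_subject = 10L,
                         n_channels = 3L, window_length = 100L,
                         sample_rate_hz = 20, noise_sd = 0.15,
                         subject_jitter = 0.08, missing_rate = 0,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_classes = as.integer(n_classes),
              windows_per_class_per_subject = as.integer(windows_per_class_per_subject),
              n_channels = as.integer(n_channels), window_length = as.integer(window_length),
              sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
              subject_jitter = subject_jitter, missing_rate = missing_rate,
              seed = as.integer(seed))
  for (f in c("n_subjects", "n_classes", "windows_per_class_per_subject",
              "n_channels", "window_length"))
    stop_if_not(is_count(cfg[[f]]), "%s must be a positive integer", f)
  stop_if_not(cfg$noise_sd >= 0 && cfg$subject_jitter >= 0, "noise/jitter must be >= 0")
  stop_if_not(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  structure(cfg, class = "synth_config")
}

# One window of one activity for one (already jittered) profile.
synth_window <- function(profile, amp_mult, freq_mult, n_channels, ti, fs, noise_sd) {
  tt <- (seq_len(ti) - 1L) / fs
  x <- matrix(0, n_channels, ti)
  if (profile$duty_pattern == "oscillatory") {
    phase <- stats::runif(1L, 0, 2 * pi)
    f0 <- profile$base_freq_hz * freq_mult
    base <- 0
    for (h in seq_along(profile$harmonic_weights))
      base <- base + profile$harmonic_weights[h] * sin(2 * pi * f0 * h * tt + phase)
    x <- (amp_mult * profile$amplitude) %o% base
  } else if (profile$duty_pattern == "ramp") {
    slope <- stats::runif(1L, 0.5, 1.5)
    x <- (amp_mult * profile$amplitude) %o% (slope * (tt - mean(tt)))
  } # static: zero dynamic part
  x <- x + profile$offset
  if (noise_sd > 0) x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), n_channels, ti)
  x
}

#' Generate a labelled synthetic pseudo-IMU dataset
#'
#' Each window is a subject-jittered class signature (a sum of harmonics of
#' the profile's base frequency with random phase, a ramp, or a static offset)
#' plus additive Gaussian noise. Generation is fully determined by
#' `config$seed`: the random stream is consumed subject by subject, class by
#' class, window by window. When `config$missing_rate > 0` the generator
#' instead returns continuous [raw_recording()]s with missing masks (see
#' [generate_recordings()]) so the preprocessing chain can be exercised.
#'
#' @param config a [synth_config()].
#' @param profiles activity profiles; defaults to [make_profiles()].
#' @return A [windowed_dataset()], or a list of `raw_recording`s when
#'   `missing_rate > 0`.
#' @export
generate_dataset <- function(config, profiles = make_profiles(config$n_channels)) {
  stopifnot(inherits(config, "synth_config"))
  stop_if_not(config$n_classes <= length(profiles),
              "n_classes (%d) exceeds the %d defined activity profiles",
              config$n_classes, length(profiles))
  if (config$missing_rate > 0) return(generate_recordings(config, profiles))
  wpc <- config$windows_per_class_per_subject
  n <- config$n_subjects * config$n_classes * wpc
  data <- array(0, c(n, config$n_channels, config$window_length))
  labels <- integer(n); subjects <- character(n)
  set.seed(config$seed)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    amp_mult <- exp(stats::rnorm(1L, 0, config$subject_jitter))
    freq_mult <- exp(stats::rnorm(1L, 0, config$subject_jitter))
    for (k in seq_len(config$n_classes)) {
      for (w in seq_len(wpc)) {
        i <- i + 1L
        data[i, , ] <- synth_window(profiles[[k]], amp_mult, freq_mult,
                                    config$n_channels, config$window_length,
                                    config$sample_rate_hz, config$noise_sd)
        labels[i] <- k
        subjects[i] <- paste0("synth", s)
      }
    }
  }
  windowed_dataset(data, labels, subjects,
                   vapply(profiles[seq_len(config$n_classes)], `[[`, "", "name"))
}

#' Generate continuous raw recordings with missing samples
#'
#' One recording per (subject, class): `windows_per_class_per_subject`
#' window-lengths of contiguous signal with per-sample labels and a Bernoulli
#' missing mask at `config$missing_rate`, for exercising
#' [interpolate_missing()] and [segment_windows()].
#'
#' @inheritParams generate_dataset
#' @return A list of [raw_recording()]s.
#' @export
generate_recordings <- function(config, profiles = make_profiles(config$n_channels)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  out <- list()
  n_samp <- config$windows_per_class_per_subject * config$window_length
  for (s in seq_len(config$n_subjects)) {
    amp_mult <- exp(stats::rnorm(1L, 0, config$subject_jitter))
    freq_mult <- exp(stats::rnorm(1L, 0, config$subject_jitter))
    for (k in seq_len(config$n_classes)) {
      sig <- synth_window(profiles[[k]], amp_mult, freq_mult, config$n_channels,
                          n_samp, config$sample_rate_hz, config$noise_sd)
      mask <- matrix(stats::runif(length(sig)) < config$missing_rate,
                     nrow(sig), ncol(sig))
      # keep at least one observed value per channel
      mask[, 1L] <- FALSE
      sig[mask] <- NA_real_
      out[[length(out) + 1L]] <-
        raw_recording(sig, config$sample_rate_hz, paste0("synth", s),
                      labels = rep(k, n_samp), missing_mask = mask)
    }
  }
  out
}

#' Per-window spectral-energy features and a nearest-centroid oracle
#'
#' `spectral_features` summarises each window by per-channel log spectral
#' energy in coarse frequency bands plus the channel mean; it is the simple
#' statistic that separates the oscillatory activity signatures, and serves as
#' an independent yardstick for what the network should at minimum achieve.
#'
#' @param dataset a [windowed_dataset()].
#' @param n_bands number of frequency bands.
#' @return A windows x features matrix.
#' @export
spectral_features <- function(dataset, n_bands = 8L) {
  d <- dataset$data
  n <- dim(d)[1L]; ch <- dim(d)[2L]; ti <- dim(d)[3L]
  half <- floor(ti / 2)
  band <- cut(seq_len(half), n_bands, labels = FALSE)
  feats <- matrix(0, n, ch * (n_bands + 1L))
  for (i in seq_len(n)) {
    row <- numeric(0)
    for (c in seq_len(ch)) {
      x <- d[i, c, ]
      p <- Mod(stats::fft(x - mean(x)))[2:(half + 1L)]^2
      row <- c(row, log1p(vapply(seq_len(n_bands),
                                 function(b) sum(p[band == b]), 0)), mean(x))
    }
    feats[i, ] <- row
  }
  feats
}

#' @rdname spectral_features
#' @param train,test `windowed_dataset`s; centroids are fit on `train`.
#' @return For `nearest_centroid_accuracy`, the fraction of `test` windows
#'   assigned to their true class by nearest class centroid in feature space.
#' @export
nearest_centroid_accuracy <- function(train, test = train) {
  ftr <- spectral_features(train); fte <- spectral_features(test)
  cent <- t(vapply(seq_along(train$class_names), function(k) {
    colMeans(ftr[train$labels == k, , drop = FALSE])
  }, numeric(ncol(ftr))))
  pred <- apply(fte, 1L, function(x) which.min(colSums((t(cent) - x)^2)))
  mean(pred == test$labels)
}
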