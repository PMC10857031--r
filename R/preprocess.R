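#' Raw multichannel inertial recording
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate, subject
#' identifier, labels and a missing-sample mask. Labels may be a single value
#' for the whole recording or one value per sample. The missing mask marks
#' samples whose value is absent (e.g. dropped packets); such entries are
#' ignored by downstream code until [interpolate_missing()] fills them.
#'
#' @param signals numeric matrix, channels x samples (sensor units, e.g. g or rad/s).
#' @param sample_rate_hz positive sampling frequency in Hz.
#' @param subject_id opaque subject identifier.
#' @param labels integer vector of length 1 (whole recording) or one per sample.
#' @param missing_mask logical matrix of the same shape as `signals` (or a
#'   per-sample vector, recycled across channels); `TRUE` marks absent values.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signals, sample_rate_hz, subject_id = "S1",
                          labels = 1L, missing_mask = NULL) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  stop_if_not(is.numeric(sample_rate_hz) && sample_rate_hz > 0,
              "sample_rate_hz must be > 0")
  n <- ncol(signals)
  if (length(labels) != 1L && length(labels) != n)
    stop("labels must have length 1 or one entry per sample", call. = FALSE)
  if (is.null(missing_mask)) {
    missing_mask <- is.na(signals)
  } else if (is.vector(missing_mask)) {
    stop_if_not(length(missing_mask) == n, "per-sample missing_mask has wrong length")
    missing_mask <- matrix(missing_mask, nrow(signals), n, byrow = TRUE)
  }
  stop_if_not(all(dim(missing_mask) == dim(signals)),
              "missing_mask must match the signal matrix shape")
  structure(list(signals = signals, sample_rate_hz = sample_rate_hz,
                 subject_id = subject_id, labels = as.integer(labels),
                 missing_mask = missing_mask),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, subject %s, %d missing\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate_hz,
              x$subject_id, sum(x$missing_mask)))
  invisible(x)
}

#' Fill missing samples by per-channel linear interpolation
#'
#' Masked samples are replaced channel-by-channel by linear interpolation
#' between the nearest observed neighbours; runs at the start or end of a
#' channel (where interpolation is undefined) take the nearest observed value.
#' Observed samples are left untouched, so the operation is idempotent.
#'
#' @param recording a [raw_recording()].
#' @return The recording with all masked values filled and the mask cleared.
#' @export
interpolate_missing <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  sig <- recording$signals
  mask <- recording$missing_mask
  n <- ncol(sig)
  for (ch in seq_len(nrow(sig))) {
    m <- mask[ch, ]
    if (!any(m)) next
    obs <- which(!m)
    if (length(obs) == 0L)
      stop(sprintf("channel %d has no observed samples; cannot interpolate", ch),
           call. = FALSE)
    # rule = 2: constant (nearest-value) extension beyond the observed range
    sig[ch, m] <- stats::approx(obs, sig[ch, obs], xout = which(m),
                                method = "linear", rule = 2)$y
  }
  recording$signals <- sig
  recording$missing_mask <- matrix(FALSE, nrow(sig), n)
  recording
}

#' Separate body and gravity acceleration with a Butterworth low-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter to each
#' channel; the filtered signal is the slowly varying gravity component and the
#' residual is the body acceleration, so `body + gravity` reconstructs the
#' input exactly. Defaults (0.3 Hz cutoff, order 3) follow the convention of
#' this dataset family; both are exposed.
#'
#' @param acc a [raw_recording()] holding accelerometer channels.
#' @param cutoff_hz low-pass cutoff in Hz, strictly below Nyquist.
#' @param order filter order.
#' @return `list(body =, gravity =)`, both `raw_recording`s.
#' @export
butterworth_body_gravity <- function(acc, cutoff_hz = 0.3, order = 3L) {
  stopifnot(inherits(acc, "raw_recording"))
  fs <- acc$sample_rate_hz
  stop_if_not(cutoff_hz > 0 && cutoff_hz < fs / 2,
              "cutoff_hz (%g) must lie in (0, Nyquist = %g)", cutoff_hz, fs / 2)
  stop_if_not(ncol(acc$signals) >= 3 * order,
              "recording too short for an order-%d filter", order)
  stop_if_not(!any(acc$missing_mask), "fill missing samples before filtering")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  gravity <- t(apply(acc$signals, 1L, function(x) zero_phase_filter(bf$b, bf$a, x)))
  body <- acc$signals - gravity
  g <- acc; g$signals <- gravity
  b <- acc; b$signals <- body
  list(body = b, gravity = g)
}

# Direct-form-II-transposed single filter pass with explicit initial state.
lfilter_df2t <- function(b, a, x, zi) {
  n <- length(x); nf <- length(b)
  y <- numeric(n)
  z <- c(zi, 0)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nf > 2L)
      z[1:(nf - 2L)] <- z[2:(nf - 1L)] + b[2:(nf - 1L)] * xi - a[2:(nf - 1L)] * yi
    z[nf - 1L] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# Zero-phase (forward-backward) filtering with symmetric-reflection padding
# and steady-state initial conditions, so constants pass exactly and edge
# transients stay out of the signal. The very low cutoffs used for gravity
# estimation have time constants of hundreds of samples, which is why the
# reflection pad spans the whole recording.
zero_phase_filter <- function(b, a, x) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1L]
  a <- c(a, rep(0, nf - length(a))) / a[1L]
  comp <- matrix(0, nf - 1L, nf - 1L)
  if (nf > 2L) comp[cbind(2:(nf - 1L), 1:(nf - 2L))] <- 1
  comp[1L, ] <- -a[-1L]
  zi <- solve(diag(nf - 1L) - t(comp), b[-1L] - a[-1L] * b[1L])
  n <- length(x)
  edge <- n - 1L
  ext <- c(x[(edge + 1L):2L], x, x[(n - 1L):(n - edge)])
  y <- lfilter_df2t(b, a, ext, zi * ext[1L])
  y <- rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[edge + seq_len(n)]
}

#' Per-channel mean and standard deviation
#'
#' Computes the statistics used by [standardize()]. In a train/test protocol
#' these must come from training data only. Standard deviations below `floor`
#' are replaced by it so constant channels map to zero rather than dividing
#' by zero.
#'
#' @param x a `raw_recording`, a `windowed_dataset`, or a channels x samples matrix.
#' @param floor minimum usable standard deviation.
#' @return `list(mean =, sd =)`, one entry per channel.
#' @export
channel_stats <- function(x, floor = 1e-8) {
  m <- channel_matrix(x)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  sdv[!is.finite(sdv) | sdv < floor] <- floor
  list(mean = mu, sd = sdv)
}

channel_matrix <- function(x) {
  if (inherits(x, "raw_recording")) return(x$signals)
  if (inherits(x, "windowed_dataset")) {
    d <- x$data # n x C x T
    return(matrix(aperm(d, c(2L, 3L, 1L)), nrow = dim(d)[2L]))
  }
  as.matrix(x)
}

#' Standardize channels to zero mean, unit variance
#'
#' Applies `(x - mean) / sd` per channel using the supplied statistics (an
#' affine, order-preserving map). Works on raw recordings and on windowed
#' datasets alike.
#'
#' @param x a `raw_recording` or `windowed_dataset`.
#' @param stats output of [channel_stats()]; defaults to statistics of `x`
#'   itself (only appropriate outside a train/test protocol).
#' @return The same type as `x`, transformed.
#' @export
standardize <- function(x, stats = channel_stats(x)) {
  if (inherits(x, "raw_recording")) {
    x$signals <- (x$signals - stats$mean) / stats$sd
    return(x)
  }
  if (inherits(x, "windowed_dataset")) {
    d <- x$data
    for (ch in seq_len(dim(d)[2L]))
      d[, ch, ] <- (d[, ch, ] - stats$mean[ch]) / stats$sd[ch]
    x$data <- d
    return(x)
  }
  (as.matrix(x) - stats$mean) / stats$sd
}

#' A collection of fixed-length labelled sensor windows
#'
#' The atomic sample is one channels x window-length segment with an activity
#' label and a subject ID; a `windowed_dataset` stores them as an
#' `n x channels x length` array together with the class vocabulary.
#'
#' @param data numeric array, `n x n_channels x window_length`.
#' @param labels integer class indices in `1..length(class_names)`.
#' @param subjects character vector of per-window subject IDs.
#' @param class_names ordered class vocabulary.
#' @return An object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(data, labels, subjects, class_names) {
  stopifnot(length(dim(data)) == 3L)
  labels <- as.integer(labels)
  subjects <- as.character(subjects)
  stop_if_not(dim(data)[1L] == length(labels) && length(labels) == length(subjects),
              "data, labels and subjects must agree on the number of windows")
  stop_if_not(all(labels >= 1L & labels <= length(class_names)),
              "every label must index class_names")
  stop_if_not(!anyNA(data), "windows must not contain missing values")
  structure(list(data = data, labels = labels, subjects = subjects,
                 class_names = as.character(class_names),
                 n_channels = dim(data)[2L], window_length = dim(data)[3L]),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d x %d, %d classes, %d subjects\n",
              dim(x$data)[1L], x$n_channels, x$window_length,
              length(x$class_names), length(unique(x$subjects))))
  invisible(x)
}

#' Subset a windowed dataset by window index
#' @param x a `windowed_dataset`.
#' @param idx integer or logical index over windows.
#' @export
dataset_subset <- function(x, idx) {
  windowed_dataset(x$data[idx, , , drop = FALSE], x$labels[idx],
                   x$subjects[idx], x$class_names)
}

#' Cut a recording into fixed-length overlapping windows
#'
#' Windows start at 0, step, 2*step, ... with
#' `step = max(1, round(window_length * (1 - overlap_fraction)))`; the number
#' of windows is `floor((N - window_length)/step) + 1`. Per-sample labels are
#' resolved to one label per window by majority vote, ties broken by the label
#' at the window's last sample; windows whose majority label equals
#' `null_label` are dropped (background/no-gesture segments).
#'
#' @param recording a [raw_recording()] with no missing samples.
#' @param window_length samples per window.
#' @param overlap_fraction in `[0, 1)`; 0.5 means consecutive windows share half
#'   their samples.
#' @param null_label optional label value whose windows are discarded.
#' @return A list of windows, each `list(data, label, subject_id)`; empty (with
#'   a warning) when the recording is shorter than one window.
#' @export
segment_windows <- function(recording, window_length, overlap_fraction = 0.5,
                            null_label = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  stop_if_not(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must lie in [0, 1)")
  stop_if_not(!any(recording$missing_mask),
              "fill missing samples before windowing")
  n <- ncol(recording$signals)
  if (window_length > n) {
    warning(sprintf("recording (%d samples) shorter than one window (%d); no windows",
                    n, window_length))
    return(list())
  }
  step <- max(1L, as.integer(round(window_length * (1 - overlap_fraction))))
  starts <- seq.int(0L, n - window_length, by = step)
  per_sample <- length(recording$labels) == n
  out <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    idx <- (s + 1L):(s + window_length)
    if (per_sample) {
      lab_run <- recording$labels[idx]
      tab <- table(lab_run)
      top <- as.integer(names(tab)[tab == max(tab)])
      lab <- if (length(top) == 1L) top else lab_run[window_length]
    } else {
      lab <- recording$labels
    }
    if (!is.null(null_label) && lab == null_label) next
    out[[i]] <- list(data = recording$signals[, idx, drop = FALSE],
                     label = lab, subject_id = recording$subject_id)
    keep[i] <- TRUE
  }
  out[keep]
}

#' Assemble segmented windows into a dataset
#'
#' @param windows list of windows as returned by [segment_windows()].
#' @param class_names class vocabulary; window labels are matched against
#'   `seq_along(class_names)` (or against `label_values` when given).
#' @param label_values optional raw label codes corresponding to `class_names`.
#' @return A [windowed_dataset()].
#' @export
bind_windows <- function(windows, class_names, label_values = seq_along(class_names)) {
  stop_if_not(length(windows) > 0L, "no windows to bind")
  ch <- nrow(windows[[1L]]$data); ti <- ncol(windows[[1L]]$data)
  data <- array(0, c(length(windows), ch, ti))
  labels <- integer(length(windows)); subjects <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    stop_if_not(nrow(w$data) == ch && ncol(w$data) == ti,
                "window %d has inconsistent shape", i)
    data[i, , ] <- w$data
    pos <- match(w$label, label_values)
    stop_if_not(!is.na(pos), "window %d has label %s outside the vocabulary",
                i, w$label)
    labels[i] <- pos
    subjects[i] <- w$subject_id
  }
  windowed_dataset(data, labels, subjects, class_names)
}

#' Write / read a windowed archive
#'
#' The archive is a compressed serialized-array container (RDS) holding the
#' window array, labels and subjects, accompanied by a JSON sidecar
#' (`<path>.json`) with the class vocabulary and preprocessing provenance.
#'
#' @param dataset a [windowed_dataset()].
#' @param path archive path (conventionally `.rds`).
#' @param provenance named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_windows <- function(dataset, path, provenance = list()) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  saveRDS(list(data = dataset$data, labels = dataset$labels,
               subjects = dataset$subjects), path)
  side <- list(class_names = dataset$class_names,
               n_channels = dataset$n_channels,
               window_length = dataset$window_length,
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  raw <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  windowed_dataset(raw$data, raw$labels, raw$subjects, side$class_names)
}
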