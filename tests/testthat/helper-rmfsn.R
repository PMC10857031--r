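# Shared fixture builders. Everything is generated in code at test time;
# no stored data files.

# A small model configuration used across unit tests.
tiny_config <- function(n_channels = 3L, window_length = 30L, n_classes = 4L,
                        filters = 6L, se_width = 3L, fc_width = 8L, ...) {
  model_config(n_channels = n_channels, window_length = window_length,
               n_classes = n_classes, filters = filters, stem_kernel = 3L,
               dilated_kernels = c(3L, 2L), se_width = se_width,
               fc_width = fc_width, dropout_rate = 0, ...)
}

# A small synthetic dataset matching tiny_config geometry.
tiny_dataset <- function(n_subjects = 3L, windows = 4L, window_length = 30L,
                         n_classes = 4L, noise_sd = 0.15, seed = 11L) {
  generate_dataset(synth_config(
    n_subjects = n_subjects, n_classes = n_classes,
    windows_per_class_per_subject = windows, n_channels = 3L,
    window_length = window_length, sample_rate_hz = 20,
    noise_sd = noise_sd, subject_jitter = 0.05, seed = seed))
}

random_confusion <- function(k, n = 200L) {
  m <- matrix(stats::rpois(k * k, 3), k, k) + diag(stats::rpois(k, n / k), k)
  dimnames(m) <- list(true = paste0("c", 1:k), pred = paste0("c", 1:k))
  m
}

# Perturb one scalar inside a nested parameter list (path of names/indices).
perturb_param <- function(params, path, i, delta) {
  if (length(path) == 1L) {
    params[[path[[1L]]]][i] <- params[[path[[1L]]]][i] + delta
    params
  } else {
    params[[path[[1L]]]] <- perturb_param(params[[path[[1L]]]], path[-1L], i, delta)
    params
  }
}

pluck_path <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

# Central finite difference of a scalar-valued function of the parameter list.
numeric_grad_at <- function(loss_fn, params, path, i, eps = 1e-5) {
  (loss_fn(perturb_param(params, path, i, eps)) -
     loss_fn(perturb_param(params, path, i, -eps))) / (2 * eps)
}
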