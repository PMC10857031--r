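#' Shipped per-dataset model and training profiles
#'
#' Loads the packaged hyperparameter profile for one of the three public
#' datasets. The published values fix the input geometry, filter count, stem
#' kernel, dilated kernel pair, dilation rates, paddings, batch size, epochs
#' and learning rate; the two unpublished widths (`fc_width`, `se_width`) are
#' resolved in each profile so that [count_parameters()] reproduces the
#' published trainable-parameter total exactly (each YAML file carries the
#' derivation note; [parameter_ledger()] makes the accounting auditable
#' layer by layer).
#'
#' @param profile `"uci_har"`, `"wisdm"` or `"opportunity"`.
#' @param overrides named list overriding profile fields (e.g. from a user
#'   config file or command-line flags).
#' @return `list(model = model_config, train = train_config, name, notes)`.
#' @export
load_model_profile <- function(profile, overrides = list()) {
  path <- system.file("extdata", "configs", paste0(profile, ".yaml"),
                      package = "rmfsn")
  if (!nzchar(path))
    stop(sprintf("unknown profile '%s'; valid profiles: uci_har, wisdm, opportunity",
                 profile), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) {
    if (nm %in% names(cfg$model)) cfg$model[[nm]] <- overrides[[nm]]
    else if (nm %in% names(cfg$train)) cfg$train[[nm]] <- overrides[[nm]]
  }
  list(model = do.call(model_config, cfg$model),
       train = do.call(train_config, cfg$train),
       name = cfg$name, notes = cfg$notes)
}
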