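#' Leave-one-subject-out folds
#'
#' One fold per subject: fold s tests exclusively on subject s's windows and
#' trains on everyone else's, so overlapping windows from one recording can
#' never leak across the train/test boundary. Folds partition the dataset.
#'
#' @param dataset a [windowed_dataset()] with at least two subjects.
#' @return A list of `list(train =, test =, subject =)` index lists.
#' @export
loso_folds <- function(dataset) {
  subs <- sort(unique(dataset$subjects))
  stop_if_not(length(subs) >= 2L, "leave-one-subject-out needs >= 2 subjects")
  lapply(subs, function(s) {
    te <- which(dataset$subjects == s)
    list(train = setdiff(seq_along(dataset$subjects), te), test = te, subject = s)
  })
}

# Class-stratified shuffled assignment of n windows into groups of
# proportions prop. Within each class, groups first get floor(prop * n_class)
# windows; leftover windows go to the groups whose global target count
# (round(prop * n)) is furthest from met, largest fractional part breaking
# ties — so both the per-class and the overall proportions are honoured.
stratified_assign <- function(labels, prop, seed) {
  set.seed(seed)
  n <- length(labels)
  target <- diff(round(cumsum(c(0, prop)) * n))
  classes <- unique(labels)
  base <- lapply(classes, function(k) floor(prop * sum(labels == k)))
  deficit <- target - Reduce(`+`, base)
  assign <- integer(n)
  for (ci in seq_along(classes)) {
    k <- classes[ci]
    idx <- sample(which(labels == k))
    sizes <- base[[ci]]
    frac <- prop * length(idx) - sizes
    extra <- length(idx) - sum(sizes)
    while (extra > 0L) {
      cand <- order(-deficit, -frac)[1L]
      sizes[cand] <- sizes[cand] + 1L
      deficit[cand] <- deficit[cand] - 1L
      frac[cand] <- -1
      extra <- extra - 1L
    }
    assign[idx] <- rep.int(seq_along(prop), sizes)
  }
  assign
}

#' Random window-level splits (comparison protocols)
#'
#' `ratio_split` partitions windows at the given proportions; `kfold_folds`
#' builds k equal folds. Both are stratified by class and window-level, which
#' means overlapping neighbour windows can land on both sides of a split —
#' the neighbourhood bias that motivates leave-one-subject-out evaluation.
#' They are provided as comparators, not as the primary protocol.
#'
#' @param dataset a [windowed_dataset()].
#' @param ratios length-3 positive vector (train, val, test) summing to 1.
#' @param seed split seed.
#' @return `ratio_split`: `list(train =, val =, test =)` of `windowed_dataset`s.
#' @export
ratio_split <- function(dataset, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stop_if_not(length(ratios) == 3L && all(ratios > 0) &&
                abs(sum(ratios) - 1) < 1e-8,
              "ratios must be three positive numbers summing to 1")
  a <- stratified_assign(dataset$labels, ratios, seed)
  list(train = dataset_subset(dataset, a == 1L),
       val = dataset_subset(dataset, a == 2L),
       test = dataset_subset(dataset, a == 3L))
}

#' @rdname ratio_split
#' @param k number of folds (>= 2, at most the number of windows).
#' @return `kfold_folds`: list of `list(train =, test =)` index lists.
#' @export
kfold_folds <- function(dataset, k = 5L, seed = 1L) {
  n <- length(dataset$labels)
  stop_if_not(k >= 2L && k <= n, "k must lie in [2, number of windows]")
  a <- stratified_assign(dataset$labels, rep(1 / k, k), seed)
  lapply(seq_len(k), function(i)
    list(train = which(a != i), test = which(a == i)))
}

#' Confusion matrix from labels and predictions
#'
#' @param true,pred integer class indices in `1..n_classes`.
#' @param class_names class vocabulary.
#' @return An `n x n` integer matrix (rows = true, columns = predicted) of
#'   class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, pred, class_names) {
  k <- length(class_names)
  m <- matrix(0L, k, k, dimnames = list(true = class_names, pred = class_names))
  for (i in seq_along(true)) m[true[i], pred[i]] <- m[true[i], pred[i]] + 1L
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class and aggregate metrics from a confusion matrix
#'
#' One-vs-rest per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`; overall accuracy is the diagonal fraction. Cells with a
#' zero denominator yield 0 and raise the `zero_denominator` flag so macro
#' averages stay defined. Macro (unweighted) averaging is reported;
#' `weighted = TRUE` weights classes by support.
#'
#' @param confusion square count matrix, rows = true classes.
#' @param weighted use support-weighted instead of macro averaging.
#' @return An `eval_report` list: `confusion`, `per_class` (data.frame),
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `zero_denominator`.
#' @export
compute_metrics <- function(confusion, weighted = FALSE) {
  m <- unclass(as.matrix(confusion))
  stop_if_not(nrow(m) == ncol(m) && nrow(m) > 0L, "confusion matrix must be square")
  stop_if_not(sum(m) > 0L, "empty confusion matrix")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  f1 <- safe(2 * prec * rec, prec + rec)
  flag <- any(tp + fp == 0) || any(tp + fn == 0) || any(prec + rec == 0)
  w <- if (weighted) rowSums(m) / sum(m) else rep(1 / nrow(m), nrow(m))
  cls <- rownames(m) %||% paste0("class", seq_len(nrow(m)))
  structure(list(
    confusion = m,
    per_class = data.frame(class = cls, precision = prec, recall = rec, f1 = f1,
                           support = rowSums(m), row.names = NULL),
    accuracy = sum(tp) / sum(m),
    macro_precision = sum(w * prec), macro_recall = sum(w * rec),
    macro_f1 = sum(w * f1),
    zero_denominator = flag), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f, macro F1 %.4f over %d classes\n",
              x$accuracy, x$macro_f1, nrow(x$per_class)))
  if (!is.null(x$fold_mean))
    cat(sprintf("  folds: %d; mean accuracy %.4f (sd %.4f)\n",
                length(x$fold_accuracy), x$fold_mean$accuracy,
                x$fold_sd$accuracy))
  invisible(x)
}

#' Train and evaluate under a cross-validation protocol
#'
#' Trains one model per fold (`loso`, `kfold`) or once on the train portion
#' (`ratio`), evaluates on the fold's test windows, and aggregates every
#' statistic as mean and standard deviation across folds. Each fold's model is
#' re-initialized from a fold-indexed seed, so folds are independent yet the
#' whole run is reproducible.
#'
#' @param dataset a [windowed_dataset()].
#' @param config a [model_config()].
#' @param tcfg a [train_config()].
#' @param protocol `"loso"`, `"ratio"` or `"kfold"`.
#' @param ratios,k protocol parameters for `ratio` / `kfold`.
#' @param verbose print fold progress.
#' @return An `eval_report` with pooled confusion matrix plus `fold_accuracy`,
#'   `fold_f1`, `fold_mean`, `fold_sd`, and the per-fold confusion matrices.
#' @export
run_protocol <- function(dataset, config, tcfg = train_config(),
                         protocol = c("loso", "ratio", "kfold"),
                         ratios = c(0.7, 0.1, 0.2), k = 5L, verbose = FALSE) {
  protocol <- match.arg(protocol)
  if (protocol == "ratio") {
    sp <- ratio_split(dataset, ratios, seed = tcfg$seed)
    fit <- train_model(sp$train, config, tcfg)
    pred <- predict(fit, sp$test)
    cm <- confusion_matrix(sp$test$labels, pred, dataset$class_names)
    rep1 <- compute_metrics(cm)
    rep1$fold_accuracy <- rep1$accuracy
    rep1$fold_confusions <- list(cm)
    return(rep1)
  }
  folds <- switch(protocol,
    loso = loso_folds(dataset),
    kfold = kfold_folds(dataset, k, seed = tcfg$seed))
  cms <- list(); accs <- numeric(0); f1s <- numeric(0)
  for (i in seq_along(folds)) {
    fo <- folds[[i]]
    tr <- dataset_subset(dataset, fo$train)
    te <- dataset_subset(dataset, fo$test)
    fold_tcfg <- tcfg
    fold_tcfg$seed <- tcfg$seed + i  # fold-indexed re-initialization
    fit <- train_model(tr, config, fold_tcfg)
    pred <- predict(fit, te)
    cm <- confusion_matrix(te$labels, pred, dataset$class_names)
    met <- compute_metrics(cm)
    cms[[i]] <- cm; accs[i] <- met$accuracy; f1s[i] <- met$macro_f1
    if (verbose) message(sprintf("fold %d/%d (%s): accuracy %.4f",
                                 i, length(folds), fo$subject %||% "", met$accuracy))
  }
  pooled <- Reduce(`+`, lapply(cms, unclass))
  rep1 <- compute_metrics(pooled)
  rep1$fold_accuracy <- accs
  rep1$fold_f1 <- f1s
  rep1$fold_mean <- list(accuracy = mean(accs), f1 = mean(f1s))
  rep1$fold_sd <- list(accuracy = stats::sd(accs), f1 = stats::sd(f1s))
  rep1$fold_confusions <- cms
  rep1
}

#' Ablation suite over the three feature blocks
#'
#' Evaluates the six canonical configurations — without the channel-attention
#' shrinkage (C), without the temporal branch (T), without the multi-scale
#' branch (M), without T and M, without all three, and the full model — under
#' one fixed protocol and seed, and returns an accuracy table.
#'
#' @param dataset a [windowed_dataset()].
#' @param base_config full [model_config()] (all blocks enabled).
#' @param tcfg a [train_config()].
#' @param protocol passed to [run_protocol()].
#' @param verbose print progress.
#' @return data.frame with columns `model`, `accuracy`, `macro_f1`,
#'   `parameters`.
#' @export
ablation_suite <- function(dataset, base_config, tcfg = train_config(),
                           protocol = "loso", verbose = FALSE) {
  stop_if_not(base_config$enable_casb && base_config$enable_tfeb &&
                base_config$enable_msfeb,
              "base_config must have all blocks enabled")
  variants <- list(
    "Without C" = c(casb = FALSE, tfeb = TRUE, msfeb = TRUE),
    "Without T" = c(casb = TRUE, tfeb = FALSE, msfeb = TRUE),
    "Without M" = c(casb = TRUE, tfeb = TRUE, msfeb = FALSE),
    "Without T and M" = c(casb = TRUE, tfeb = FALSE, msfeb = FALSE),
    "Without C, T, and M" = c(casb = FALSE, tfeb = FALSE, msfeb = FALSE),
    "RMFSN" = c(casb = TRUE, tfeb = TRUE, msfeb = TRUE))
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    cfg <- base_config
    cfg$enable_casb <- v[["casb"]]; cfg$enable_tfeb <- v[["tfeb"]]
    cfg$enable_msfeb <- v[["msfeb"]]
    if (verbose) message("ablation: ", nm)
    rep1 <- run_protocol(dataset, cfg, tcfg, protocol)
    data.frame(model = nm,
               accuracy = rep1$fold_mean$accuracy %||% rep1$accuracy,
               macro_f1 = rep1$macro_f1,
               parameters = count_parameters(cfg))
  })
  do.call(rbind, rows)
}

#' Channel-selection heatmap of the shrinkage block
#'
#' Records, for each evaluated window, either the post-shrinkage activation
#' magnitude or the binary survival mask (`|x| > tau`) per feature channel and
#' timestep — the map that visualizes which feature channels the block keeps
#' for a given activity.
#'
#' @param fit a trained `rmfsn_fit` with the shrinkage block enabled.
#' @param windows a [windowed_dataset()] or window array.
#' @param mode `"magnitude"` or `"mask"`.
#' @return A list of `filters x timesteps` matrices, one per window.
#' @export
selection_heatmap <- function(fit, windows, mode = c("magnitude", "mask")) {
  mode <- match.arg(mode)
  stop_if_not(fit$config$enable_casb,
              "selection heatmaps require the shrinkage block to be enabled")
  x <- as_batch(windows, fit$config)
  out <- model_forward(x, fit$params, fit$config, fit$state, training = FALSE)
  mask <- out$cache$casb$mask
  xin <- out$cache$casb$x
  taux <- out$cache$casb$taux
  lapply(seq_len(dim(x)[3L]), function(i) {
    if (mode == "mask") mask[, , i] * 1
    else pmax(abs(xin[, , i]) - taux[, , i], 0)
  })
}
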