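#' Training configuration
#'
#' @param epochs full passes over the training windows.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param device label recorded in reports (computation is CPU-only).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, learning_rate = 1e-3,
                         seed = 1L, device = "cpu") {
  stop_if_not(is_count(epochs) && is_count(batch_size), "epochs and batch_size must be >= 1")
  stop_if_not(learning_rate > 0, "learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 device = device),
            class = "train_config")
}

ce_loss <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(labels, seq_along(labels))], 1e-12)))
}

# Adam moment/step update applied recursively over the parameter structure.
adam_step <- function(params, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(params)) {
    keys <- names(params) %||% seq_along(params)
    for (k in keys) {
      if (is.null(grads[[k]])) next
      upd <- adam_step(params[[k]], grads[[k]], m[[k]], v[[k]], lr, t,
                       beta1, beta2, eps)
      params[[k]] <- upd$p; m[[k]] <- upd$m; v[[k]] <- upd$v
    }
    return(list(p = params, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = params - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

zeros_like <- function(x) if (is.list(x)) lapply(x, zeros_like) else x * 0

#' Train the network with cross-entropy and Adam
#'
#' Minimizes multinomial cross-entropy over shuffled mini-batches with the
#' adaptive-moment (Adam) optimizer. Fully seeded: initialization, shuffling
#' and dropout all derive from `tcfg$seed`, so a given seed and dataset give
#' an identical loss history.
#'
#' @param dataset training [windowed_dataset()] covering at least two classes.
#' @param config a [model_config()].
#' @param tcfg a [train_config()].
#' @param init optional `list(params, state)` to continue from.
#' @param verbose print per-epoch mean loss.
#' @return `list(params, state, loss_history, config, tcfg)` of class
#'   `rmfsn_fit`.
#' @export
train_model <- function(dataset, config, tcfg = train_config(), init = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  n <- dim(dataset$data)[1L]
  stop_if_not(n > 0L, "empty training dataset")
  stop_if_not(length(unique(dataset$labels)) >= 2L,
              "training data must cover at least two classes")
  mdl <- init %||% init_model(config, seed = tcfg$seed)
  params <- mdl$params; state <- mdl$state
  m <- zeros_like(params); v <- zeros_like(params)
  set.seed(tcfg$seed + 1L)  # shuffling / dropout stream
  loss_hist <- numeric(tcfg$epochs)
  step <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    ep_loss <- 0
    for (bidx in batches) {
      x <- as_batch(dataset$data[bidx, , , drop = FALSE], config)
      labs <- dataset$labels[bidx]
      fw <- model_forward(x, params, config, state, training = TRUE)
      state <- fw$state
      loss <- ce_loss(fw$probs, labs)
      ep_loss <- ep_loss + loss * length(bidx)
      dlogits <- (fw$probs - one_hot(labs, config$n_classes)) / length(bidx)
      grads <- model_backward(dlogits, params, config, fw$cache)
      step <- step + 1L
      upd <- adam_step(params, grads, m, v, tcfg$learning_rate, step)
      params <- upd$p; m <- upd$m; v <- upd$v
    }
    loss_hist[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, loss_hist[ep]))
  }
  structure(list(params = params, state = state, loss_history = loss_hist,
                 config = config, tcfg = tcfg),
            class = "rmfsn_fit")
}

#' @export
print.rmfsn_fit <- function(x, ...) {
  cat(sprintf("<rmfsn_fit> %d filters, %d classes; %d epochs, final loss %.4f\n",
              x$config$filters, x$config$n_classes,
              length(x$loss_history), utils::tail(x$loss_history, 1L)))
  invisible(x)
}

#' Predict class labels for windows
#'
#' @param object an `rmfsn_fit`.
#' @param newdata a [windowed_dataset()] or window array.
#' @param type `"class"` for label indices, `"prob"` for the probability matrix.
#' @param ... unused.
#' @export
predict.rmfsn_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- rmfsn_forward(newdata, object$params, object$config, object$state)
  if (type == "prob") probs else max.col(probs, ties.method = "first")
}

#' Save / load a model checkpoint
#'
#' Serialized-tensor container (RDS) plus a JSON config sidecar.
#' @param fit an `rmfsn_fit`.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit[c("params", "state", "loss_history", "tcfg")], path)
  jsonlite::write_json(unclass(fit$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- readRDS(path)
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, cfgl)
  structure(c(raw, list(config = cfg)), class = "rmfsn_fit")
}
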