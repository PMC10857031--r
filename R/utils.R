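# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

stop_if_not <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

#' @keywords internal
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

# Collapse (C, T, B) <-> (C, T*B) without copying semantics surprises.
mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], d[2L] * d[3L])
  x
}

arr3 <- function(x, ti, b) {
  dim(x) <- c(nrow(x), ti, b)
  x
}

# One-hot matrix (K x B) from integer labels in 1..K.
one_hot <- function(labels, k) {
  b <- length(labels)
  y <- matrix(0, k, b)
  y[cbind(labels, seq_len(b))] <- 1
  y
}
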