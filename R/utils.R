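#' Derive a child seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage label to a child
#' seed, so that every stochastic stage of a pipeline run has its own
#' reproducible stream.  Kept strictly below 2^31 so the result is always a
#' valid R integer.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return integer seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # small multiplicative hash of the label, folded into the seed
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
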