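#' Derive a reproducible sub-seed from a global seed and a stage label
#'
#' Stages of the pipeline consume independent random streams derived from one
#' global seed, so any stage can be re-run in isolation and reproduce its
#' output. The derivation hashes the label into a fixed offset and folds it
#' into the seed modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer global seed.
#' @param label character stage label, e.g. `"simulate"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  s <- (abs(as.numeric(seed)) * 48271 + h) %% 2147483646
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sswool <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "sswool_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
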