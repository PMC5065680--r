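`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Thin wrapper around [withr::with_seed()] so that every stochastic step in
#' the pipeline can be replayed exactly from a recorded integer seed without
#' disturbing the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a child seed from a base seed and a stage index, kept below 2^31.
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  s <- as.double(base_seed)
  for (k in idx) s <- (s * 69069 + k) %% 2147483629
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
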