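# Internal helpers: argument checks, error conditions, seed derivation.

ecoStop <- function(class, msg, call. = FALSE, data = NULL) {
  cond <- structure(
    class = c(class, "ecogrs_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, data = data)
  )
  stop(cond)
}

checkFinite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    ecoStop("ecogrs_invalid_argument", sprintf("'%s' must be finite numeric", what))
  invisible(x)
}

checkProb <- function(x, what, openRight = FALSE) {
  checkFinite(x, what)
  hi <- if (openRight) x >= 1 else x > 1
  if (any(x < 0) || any(hi))
    ecoStop("ecogrs_invalid_argument",
            sprintf("'%s' must lie in [0,%s", what, if (openRight) "1)" else "1]"))
  invisible(x)
}

checkFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    ecoStop("ecogrs_invalid_argument", sprintf("'%s' must be TRUE or FALSE", what))
  invisible(x)
}

# Derive per-stage sub-seeds from one master seed by fixed offsets, keeping
# the result inside the 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483587) + 1L
}

# Inverse logit, numerically safe at the extremes.
invLogit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
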