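# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Root-mean-square error between two equal-length vectors.
#' Root-mean-square error
#'
#' @param a,b numeric vectors of equal length.
#' @return RMSE as a single number.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stopf("rmse: length mismatch (%d vs %d)", length(a), length(b))
  sqrt(mean((a - b)^2))
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919 + 11) %% 2147483647)
}
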