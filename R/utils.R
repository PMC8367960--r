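#' Round half away from zero
#'
#' Deterministic "half-up" rounding used wherever a printed table or an
#' integer head-count is reproduced. Base [round()] rounds half to even
#' (banker's rounding), which cannot reproduce conventionally rounded
#' field-report tables.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (>= 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(1.905, 2)   # 1.91
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 1.905 (stored below .905)
  # still round up as printed field tables do
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Truncate toward zero at a number of decimals
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (>= 0).
#' @return numeric vector truncated toward zero.
#' @export
trunc_decimals <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  trunc(x * p + sign(x) * sqrt(.Machine$double.eps)) / p
}

# collect validation failures and raise them all at once
validate_all <- function(checks) {
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    stop("validation failed: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible 32-bit sub-seed from a root seed and a stream label,
# so adding a generator never shifts another generator's draws
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}
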