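#' @keywords internal
"_PACKAGE"

#' z-score a numeric vector
#'
#' Centres and scales using the mean and standard deviation of the
#' non-missing values. A vector with zero variance returns zeros (with a
#' warning) rather than NaN so that degenerate synthetic columns do not
#' poison downstream models.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length with mean 0 and SD 1 over the
#'   non-missing entries.
#' @export
zscore <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("zero or undefined variance; returning centred zeros")
    return(ifelse(is.na(x), NA_real_, 0))
  }
  (x - m) / s
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Run code with a locally seeded RNG
#'
#' Evaluates `expr` after seeding the RNG, restoring the caller's RNG state
#' on exit so that library code does not perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit seed from a base seed, so that separate
# stages draw from reproducible but non-overlapping streams. Arithmetic in
# doubles to avoid 32-bit overflow; the result always fits in an integer.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 1e6) * 1103 + (as.numeric(stream) %% 1e6) * 12347
  as.integer(s %% 2147483562) + 1L
}
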