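#' Run code with a temporary, isolated RNG seed
#'
#' All stochastic operators in the package take an explicit `seed` and leave
#' the caller's RNG state untouched.
#'
#' @param seed integer seed.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a reproducible sub-seed from a base seed and a small stream offset,
# kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 97 + 1) %% 2147483647L)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (non_negative && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_vec3 <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a numeric 3-vector.", name))
  }
  if (positive && any(x <= 0)) abort(sprintf("`%s` must be > 0 in every axis.", name))
  invisible(x)
}

# Recycle a scalar or 3-vector expansion factor to per-axis form.
as_lambda3 <- function(lambda) {
  if (length(lambda) == 1L) rep(as.numeric(lambda), 3L) else as.numeric(lambda)
}

fmt_num <- function(x) signif(x, 6)
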