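# Shared helpers: link functions, the 5-year age grid, Wilson intervals.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' The modelling age grid
#'
#' Age-specific quantities are modelled on a fixed grid of 5-year band
#' midpoints (17, 22, ..., 62) plus a single open-ended 65+ cell, evaluated
#' at 65. Prevalence is assumed constant above 65 because survey data above
#' that age are scarce.
#'
#' @return Numeric vector of grid ages (length 11).
#' @export
age_grid <- function() c(seq(17, 62, by = 5), 65)

# Lower bounds of the grid bands: 15, 20, ..., 60, 65(+).
age_band_lower <- function() c(seq(15, 60, by = 5), 65)

# Index of the grid band containing age a (a >= 15; ages above 65 fold into
# the top cell).
age_band_index <- function(a) {
  if (any(a < 15)) stop("ages below 15 are outside the modelling grid")
  pmin(floor((a - 15) / 5) + 1L, 11L)
}

# Grid cell indices spanned by a closed age band [lower, upper];
# upper = Inf denotes an open-ended band.
age_band_indices <- function(lower, upper) {
  lo <- age_band_index(lower)
  hi <- if (is.infinite(upper)) 11L else age_band_index(min(upper, 65))
  if (hi < lo) stop("age band upper bound below lower bound")
  seq.int(lo, hi)
}

#' Wilson score interval upper limit
#'
#' Upper limit of the Wilson 95% (by default) score interval for a binomial
#' proportion, without continuity correction.
#'
#' @param p Observed proportion.
#' @param n Sample size.
#' @param level Confidence level (default 0.95).
#' @return Upper confidence limit.
#' @export
wilson_upper <- function(p, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

#' Invert the Wilson upper limit for the effective sample size
#'
#' Finds the sample size n at which the Wilson upper confidence limit for
#' proportion \code{p} equals a reported (design-adjusted) upper limit.
#' Wider reported intervals than simple random sampling would give imply a
#' smaller effective n.
#'
#' @param p Observed proportion, in (0, 1).
#' @param upper Reported upper confidence limit (must exceed \code{p}).
#' @param n_max Upper bracket for the search (default 1e7).
#' @param level Confidence level of the reported interval.
#' @param tol Convergence tolerance on the upper limit.
#' @return Effective sample size (positive real), or NA with a warning when
#'   the inversion is not bracketed in [1, n_max].
#' @export
wilson_invert_n <- function(p, upper, n_max = 1e7, level = 0.95, tol = 1e-6) {
  if (upper <= p) stop("reported upper limit must exceed the proportion")
  f <- function(n) wilson_upper(p, n, level) - upper
  # wilson_upper is decreasing in n: f(1) should be >= 0, f(n_max) <= 0
  if (f(1) < 0 || f(n_max) > 0) {
    warning("Wilson inversion not bracketed; falling back to design effect")
    return(NA_real_)
  }
  stats::uniroot(f, c(1, n_max), tol = tol)$root
}

# round-half-up preserving sums is not needed; base round suffices for counts
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
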