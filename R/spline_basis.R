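# Natural cubic spline bases for age patterns and time trends.

#' Candidate age-spline knot sets
#'
#' The eight interior-knot configurations considered for the age pattern:
#' one knot at 20, 25, 30, or 35, or two knots at (20,35), (20,40),
#' (25,35), (25,40).
#'
#' @return List of numeric vectors.
#' @export
age_knot_candidates <- function() {
  list(20, 25, 30, 35, c(20, 35), c(20, 40), c(25, 35), c(25, 40))
}

.make_spline_basis <- function(kind, knots, boundary, center, eval_at,
                               recode_top = NULL) {
  if (any(knots <= boundary[1] | knots >= boundary[2]))
    stop("interior knot(s) outside (", boundary[1], ", ", boundary[2], ")")
  template <- splines::ns(seq(boundary[1], boundary[2], length.out = 50),
                          knots = knots, Boundary.knots = boundary)
  evaluate <- function(x) {
    if (!is.null(recode_top)) x <- pmin(x, recode_top)
    b <- stats::predict(template, x)
    ctr <- stats::predict(template, if (is.null(recode_top)) center
                          else min(center, recode_top))
    sweep(b, 2, as.numeric(ctr))
  }
  structure(list(kind = kind, knots = knots, boundary = boundary,
                 center = center, K = length(knots) + 1L,
                 eval_at = eval_at, matrix = evaluate(eval_at),
                 evaluate = evaluate),
            class = "spline_basis")
}

#' Natural cubic spline basis over age
#'
#' Basis evaluated at the 5-year band midpoints of the modelling age grid.
#' Natural (restricted) cubic splines are linear beyond the boundary knots;
#' ages above 65 are recoded to 65 before evaluation so the modelled
#' prevalence is constant in the open-ended 65+ band, and the basis is
#' centered at age 30 (each column is zero there), which identifies the
#' hierarchical intercepts as the logit prevalence at age 30.
#'
#' @param knots Interior knot position(s); the conventional candidates are
#'   \code{\link{age_knot_candidates}}, but any knots in (15, 65) are
#'   accepted.
#' @param boundary Boundary knots (default c(15, 65)).
#' @param center Centering age (default 30).
#' @return A \code{spline_basis}: interior \code{knots}, \code{boundary},
#'   basis dimension \code{K} (interior knots + 1), the basis
#'   \code{matrix} over \code{\link{age_grid}}, and an \code{evaluate}
#'   function for arbitrary ages.
#' @export
build_age_spline_basis <- function(knots = 30, boundary = c(15, 65),
                                   center = 30) {
  .make_spline_basis("age", knots, boundary, center, age_grid(),
                     recode_top = 65)
}

#' Natural cubic spline basis over calendar time
#'
#' One interior knot at the median year of data collection (2011 by
#' default), centered there, evaluated over the span of study years.
#'
#' @param years Calendar years covered (default 2000:2018).
#' @param knot Interior knot year (default 2011).
#' @param center Centering year (default the knot).
#' @return A \code{spline_basis} over \code{years}.
#' @export
build_time_spline_basis <- function(years = 2000:2018, knot = 2011,
                                    center = knot) {
  .make_spline_basis("time", knot, range(years), center, years)
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Natural cubic spline basis (", x$kind, ")\n", sep = "")
  cat("  interior knots:", paste(x$knots, collapse = ", "),
      " boundary: [", x$boundary[1], ", ", x$boundary[2], "]\n", sep = "")
  cat("  K =", x$K, " centered at", x$center, "\n")
  invisible(x)
}
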