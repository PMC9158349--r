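# Post-processing: country predictions, imputation of data-less countries,
# and population-weighted aggregation to broad age groups, regions, and the
# world.

#' Posterior prediction draws for countries with data
#'
#' Evaluates the prediction equation per posterior draw: global +
#' super-region + region + country intercepts plus the country's age and
#' time spline terms, inverse-logit transformed. Study-level effects and
#' crosswalk offsets are excluded: predictions are at the reference
#' (gold-standard) instrument for a nationally representative population.
#'
#' @param fit An \code{ipv_fit}.
#' @param countries Country codes (default all countries in the fit).
#' @param ages Age-grid values (default the full \code{\link{age_grid}}).
#' @param year Calendar year of prediction (default the time-basis center).
#' @return Array \code{[draw, country, age]} of prevalence draws, with an
#'   \code{ages} attribute.
#' @export
predict_country <- function(fit, countries = NULL, ages = age_grid(),
                            year = NULL) {
  spec <- fit$spec
  countries <- countries %||% spec$countries
  year <- year %||% spec$time_basis$center
  miss <- setdiff(countries, spec$countries)
  if (length(miss))
    stop("country not in the fitted model (use impute_country): ",
         paste(miss, collapse = ", "))
  ci <- match(countries, spec$countries)
  d <- fit$draws
  nd <- fit$n_draws
  Arows <- spec$age_basis$evaluate(ages)
  Trow <- as.numeric(spec$time_basis$evaluate(year))
  out <- array(NA_real_, c(nd, length(countries), length(ages)),
               dimnames = list(NULL, countries, ages))
  for (j in seq_along(ci)) {
    c_ <- ci[j]
    z <- spec$country_super[c_]; r <- spec$country_region[c_]
    alpha <- d$u_g + d$u_z[, z] + d$u_r[, r] + d$u_c[, c_]
    lam <- vapply(seq_len(spec$age_basis$K), function(k)
      d$eta_g[, k] + d$eta_z[, z, k] + d$eta_r[, r, k] + d$eta_c[, c_, k],
      numeric(nd))
    phi <- vapply(seq_len(spec$time_basis$K), function(k)
      d$phi_g[, k] + d$phi_z[, z, k] + d$phi_r[, r, k] + d$phi_c[, c_, k],
      numeric(nd))
    tt <- as.numeric(phi %*% Trow)
    out[, j, ] <- inv_logit(alpha + tt + lam %*% t(Arows))
  }
  attr(out, "ages") <- ages
  attr(out, "year") <- year
  out
}

#' Impute prediction draws for a country without data
#'
#' A data-less country inherits its region's posterior curve plus fresh
#' country-level deviations drawn per posterior draw from their estimated
#' distributions: an intercept from N(0, sigma_c) and (by default) age
#' spline deviations from N(0, upsilon_k); time-trend deviations are
#' shared with the region unless \code{time_deviation = TRUE}. The extra
#' sampling widens the intervals relative to sibling countries with data.
#'
#' @param fit An \code{ipv_fit}.
#' @param region_id,super_region_id Location of the country in the
#'   hierarchy; a region with no fitted data also receives a fresh
#'   regional deviation (its super-region must appear in the fit).
#' @param ages,year As \code{\link{predict_country}}.
#' @param age_deviation Draw fresh age-spline deviations (default TRUE).
#' @param time_deviation Draw fresh time-trend deviations (default FALSE).
#' @param seed Seed for the fresh deviations.
#' @return Array \code{[draw, 1, age]} of prevalence draws, flagged with
#'   attribute \code{imputed = TRUE}.
#' @export
impute_country <- function(fit, region_id, super_region_id = NULL,
                           ages = age_grid(), year = NULL,
                           age_deviation = TRUE, time_deviation = FALSE,
                           seed = 1) {
  spec <- fit$spec
  year <- year %||% spec$time_basis$center
  r <- match(region_id, spec$regions)
  z <- if (is.null(super_region_id)) {
    if (is.na(r)) stop("region not in the fitted model and no ",
                       "super_region_id given: ", region_id)
    # region determines the super-region among fitted countries
    spec$country_super[match(r, spec$country_region)]
  } else match(super_region_id, spec$supers)
  if (is.na(z)) stop("super-region not in the fitted model")
  d <- fit$draws
  nd <- fit$n_draws
  set.seed(seed)
  u_new <- stats::rnorm(nd, 0, d$sigma_c)
  Ka <- spec$age_basis$K; Kt <- spec$time_basis$K
  eta_new <- if (age_deviation)
    vapply(seq_len(Ka), function(k) stats::rnorm(nd, 0, d$ups_c[, k]),
           numeric(nd))
  else matrix(0, nd, Ka)
  phi_new <- if (time_deviation)
    vapply(seq_len(Kt), function(k) stats::rnorm(nd, 0, d$om_c[, k]),
           numeric(nd))
  else matrix(0, nd, Kt)
  # a region with no fitted data gets a fresh regional effect as well
  u_r_part <- if (is.na(r)) stats::rnorm(nd, 0, d$sigma_r) else d$u_r[, r]
  eta_r_part <- function(k)
    if (is.na(r)) stats::rnorm(nd, 0, d$ups_r[, k]) else d$eta_r[, r, k]
  phi_r_part <- function(k)
    if (is.na(r)) stats::rnorm(nd, 0, d$om_r[, k]) else d$phi_r[, r, k]
  alpha <- d$u_g + d$u_z[, z] + u_r_part + u_new
  lam <- vapply(seq_len(Ka), function(k)
    d$eta_g[, k] + d$eta_z[, z, k] + eta_r_part(k) + eta_new[, k],
    numeric(nd))
  phi <- vapply(seq_len(Kt), function(k)
    d$phi_g[, k] + d$phi_z[, z, k] + phi_r_part(k) + phi_new[, k],
    numeric(nd))
  Arows <- spec$age_basis$evaluate(ages)
  Trow <- as.numeric(spec$time_basis$evaluate(year))
  out <- array(inv_logit(alpha + as.numeric(phi %*% Trow) +
                           lam %*% t(Arows)),
               c(nd, 1, length(ages)),
               dimnames = list(NULL, "imputed", ages))
  attr(out, "ages") <- ages
  attr(out, "year") <- year
  attr(out, "imputed") <- TRUE
  out
}

#' Jointly constrained lifetime and past-year predictions
#'
#' Applies the joint outcome constraints (past-year prevalence at most the
#' lifetime prevalence everywhere; lifetime at most 3 times past-year in
#' the 15-19 band) to aligned prediction draws from the two outcome fits.
#' The constraints bind at prediction for countries lacking data on one
#' (or both) outcomes: for each target country, the side with data is
#' predicted from its fit and the missing side imputed from its region,
#' then violating aligned draw pairs are rejected (or projected, with
#' \code{mode = "cap"}).
#'
#' @param fit_lifetime,fit_past_year Fits of the two outcomes (equal
#'   numbers of posterior draws).
#' @param hierarchy \code{geo_hierarchy}.
#' @param countries Target country codes; defaults to countries present in
#'   exactly one of the two fits.
#' @param ages,year As \code{\link{predict_country}}.
#' @param mode,rr_max,min_acceptance Passed to
#'   \code{\link{apply_constraints}}.
#' @param seed Seed for the imputation draws.
#' @return List with constrained draw arrays \code{lifetime} and
#'   \code{past_year} (\code{[draw, country, age]}), the \code{acceptance}
#'   rate and \code{retained} indices.
#' @export
constrained_predictions <- function(fit_lifetime, fit_past_year, hierarchy,
                                    countries = NULL, ages = age_grid(),
                                    year = NULL, mode = "reject",
                                    rr_max = 3, min_acceptance = 0.01,
                                    seed = 1) {
  if (fit_lifetime$n_draws != fit_past_year$n_draws)
    stop("the two fits must have equal numbers of draws to align")
  if (is.null(countries)) {
    countries <- union(
      setdiff(fit_lifetime$spec$countries, fit_past_year$spec$countries),
      setdiff(fit_past_year$spec$countries, fit_lifetime$spec$countries))
    if (!length(countries))
      stop("no countries lack one outcome; supply `countries` explicitly")
  }
  get_draws <- function(fit, cc, k) {
    if (cc %in% fit$spec$countries)
      predict_country(fit, cc, ages, year)
    else {
      h <- hierarchy_lookup(hierarchy, cc)
      impute_country(fit, h$region_id, h$super_region_id, ages, year,
                     seed = seed + k)
    }
  }
  nd <- fit_lifetime$n_draws
  life <- array(NA_real_, c(nd, length(countries), length(ages)),
                dimnames = list(NULL, countries, ages))
  past <- life
  for (k in seq_along(countries)) {
    life[, k, ] <- get_draws(fit_lifetime, countries[k], k)
    past[, k, ] <- get_draws(fit_past_year, countries[k], 1000 + k)
  }
  con <- apply_constraints(matrix(life, nd), matrix(past, nd),
                           ages = rep(ages, each = length(countries)),
                           rr_max = rr_max, mode = mode,
                           min_acceptance = min_acceptance)
  nk <- nrow(con$lifetime)
  out_l <- array(con$lifetime, c(nk, length(countries), length(ages)),
                 dimnames = list(NULL, countries, ages))
  out_p <- array(con$past_year, c(nk, length(countries), length(ages)),
                 dimnames = list(NULL, countries, ages))
  attr(out_l, "ages") <- ages; attr(out_p, "ages") <- ages
  attr(out_l, "year") <- year %||% fit_lifetime$spec$time_basis$center
  attr(out_p, "year") <- attr(out_l, "year")
  list(lifetime = out_l, past_year = out_p,
       acceptance = con$acceptance, retained = con$retained)
}

#' Aggregate prevalence draws over ages and geography
#'
#' Within each country, age-specific prevalence draws are collapsed to a
#' broad age group using weights equal to the 2018 female population times
#' the proportion of women who ever had sex (the ever-partnered
#' denominator proxy). Aggregation to region, super-region, or the world
#' sums the implied numbers of affected women across member countries
#' before dividing by the summed weights (count-summing), per draw; the
#' draws are then summarized by the posterior median and equal-tailed 95%
#' credible interval.
#'
#' @param country_draws Array \code{[draw, country, age]} (from
#'   \code{\link{predict_country}}; imputed countries may be bound in).
#' @param population2018 2018 population table with
#'   \code{ever_sex_proportion}.
#' @param hierarchy \code{geo_hierarchy}.
#' @param level \code{"country"}, \code{"region"}, \code{"super_region"}
#'   or \code{"global"}.
#' @param age_range Broad age group as \code{c(lower, upper)} (default
#'   15-49); upper may be \code{Inf}.
#' @param level_prob Credible level (default 0.95).
#' @return Data frame of prevalence estimates: one row per unit with
#'   median and credible bounds.
#' @export
aggregate_prevalence <- function(country_draws, population2018, hierarchy,
                                 level = c("country", "region",
                                           "super_region", "global"),
                                 age_range = c(15, 49),
                                 level_prob = 0.95) {
  level <- match.arg(level)
  ages <- attr(country_draws, "ages") %||%
    as.numeric(dimnames(country_draws)[[3]])
  cells <- age_band_indices(age_range[1], age_range[2])
  cell_ages <- age_grid()[cells]
  keep <- match(cell_ages, ages)
  if (anyNA(keep))
    stop("country_draws do not cover the requested age range")
  countries <- dimnames(country_draws)[[2]]
  nd <- dim(country_draws)[1]
  # per-country ever-sex-weighted age weights and broad prevalence draws
  Wc <- numeric(length(countries))
  prev <- matrix(NA_real_, nd, length(countries))
  for (j in seq_along(countries)) {
    pw <- population_grid_weights(population2018, countries[j])
    esp <- pw$ever_sex_proportion %||% rep(1, nrow(pw))
    w <- pw$weight[cells] * esp[cells]
    Wc[j] <- sum(w)
    prev[, j] <- (country_draws[, j, keep, drop = FALSE][, 1, ] %*% w) /
      sum(w)
  }
  h <- hierarchy_lookup(hierarchy, countries)
  unit <- switch(level, country = countries, region = h$region_id,
                 super_region = h$super_region_id,
                 global = rep("global", length(countries)))
  q <- c((1 - level_prob) / 2, 0.5, 1 - (1 - level_prob) / 2)
  rows <- lapply(unique(unit), function(u) {
    j <- which(unit == u)
    agg <- (prev[, j, drop = FALSE] %*% Wc[j]) / sum(Wc[j])
    s <- stats::quantile(agg, q, names = FALSE)
    data.frame(level = level, unit = u,
               age_group = paste0(age_range[1], "-",
                                  ifelse(is.infinite(age_range[2]), "plus",
                                         age_range[2])),
               median = s[2], ci_lower = s[1], ci_upper = s[3],
               n_draws = nd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
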