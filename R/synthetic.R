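# Synthetic VAW-database generator: emits surveys with the statistical
# structure the hierarchical model assumes (nested random effects, spline
# age/time patterns, heterogeneous age bands, mixed instruments, missing
# denominators), with full ground truth retained for recovery testing.

#' Define the ground truth of a synthetic survey database
#'
#' Collects the generative settings: hierarchy sizes, random-effect
#' standard deviations, the true age and time spline coefficients, true
#' adjustment log odds ratios (defaults echo the magnitudes reported for
#' real crosswalk factors, e.g. a physical-only odds ratio near 0.86 for
#' lifetime IPV), instrument mix probabilities, and survey design
#' parameters. These defaults emulate the marginal characteristics of the
#' global IPV study database (about 85% nationally representative studies,
#' roughly half of observations needing some adjustment, design effect
#' 2.5).
#'
#' @param n_super,n_regions,n_countries Hierarchy sizes.
#' @param study_dist Probabilities of a country having 1, 2, 3, or 4
#'   studies.
#' @param seed Integer seed.
#' @param ... Overrides for any default setting (see the function body for
#'   the full list).
#' @return List of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(n_super = 2, n_regions = 3, n_countries = 6,
                            study_dist = c(0.6, 0.3, 0.1, 0), seed = 1,
                            ...) {
  truth <- list(
    n_super = n_super, n_regions = n_regions, n_countries = n_countries,
    study_dist = study_dist, seed = seed,
    years = 2000:2018, time_knot = 2011,
    # period weights for study year draws (2000-04, 05-09, 10-14, 15-18)
    period_weights = c(0.18, 0.21, 0.37, 0.24),
    # logit prevalence at age 30 in 2011 (~27% lifetime, ~13% past-year)
    u_g = c(lifetime = logit(0.27), past_year = logit(0.13)),
    sd_z = 0.35, sd_r = 0.25, sd_c = 0.35,
    sd_national = 0.18, tau_subnational = 0.18,
    age_knots = 25,
    eta_g = list(lifetime = c(0.9, 0.4), past_year = c(-0.6, -1.2)),
    sd_eta = c(z = 0.12, r = 0.08, c = 0.12),
    phi_g = list(lifetime = c(-0.08, -0.04), past_year = c(-0.06, -0.03)),
    sd_phi = c(z = 0.04, r = 0.03, c = 0.04),
    # true adjustment log odds ratios by outcome
    beta = list(
      lifetime = c(severe = log(0.38), physical_only = log(0.86),
                   sexual_only = log(0.26), all_women = log(0.79),
                   currently_partnered = log(0.91),
                   current_recent = log(0.84), urban = log(0.92),
                   rural = log(1.03)),
      past_year = c(severe = log(0.57), physical_only = log(0.81),
                    sexual_only = log(0.31), all_women = log(0.79),
                    currently_partnered = log(0.99),
                    current_recent = log(0.97), urban = log(0.91),
                    rural = log(1.04))),
    # per-study probabilities of needing each instrument adjustment
    # (marginal shares of studies requiring each adjustment in the global
    # IPV study database)
    p_covariate = c(severe = 0.013, physical_only = 0.21,
                    sexual_only = 0.016, all_women = 0.06,
                    currently_partnered = 0.09, current_recent = 0.31),
    # share of studies using the standard gold instrument outright (their
    # adjustments co-occur in the remainder, matching the observed excess
    # of fully reference observations over what independence would give)
    p_gold_standard = 0.30,
    # probability an affected study also reports the reference instrument
    p_reference_extra = 0.7,
    geo_probs = c(national = 0.85, urban = 0.055, rural = 0.045,
                  mixed_subnational = 0.05),
    # probability a national study also reports urban + rural strata
    p_geo_all3 = 0.10,
    p_both_outcomes = 0.85,
    p_age_bands = 0.6,          # 5-year bands 15-49 vs broad 15-49 only
    p_missing_denominator = 0.04,
    p_report_ci = 0.30,
    design_effect = 2.5,
    n_total_meanlog = c(national = log(2800), subnational = log(900)),
    n_total_sdlog = 0.4)
  dots <- list(...)
  truth[names(dots)] <- dots
  class(truth) <- "synthetic_truth"
  truth
}

# Smooth declining female age pyramid for one unit.
.pyramid <- function(base, decline) base * exp(-decline * (0:10))

#' Generate a synthetic survey database
#'
#' Draws hierarchy effects and spline-coefficient deviations from the
#' model's own distributions, builds true country-age-time prevalence
#' surfaces, and simulates surveys: mixed instruments (with the true
#' adjustment applied on the log-odds scale inside each age cell), mixed
#' age reporting (5-year bands vs a broad 15-49 band), national and
#' sub-national strata, missing denominators, and optionally reported
#' design-adjusted Wilson confidence limits. Counts are binomial with the
#' design-deflated effective sample size.
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @return List with \code{observations}, \code{hierarchy},
#'   \code{population2010}, \code{population2018} data frames and
#'   \code{truth} augmented with the drawn effects and the true prevalence
#'   array \code{p_true[country, age cell, year, outcome]} (reference
#'   instrument, no study effect).
#' @export
generate_database <- function(truth) {
  set.seed(truth$seed)
  oc <- c("lifetime", "past_year")

  # ---- hierarchy ----
  cc <- sprintf("C%02d", seq_len(truth$n_countries))
  rg <- sprintf("R%02d", rep_len(seq_len(truth$n_regions), truth$n_countries))
  r2z <- sprintf("SR%d", rep_len(seq_len(truth$n_super), truth$n_regions))
  hier <- geo_hierarchy(data.frame(
    country_code = cc, region_id = rg, super_region_id = r2z[match(rg,
      sprintf("R%02d", seq_len(truth$n_regions)))],
    stringsAsFactors = FALSE))

  # ---- population tables ----
  base <- exp(stats::rnorm(truth$n_countries, log(5e5), 0.7))
  pop_rows <- function(year, decline, with_esp) {
    esp <- c(0.42, 0.78, 0.93, 0.98, rep(1, 7))
    rows <- list()
    for (i in seq_len(truth$n_countries)) {
      w <- .pyramid(base[i], decline)
      rows[[i]] <- data.frame(region_or_country = cc[i], age = age_grid(),
                              weight = w, reference_year = year,
                              stringsAsFactors = FALSE)
      if (with_esp) rows[[i]]$ever_sex_proportion <- esp
    }
    df <- do.call(rbind, rows)
    # regional aggregates
    for (r in unique(rg)) {
      members <- cc[rg == r]
      agg <- stats::aggregate(weight ~ age,
                              df[df$region_or_country %in% members, ], sum)
      add <- data.frame(region_or_country = r, age = agg$age,
                        weight = agg$weight, reference_year = year,
                        stringsAsFactors = FALSE)
      if (with_esp) add$ever_sex_proportion <- esp[match(agg$age, age_grid())]
      df <- rbind(df, add)
    }
    df
  }
  pop2010 <- pop_rows(2010, 0.12, FALSE)
  pop2018 <- pop_rows(2018, 0.115, TRUE)

  # ---- true effects ----
  Ab <- build_age_spline_basis(truth$age_knots)
  Tb <- build_time_spline_basis(truth$years, truth$time_knot)
  K <- Ab$K; Kt <- Tb$K
  zi <- match(hier$super_region_id, unique(hier$super_region_id))
  ri <- match(hier$region_id, unique(hier$region_id))
  nz <- max(zi); nr <- max(ri); nc <- truth$n_countries
  eff <- list()
  for (o in oc) {
    eff[[o]] <- list(
      u_z = stats::rnorm(nz, 0, truth$sd_z),
      u_r = stats::rnorm(nr, 0, truth$sd_r),
      u_c = stats::rnorm(nc, 0, truth$sd_c),
      eta_z = matrix(stats::rnorm(nz * K, 0, truth$sd_eta["z"]), nz, K),
      eta_r = matrix(stats::rnorm(nr * K, 0, truth$sd_eta["r"]), nr, K),
      eta_c = matrix(stats::rnorm(nc * K, 0, truth$sd_eta["c"]), nc, K),
      phi_z = matrix(stats::rnorm(nz * Kt, 0, truth$sd_phi["z"]), nz, Kt),
      phi_r = matrix(stats::rnorm(nr * Kt, 0, truth$sd_phi["r"]), nr, Kt),
      phi_c = matrix(stats::rnorm(nc * Kt, 0, truth$sd_phi["c"]), nc, Kt))
  }

  # true logit prevalence at reference instrument per country/age/year
  ny <- length(truth$years)
  p_true <- array(NA_real_, c(nc, 11, ny, 2),
                  dimnames = list(cc, age_grid(), truth$years, oc))
  logit_cell <- function(o, ci, cell, yidx, us = 0) {
    e <- eff[[o]]
    lam <- truth$eta_g[[o]] + e$eta_z[zi[ci], ] + e$eta_r[ri[ci], ] +
      e$eta_c[ci, ]
    ph <- truth$phi_g[[o]] + e$phi_z[zi[ci], ] + e$phi_r[ri[ci], ] +
      e$phi_c[ci, ]
    truth$u_g[[o]] + e$u_z[zi[ci]] + e$u_r[ri[ci]] + e$u_c[ci] + us +
      as.numeric(Ab$matrix[cell, , drop = FALSE] %*% lam) +
      as.numeric(Tb$matrix[yidx, , drop = FALSE] %*% ph)
  }
  for (o in oc) for (ci in seq_len(nc)) for (yi in seq_len(ny))
    p_true[ci, , yi, match(o, oc)] <-
      inv_logit(logit_cell(o, ci, 1:11, yi))
  if (any(p_true < 0.001 | p_true > 0.999))
    stop("generative settings yield prevalence outside (0.001, 0.999)")

  # ---- studies ----
  n_studies <- sample.int(length(truth$study_dist), truth$n_countries,
                          replace = TRUE, prob = truth$study_dist)
  rows <- list()
  sid <- 0
  for (ci in seq_len(nc)) {
    for (s in seq_len(n_studies[ci])) {
      sid <- sid + 1
      study <- sprintf("S%03d", sid)
      period <- sample.int(4, 1, prob = truth$period_weights)
      yr_lo <- c(2000, 2005, 2010, 2015)[period]
      yr_hi <- c(2004, 2009, 2014, 2018)[period]
      year <- sample(yr_lo:yr_hi, 1)
      yidx <- match(year, truth$years)
      geo <- sample(names(truth$geo_probs), 1, prob = truth$geo_probs)
      all3 <- geo == "national" && stats::runif(1) < truth$p_geo_all3
      subnat <- geo != "national"
      sd_s <- truth$sd_national + if (subnat) truth$tau_subnational else 0
      gold <- stats::runif(1) < truth$p_gold_standard
      aff <- if (gold) rep(FALSE, 6)
             else stats::runif(6) <
               pmin(truth$p_covariate / (1 - truth$p_gold_standard), 1)
      names(aff) <- names(truth$p_covariate)
      # resolve instrument (mutually exclusive levels)
      vt <- if (aff["physical_only"]) "physical_only"
            else if (aff["sexual_only"]) "sexual_only"
            else "physical_and_or_sexual"
      sev <- if (aff["severe"]) "severe_only" else "all"
      pp <- if (aff["all_women"]) "all_women"
            else if (aff["currently_partnered"]) "currently_partnered"
            else "ever_partnered"
      pr <- if (aff["current_recent"]) "current_or_most_recent"
            else "any_partner"
      ocs <- if (stats::runif(1) < truth$p_both_outcomes) oc
             else sample(oc, 1)
      bands <- stats::runif(1) < truth$p_age_bands
      miss_denom <- stats::runif(1) < truth$p_missing_denominator
      report_ci <- stats::runif(1) < truth$p_report_ci
      n_total <- exp(stats::rnorm(1, truth$n_total_meanlog[
        if (subnat) "subnational" else "national"], truth$n_total_sdlog))
      shares7 <- population_shares(pop2010, cc[ci], 1:7)
      for (o in ocs) {
        us <- stats::rnorm(1, 0, sd_s)
        emit <- function(lo, hi, vt., sev., pp., pr., geo., n_share) {
          cells <- age_band_indices(lo, hi)
          w <- population_shares(pop2010, cc[ci], cells)
          X <- sum(truth$beta[[o]][c("severe", "physical_only",
                                     "sexual_only", "all_women",
                                     "currently_partnered",
                                     "current_recent")] *
                   c(sev. == "severe_only", vt. == "physical_only",
                     vt. == "sexual_only", pp. == "all_women",
                     pp. == "currently_partnered",
                     pr. == "current_or_most_recent")) +
            truth$beta[[o]]["urban"] * (geo. == "urban") +
            truth$beta[[o]]["rural"] * (geo. == "rural")
          p <- sum(inv_logit(logit_cell(o, ci, cells, yidx, us) + X) * w)
          n_age <- n_total * n_share
          n_eff <- max(round(n_age / truth$design_effect), 5)
          yy <- stats::rbinom(1, n_eff, p)
          prev <- yy / n_eff
          data.frame(
            obs_id = NA_character_, study_id = study, country_code = cc[ci],
            year_start = year, year_end = year, outcome = o,
            violence_type = vt., severity = sev., population = pp.,
            partner_ref = pr., geo = geo., age_lower = lo, age_upper = hi,
            prevalence = prev,
            denominator = if (miss_denom) NA_real_ else round(n_age),
            total_n = if (miss_denom) NA_real_ else round(n_total),
            se = NA_real_,
            ci_lower = NA_real_,
            ci_upper = if (report_ci && prev > 0 && prev < 1)
              wilson_upper(prev, n_eff) else NA_real_,
            publication_year = year + 2, stringsAsFactors = FALSE)
        }
        # broad band at the primary instrument
        rows[[length(rows) + 1]] <- emit(15, 49, vt, sev, pp, pr, geo, 1)
        # granular 5-year bands
        if (bands)
          for (b in 1:7)
            rows[[length(rows) + 1]] <-
              emit(15 + 5 * (b - 1), 19 + 5 * (b - 1), vt, sev, pp, pr,
                   geo, shares7[b])
        # reference-instrument extras enabling exact matching
        for (cv in names(aff)[aff]) {
          if (stats::runif(1) >= truth$p_reference_extra) next
          vt2 <- vt; sev2 <- sev; pp2 <- pp; pr2 <- pr
          if (cv %in% c("physical_only", "sexual_only"))
            vt2 <- "physical_and_or_sexual"
          if (cv == "severe") sev2 <- "all"
          if (cv %in% c("all_women", "currently_partnered"))
            pp2 <- "ever_partnered"
          if (cv == "current_recent") pr2 <- "any_partner"
          rows[[length(rows) + 1]] <- emit(15, 49, vt2, sev2, pp2, pr2,
                                           geo, 1)
        }
        # urban + rural strata alongside a national estimate
        if (all3) {
          rows[[length(rows) + 1]] <- emit(15, 49, vt, sev, pp, pr,
                                           "urban", 0.45)
          rows[[length(rows) + 1]] <- emit(15, 49, vt, sev, pp, pr,
                                           "rural", 0.55)
        }
      }
    }
  }
  obs <- do.call(rbind, rows)
  obs$obs_id <- sprintf("O%05d", seq_len(nrow(obs)))
  rownames(obs) <- NULL
  obs$age_open <- FALSE
  truth$effects <- eff
  truth$hier_index <- list(zi = zi, ri = ri)
  truth$p_true <- p_true
  list(observations = obs, hierarchy = hier, population2010 = pop2010,
       population2018 = pop2018, truth = truth)
}

#' Build a named synthetic fixture
#'
#' Three standard profiles: \code{"tiny"} (2 super-regions, 3 regions, 6
#' countries; unit-test scale), \code{"desk"} (7 super-regions, 21 regions,
#' 40 countries; integration scale), and \code{"paperlike"} (7
#' super-regions, 21 regions, 160 countries, roughly 300 studies and 1,500
#' age-specific rows, with about half the observations needing some
#' adjustment).
#'
#' @param profile Fixture profile.
#' @param seed Integer seed.
#' @return As \code{\link{generate_database}}.
#' @export
make_fixture <- function(profile = c("tiny", "desk", "paperlike"), seed = 1) {
  profile <- match.arg(profile)
  truth <- switch(profile,
    tiny = synthetic_truth(n_super = 2, n_regions = 3, n_countries = 6,
                           study_dist = c(0.4, 0.4, 0.2, 0), seed = seed),
    desk = synthetic_truth(n_super = 7, n_regions = 21, n_countries = 40,
                           study_dist = c(0.55, 0.35, 0.1, 0), seed = seed),
    paperlike = synthetic_truth(n_super = 7, n_regions = 21,
                                n_countries = 160,
                                study_dist = c(0.5, 0.27, 0.1, 0.13),
                                seed = seed))
  generate_database(truth)
}

#' Write a synthetic fixture to CSV files
#'
#' Emits the same schemas the readers consume: observations, hierarchy and
#' the two population tables as CSV, and the ground truth (without the
#' large prevalence array) as JSON.
#'
#' @param db List from \code{\link{generate_database}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_observations(db$observations, file.path(dir, "observations.csv"))
  utils::write.csv(db$hierarchy, file.path(dir, "hierarchy.csv"),
                   row.names = FALSE)
  utils::write.csv(db$population2010, file.path(dir, "population_2010.csv"),
                   row.names = FALSE)
  utils::write.csv(db$population2018, file.path(dir, "population_2018.csv"),
                   row.names = FALSE)
  tr <- unclass(db$truth)
  tr$p_true <- NULL; tr$effects <- NULL; tr$hier_index <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
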