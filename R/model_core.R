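# The five-level Bayesian binomial meta-regression: model specification,
# JAGS code, age-standardization, likelihood, and outcome constraints.

# JAGS code for one outcome. Hierarchical intercepts (world, super-region,
# region, country, study), country-specific age-spline coefficients built
# from global + super-region + region + country deviations, the analogous
# time-trend coefficients, a fixed crosswalk offset X, and binomial
# observations whose success probability is the population-weighted
# (age-standardized) mean of the age-cell prevalences over the
# observation's age band.
.jags_model_code <- "
model {
  for (i in 1:Nobs) {
    y[i] ~ dbin(p[i], N[i])
    p[i] <- inprod(W[i,], pa[i,])
    for (a in 1:Ng) { pa[i,a] <- ilogit(mu[i] + gam[ci[i],a]) }
    mu[i] <- u_g + u_z[zi[i]] + u_r[ri[i]] + u_c[ci[i]] + u_s[si[i]] +
             delta[ci[i], ti[i]] + X[i]
  }
  for (c in 1:Nc) {
    for (a in 1:Ng) { gam[c,a] <- inprod(lambda[c,], A[a,]) }
    for (t in 1:Nt) { delta[c,t] <- inprod(phis[c,], Tb[t,]) }
    for (k in 1:Ka) { lambda[c,k] <- eta_g[k] + eta_z[zc[c],k] +
                      eta_r[rc[c],k] + eta_c[c,k] }
    for (k in 1:Kt) { phis[c,k] <- phi_g[k] + phi_z[zc[c],k] +
                      phi_r[rc[c],k] + phi_c[c,k] }
    u_c[c] ~ dnorm(0, pow(sigma_c, -2))
    for (k in 1:Ka) { eta_c[c,k] ~ dnorm(0, pow(ups_c[k], -2)) }
    for (k in 1:Kt) { phi_c[c,k] ~ dnorm(0, pow(om_c[k], -2)) }
  }
  for (r in 1:Nr) {
    u_r[r] ~ dnorm(0, pow(sigma_r, -2))
    for (k in 1:Ka) { eta_r[r,k] ~ dnorm(0, pow(ups_r[k], -2)) }
    for (k in 1:Kt) { phi_r[r,k] ~ dnorm(0, pow(om_r[k], -2)) }
  }
  for (z in 1:Nz) {
    u_z[z] ~ dnorm(0, pow(sigma_z, -2))
    for (k in 1:Ka) { eta_z[z,k] ~ dnorm(0, pow(ups_z[k], -2)) }
    for (k in 1:Kt) { phi_z[z,k] ~ dnorm(0, pow(om_z[k], -2)) }
  }
  # sub-national studies get an inflated random-effect SD (sigma_n + tau)
  for (s in 1:Ns) { u_s[s] ~ dnorm(0, pow(sigma_n + tau * sub[s], -2)) }
  u_g ~ dnorm(0, 0.001)
  for (k in 1:Ka) {
    eta_g[k] ~ dnorm(0, 0.001)
    ups_z[k] ~ dt(0, pow(25, -2), 1) T(0,)
    ups_r[k] ~ dt(0, pow(25, -2), 1) T(0,)
    ups_c[k] ~ dt(0, pow(25, -2), 1) T(0,)
  }
  for (k in 1:Kt) {
    phi_g[k] ~ dnorm(0, 0.001)
    om_z[k] ~ dt(0, pow(25, -2), 1) T(0,)
    om_r[k] ~ dt(0, pow(25, -2), 1) T(0,)
    om_c[k] ~ dt(0, pow(25, -2), 1) T(0,)
  }
  sigma_z ~ dt(0, pow(25, -2), 1) T(0,)
  sigma_r ~ dt(0, pow(25, -2), 1) T(0,)
  sigma_c ~ dt(0, pow(25, -2), 1) T(0,)
  sigma_n ~ dt(0, pow(25, -2), 1) T(0,)
  tau ~ dt(0, pow(25, -2), 1) T(0,)
}"

#' Build a model specification
#'
#' Assembles everything one outcome's meta-regression needs: index maps for
#' the country/region/super-region/study tree, the age and time spline
#' bases, per-observation age-standardization weight rows (the country's
#' region's 2010 female age distribution, normalized over the observation's
#' band; a one-hot row for single-band observations), and the fixed
#' crosswalk offsets from one adjustment-factor vector.
#'
#' @param data Prepared modelling dataset for one outcome (from
#'   \code{\link{prepare_observations}} + \code{\link{build_datasets}}).
#' @param hierarchy \code{geo_hierarchy}.
#' @param population2010 2010 population weight table (regional keys).
#' @param outcome \code{"lifetime"} or \code{"past_year"}.
#' @param adjustment Optional \code{adjustment_factors} table (or one
#'   element of an \code{adjustment_draws}); when \code{NULL} all offsets
#'   are zero and any observation needing adjustment raises an error.
#' @param age_knots Interior knots for the age spline (default 30).
#' @param time_knot Interior knot year for the time spline (default 2011).
#' @param years Calendar-year range of the time basis (default 2000:2018,
#'   extended if the data require).
#' @return List of class \code{ipv_model_spec}.
#' @export
ipv_model_spec <- function(data, hierarchy, population2010, outcome,
                           adjustment = NULL, age_knots = 30,
                           time_knot = 2011, years = 2000:2018) {
  d <- data[data$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) stop("no observations for outcome ", outcome)
  if (any(d$y > round(d$n_eff)))
    stop("y exceeds effective sample size for some observations")
  yr <- range(c(years, d$year_end))
  years <- seq(yr[1], yr[2])
  h <- hierarchy_lookup(hierarchy, d$country_code)
  countries <- sort(unique(d$country_code))
  hsub <- hierarchy_lookup(hierarchy, countries)
  regions <- sort(unique(hsub$region_id))
  supers <- sort(unique(hsub$super_region_id))
  studies <- sort(unique(d$study_id))
  ci <- match(d$country_code, countries)
  si <- match(d$study_id, studies)
  rc <- match(hsub$region_id, regions)
  zc <- match(hsub$super_region_id, supers)
  # study-level sub-national indicator (any non-national geo)
  sub <- vapply(studies, function(s)
    as.integer(any(d$geo[d$study_id == s] != "national")), integer(1))
  Ab <- build_age_spline_basis(age_knots)
  Tb <- build_time_spline_basis(years, time_knot)
  # standardization weight rows over the age grid
  W <- matrix(0, nrow(d), 11)
  for (i in seq_len(nrow(d))) {
    cells <- age_band_indices(d$age_lower[i], d$age_upper[i])
    W[i, cells] <- population_shares(population2010, h$region_id[i], cells)
  }
  X <- if (is.null(adjustment)) {
    needs <- rowSums(d[paste0("adj_", .covariates)]) > 0
    if (any(needs))
      stop("observations need adjustment but no factors supplied: ",
           paste(utils::head(d$obs_id[needs], 5), collapse = ", "))
    numeric(nrow(d))
  } else resolve_offsets(d, adjustment, hierarchy)
  jd <- list(Nobs = nrow(d), Ng = 11L, Nc = length(countries),
             Nr = length(regions), Nz = length(supers),
             Ns = length(studies), Ka = Ab$K, Kt = Tb$K,
             Nt = length(years),
             y = as.integer(round(d$y)), N = as.integer(round(d$n_eff)),
             W = W, A = Ab$matrix, Tb = Tb$matrix,
             ci = ci, ri = rc[ci], zi = zc[ci], si = si,
             ti = match(d$year_end, years), zc = zc, rc = rc,
             sub = as.integer(sub), X = X)
  structure(list(data = d, jags_data = jd, countries = countries,
                 regions = regions, supers = supers, studies = studies,
                 country_region = rc, country_super = zc,
                 age_basis = Ab, time_basis = Tb, years = years,
                 outcome = outcome,
                 adjustment_id = attr(adjustment, "draw_id") %||% NA),
            class = "ipv_model_spec")
}

#' MCMC configuration
#'
#' The \code{"full"} profile carries the full-scale settings (4 chains
#' of 50,000 iterations, 10,000 adaptation, 5,000 warm-up, thinning 20,
#' retaining 2,250 draws per chain); the \code{"desk"} profile (default)
#' is a reduced configuration for synthetic-data work: 2 chains of 4,000
#' iterations, 500 adaptation, 1,000 warm-up, thinning 2.
#'
#' @param profile \code{"desk"} or \code{"full"}; individual fields may be
#'   overridden.
#' @param chains,iterations,adaptation,warmup,thin,seed MCMC settings.
#' @return List of class \code{mcmc_config}; \code{$retained} gives draws
#'   per chain.
#' @export
mcmc_config <- function(profile = c("desk", "full"), chains = NULL,
                        iterations = NULL, adaptation = NULL, warmup = NULL,
                        thin = NULL, seed = 1) {
  profile <- match.arg(profile)
  def <- switch(profile,
    desk = list(chains = 2, iterations = 4000, adaptation = 500,
                warmup = 1000, thin = 2),
    full = list(chains = 4, iterations = 50000, adaptation = 10000,
                 warmup = 5000, thin = 20))
  cfg <- list(chains = chains %||% def$chains,
              iterations = iterations %||% def$iterations,
              adaptation = adaptation %||% def$adaptation,
              warmup = warmup %||% def$warmup,
              thin = thin %||% def$thin, seed = seed, profile = profile)
  if (any(unlist(cfg[1:5]) <= 0)) stop("all MCMC settings must be positive")
  cfg$retained <- (cfg$iterations - cfg$warmup) / cfg$thin
  if (cfg$retained <= 0) stop("no draws retained: warmup >= iterations")
  class(cfg) <- "mcmc_config"
  cfg
}

.monitors <- c("u_g", "u_z", "u_r", "u_c", "u_s",
               "sigma_z", "sigma_r", "sigma_c", "sigma_n", "tau",
               "eta_g", "eta_z", "eta_r", "eta_c",
               "ups_z", "ups_r", "ups_c",
               "phi_g", "phi_z", "phi_r", "phi_c",
               "om_z", "om_r", "om_c", "p")

# Extract a monitored node into a draws x dim matrix (or vector) from the
# pooled chains.
.extract_node <- function(mat, name) {
  cols <- grep(paste0("^", name, "(\\[|$)"), colnames(mat))
  if (!length(cols)) stop("node not monitored: ", name)
  sub <- mat[, cols, drop = FALSE]
  nm <- colnames(sub)
  if (all(nm == name)) return(as.numeric(sub))
  idx <- regmatches(nm, regexpr("\\[.*\\]", nm))
  if (grepl(",", idx[1])) {
    ij <- do.call(rbind, lapply(strsplit(gsub("\\[|\\]", "", idx), ","),
                                as.integer))
    arr <- array(NA_real_, c(nrow(sub), max(ij[, 1]), max(ij[, 2])))
    for (j in seq_along(cols)) arr[, ij[j, 1], ij[j, 2]] <- sub[, j]
    arr
  } else {
    ord <- order(as.integer(gsub("\\[|\\]", "", idx)))
    sub[, ord, drop = FALSE]
  }
}

#' Fit the hierarchical IPV meta-regression
#'
#' Gibbs sampling (JAGS) of the five-level binomial meta-regression for one
#' outcome: binomial counts with age-standardized success probabilities,
#' nested normal random intercepts with half-Cauchy(0, 25) scale priors
#' (sub-national studies receive an additive variance inflation),
#' hierarchical natural-cubic-spline age and time coefficients, and fixed
#' crosswalk offsets. Diffuse N(0, variance 1000) priors are placed on the
#' global intercept and global spline coefficients.
#'
#' @param data Prepared modelling dataset (both outcomes may be present;
#'   rows for \code{outcome} are used).
#' @param hierarchy \code{geo_hierarchy}.
#' @param population2010 2010 population weight table.
#' @param outcome \code{"lifetime"} or \code{"past_year"}.
#' @param adjustment Optional adjustment-factor table (one vector).
#' @param cfg An \code{\link{mcmc_config}}.
#' @param age_knots,time_knot,years Passed to \code{\link{ipv_model_spec}}.
#' @param quiet Suppress JAGS progress output.
#' @return Object of class \code{ipv_fit}: posterior draw matrices in
#'   \code{$draws} (pooled over chains), the coda \code{$samples}, the
#'   \code{$spec}, \code{$cfg} and the modelling data.
#' @export
fit_ipv_model <- function(data, hierarchy, population2010, outcome,
                          adjustment = NULL, cfg = mcmc_config(),
                          age_knots = 30, time_knot = 2011,
                          years = 2000:2018, quiet = TRUE) {
  spec <- ipv_model_spec(data, hierarchy, population2010, outcome,
                         adjustment, age_knots, time_knot, years)
  fit_ipv_spec(spec, cfg, quiet = quiet)
}

#' Fit a prepared model specification
#'
#' Lower-level entry point of \code{\link{fit_ipv_model}} taking an
#' existing \code{ipv_model_spec}.
#'
#' @param spec An \code{\link{ipv_model_spec}}.
#' @param cfg An \code{\link{mcmc_config}}.
#' @param quiet Suppress JAGS progress output.
#' @return An \code{ipv_fit}.
#' @export
fit_ipv_spec <- function(spec, cfg = mcmc_config(), quiet = TRUE) {
  inits <- lapply(seq_len(cfg$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (cfg$seed * 1000 + ch) %% 2147483647))
  t0 <- Sys.time()
  run <- function() {
    m <- rjags::jags.model(textConnection(.jags_model_code),
                           data = spec$jags_data, inits = inits,
                           n.chains = cfg$chains, n.adapt = cfg$adaptation,
                           quiet = TRUE)
    stats::update(m, cfg$warmup, progress.bar = "none")
    rjags::coda.samples(m, .monitors, n.iter = cfg$iterations - cfg$warmup,
                        thin = cfg$thin, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  mat <- do.call(rbind, lapply(samples, as.matrix))
  draws <- lapply(stats::setNames(.monitors, .monitors),
                  function(nm) .extract_node(mat, nm))
  structure(list(draws = draws, samples = samples, spec = spec, cfg = cfg,
                 data = spec$data, outcome = spec$outcome,
                 n_draws = nrow(mat),
                 runtime = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
            class = "ipv_fit")
}

#' Linear predictor of the meta-regression
#'
#' The logit-scale prediction for one observation context: intercept sum
#' (world + super-region + region + country + study) plus the age-spline
#' term, the time-trend term, and the crosswalk offset.
#'
#' @param params List with \code{alpha} (summed intercepts), \code{lambda}
#'   (age coefficients, length K) and \code{phi} (time coefficients).
#' @param age Age (years) at which to evaluate.
#' @param year Calendar year.
#' @param age_basis,time_basis \code{spline_basis} objects.
#' @param X Crosswalk offset (default 0).
#' @return Logit prevalence.
#' @export
linear_predictor <- function(params, age, year, age_basis, time_basis,
                             X = 0) {
  as.numeric(params$alpha +
    age_basis$evaluate(age) %*% params$lambda +
    time_basis$evaluate(year) %*% params$phi + X)
}

#' Age-standardized prevalence
#'
#' Population-weighted average of age-specific prevalences: wide age bands
#' are expressed as \eqn{\sum_a \mathrm{logit}^{-1}(\ell_a) w_a / \sum_a
#' w_a} over the 5-year cells the band spans. With a single cell this
#' reduces to the plain inverse logit.
#'
#' @param cell_logits Logit prevalence at each age cell of the band.
#' @param weights Population weights of those cells (any positive scale).
#' @return Prevalence in (0, 1).
#' @export
age_standardize <- function(cell_logits, weights) {
  if (length(cell_logits) != length(weights))
    stop("cell_logits and weights differ in length")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  sum(inv_logit(cell_logits) * weights) / sum(weights)
}

#' Binomial log likelihood of a dataset
#'
#' Sum of binomial log probability masses at the (age-standardized)
#' success probabilities; effective sample sizes are rounded to integers.
#'
#' @param p Per-observation success probabilities.
#' @param y Survey-adjusted counts.
#' @param n Effective sample sizes.
#' @return Total log likelihood.
#' @export
log_likelihood <- function(p, y, n) {
  if (any(round(y) > round(n))) stop("y exceeds n")
  sum(stats::dbinom(round(y), round(n), p, log = TRUE))
}

# Pure-R reconstruction of the standardized success probabilities for one
# posterior draw; mirrors the JAGS likelihood (used in tests and oracles).
compute_p_draw <- function(fit, draw) {
  jd <- fit$spec$jags_data
  d <- fit$draws
  lam <- matrix(NA_real_, jd$Nc, jd$Ka)
  phs <- matrix(NA_real_, jd$Nc, jd$Kt)
  for (k in seq_len(jd$Ka))
    lam[, k] <- d$eta_g[draw, k] + d$eta_z[draw, jd$zc, k] +
      d$eta_r[draw, jd$rc, k] + d$eta_c[draw, , k]
  for (k in seq_len(jd$Kt))
    phs[, k] <- d$phi_g[draw, k] + d$phi_z[draw, jd$zc, k] +
      d$phi_r[draw, jd$rc, k] + d$phi_c[draw, , k]
  gam <- lam %*% t(jd$A)
  delta <- phs %*% t(jd$Tb)
  p <- numeric(jd$Nobs)
  for (i in seq_len(jd$Nobs)) {
    mu <- d$u_g[draw] + d$u_z[draw, jd$zi[i]] + d$u_r[draw, jd$ri[i]] +
      d$u_c[draw, jd$ci[i]] + d$u_s[draw, jd$si[i]] +
      delta[jd$ci[i], jd$ti[i]] + jd$X[i]
    p[i] <- sum(jd$W[i, ] * inv_logit(mu + gam[jd$ci[i], ]))
  }
  p
}

#' Enforce the joint outcome constraints on prediction draws
#'
#' Past-year IPV prevalence cannot exceed lifetime IPV prevalence, and at
#' ages 15-19 the lifetime to past-year prevalence ratio is at most 3
#' (young women's two recall windows largely coincide). \code{"reject"}
#' mode (default) retains only aligned draw pairs satisfying both
#' constraints at every supplied cell; \code{"cap"} mode instead projects
#' violating past-year draws onto the constraint boundary
#' (\eqn{p^{past} \leftarrow \min(p^{past}, p^{life})}, then
#' \eqn{p^{past} \leftarrow \max(p^{past}, p^{life}/3)} in the 15-19
#' band).
#'
#' @param lifetime,past_year Aligned draw matrices (draws x cells) of
#'   predicted prevalence for the same cells.
#' @param ages Age (grid value) of each cell column, used to locate the
#'   15-19 band.
#' @param rr_max Maximum lifetime/past-year ratio at 15-19 (default 3).
#' @param mode \code{"reject"} or \code{"cap"}.
#' @param min_acceptance Rejection rate guard: error (suggesting model
#'   misfit) when fewer than this fraction of draws survive.
#' @return List with constrained \code{lifetime} and \code{past_year}
#'   matrices, the \code{retained} draw indices (reject mode) and the
#'   \code{acceptance} rate.
#' @export
apply_constraints <- function(lifetime, past_year, ages, rr_max = 3,
                              mode = c("reject", "cap"),
                              min_acceptance = 0.01) {
  mode <- match.arg(mode)
  if (!all(dim(lifetime) == dim(past_year)))
    stop("lifetime and past_year draws are not aligned")
  if (length(ages) != ncol(lifetime))
    stop("ages must give one age per cell column")
  young <- which(ages >= 15 & ages < 20)
  if (mode == "reject") {
    ok_order <- rowSums(past_year > lifetime) == 0
    ok_rr <- if (length(young))
      rowSums(lifetime[, young, drop = FALSE] >
                rr_max * past_year[, young, drop = FALSE]) == 0
    else TRUE
    keep <- which(ok_order & ok_rr)
    acc <- length(keep) / nrow(lifetime)
    if (acc < min_acceptance)
      stop("constraint acceptance rate ", signif(acc, 3),
           " below ", min_acceptance, "; the joint model may be misfit")
    list(lifetime = lifetime[keep, , drop = FALSE],
         past_year = past_year[keep, , drop = FALSE],
         retained = keep, acceptance = acc)
  } else {
    past2 <- pmin(past_year, lifetime)
    if (length(young))
      past2[, young] <- pmax(past2[, young, drop = FALSE],
                             lifetime[, young, drop = FALSE] / rr_max)
    list(lifetime = lifetime, past_year = past2, retained = NULL,
         acceptance = 1)
  }
}

#' Serialize a run manifest
#'
#' Records what a fit needs for reproduction: outcome, knots, prior
#' settings, MCMC configuration, seed, adjustment-draw id and data
#' dimensions.
#'
#' @param fit An \code{ipv_fit}.
#' @param path Optional JSON output path.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(fit, path = NULL) {
  m <- list(outcome = fit$outcome,
            age_knots = fit$spec$age_basis$knots,
            time_knot = fit$spec$time_basis$knots,
            years = range(fit$spec$years),
            priors = list(intercept = "N(0, var 1000)",
                          scales = "half-Cauchy(0, 25)"),
            mcmc = unclass(fit$cfg)[c("chains", "iterations", "adaptation",
                                      "warmup", "thin", "seed", "profile")],
            adjustment_id = fit$spec$adjustment_id,
            n_obs = fit$spec$jags_data$Nobs,
            n_countries = fit$spec$jags_data$Nc,
            n_studies = fit$spec$jags_data$Ns)
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
    return(invisible(m))
  }
  m
}
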