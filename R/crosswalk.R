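# Crosswalk adjustment factors: exact matching within surveys, paired odds
# ratios, stratified random-effects meta-analysis, the geographic-strata
# random-effects logistic model, and Latin hypercube sampling of adjustment
# vectors.

# Exact-matching keys per covariate: the instrument dimensions that must be
# identical between the exposed and reference observation of a pair (the
# survey identifier and age band are always matched).
.match_fields <- list(
  severe = c("population", "violence_type", "geo", "partner_ref"),
  physical_only = c("population", "geo", "severity", "partner_ref"),
  sexual_only = c("population", "geo", "severity", "partner_ref"),
  all_women = c("violence_type", "geo", "severity", "partner_ref"),
  currently_partnered = c("violence_type", "geo", "severity", "partner_ref"),
  current_recent = c("population", "violence_type", "geo", "severity")
)

# Reference-level condition for the dimension a covariate adjusts.
.is_reference <- function(obs, covariate) {
  switch(covariate,
    severe = obs$severity == "all",
    physical_only = ,
    sexual_only = obs$violence_type == "physical_and_or_sexual",
    all_women = ,
    currently_partnered = obs$population == "ever_partnered",
    current_recent = obs$partner_ref == "any_partner",
    stop("unknown covariate: ", covariate))
}

#' Exact-match exposed and reference observations within surveys
#'
#' For one adjustment covariate, forms matched pairs within each survey:
#' an observation at the non-reference level paired with one at the
#' reference level that is identical on every other matching dimension
#' (including the age band). When several candidate pairs exist in a
#' survey, the one closest to the gold-standard optimal set is retained
#' (most reference-level instrument fields, ties broken by the selection
#' rule order), so each survey contributes at most one pair.
#'
#' @param adjustment_data Adjustment dataset (broadest age band per study
#'   and instrument), with \code{adj_*} indicator columns.
#' @param covariate One of \code{"severe"}, \code{"physical_only"},
#'   \code{"sexual_only"}, \code{"all_women"}, \code{"currently_partnered"},
#'   \code{"current_recent"}.
#' @param outcome \code{"lifetime"} or \code{"past_year"}.
#' @return Data frame of matched pairs (possibly empty) with the exposed
#'   and reference prevalence, effective sample sizes and ids.
#' @export
exact_match <- function(adjustment_data, covariate, outcome) {
  if (!covariate %in% names(.match_fields))
    stop("unknown covariate: ", covariate)
  d <- adjustment_data[adjustment_data$outcome == outcome, , drop = FALSE]
  col <- paste0("adj_", covariate)
  out <- list()
  for (idx in split(seq_len(nrow(d)), d$study_id)) {
    exp_i <- idx[d[[col]][idx] == 1]
    ref_i <- idx[d[[col]][idx] == 0 & .is_reference(d[idx, ], covariate)]
    if (!length(exp_i) || !length(ref_i)) next
    keys <- c(.match_fields[[covariate]], "age_lower", "age_upper")
    cand <- expand.grid(e = exp_i, r = ref_i)
    ok <- vapply(seq_len(nrow(cand)), function(j) {
      all(vapply(keys, function(k) {
        ve <- d[[k]][cand$e[j]]; vr <- d[[k]][cand$r[j]]
        identical(ve, vr) || (is.numeric(ve) && isTRUE(ve == vr))
      }, logical(1)))
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    # closeness to the optimal set: fewest non-reference fields, ties by
    # the ordered selection-rule ranking, reference row first then exposed
    rk <- .instrument_rank(d)
    score <- function(i) c(sum(rk[i, ] > 0), rk[i, ])
    sc <- t(vapply(seq_len(nrow(cand)), function(j)
      c(score(cand$r[j]), score(cand$e[j])), numeric(10)))
    best <- do.call(order, as.data.frame(sc))[1]
    e <- cand$e[best]; r <- cand$r[best]
    out[[length(out) + 1]] <- data.frame(
      survey_id = d$study_id[e], covariate = covariate, outcome = outcome,
      country_code = d$country_code[e],
      exposed_obs = d$obs_id[e], reference_obs = d$obs_id[r],
      p1 = d$prevalence[e], n1 = d$n_eff[e],
      p0 = d$prevalence[r], n0 = d$n_eff[r],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(survey_id = character(), covariate = character(),
                      outcome = character(), country_code = character(),
                      exposed_obs = character(), reference_obs = character(),
                      p1 = numeric(), n1 = numeric(), p0 = numeric(),
                      n0 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Odds ratio of a matched pair
#'
#' Log odds ratio comparing the exposed (non-reference) observation to its
#' matched reference, with the standard error from the implied 2x2 table:
#' \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}. A zero cell triggers the usual 0.5
#' continuity correction on all four cells (with a message).
#'
#' @param p1,n1 Exposed prevalence and effective sample size.
#' @param p0,n0 Reference prevalence and effective sample size.
#' @return Named vector \code{c(log_or, se)}.
#' @export
pair_odds_ratio <- function(p1, n1, p0, n0) {
  if (is.na(n1) || is.na(n0)) stop("effective sample sizes required")
  a <- round(p1 * n1); b <- round(n1) - a
  c_ <- round(p0 * n0); d <- round(n0) - c_
  if (min(a, b, c_, d) == 0) {
    message("zero cell in matched pair; applying 0.5 continuity correction")
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  c(log_or = log((a / b) / (c_ / d)),
    se = sqrt(1 / a + 1 / b + 1 / c_ + 1 / d))
}

#' Pool matched-pair odds ratios by random-effects meta-analysis
#'
#' DerSimonian-Laird random-effects pooling of the matched-pair log odds
#' ratios, stratified by super-region, plus an overall pooled estimate.
#' A super-region stratum is used for adjustment only when it contributes
#' more than three pairs; otherwise the overall factor stands in
#' (\code{used_level = "overall"}).
#'
#' @param pairs Data frame from \code{\link{exact_match}} with
#'   \code{log_or}, \code{se} columns (added here if absent) and a
#'   \code{super_region_id} column.
#' @param method \code{metafor} estimator (default \code{"DL"}; e.g.
#'   \code{"REML"} is accepted).
#' @return Data frame of factor entries: one row per super-region stratum
#'   present plus one \code{"overall"} row, with pooled log OR, SE, 95% CI
#'   on the OR scale, number of pairs and \code{used_level}.
#' @export
meta_analyze <- function(pairs, method = "DL") {
  if (!nrow(pairs)) stop("no matched pairs to pool")
  if (is.null(pairs$log_or)) {
    lo <- t(vapply(seq_len(nrow(pairs)), function(i)
      pair_odds_ratio(pairs$p1[i], pairs$n1[i], pairs$p0[i], pairs$n0[i]),
      numeric(2)))
    pairs$log_or <- lo[, 1]; pairs$se <- lo[, 2]
  }
  pool <- function(sub) {
    fit <- metafor::rma(yi = sub$log_or, sei = sub$se, method = method)
    c(est = as.numeric(fit$b), se = fit$se,
      ci_lb = fit$ci.lb, ci_ub = fit$ci.ub)
  }
  ov <- pool(pairs)
  rows <- list(data.frame(stratum = "overall", log_or = ov["est"],
                          se = ov["se"], ci_lb = ov["ci_lb"],
                          ci_ub = ov["ci_ub"], n_matches = nrow(pairs),
                          used_level = "overall", stringsAsFactors = FALSE))
  for (sr in unique(pairs$super_region_id)) {
    sub <- pairs[pairs$super_region_id == sr, , drop = FALSE]
    st <- pool(sub)
    used <- if (nrow(sub) > 3) "super_region" else "overall"
    rows[[length(rows) + 1]] <- data.frame(
      stratum = sr, log_or = st["est"], se = st["se"], ci_lb = st["ci_lb"],
      ci_ub = st["ci_ub"], n_matches = nrow(sub), used_level = used,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$or <- exp(out$log_or)
  out$or_ci_lb <- exp(out$ci_lb)
  out$or_ci_ub <- exp(out$ci_ub)
  rownames(out) <- NULL
  out
}

#' Geographic-strata adjustment factors
#'
#' Urban-vs-national and rural-vs-national log odds ratios estimated from a
#' random-effects logistic regression on grouped binomial counts, using
#' only surveys that report all three geographic strata: one random
#' intercept per survey and urban/rural random slopes varying by
#' super-region. Falls back to a pooled fixed-effect contrast (with a
#' warning) when fewer than two qualifying surveys exist.
#'
#' @param adjustment_data Adjustment dataset with \code{n_eff}, \code{y}.
#' @param hierarchy \code{geo_hierarchy}.
#' @param outcome \code{"lifetime"} or \code{"past_year"}.
#' @return Factor entries (as in \code{\link{meta_analyze}}) for covariates
#'   \code{"urban"} and \code{"rural"}.
#' @export
fit_geo_strata_factors <- function(adjustment_data, hierarchy, outcome) {
  d <- adjustment_data[adjustment_data$outcome == outcome &
                         adjustment_data$geo %in%
                           c("national", "urban", "rural"), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(d)), d$study_id), function(idx) {
    if (all(c("national", "urban", "rural") %in% d$geo[idx])) idx
    else integer()
  }), use.names = FALSE)
  d <- d[keep, , drop = FALSE]
  empty <- data.frame(covariate = character(), stratum = character(),
                      log_or = numeric(), se = numeric(),
                      n_matches = integer(), used_level = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(d)) return(empty)
  d$super_region_id <- hierarchy_lookup(hierarchy, d$country_code)$super_region_id
  d$urban <- as.integer(d$geo == "urban")
  d$rural <- as.integer(d$geo == "rural")
  d$yr <- round(d$y); d$nn <- pmax(round(d$n_eff), d$yr)
  n_surv <- length(unique(d$study_id))
  n_sr <- length(unique(d$super_region_id))
  rows <- list()
  if (n_surv >= 2) {
    form <- if (n_sr >= 2)
      cbind(yr, nn - yr) ~ urban + rural + (1 | study_id) +
        (0 + urban + rural | super_region_id)
    else
      cbind(yr, nn - yr) ~ urban + rural + (1 | study_id)
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(form, data = d, family = stats::binomial())))
    fe <- lme4::fixef(fit)
    vc <- sqrt(diag(as.matrix(stats::vcov(fit))))
    re <- if (n_sr >= 2) lme4::ranef(fit)$super_region_id else NULL
    for (cov in c("urban", "rural")) {
      nm <- vapply(unique(d$super_region_id), function(sr)
        length(unique(d$study_id[d$super_region_id == sr])), integer(1))
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cov, stratum = "overall", log_or = unname(fe[cov]),
        se = unname(vc[cov]), n_matches = n_surv, used_level = "overall",
        stringsAsFactors = FALSE)
      for (sr in unique(d$super_region_id)) {
        dev <- if (!is.null(re) && sr %in% rownames(re)) re[sr, cov] else 0
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cov, stratum = sr, log_or = unname(fe[cov]) + dev,
          se = unname(vc[cov]), n_matches = unname(nm[sr]),
          used_level = if (nm[sr] > 3) "super_region" else "overall",
          stringsAsFactors = FALSE)
      }
    }
  } else {
    warning("fewer than 2 surveys with all three geographic strata; ",
            "using a pooled fixed-effect contrast")
    fit <- stats::glm(cbind(yr, nn - yr) ~ urban + rural, data = d,
                      family = stats::binomial())
    co <- summary(fit)$coefficients
    for (cov in c("urban", "rural"))
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cov, stratum = "overall", log_or = co[cov, 1],
        se = co[cov, 2], n_matches = n_surv, used_level = "overall",
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Estimate all crosswalk adjustment factors
#'
#' Runs exact matching, paired odds ratios, and stratified random-effects
#' pooling for every binary adjustment covariate and both outcomes, plus
#' the geographic-strata logistic model. For the all-women factor applied
#' to past-year IPV, the lifetime factor is reused when past-year matching
#' yields no pairs (there are typically too few to pool). Point estimates
#' of structurally bound factors (severe, physical-only, sexual-only,
#' all-women) are truncated at the null.
#'
#' @param adjustment_data Adjustment dataset from \code{\link{build_datasets}}
#'   after \code{\link{prepare_observations}}.
#' @param hierarchy \code{geo_hierarchy}.
#' @param outcomes Outcomes to estimate factors for.
#' @param method Meta-analysis estimator (default \code{"DL"}).
#' @return Data frame of class \code{adjustment_factors}: one row per
#'   (covariate, outcome, stratum) with pooled log OR, SE, number of
#'   matches, \code{used_level} and \code{bound} flag.
#' @export
crosswalk_factors <- function(adjustment_data, hierarchy,
                              outcomes = c("lifetime", "past_year"),
                              method = "DL") {
  adjustment_data$super_region_id <-
    hierarchy_lookup(hierarchy, adjustment_data$country_code)$super_region_id
  rows <- list()
  for (oc in outcomes) {
    for (cov in names(.match_fields)) {
      pairs <- exact_match(adjustment_data, cov, oc)
      if (!nrow(pairs)) next
      pairs$super_region_id <-
        hierarchy_lookup(hierarchy, pairs$country_code)$super_region_id
      ent <- meta_analyze(pairs, method = method)
      ent$covariate <- cov
      ent$outcome <- oc
      rows[[length(rows) + 1]] <- ent
    }
    geo <- fit_geo_strata_factors(adjustment_data, hierarchy, oc)
    if (nrow(geo)) {
      geo$outcome <- oc
      rows[[length(rows) + 1]] <- geo
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(covariate = r$covariate, outcome = r$outcome,
                       stratum = r$stratum, log_or = r$log_or, se = r$se,
                       n_matches = r$n_matches, used_level = r$used_level,
                       stringsAsFactors = FALSE)
    base
  }))
  # all-women factor for past-year reuses the lifetime one when absent
  if (all(c("lifetime", "past_year") %in% outcomes)) {
    has_py <- any(out$covariate == "all_women" & out$outcome == "past_year")
    lt <- out[out$covariate == "all_women" & out$outcome == "lifetime", ,
              drop = FALSE]
    if (!has_py && nrow(lt)) {
      lt$outcome <- "past_year"
      out <- rbind(out, lt)
    }
  }
  out$bound <- out$covariate %in% .bound_covariates
  out$log_or[out$bound] <- pmin(out$log_or[out$bound], 0)
  rownames(out) <- NULL
  class(out) <- c("adjustment_factors", "data.frame")
  out
}

#' Sample adjustment vectors by Latin hypercube
#'
#' Draws \code{D} complete adjustment-factor vectors representing the
#' uncertainty of the meta-analyzed log odds ratios: each entry is sampled
#' from Normal(log OR, SE), stratified over [0,1] by Latin hypercube
#' sampling, and from the normal truncated above at the null for
#' structurally bound covariates (so, e.g., a severe-only estimate can
#' never be adjusted upward past the all-severity one).
#'
#' @param factors \code{adjustment_factors} table.
#' @param D Number of vectors (default 10).
#' @param seed Integer seed.
#' @return Object of class \code{adjustment_draws}: list of \code{D} factor
#'   tables with sampled \code{log_or} columns.
#' @export
sample_adjustment_vectors <- function(factors, D = 10, seed = 1) {
  if (D < 1) stop("D must be at least 1")
  set.seed(seed)
  u <- lhs::randomLHS(D, nrow(factors))
  draws <- vector("list", D)
  q <- matrix(NA_real_, D, nrow(factors))
  for (j in seq_len(nrow(factors))) {
    mu <- factors$log_or[j]; sd <- factors$se[j]
    if (sd == 0) { q[, j] <- mu; next }
    if (isTRUE(factors$bound[j])) {
      # quantile of the normal truncated above at 0
      pmax0 <- stats::pnorm(0, mu, sd)
      q[, j] <- stats::qnorm(u[, j] * pmax0, mu, sd)
    } else {
      q[, j] <- stats::qnorm(u[, j], mu, sd)
    }
  }
  for (d in seq_len(D)) {
    tab <- factors
    tab$log_or <- q[d, ]
    draws[[d]] <- tab
  }
  structure(list(draws = draws, D = D, seed = seed),
            class = "adjustment_draws")
}

#' Crosswalk offsets for observations
#'
#' Computes each observation's total adjustment offset
#' \eqn{X = \sum_j \beta_j C_j} on the log-odds scale, resolving each
#' active indicator against the factor table: the super-region entry when
#' its \code{used_level} is \code{"super_region"}, otherwise the overall
#' entry. Errors when an observation needs a covariate with no estimated
#' factor.
#'
#' @param obs Prepared observations with \code{adj_*} columns.
#' @param factors One \code{adjustment_factors} table (or one element of an
#'   \code{adjustment_draws}).
#' @param hierarchy \code{geo_hierarchy}.
#' @return Numeric vector of offsets, one per observation.
#' @export
resolve_offsets <- function(obs, factors, hierarchy) {
  .offsets_impl(obs, factors, hierarchy, drop = FALSE)$X
}

#' Drop observations whose required adjustment factor is missing
#'
#' When a covariate produced no matched pairs its factor is absent and
#' observations needing it cannot be placed on the reference instrument
#' scale; this filter removes them (with a message naming them) so the
#' remaining dataset can be modelled.
#'
#' @param obs Prepared observations with \code{adj_*} columns.
#' @param factors \code{adjustment_factors} table.
#' @param hierarchy \code{geo_hierarchy}.
#' @return \code{obs} restricted to adjustable rows.
#' @export
filter_adjustable <- function(obs, factors, hierarchy) {
  ok <- .offsets_impl(obs, factors, hierarchy, drop = TRUE)$ok
  if (!all(ok))
    message("dropping ", sum(!ok), " observation(s) lacking an estimated ",
            "adjustment factor: ",
            paste(utils::head(obs$obs_id[!ok], 8), collapse = ", "))
  obs[ok, , drop = FALSE]
}

.offsets_impl <- function(obs, factors, hierarchy, drop = FALSE) {
  sr <- hierarchy_lookup(hierarchy, obs$country_code)$super_region_id
  X <- numeric(nrow(obs))
  ok <- rep(TRUE, nrow(obs))
  for (cov in .covariates) {
    col <- paste0("adj_", cov)
    act <- which(obs[[col]] == 1)
    if (!length(act)) next
    for (i in act) {
      f <- factors[factors$covariate == cov &
                     factors$outcome == obs$outcome[i], , drop = FALSE]
      if (!nrow(f)) {
        if (drop) { ok[i] <- FALSE; next }
        stop("no adjustment factor estimated for covariate '", cov,
             "' (outcome ", obs$outcome[i], ") needed by ", obs$obs_id[i])
      }
      row <- f[f$stratum == sr[i] & f$used_level == "super_region", ,
               drop = FALSE]
      if (!nrow(row)) row <- f[f$stratum == "overall", , drop = FALSE]
      if (!nrow(row)) row <- f[1, , drop = FALSE]
      X[i] <- X[i] + row$log_or[1]
    }
  }
  list(X = X, ok = ok)
}
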