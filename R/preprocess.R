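# Pre-processing: metadata imputation, denominator allocation, effective
# sample sizes, optimal-set selection, and construction of the adjustment
# and modelling datasets.

#' Impute missing observation metadata
#'
#' Missing end year of data collection is replaced by the publication year
#' (a proxy for the survey date); a missing upper age is treated as an
#' open-ended band. Each imputation is flagged.
#'
#' @param obs Observation data frame.
#' @return \code{obs} with imputations applied and \code{imputed_end_year},
#'   \code{imputed_upper_age} flags.
#' @export
impute_metadata <- function(obs) {
  obs$imputed_end_year <- FALSE
  obs$imputed_upper_age <- FALSE
  m <- is.na(obs$year_end)
  if (any(m)) {
    no_proxy <- m & is.na(obs$publication_year)
    if (any(no_proxy))
      stop("end year and publication year both missing for: ",
           paste(obs$obs_id[no_proxy], collapse = ", "))
    obs$year_end[m] <- obs$publication_year[m]
    obs$imputed_end_year[m] <- TRUE
  }
  if (is.null(obs$age_open)) obs$age_open <- is.infinite(obs$age_upper)
  ua <- is.na(obs$age_upper)
  if (any(ua)) {
    obs$age_upper[ua] <- Inf
    obs$age_open[ua] <- TRUE
    obs$imputed_upper_age[ua] <- TRUE
  }
  obs
}

#' Impute age-specific denominators
#'
#' Within each study, missing age-specific denominators are allocated from
#' the study's overall sample size proportionally to the country's 2010
#' female age distribution over each observation's age band. When the
#' overall sample size itself is unknown, conservative defaults of 3,000
#' (nationally representative) and 1,000 (sub-national) respondents are
#' used.
#'
#' @param obs Observation data frame (one outcome's rows or mixed; grouping
#'   is by study_id x outcome).
#' @param pop2010 Population weight table (reference year 2010), keyed by
#'   country code (falling back to the study's region when absent).
#' @param hierarchy Optional \code{geo_hierarchy} for the region fallback.
#' @param n_national,n_subnational Default overall sample sizes.
#' @return \code{obs} with \code{denominator} filled and
#'   \code{imputed_denominator}, \code{imputed_total_n} flags.
#' @export
impute_denominators <- function(obs, pop2010, hierarchy = NULL,
                                n_national = 3000, n_subnational = 1000) {
  obs$imputed_denominator <- FALSE
  obs$imputed_total_n <- FALSE
  groups <- split(seq_len(nrow(obs)), paste(obs$study_id, obs$outcome))
  for (idx in groups) {
    need <- idx[is.na(obs$denominator[idx])]
    if (!length(need)) next
    total <- obs$total_n[idx][!is.na(obs$total_n[idx])][1]
    if (is.na(total) || is.null(total) || !length(total)) {
      total <- if (obs$geo[idx[1]] == "national") n_national else n_subnational
      obs$imputed_total_n[idx] <- TRUE
    }
    # remaining budget after rows with known denominators
    known <- sum(obs$denominator[idx], na.rm = TRUE)
    budget <- max(total - known, 0)
    key <- obs$country_code[idx[1]]
    if (!key %in% pop2010$region_or_country && !is.null(hierarchy))
      key <- hierarchy_lookup(hierarchy, key)$region_id
    # population mass of each needy row's band
    mass <- vapply(need, function(i) {
      cells <- age_band_indices(obs$age_lower[i], obs$age_upper[i])
      sum(population_grid_weights(pop2010, key)$weight[cells])
    }, numeric(1))
    if (any(mass <= 0) || sum(mass) == 0)
      stop("population weights do not cover the age range of: ",
           paste(obs$obs_id[need], collapse = ", "))
    obs$denominator[need] <- budget * mass / sum(mass)
    obs$imputed_denominator[need] <- TRUE
  }
  obs
}

#' Effective sample size of one observation
#'
#' Complex survey designs inflate sampling variance. When a design-adjusted
#' 95% CI is reported, the effective sample size is the n whose Wilson upper
#' limit at the observed prevalence equals the reported upper limit
#' (numerical inversion). When only a standard error is reported,
#' \eqn{n_{eff} = p(1-p)/SE^2}. Otherwise the denominator is divided by a
#' default design effect of 2.5 (the median from standardized DHS
#' analyses).
#'
#' @param prevalence Observed proportion.
#' @param denominator Reported (or imputed) number of respondents.
#' @param se Optional design-adjusted standard error.
#' @param ci_upper Optional design-adjusted upper 95% confidence limit.
#' @param design_effect Fallback design effect (default 2.5).
#' @return Positive effective sample size.
#' @export
effective_sample_size <- function(prevalence, denominator, se = NA,
                                  ci_upper = NA, design_effect = 2.5) {
  if (!is.na(ci_upper) && prevalence > 0 && prevalence < 1) {
    if (ci_upper <= prevalence)
      stop("reported upper limit must exceed the prevalence")
    n <- wilson_invert_n(prevalence, ci_upper,
                         n_max = max(10 * denominator, 1e4, na.rm = TRUE))
    if (!is.na(n)) return(n)
    # fall through to the design-effect rule (warning already emitted)
  }
  if (!is.na(se) && prevalence > 0 && prevalence < 1)
    return(prevalence * (1 - prevalence) / se^2)
  if (is.na(denominator)) stop("denominator required for design-effect rule")
  denominator / design_effect
}

# Instrument ranking used for optimal-set selection and reference-candidate
# ordering: smaller is closer to the gold standard, compared field by field
# in the stated order of the selection rules.
.instrument_rank <- function(obs) {
  cbind(severity = match(obs$severity, .severities) - 1L,
        type = match(obs$violence_type, .violence_types) - 1L,
        population = match(obs$population, .populations) - 1L,
        partner = match(obs$partner_ref, .partner_refs) - 1L)
}

#' Select the optimal instrument set
#'
#' Within each (study, outcome, age stratum), keeps exactly one observation,
#' chosen by four ordered preference rules: all-severity over severe-only;
#' physical and/or sexual over physical-only over sexual-only; ever-partnered
#' over all-women over currently-partnered; any partner over
#' current/most-recent. Marks \code{in_optimal_set = TRUE} when all four
#' fields are at the gold-standard reference level.
#'
#' @param obs Observation data frame.
#' @return Filtered data frame with one row per (study, outcome, geo, age
#'   stratum) and an \code{in_optimal_set} column.
#' @export
select_optimal_set <- function(obs) {
  if (!nrow(obs)) stop("empty observation set")
  key <- paste(obs$study_id, obs$outcome, obs$geo,
               obs$age_lower, obs$age_upper)
  rk <- .instrument_rank(obs)
  keep <- unlist(lapply(split(seq_len(nrow(obs)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    o <- idx[order(rk[idx, 1], rk[idx, 2], rk[idx, 3], rk[idx, 4])]
    o[1]
  }), use.names = FALSE)
  out <- obs[sort(keep), , drop = FALSE]
  out$in_optimal_set <- rowSums(.instrument_rank(out)) == 0
  rownames(out) <- NULL
  out
}

#' Attach crosswalk adjustment indicators
#'
#' Adds one binary column per adjustment covariate (prefixed \code{adj_}):
#' severe-only definition, physical-only and sexual-only violence types,
#' all-women and currently-partnered denominators, current/most-recent
#' partner reference, and urban/rural geographic strata. Mixed sub-national
#' surveys carry no geographic indicator (they keep the sub-national
#' variance class instead). An all-zero indicator vector means the
#' observation is at the reference (gold-standard) level for every
#' covariate.
#'
#' @param obs Observation data frame.
#' @return \code{obs} with \code{adj_*} columns.
#' @export
adjustment_indicators <- function(obs) {
  obs$adj_severe <- as.integer(obs$severity == "severe_only")
  obs$adj_physical_only <- as.integer(obs$violence_type == "physical_only")
  obs$adj_sexual_only <- as.integer(obs$violence_type == "sexual_only")
  obs$adj_all_women <- as.integer(obs$population == "all_women")
  obs$adj_currently_partnered <-
    as.integer(obs$population == "currently_partnered")
  obs$adj_current_recent <-
    as.integer(obs$partner_ref == "current_or_most_recent")
  obs$adj_urban <- as.integer(obs$geo == "urban")
  obs$adj_rural <- as.integer(obs$geo == "rural")
  obs
}

#' Build the adjustment and modelling datasets
#'
#' Splits pre-processed observations into the two analysis datasets. The
#' adjustment dataset keeps, for each study, outcome, instrument combination
#' and geographic stratum, only the broadest age band (maximal width, ties
#' broken toward the band covering the most 5-year cells); it feeds the
#' exact-matching crosswalk. The modelling dataset applies optimal-set
#' selection, keeps the most granular non-overlapping age strata, and drops
#' urban/rural rows of studies that also report a national (or mixed)
#' estimate.
#'
#' @param obs Pre-processed observation data frame.
#' @return List with elements \code{adjustment} and \code{modeling}.
#' @export
build_datasets <- function(obs) {
  obs <- adjustment_indicators(obs)

  # -- adjustment dataset: broadest band per study x outcome x instrument --
  width <- ifelse(is.infinite(obs$age_upper), 65 - obs$age_lower + 5,
                  obs$age_upper - obs$age_lower)
  ncells <- vapply(seq_len(nrow(obs)), function(i)
    length(age_band_indices(obs$age_lower[i], obs$age_upper[i])), integer(1))
  akey <- paste(obs$study_id, obs$outcome, obs$violence_type, obs$severity,
                obs$population, obs$partner_ref, obs$geo)
  keep_a <- unlist(lapply(split(seq_len(nrow(obs)), akey), function(idx) {
    o <- idx[order(-width[idx], -ncells[idx])]
    o[1]
  }), use.names = FALSE)
  adjustment <- obs[sort(keep_a), , drop = FALSE]
  rownames(adjustment) <- NULL

  # -- modelling dataset --
  mod <- select_optimal_set(obs)
  # drop urban/rural strata when the study has a national-level row
  drop <- logical(nrow(mod))
  for (idx in split(seq_len(nrow(mod)), paste(mod$study_id, mod$outcome))) {
    if (any(mod$geo[idx] %in% c("national", "mixed_subnational")))
      drop[idx[mod$geo[idx] %in% c("urban", "rural")]] <- TRUE
  }
  mod <- mod[!drop, , drop = FALSE]
  # most granular, non-overlapping age strata per study x outcome x geo
  keep_m <- integer()
  for (idx in split(seq_len(nrow(mod)), paste(mod$study_id, mod$outcome,
                                              mod$geo))) {
    w <- ifelse(is.infinite(mod$age_upper[idx]), 65 - mod$age_lower[idx] + 5,
                mod$age_upper[idx] - mod$age_lower[idx])
    o <- idx[order(w, mod$age_lower[idx])]
    kept <- integer()
    for (i in o) {
      ci <- age_band_indices(mod$age_lower[i], mod$age_upper[i])
      taken <- unlist(lapply(kept, function(k)
        age_band_indices(mod$age_lower[k], mod$age_upper[k])))
      if (!length(intersect(ci, taken))) kept <- c(kept, i)
      else if (any(vapply(kept, function(k)
        mod$age_lower[k] == mod$age_lower[i] &&
        mod$age_upper[k] == mod$age_upper[i], logical(1))) &&
        length(setdiff(ci, taken)))
        stop("overlapping age strata cannot be disambiguated for: ",
             paste(mod$obs_id[c(kept, i)], collapse = ", "))
    }
    keep_m <- c(keep_m, kept)
  }
  modeling <- mod[sort(keep_m), , drop = FALSE]
  rownames(modeling) <- NULL
  list(adjustment = adjustment, modeling = modeling)
}

#' Prepare observations for analysis
#'
#' Full pre-processing pipeline: metadata imputation, denominator
#' allocation, effective sample sizes, survey-adjusted binomial counts
#' (\code{y = round(prevalence * n_eff)}), and adjustment indicators.
#'
#' @param obs Raw observation data frame.
#' @param pop2010 2010 population weight table.
#' @param hierarchy Optional \code{geo_hierarchy} (validates countries and
#'   enables the regional population fallback).
#' @param design_effect Fallback design effect (default 2.5).
#' @param n_national,n_subnational Default overall sample sizes for studies
#'   with no reported denominator at all.
#' @return Data frame with \code{n_eff} and \code{y} columns added.
#' @export
prepare_observations <- function(obs, pop2010, hierarchy = NULL,
                                 design_effect = 2.5,
                                 n_national = 3000, n_subnational = 1000) {
  if (!is.null(hierarchy)) validate_observations(obs, hierarchy)
  obs <- impute_metadata(obs)
  obs <- impute_denominators(obs, pop2010, hierarchy,
                             n_national, n_subnational)
  obs$n_eff <- vapply(seq_len(nrow(obs)), function(i)
    effective_sample_size(obs$prevalence[i], obs$denominator[i],
                          se = obs$se[i], ci_upper = obs$ci_upper[i],
                          design_effect = design_effect), numeric(1))
  obs$y <- clamp(round(obs$prevalence * obs$n_eff), 0, round(obs$n_eff))
  adjustment_indicators(obs)
}
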