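# Model validation: posterior predictive checks, in-sample error metrics,
# and held-out cross-validation by countries or studies.

#' Posterior predictive check table
#'
#' For every observation: the observed prevalence with its Wilson 95%
#' interval at the effective sample size, the model's fitted prevalence
#' (posterior median and credible interval of the observation's own
#' success probability, which includes its study effect and crosswalk
#' offset, so the comparison is on the observation's instrument scale),
#' and a replicated-data predictive interval from Binomial(N, p) draws.
#'
#' @param fit An \code{ipv_fit}.
#' @param level Interval level (default 0.95).
#' @param seed Seed for the binomial replicates.
#' @return Data frame of class \code{ipv_ppc} (one row per observation)
#'   with inside/outside flags; plot with \code{plot()}.
#' @export
posterior_predictive_check <- function(fit, level = 0.95, seed = 1) {
  d <- fit$data
  p <- fit$draws$p
  n <- fit$spec$jags_data$N
  q <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  set.seed(seed)
  qs <- apply(p, 2, stats::quantile, probs = q)
  yrep <- matrix(stats::rbinom(length(p), rep(n, each = nrow(p)),
                               as.numeric(p)), nrow(p))
  prep <- sweep(yrep, 2, n, "/")
  qr <- apply(prep, 2, stats::quantile, probs = q)
  z <- stats::qnorm(1 - (1 - level) / 2)
  obs_se <- sqrt(d$prevalence * (1 - d$prevalence) / n)
  out <- data.frame(
    obs_id = d$obs_id, study_id = d$study_id,
    country_code = d$country_code, outcome = d$outcome,
    year = d$year_end, age_lower = d$age_lower, age_upper = d$age_upper,
    observed = d$prevalence,
    obs_lower = pmax(d$prevalence - z * obs_se, 0),
    obs_upper = pmin(d$prevalence + z * obs_se, 1),
    pred_median = qs[2, ], pred_lower = qs[1, ], pred_upper = qs[3, ],
    rep_lower = qr[1, ], rep_upper = qr[3, ],
    stringsAsFactors = FALSE)
  out$inside_cri <- out$observed >= out$pred_lower &
    out$observed <= out$pred_upper
  out$inside_pi <- out$observed >= out$rep_lower &
    out$observed <= out$rep_upper
  class(out) <- c("ipv_ppc", "data.frame")
  out
}

#' @export
plot.ipv_ppc <- function(x, hierarchy = NULL, max_panels = 16, ...) {
  group <- if (!is.null(hierarchy))
    hierarchy_lookup(hierarchy, x$country_code)$region_id
  else x$country_code
  units <- utils::head(unique(group), max_panels)
  nr <- ceiling(sqrt(length(units)))
  op <- graphics::par(mfrow = c(nr, ceiling(length(units) / nr)),
                      mar = c(2.5, 3, 2, 0.5))
  on.exit(graphics::par(op))
  for (u in units) {
    s <- x[group == u, , drop = FALSE]
    i <- seq_len(nrow(s))
    graphics::plot(i, s$observed, ylim = c(0, max(s$obs_upper,
                                                  s$pred_upper) * 1.05),
                   pch = 17, col = "grey40", xlab = "", ylab = "prevalence",
                   main = u, cex.main = 0.9, ...)
    graphics::segments(i, s$obs_lower, i, s$obs_upper, col = "grey40")
    graphics::points(i + 0.2, s$pred_median, pch = 16, col = "goldenrod2")
    graphics::segments(i + 0.2, s$pred_lower, i + 0.2, s$pred_upper,
                       col = "goldenrod2")
  }
  invisible(x)
}

#' In-sample comparison metrics
#'
#' Prediction errors on the percentage-point scale (error = observed -
#' predicted), summarized by the median error, median absolute error, and
#' the shares of observations falling below and above the 95% credible
#' interval of their fitted prevalence.
#'
#' @param x An \code{ipv_fit}, or a data frame with columns
#'   \code{observed}, \code{predicted}, \code{lower}, \code{upper}
#'   (proportions).
#' @param ... Unused.
#' @return List of class \code{validation_report}.
#' @export
in_sample_metrics <- function(x, ...) UseMethod("in_sample_metrics")

#' @rdname in_sample_metrics
#' @export
in_sample_metrics.ipv_fit <- function(x, ...) {
  ppc <- posterior_predictive_check(x)
  in_sample_metrics(data.frame(observed = ppc$observed,
                               predicted = ppc$pred_median,
                               lower = ppc$pred_lower,
                               upper = ppc$pred_upper),
                    scope = "in_sample")
}

#' @rdname in_sample_metrics
#' @param scope Label for the report.
#' @export
in_sample_metrics.data.frame <- function(x, scope = "in_sample", ...) {
  err <- (x$observed - x$predicted) * 100
  structure(list(scope = scope, n_units = nrow(x),
                 median_error = stats::median(err),
                 median_abs_error = stats::median(abs(err)),
                 pct_below_ci = 100 * mean(x$observed < x$lower),
                 pct_above_ci = 100 * mean(x$observed > x$upper),
                 n_repeats = 1L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (", x$scope, ", n = ", x$n_units, ")\n", sep = "")
  cat(sprintf("  median error:          %5.2f %% points\n", x$median_error))
  cat(sprintf("  median absolute error: %5.2f %% points\n",
              x$median_abs_error))
  cat(sprintf("  outside 95%% CrI:       %4.1f%% below, %4.1f%% above\n",
              x$pct_below_ci, x$pct_above_ci))
  if (x$n_repeats > 1) cat("  repeats:", x$n_repeats, "\n")
  invisible(x)
}

# Predict held-out observations from a fit: country-level curves (fitted
# or imputed), age-standardized over each observation's band, with the
# observation's crosswalk offset applied so the comparison is
# like-with-like on its instrument scale.
.predict_heldout <- function(fit, heldout, hierarchy, population2010,
                             adjustment = NULL, seed = 1) {
  h <- hierarchy_lookup(hierarchy, heldout$country_code)
  X <- if (is.null(adjustment)) numeric(nrow(heldout))
       else resolve_offsets(heldout, adjustment, hierarchy)
  nd <- fit$n_draws
  out <- matrix(NA_real_, nd, nrow(heldout))
  imput <- list()
  for (i in seq_len(nrow(heldout))) {
    cells <- age_band_indices(heldout$age_lower[i], heldout$age_upper[i])
    w <- population_shares(population2010, h$region_id[i], cells)
    cc <- heldout$country_code[i]
    if (cc %in% fit$spec$countries) {
      pr <- predict_country(fit, cc, ages = age_grid()[cells],
                            year = heldout$year_end[i])
      lp <- logit(pr[, 1, , drop = FALSE][, 1, ])
    } else {
      key <- paste(cc, heldout$year_end[i])
      if (is.null(imput[[key]]))
        imput[[key]] <- impute_country(fit, h$region_id[i],
                                       h$super_region_id[i],
                                       year = heldout$year_end[i],
                                       seed = seed + i)
      lp <- logit(imput[[key]][, 1, cells, drop = FALSE][, 1, ])
    }
    lp <- matrix(lp, nrow = nd)
    out[, i] <- (inv_logit(lp + X[i]) %*% w)
  }
  out
}

#' Out-of-sample cross-validation
#'
#' Repeatedly refits the model with 20% of countries (or studies) held
#' out, predicts the held-out age-specific observations, and compares them
#' with the known-but-excluded values; the across-repeat medians of the
#' in-sample-style metrics are reported. Country exclusion is stratified
#' by region so no region loses all its countries; held-out countries are
#' predicted through regional imputation, held-out studies through their
#' country's prediction. Repeats failing the convergence screen are
#' redrawn (and logged).
#'
#' @param data Prepared modelling dataset.
#' @param hierarchy,population2010 As \code{\link{fit_ipv_model}}.
#' @param outcome Outcome to validate.
#' @param mode \code{"countries"} or \code{"studies"}.
#' @param fraction Held-out fraction (default 0.20).
#' @param repeats Number of repeats (default 20).
#' @param cfg \code{\link{mcmc_config}}.
#' @param adjustment Optional adjustment factors (used for both fitting
#'   and instrument-scale comparison of held-out rows).
#' @param seed Seed controlling fold draws.
#' @param psrf_exclude Convergence screen for a repeat (default 1.5).
#' @param max_redraws Maximum redraws per failing repeat.
#' @param ... Passed to \code{\link{fit_ipv_model}}.
#' @return \code{validation_report} with across-repeat medians, plus a
#'   \code{per_repeat} table attribute.
#' @export
out_of_sample_cv <- function(data, hierarchy, population2010, outcome,
                             mode = c("countries", "studies"),
                             fraction = 0.20, repeats = 20,
                             cfg = mcmc_config(), adjustment = NULL,
                             seed = 1, psrf_exclude = 1.5,
                             max_redraws = 3, ...) {
  mode <- match.arg(mode)
  d <- data[data$outcome == outcome, , drop = FALSE]
  if (fraction <= 0)
    return(structure(list(scope = paste0("oos_", mode), n_units = 0L,
                          median_error = NA_real_,
                          median_abs_error = NA_real_,
                          pct_below_ci = NA_real_, pct_above_ci = NA_real_,
                          n_repeats = 0L), class = "validation_report"))
  h <- hierarchy_lookup(hierarchy, d$country_code)
  per <- list()
  attempt_seed <- seed
  for (rep_i in seq_len(repeats)) {
    done <- FALSE
    for (try_i in seq_len(max_redraws + 1)) {
      attempt_seed <- attempt_seed + 1
      set.seed(attempt_seed)
      if (mode == "countries") {
        # stratified by region: hold out ~fraction within each region,
        # never a region's last country
        held <- unlist(lapply(split(unique(d$country_code),
                                    h$region_id[!duplicated(d$country_code)]),
                              function(ccs) {
          k <- min(floor(length(ccs) * fraction + stats::runif(1)),
                   length(ccs) - 1)
          if (k < 1) character() else sample(ccs, k)
        }), use.names = FALSE)
        if (!length(held)) held <- sample(unique(d$country_code), 1)
        out_rows <- d$country_code %in% held
      } else {
        studies <- unique(d$study_id)
        k <- max(1, round(length(studies) * fraction))
        held <- sample(studies, k)
        out_rows <- d$study_id %in% held
      }
      train <- d[!out_rows, , drop = FALSE]
      test <- d[out_rows, , drop = FALSE]
      if (!nrow(test) || !nrow(train)) next
      cfg_r <- cfg; cfg_r$seed <- attempt_seed
      fit <- try(fit_ipv_model(train, hierarchy, population2010, outcome,
                               adjustment = adjustment, cfg = cfg_r, ...),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      mx <- suppressWarnings(diagnostics(fit)$max_psrf_reported)
      if (!is.na(mx) && mx > psrf_exclude) {
        message("repeat ", rep_i, " failed convergence (PSRF ",
                signif(mx, 3), "); redrawing")
        next
      }
      pr <- .predict_heldout(fit, test, hierarchy, population2010,
                             adjustment, seed = attempt_seed)
      qs <- apply(pr, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
      m <- in_sample_metrics(data.frame(observed = test$prevalence,
                                        predicted = qs[2, ],
                                        lower = qs[1, ],
                                        upper = qs[3, ]),
                             scope = paste0("oos_", mode))
      per[[rep_i]] <- data.frame(repeat_i = rep_i,
                                 n_held = length(held),
                                 n_obs = nrow(test),
                                 median_error = m$median_error,
                                 median_abs_error = m$median_abs_error,
                                 pct_below_ci = m$pct_below_ci,
                                 pct_above_ci = m$pct_above_ci)
      done <- TRUE
      break
    }
    if (!done) stop("cross-validation repeat ", rep_i,
                    " failed after ", max_redraws + 1, " attempts")
  }
  tab <- do.call(rbind, per)
  structure(list(scope = paste0("oos_", mode),
                 n_units = round(stats::median(tab$n_held)),
                 median_error = stats::median(tab$median_error),
                 median_abs_error = stats::median(tab$median_abs_error),
                 pct_below_ci = stats::median(tab$pct_below_ci),
                 pct_above_ci = stats::median(tab$pct_above_ci),
                 n_repeats = repeats, per_repeat = tab),
            class = "validation_report")
}
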