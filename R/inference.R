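# Inference utilities: mixing fits over sampled adjustment vectors,
# convergence diagnostics, information criteria, and spline selection.

#' Fit the model over sampled adjustment vectors and mix the posteriors
#'
#' Uncertainty in the crosswalk factors is propagated by refitting the
#' model once per sampled adjustment vector and pooling all posterior
#' draws with equal weight; summaries computed on the mixture then carry
#' both within-fit and between-vector variability. Sub-fits failing a
#' (lenient) convergence screen are excluded with a warning; if fewer than
#' half survive, the run errors.
#'
#' @param data,hierarchy,population2010,outcome As
#'   \code{\link{fit_ipv_model}}.
#' @param adj_draws An \code{\link{sample_adjustment_vectors}} result.
#' @param cfg \code{\link{mcmc_config}}; each sub-fit gets a distinct seed
#'   derived from \code{cfg$seed}.
#' @param psrf_exclude Exclude a sub-fit when the maximum potential scale
#'   reduction factor of its scalar hyperparameters exceeds this (default
#'   1.5).
#' @param ... Passed to \code{\link{fit_ipv_model}} (knots, years, quiet).
#' @return An \code{ipv_fit} whose draws are the equal-weight mixture, with
#'   \code{$fit_index} mapping each pooled draw to its source fit and
#'   \code{$mixture} metadata.
#' @export
fit_mixed_over_adjustments <- function(data, hierarchy, population2010,
                                       outcome, adj_draws,
                                       cfg = mcmc_config(),
                                       psrf_exclude = 1.5, ...) {
  D <- adj_draws$D
  if (D < 1) stop("at least one adjustment vector required")
  fits <- vector("list", D)
  keep <- logical(D)
  for (d in seq_len(D)) {
    cfg_d <- cfg
    cfg_d$seed <- cfg$seed + d - 1
    tab <- adj_draws$draws[[d]]
    attr(tab, "draw_id") <- d
    fits[[d]] <- fit_ipv_model(data, hierarchy, population2010, outcome,
                               adjustment = tab, cfg = cfg_d, ...)
    mx <- suppressWarnings(diagnostics(fits[[d]])$max_psrf_reported)
    keep[d] <- is.na(mx) || mx <= psrf_exclude
    if (!keep[d])
      warning("adjustment draw ", d, " excluded: max PSRF ",
              signif(mx, 3), " > ", psrf_exclude)
  }
  if (sum(keep) < D / 2)
    stop("fewer than half of the adjustment-draw fits converged")
  kept <- which(keep)
  pool <- function(get) {
    parts <- lapply(kept, function(d) get(fits[[d]]))
    if (is.null(dim(parts[[1]])) || length(dim(parts[[1]])) <= 2)
      do.call(rbind, lapply(parts, function(x)
        if (is.null(dim(x))) matrix(x, ncol = 1) else x))
    else {
      dm <- dim(parts[[1]])
      out <- array(NA_real_, c(sum(vapply(parts, function(x) dim(x)[1],
                                          numeric(1))), dm[2], dm[3]))
      at <- 0
      for (p in parts) {
        out[at + seq_len(dim(p)[1]), , ] <- p
        at <- at + dim(p)[1]
      }
      out
    }
  }
  draws <- lapply(stats::setNames(names(fits[[kept[1]]]$draws),
                                  names(fits[[kept[1]]]$draws)),
                  function(nm) {
                    x <- pool(function(f) f$draws[[nm]])
                    if (is.matrix(x) && ncol(x) == 1 &&
                        is.null(dim(fits[[kept[1]]]$draws[[nm]])))
                      as.numeric(x) else x
                  })
  n_per <- vapply(kept, function(d) fits[[d]]$n_draws, numeric(1))
  base <- fits[[kept[1]]]
  structure(list(draws = draws, samples = base$samples, spec = base$spec,
                 cfg = cfg, data = base$data, outcome = outcome,
                 n_draws = sum(n_per),
                 fit_index = rep(seq_along(kept), times = n_per),
                 mixture = list(D = D, kept = kept,
                                seeds = cfg$seed + kept - 1)),
            class = c("ipv_fit_mixture", "ipv_fit"))
}

#' Convergence diagnostics
#'
#' Potential scale reduction factor (PSRF, split over chains) and effective
#' sample size for every monitored parameter. The run passes when the
#' maximum PSRF is close to one (default threshold 1.05) and the minimum
#' effective sample size over the reported prevalence nodes reaches 1,000.
#'
#' @param fit An \code{ipv_fit} (needs >= 2 chains).
#' @param psrf_threshold Pass threshold on the maximum PSRF.
#' @param ess_min Required effective sample size (default 1000).
#' @return Object of class \code{ipv_diagnostics}: per-parameter table,
#'   \code{max_psrf}, \code{min_ess}, \code{pass}.
#' @export
diagnostics <- function(fit, psrf_threshold = 1.05, ess_min = 1000) {
  if (length(fit$samples) < 2)
    stop("diagnostics require at least 2 chains")
  gd <- try(coda::gelman.diag(fit$samples, autoburnin = FALSE,
                              multivariate = FALSE), silent = TRUE)
  if (inherits(gd, "try-error")) {
    # singular covariance on degenerate nodes; fall back per-variable
    mats <- lapply(fit$samples, as.matrix)
    psrf <- vapply(seq_len(ncol(mats[[1]])), function(j) {
      one <- coda::mcmc.list(lapply(mats, function(m) coda::mcmc(m[, j])))
      out <- try(coda::gelman.diag(one, autoburnin = FALSE)$psrf[1, 1],
                 silent = TRUE)
      if (inherits(out, "try-error")) NA_real_ else out
    }, numeric(1))
    names(psrf) <- colnames(mats[[1]])
  } else {
    psrf <- gd$psrf[, 1]
    if (is.null(names(psrf)))
      names(psrf) <- rownames(gd$psrf) %||%
        colnames(as.matrix(fit$samples[[1]]))
  }
  ess <- coda::effectiveSize(fit$samples)
  tab <- data.frame(parameter = names(psrf), psrf = unname(psrf),
                    ess = unname(ess[names(psrf)]),
                    stringsAsFactors = FALSE)
  is_p <- grepl("^p\\[", tab$parameter)
  mx_all <- suppressWarnings(max(tab$psrf, na.rm = TRUE))
  mx_rep <- suppressWarnings(max(tab$psrf[is_p], na.rm = TRUE))
  mn_ess <- suppressWarnings(min(tab$ess[is_p], na.rm = TRUE))
  structure(list(table = tab, max_psrf = mx_all,
                 max_psrf_reported = mx_rep, min_ess = mn_ess,
                 psrf_threshold = psrf_threshold, ess_min = ess_min,
                 pass = isTRUE(mx_all <= psrf_threshold &&
                                 mn_ess >= ess_min)),
            class = "ipv_diagnostics")
}

#' @export
print.ipv_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics over", nrow(x$table), "monitored parameters\n")
  cat("  max PSRF:", signif(x$max_psrf, 4),
      "(threshold", x$psrf_threshold, ")\n")
  cat("  min ESS of reported prevalences:", round(x$min_ess),
      "(required", x$ess_min, ")\n")
  cat("  pass:", x$pass, "\n")
  invisible(x)
}

#' Export traceplots
#'
#' Writes (or draws) traceplots for selected monitored parameters.
#'
#' @param fit An \code{ipv_fit}.
#' @param pars Parameter name patterns (default the scalar
#'   hyperparameters).
#' @param file Optional PDF path; when \code{NULL}, plots on the active
#'   device.
#' @export
traceplots <- function(fit, pars = c("u_g", "sigma_c", "sigma_n", "tau"),
                       file = NULL) {
  cols <- unlist(lapply(pars, function(p)
    grep(paste0("^", p, "(\\[|$)"), colnames(fit$samples[[1]]),
         value = TRUE)))
  if (!is.null(file)) {
    grDevices::pdf(file)
    on.exit(grDevices::dev.off())
  }
  coda::traceplot(fit$samples[, cols, drop = FALSE])
  invisible(cols)
}

# Pointwise log-likelihood matrix (draws x observations).
.pointwise_ll <- function(fit) {
  y <- fit$spec$jags_data$y
  n <- fit$spec$jags_data$N
  p <- fit$draws$p
  t(vapply(seq_along(y), function(i)
    stats::dbinom(y[i], n[i], p[, i], log = TRUE), numeric(nrow(p))))
}

#' Widely Applicable Information Criterion
#'
#' WAIC from the pointwise binomial log likelihood of the modelling
#' dataset at the age-standardized success probabilities.
#'
#' @param fit An \code{ipv_fit}.
#' @return List with \code{waic}, \code{lppd}, \code{p_waic}.
#' @export
waic <- function(fit) {
  ll <- .pointwise_ll(fit)            # obs x draws
  m <- apply(ll, 1, max)
  lppd <- sum(m + log(rowMeans(exp(ll - m))))
  p_waic <- sum(apply(ll, 1, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Deviance Information Criterion
#'
#' DIC with the effective number of parameters from the difference between
#' the posterior mean deviance and the deviance at the posterior mean
#' success probabilities.
#'
#' @param fit An \code{ipv_fit}.
#' @return List with \code{dic}, \code{dbar}, \code{pd}.
#' @export
dic <- function(fit) {
  y <- fit$spec$jags_data$y
  n <- fit$spec$jags_data$N
  ll <- .pointwise_ll(fit)
  dbar <- mean(-2 * colSums(ll))
  dhat <- -2 * sum(stats::dbinom(y, n, colMeans(fit$draws$p), log = TRUE))
  pd <- dbar - dhat
  list(dic = dhat + 2 * pd, dbar = dbar, pd = pd)
}

#' Choose the age-spline knot configuration
#'
#' Fits each candidate interior-knot set and compares WAIC (reporting DIC
#' alongside); the lowest WAIC wins, with ties broken toward fewer knots.
#'
#' @param data,hierarchy,population2010,outcome,adjustment,cfg As
#'   \code{\link{fit_ipv_model}}.
#' @param candidates List of knot sets (default
#'   \code{\link{age_knot_candidates}}).
#' @param ... Passed to \code{\link{fit_ipv_model}}.
#' @return List with \code{table} (one row per candidate) and
#'   \code{chosen} (the selected knot vector).
#' @export
select_spline <- function(data, hierarchy, population2010, outcome,
                          adjustment = NULL,
                          candidates = age_knot_candidates(),
                          cfg = mcmc_config(), ...) {
  if (length(candidates) < 2) stop("need at least 2 candidate knot sets")
  rows <- lapply(candidates, function(kn) {
    fit <- fit_ipv_model(data, hierarchy, population2010, outcome,
                         adjustment = adjustment, cfg = cfg,
                         age_knots = kn, ...)
    w <- waic(fit); d <- dic(fit)
    data.frame(knots = paste(kn, collapse = ","), n_knots = length(kn),
               waic = w$waic, p_waic = w$p_waic, dic = d$dic, pd = d$pd,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- order(tab$waic, tab$n_knots)[1]
  list(table = tab, chosen = candidates[[best]])
}
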