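# S3 methods for fitted ipv_fit objects.

#' @export
print.ipv_fit <- function(x, ...) {
  jd <- x$spec$jags_data
  cat("Hierarchical IPV meta-regression (", x$outcome, ")\n", sep = "")
  cat("  observations:", jd$Nobs, " studies:", jd$Ns,
      " countries:", jd$Nc, " regions:", jd$Nr,
      " super-regions:", jd$Nz, "\n")
  cat("  age knots:", paste(x$spec$age_basis$knots, collapse = ", "),
      " time knot:", paste(x$spec$time_basis$knots, collapse = ", "), "\n")
  cat("  posterior draws:", x$n_draws, "(", x$cfg$chains, "chains )\n")
  if (inherits(x, "ipv_fit_mixture"))
    cat("  mixed over", length(x$mixture$kept), "adjustment vectors\n")
  inv <- inv_logit(stats::median(x$draws$u_g))
  cat("  median prevalence at age 30, reference year:",
      sprintf("%.1f%%", 100 * inv), "\n")
  invisible(x)
}

#' @export
summary.ipv_fit <- function(object, ...) {
  d <- object$draws
  sm <- function(v) c(median = stats::median(v),
                      lower = stats::quantile(v, 0.025, names = FALSE),
                      upper = stats::quantile(v, 0.975, names = FALSE))
  pars <- rbind(u_g = sm(d$u_g), sigma_z = sm(d$sigma_z),
                sigma_r = sm(d$sigma_r), sigma_c = sm(d$sigma_c),
                sigma_national = sm(d$sigma_n),
                sigma_subnational = sm(d$sigma_n + d$tau))
  out <- list(fit = object, parameters = pars)
  class(out) <- "summary.ipv_fit"
  out
}

#' @export
print.summary.ipv_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior medians (95% CrI):\n")
  p <- x$parameters
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-18s %7.3f (%.3f, %.3f)\n", rownames(p)[i],
                p[i, 1], p[i, 2], p[i, 3]))
  invisible(x)
}

#' @export
coef.ipv_fit <- function(object, ...) {
  d <- object$draws
  c(u_g = mean(d$u_g),
    stats::setNames(colMeans(d$eta_g),
                    paste0("eta_g", seq_len(ncol(d$eta_g)))),
    stats::setNames(colMeans(d$phi_g),
                    paste0("phi_g", seq_len(ncol(d$phi_g)))),
    sigma_z = mean(d$sigma_z), sigma_r = mean(d$sigma_r),
    sigma_c = mean(d$sigma_c), sigma_n = mean(d$sigma_n),
    tau = mean(d$tau))
}

#' Predict method for IPV model fits
#'
#' Country-level prevalence predictions at the reference instrument,
#' summarized by posterior median and 95% credible interval, or returned
#' as raw draws.
#'
#' @param object An \code{ipv_fit}.
#' @param countries Country codes (default all in the fit).
#' @param ages Age-grid values.
#' @param year Prediction year.
#' @param draws Return the draw array instead of summaries.
#' @param ... Unused.
#' @return Data frame of estimates, or the draw array when
#'   \code{draws = TRUE}.
#' @export
predict.ipv_fit <- function(object, countries = NULL, ages = age_grid(),
                            year = NULL, draws = FALSE, ...) {
  arr <- predict_country(object, countries, ages, year)
  if (draws) return(arr)
  rows <- expand.grid(country = dimnames(arr)[[2]], age = ages,
                      stringsAsFactors = FALSE)
  qs <- t(vapply(seq_len(nrow(rows)), function(i) {
    v <- arr[, rows$country[i], as.character(rows$age[i])]
    stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  }, numeric(3)))
  data.frame(rows, year = attr(arr, "year"), median = qs[, 2],
             ci_lower = qs[, 1], ci_upper = qs[, 3],
             stringsAsFactors = FALSE)
}

#' @export
plot.ipv_fit <- function(x, hierarchy = NULL, ...) {
  plot(posterior_predictive_check(x), hierarchy = hierarchy, ...)
}

#' Simulate replicated survey counts from the posterior predictive
#'
#' @param object An \code{ipv_fit}.
#' @param nsim Number of replicated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix (observations x nsim) of replicated counts.
#' @export
simulate.ipv_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$spec$jags_data$N
  p <- object$draws$p
  idx <- sample.int(nrow(p), nsim, replace = nsim > nrow(p))
  out <- vapply(idx, function(d) stats::rbinom(length(n), n, p[d, ]),
                numeric(length(n)))
  rownames(out) <- object$data$obs_id
  out
}

#' @export
residuals.ipv_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  phat <- apply(object$draws$p, 2, stats::median)
  r <- object$data$prevalence - phat
  if (type == "pearson") {
    n <- object$spec$jags_data$N
    r <- r / sqrt(phat * (1 - phat) / n)
  }
  stats::setNames(r, object$data$obs_id)
}
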