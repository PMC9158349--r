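# Model-core arithmetic: linear predictor, age-standardization,
# likelihood, constraints, MCMC configuration, and consistency of the
# sampler's standardized probabilities with an independent reconstruction.

test_that("age standardization equals brute-force weighted summation", {
  # age-constant prevalence is invariant to the weights
  p <- 0.23
  expect_equal(age_standardize(rep(qlogis(p), 5), runif(5, 1, 9)), p)
  # two bands, equal weights: midpoint
  expect_equal(age_standardize(qlogis(c(0.1, 0.3)), c(1, 1)), 0.2)
  # unequal weights: direct summation oracle
  lg <- qlogis(c(0.12, 0.25, 0.4))
  w <- c(3, 5, 2)
  oracle <- 0
  for (i in 1:3) oracle <- oracle + plogis(lg[i]) * w[i]
  oracle <- oracle / sum(w)
  expect_equal(age_standardize(lg, w), oracle, tolerance = 1e-12)
  expect_error(age_standardize(lg, c(1, 2)), "length")
  expect_error(age_standardize(lg, c(-1, 0, 0)), "weights")
})

test_that("standardized prevalence stays within the band's range", {
  set.seed(4)
  for (i in 1:25) {
    lg <- rnorm(6, -1, 1)
    w <- runif(6, 0.1, 5)
    s <- age_standardize(lg, w)
    expect_gte(s, min(plogis(lg)))
    expect_lte(s, max(plogis(lg)))
    expect_true(s > 0 && s < 1)
  }
})

test_that("linear predictor assembles intercepts, splines, and offsets", {
  Ab <- build_age_spline_basis(25)
  Tb <- build_time_spline_basis(2000:2018, 2011)
  prm <- list(alpha = -1, lambda = c(0.5, -0.2), phi = c(0.1, 0.05))
  # all spline terms vanish at the centering points
  expect_equal(linear_predictor(prm, 30, 2011, Ab, Tb), -1)
  # a covariate offset shifts the logit by exactly its log OR
  expect_equal(linear_predictor(prm, 30, 2011, Ab, Tb, X = -0.3),
               -1.3)
  # hand-assembled sum at an arbitrary age/year
  hand <- -1 + sum(Ab$evaluate(22) * prm$lambda) +
    sum(Tb$evaluate(2005) * prm$phi) + 0.2
  expect_equal(linear_predictor(prm, 22, 2005, Ab, Tb, X = 0.2), hand)
})

test_that("log likelihood matches an independent binomial summation", {
  y <- c(10, 25, 3, 40, 0)
  n <- c(50, 100, 20, 90, 30)
  p <- c(0.2, 0.22, 0.2, 0.45, 0.05)
  oracle <- 0
  for (i in 1:5)
    oracle <- oracle + lchoose(n[i], y[i]) + y[i] * log(p[i]) +
      (n[i] - y[i]) * log(1 - p[i])
  expect_equal(log_likelihood(p, y, n), oracle)
  # the per-observation term is maximized at the empirical proportion
  ll_at <- function(pp) log_likelihood(pp, 10, 50)
  expect_gt(ll_at(0.2), ll_at(0.25))
  expect_gt(ll_at(0.2), ll_at(0.15))
  expect_error(log_likelihood(0.5, 60, 50), "exceeds")
})

test_that("mcmc configurations retain the documented draw counts", {
  full <- mcmc_config("full")
  expect_equal(full$chains, 4)
  expect_equal(full$retained, 2250)        # (50000 - 5000) / 20
  desk <- mcmc_config()
  expect_equal(desk$retained, 1500)
  expect_error(mcmc_config(warmup = 5000, iterations = 4000), "retained")
  expect_error(mcmc_config(chains = 0), "positive")
})

test_that("sampler probabilities match an independent reconstruction", {
  fit <- tiny_fit("lifetime")
  for (d in c(1, 57, fit$n_draws)) {
    expect_equal(ipvmeta:::compute_p_draw(fit, d),
                 as.numeric(fit$draws$p[d, ]), tolerance = 1e-6)
  }
})

test_that("standardization weights span wide bands and point to 5-year cells", {
  fit <- tiny_fit("lifetime")
  jd <- fit$spec$jags_data
  d <- fit$spec$data
  for (i in seq_len(jd$Nobs)) {
    cells <- ipvmeta:::age_band_indices(d$age_lower[i], d$age_upper[i])
    expect_equal(which(jd$W[i, ] > 0), cells)
    expect_equal(sum(jd$W[i, ]), 1)
  }
  # broad bands genuinely mix several cells
  wide <- d$age_upper - d$age_lower > 5
  expect_true(any(rowSums(jd$W[wide, , drop = FALSE] > 0) > 1))
})

test_that("constraints reject or project violating draw pairs", {
  ages <- c(17, 22)
  life <- rbind(c(0.30, 0.35), c(0.20, 0.25), c(0.40, 0.30))
  past <- rbind(c(0.10, 0.12), c(0.25, 0.10), c(0.08, 0.28))
  # draw 2 violates past <= life; draw 3 violates RR <= 3 at 15-19
  con <- apply_constraints(life, past, ages)
  expect_equal(con$retained, 1L)
  expect_equal(con$acceptance, 1 / 3)
  # all-satisfying draws pass through unchanged
  ok <- apply_constraints(life[1, , drop = FALSE],
                          past[1, , drop = FALSE], ages)
  expect_equal(ok$lifetime, life[1, , drop = FALSE])
  expect_equal(ok$acceptance, 1)
  # cap mode projects instead of rejecting
  cap <- apply_constraints(life, past, ages, mode = "cap")
  expect_equal(nrow(cap$past_year), 3)
  expect_true(all(cap$past_year <= cap$lifetime + 1e-12))
  expect_true(all(cap$lifetime[, 1] <= 3 * cap$past_year[, 1] + 1e-12))
  # hopeless constraints raise the misfit error
  bad_p <- matrix(0.9, 50, 2)
  bad_l <- matrix(0.1, 50, 2)
  expect_error(apply_constraints(bad_l, bad_p, ages), "acceptance rate")
})

test_that("run manifests record reproducibility metadata", {
  fit <- tiny_fit("lifetime")
  f <- withr::local_tempfile(fileext = ".json")
  run_manifest(fit, f)
  m <- jsonlite::read_json(f)
  expect_equal(m$outcome, "lifetime")
  expect_equal(m$age_knots, 25)
  expect_equal(m$mcmc$seed, 5)
  expect_equal(m$n_countries, length(fit$spec$countries))
})
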