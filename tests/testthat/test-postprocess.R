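# Prediction, country imputation, and population-weighted aggregation.

test_that("predictions invert the prediction equation without study effects", {
  # all hierarchy effects zero: prediction is inv-logit(u_g + age + time)
  f <- fake_fit(n_draws = 3, u_g = -1, eta_g = c(0.5, -0.2),
                phi_g = c(0.1, 0))
  pr <- predict_country(f, "C01", ages = c(17, 30, 47), year = 2011)
  Ab <- f$spec$age_basis
  expected <- plogis(-1 + as.numeric(Ab$evaluate(c(17, 30, 47)) %*%
                                       c(0.5, -0.2)))
  expect_equal(as.numeric(pr[1, 1, ]), expected)
  # at the centering age and year the prediction is inv-logit(u_g)
  expect_equal(as.numeric(pr[, 1, "30"]), rep(plogis(-1), 3))
  # nonzero hierarchy effects stack on the logit scale
  f2 <- fake_fit(n_draws = 2, u_g = -1, u_z = c(0.3, 0), u_r = c(-0.1, 0),
                 u_c = c(0.2, 0))
  pr2 <- predict_country(f2, "C01", ages = 30, year = 2011)
  expect_equal(as.numeric(pr2[1, 1, 1]), plogis(-1 + 0.3 - 0.1 + 0.2))
  expect_error(predict_country(f2, "C99"), "impute_country")
})

test_that("fitted tiny-model predictions track the generating truth", {
  fit <- tiny_fit("lifetime")
  db <- tiny_db()
  pl <- predict_country(fit, year = 2011)
  tr <- db$truth$p_true[dimnames(pl)[[2]], , "2011", "lifetime"]
  est <- apply(pl, c(2, 3), median)
  expect_gt(cor(as.numeric(tr), as.numeric(est)), 0.4)
  expect_lt(mean(abs(tr - est)), 0.15)
})

test_that("imputed countries shrink to the region as sigma_c vanishes", {
  f <- fake_fit(n_draws = 200, u_g = -1, u_z = c(0.2, 0), u_r = c(0.1, 0),
                sigma_c = 1e-12)
  imp <- impute_country(f, "R01", "SR1", ages = 30, year = 2011,
                        age_deviation = FALSE, seed = 3)
  expect_equal(as.numeric(imp[, 1, 1]), rep(plogis(-1 + 0.2 + 0.1), 200),
               tolerance = 1e-6)
  expect_true(attr(imp, "imputed"))
})

test_that("imputed countries carry wider intervals than data countries", {
  fit <- tiny_fit("lifetime")
  db <- tiny_db()
  h <- db$hierarchy
  cc <- fit$spec$countries[1]
  reg <- ipvmeta:::hierarchy_lookup(h, cc)$region_id
  sr <- ipvmeta:::hierarchy_lookup(h, cc)$super_region_id
  pr <- predict_country(fit, cc, ages = 30, year = 2011)
  imp <- impute_country(fit, reg, sr, ages = 30, year = 2011, seed = 8)
  width <- function(x) diff(quantile(x, c(0.025, 0.975)))
  expect_gte(width(imp[, 1, 1]), width(pr[, 1, 1]))
})

test_that("aggregation reduces to members and conserves counts", {
  nd <- 50
  set.seed(9)
  # three countries, deterministic draws
  f <- fake_fit(n_draws = nd, u_c = c(qlogis(0.2), qlogis(0.4), qlogis(0.3)))
  pr <- predict_country(f, ages = age_grid(), year = 2011)
  h <- geo_hierarchy(data.frame(
    country_code = c("C01", "C02", "C03"),
    region_id = c("R1", "R1", "R2"), super_region_id = "Z1"))
  pop <- toy_population(c("C01", "C02", "C03"), year = 2018,
                        esp = rep(1, 11))
  # single-country region equals the country
  ag_c <- aggregate_prevalence(pr, pop, h, "country")
  ag_r <- aggregate_prevalence(pr, pop, h, "region")
  expect_equal(ag_r$median[ag_r$unit == "R2"],
               ag_c$median[ag_c$unit == "C03"])
  # two equal-weight countries at constant 0.2 and 0.4 average to 0.3
  f2 <- fake_fit(n_draws = 4, u_c = qlogis(c(0.2, 0.4)))
  pr2 <- predict_country(f2, ages = age_grid(), year = 2011)
  h2 <- geo_hierarchy(data.frame(country_code = c("C01", "C02"),
                                 region_id = "R1", super_region_id = "Z1"))
  pop2 <- toy_population(c("C01", "C02"), year = 2018, esp = rep(1, 11))
  ag2 <- aggregate_prevalence(pr2, pop2, h2, "region")
  expect_equal(ag2$median, 0.3, tolerance = 1e-9)
})

test_that("aggregation matches a brute-force count summation", {
  nd <- 8
  set.seed(10)
  f <- fake_fit(n_draws = nd, u_c = qlogis(c(0.15, 0.33, 0.27)))
  pr <- predict_country(f, ages = age_grid(), year = 2011)
  h <- geo_hierarchy(data.frame(
    country_code = c("C01", "C02", "C03"), region_id = "R1",
    super_region_id = "Z1"))
  wts <- list(c(9, 8, 7, 6, 5, 4, 3, 2, 1, 1, 1) * 100,
              c(5, 5, 5, 4, 4, 4, 3, 3, 3, 2, 2) * 80,
              c(2, 3, 4, 5, 6, 5, 4, 3, 2, 1, 1) * 150)
  esp <- c(0.4, 0.8, 0.95, 1, 1, 1, 1, 1, 1, 1, 1)
  pop <- do.call(rbind, lapply(1:3, function(i)
    data.frame(region_or_country = sprintf("C%02d", i), age = age_grid(),
               weight = wts[[i]], reference_year = 2018,
               ever_sex_proportion = esp)))
  cells <- 1:7   # 15-49
  # oracle: per draw, sum affected women over countries and ages, divide
  # by total weighted women
  oracle <- numeric(nd)
  for (d in 1:nd) {
    num <- den <- 0
    for (i in 1:3) {
      w <- wts[[i]][cells] * esp[cells]
      num <- num + sum(pr[d, i, cells] * w)
      den <- den + sum(w)
    }
    oracle[d] <- num / den
  }
  ag <- aggregate_prevalence(pr, pop, h, "global", age_range = c(15, 49))
  expect_equal(ag$median, median(oracle), tolerance = 1e-12)
  # order invariance: aggregating countries directly to global equals
  # weighting the region level (single region here)
  agr <- aggregate_prevalence(pr, pop, h, "region")
  expect_equal(agr$median, ag$median, tolerance = 1e-12)
  # aggregate lies within the member range per draw
  agc <- aggregate_prevalence(pr, pop, h, "country")
  expect_true(ag$median >= min(agc$median) && ag$median <= max(agc$median))
})

test_that("joint constraint surface pairs fits and enforces both rules", {
  fit_l <- tiny_fit("lifetime")
  fit_p <- tiny_fit("past_year")
  db <- tiny_db()
  cc <- fit_l$spec$countries[1:2]
  cp <- constrained_predictions(fit_l, fit_p, db$hierarchy,
                                countries = cc, year = 2011,
                                mode = "cap")
  expect_true(all(cp$past_year <= cp$lifetime + 1e-12))
  young <- which(attr(cp$lifetime, "ages") >= 15 &
                   attr(cp$lifetime, "ages") < 20)
  expect_true(all(cp$lifetime[, , young] <=
                    3 * cp$past_year[, , young] + 1e-9))
})
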