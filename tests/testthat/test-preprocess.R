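# Pre-processing: denominators, effective sample sizes, metadata
# imputation, optimal-set selection, dataset construction.

base_obs <- function(n, ...) {
  out <- data.frame(
    obs_id = paste0("O", seq_len(n)), study_id = "S1", country_code = "C1",
    year_start = 2010, year_end = 2010, outcome = "lifetime",
    violence_type = "physical_and_or_sexual", severity = "all",
    population = "ever_partnered", partner_ref = "any_partner",
    geo = "national", age_lower = 15, age_upper = 49, prevalence = 0.2,
    denominator = NA_real_, total_n = NA_real_, se = NA_real_,
    ci_lower = NA_real_, ci_upper = NA_real_, publication_year = 2012,
    age_open = FALSE, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) out[[nm]] <- mods[[nm]]
  out
}

test_that("denominators are allocated proportionally to 2010 population", {
  # two bands with equal population -> even split
  pop <- toy_population("C1")
  obs <- base_obs(2, age_lower = c(15, 20), age_upper = c(19, 24),
                  total_n = 1000)
  out <- impute_denominators(obs, pop)
  expect_equal(out$denominator, c(500, 500))
  expect_true(all(out$imputed_denominator))
  # shares 0.6/0.4 -> 600/400
  pop2 <- toy_population("C1", weights = c(60, 40, rep(1, 9)))
  out2 <- impute_denominators(obs, pop2)
  expect_equal(out2$denominator, c(600, 400))
  expect_equal(sum(out2$denominator), 1000)
})

test_that("studies with no sample size get the 3000/1000 defaults", {
  pop <- toy_population("C1")
  nat <- impute_denominators(base_obs(1), pop)
  expect_equal(nat$denominator, 3000)
  expect_true(nat$imputed_total_n)
  sub <- impute_denominators(base_obs(1, geo = "urban"), pop)
  expect_equal(sub$denominator, 1000)
})

test_that("age range outside the population table errors", {
  pop <- toy_population("C1")
  obs <- base_obs(1, age_lower = 10, age_upper = 14, total_n = 100)
  expect_error(impute_denominators(obs, pop))
})

test_that("effective sample size follows the CI > SE > design-effect rules", {
  # no CI/SE: design effect 2.5
  expect_equal(effective_sample_size(0.2, 2500), 1000)
  # SE exactly sqrt(p(1-p)/n): no design effect
  p <- 0.3; n <- 1200
  expect_equal(effective_sample_size(p, n, se = sqrt(p * (1 - p) / n)), n,
               tolerance = 1e-9)
  # Wilson inversion: round-trip through the reported upper limit
  up <- wilson_upper(0.30, 850)
  n_eff <- effective_sample_size(0.30, 2000, ci_upper = up)
  expect_equal(n_eff, 850, tolerance = 1e-3)
  expect_equal(wilson_upper(0.30, n_eff), up, tolerance = 1e-6)
  # reported upper below the prevalence is impossible
  expect_error(effective_sample_size(0.30, 2000, ci_upper = 0.25),
               "upper limit")
})

test_that("wilson inversion matches a grid-search oracle", {
  # oracle: dense grid over n, pick the n whose upper limit is closest
  p <- 0.30; upper <- 0.35
  grid <- seq(1, 5000, by = 0.25)
  oracle_n <- grid[which.min(abs(wilson_upper(p, grid) - upper))]
  n_inv <- wilson_invert_n(p, upper)
  expect_equal(n_inv, oracle_n, tolerance = 1e-3)
  expect_equal(wilson_upper(p, n_inv), 0.35, tolerance = 1e-6)
})

test_that("effective sample size shrinks as reported CIs widen", {
  p <- 0.25; n <- 2000
  uppers <- wilson_upper(p, c(1800, 900, 300, 100))
  ess <- vapply(uppers, function(u)
    effective_sample_size(p, n, ci_upper = u), numeric(1))
  expect_true(all(diff(ess) < 0))
})

test_that("metadata imputation uses publication year and open-ended ages", {
  obs <- base_obs(2, year_end = c(NA, 2010), publication_year = 2014)
  out <- impute_metadata(obs)
  expect_equal(out$year_end, c(2014, 2010))
  expect_equal(out$imputed_end_year, c(TRUE, FALSE))
  # nothing missing -> unchanged
  clean <- base_obs(1)
  expect_equal(impute_metadata(clean)$year_end, 2010)
  # upper age missing -> open-ended with flag
  ua <- base_obs(1, age_upper = NA_real_)
  out2 <- impute_metadata(ua)
  expect_true(is.infinite(out2$age_upper))
  expect_true(out2$imputed_upper_age)
  # both end year and publication year missing is unresolvable
  bad <- base_obs(1, year_end = NA_real_, publication_year = NA_real_)
  expect_error(impute_metadata(bad), "publication year")
})

test_that("optimal-set selection applies the four ordered rules", {
  # severity: all > severe_only
  o <- base_obs(2, severity = c("severe_only", "all"))
  expect_equal(select_optimal_set(o)$severity, "all")
  # type: physical_only preferred over sexual_only when combined absent
  o <- base_obs(2, violence_type = c("physical_only", "sexual_only"))
  expect_equal(select_optimal_set(o)$violence_type, "physical_only")
  # population order, then partner order
  o <- base_obs(3, population = c("currently_partnered", "all_women",
                                  "ever_partnered"))
  expect_equal(select_optimal_set(o)$population, "ever_partnered")
  o <- base_obs(2, partner_ref = c("current_or_most_recent", "any_partner"))
  expect_equal(select_optimal_set(o)$partner_ref, "any_partner")
  # single observation is kept as itself
  one <- base_obs(1, severity = "severe_only")
  kept <- select_optimal_set(one)
  expect_equal(kept$obs_id, "O1")
  expect_false(kept$in_optimal_set)
  # gold standard flagged
  expect_true(select_optimal_set(base_obs(1))$in_optimal_set)
  expect_error(select_optimal_set(base_obs(1)[0, ]), "empty")
})

test_that("adjustment indicators are all-zero iff fully at reference", {
  prep <- tiny_prepared()
  C <- as.matrix(prep[paste0("adj_", ipvmeta:::.covariates)])
  ref <- prep$violence_type == "physical_and_or_sexual" &
    prep$severity == "all" & prep$population == "ever_partnered" &
    prep$partner_ref == "any_partner" &
    prep$geo %in% c("national", "mixed_subnational")
  expect_equal(rowSums(C) == 0, ref)
})

test_that("dataset split keeps broadest bands vs granular strata", {
  # study reporting 15-49 plus seven 5-year bands
  o <- base_obs(8, age_lower = c(15, seq(15, 45, 5)),
                age_upper = c(49, seq(19, 49, 5)), denominator = 300)
  ds <- build_datasets(o)
  expect_equal(nrow(ds$adjustment), 1)
  expect_equal(ds$adjustment$age_upper, 49)
  expect_equal(nrow(ds$modeling), 7)
  expect_true(all(ds$modeling$age_upper - ds$modeling$age_lower == 4))
  # national + urban + rural: modelling keeps national only
  o2 <- base_obs(3, geo = c("national", "urban", "rural"),
                 denominator = 300)
  ds2 <- build_datasets(o2)
  expect_equal(ds2$modeling$geo, "national")
  expect_equal(sort(ds2$adjustment$geo), c("national", "rural", "urban"))
  # a lone urban stratum is kept
  o3 <- base_obs(1, geo = "urban", denominator = 300)
  expect_equal(build_datasets(o3)$modeling$geo, "urban")
})

test_that("modelling age strata are disjoint within studies", {
  mod <- tiny_datasets()$modeling
  for (key in unique(paste(mod$study_id, mod$outcome, mod$geo))) {
    s <- mod[paste(mod$study_id, mod$outcome, mod$geo) == key, ]
    cells <- unlist(lapply(seq_len(nrow(s)), function(i)
      ipvmeta:::age_band_indices(s$age_lower[i], s$age_upper[i])))
    expect_equal(anyDuplicated(cells), 0)
  }
})

test_that("prepared counts reproduce prevalence within rounding", {
  prep <- tiny_prepared()
  expect_true(all(abs(prep$y / prep$n_eff - prep$prevalence) <=
                    1 / (2 * prep$n_eff) + 1e-9))
  expect_true(all(prep$y <= round(prep$n_eff)))
})
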