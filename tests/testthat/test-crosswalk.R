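# Exact matching, paired odds ratios, meta-analytic pooling, geographic
# strata model, and adjustment-vector sampling.

adj_obs <- function(n, ...) {
  out <- data.frame(
    obs_id = paste0("A", seq_len(n)), study_id = "S1", country_code = "C1",
    year_start = 2010, year_end = 2010, outcome = "lifetime",
    violence_type = "physical_and_or_sexual", severity = "all",
    population = "ever_partnered", partner_ref = "any_partner",
    geo = "national", age_lower = 15, age_upper = 49, prevalence = 0.25,
    denominator = 1000, total_n = NA_real_, se = NA_real_,
    ci_lower = NA_real_, ci_upper = NA_real_, publication_year = 2012,
    age_open = FALSE, n_eff = 400, y = 100, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) out[[nm]] <- mods[[nm]]
  adjustment_indicators(out)
}

test_that("exact matching pairs within surveys on the right keys", {
  d <- adj_obs(2, violence_type = c("physical_only",
                                    "physical_and_or_sexual"),
               prevalence = c(0.20, 0.25))
  m <- exact_match(d, "physical_only", "lifetime")
  expect_equal(nrow(m), 1)
  expect_equal(m$p1, 0.20)
  expect_equal(m$p0, 0.25)
  # only one level present: no match
  single <- adj_obs(1, violence_type = "physical_only")
  expect_equal(nrow(exact_match(single, "physical_only", "lifetime")), 0)
  # differing age bands do not match
  d2 <- adj_obs(2, violence_type = c("physical_only",
                                     "physical_and_or_sexual"),
                age_upper = c(49, 54))
  expect_equal(nrow(exact_match(d2, "physical_only", "lifetime")), 0)
})

test_that("among candidate references the one closest to the optimal set wins", {
  d <- adj_obs(3, violence_type = c("physical_only",
                                    "physical_and_or_sexual",
                                    "physical_and_or_sexual"),
               partner_ref = "current_or_most_recent",
               prevalence = c(0.20, 0.25, 0.28))
  # make the third row's partner reference the gold-standard level, and
  # the exposed row share the non-reference partner level with row 2
  d$partner_ref[3] <- "any_partner"
  m <- exact_match(d, "physical_only", "lifetime")
  # row 3 differs from the exposed row on partner_ref (a matching key for
  # physical_only), so only row 2 is an eligible reference
  expect_equal(m$reference_obs, "A2")
  # when both candidates are eligible, prefer the more reference-like pair
  d2 <- adj_obs(4, severity = c("severe_only", "severe_only",
                                "severe_only", "all"),
                population = c("all_women", "all_women", "ever_partnered",
                               "ever_partnered"),
                prevalence = c(0.10, 0.15, 0.17, 0.30))
  # exposed candidates: rows 1-3 (severe); references for 'severe': row 4
  # matched on population etc.; only row 3 shares population with row 4
  m2 <- exact_match(d2, "severe", "lifetime")
  expect_equal(nrow(m2), 1)
  expect_equal(m2$exposed_obs, "A3")
  expect_equal(m2$reference_obs, "A4")
})

test_that("paired odds ratios match 2x2 arithmetic", {
  # equal prevalences: OR = 1
  expect_equal(pair_odds_ratio(0.2, 100, 0.2, 100)[["log_or"]], 0)
  # worked 2x2: p1=0.20 (N=100), p0=0.25 (N=100)
  out <- pair_odds_ratio(0.20, 100, 0.25, 100)
  expect_equal(exp(out[["log_or"]]), (20 / 80) / (25 / 75))
  expect_equal(out[["se"]], sqrt(1 / 20 + 1 / 80 + 1 / 25 + 1 / 75))
  # zero cell engages the continuity correction and stays finite
  expect_message(out0 <- pair_odds_ratio(0, 50, 0.3, 50), "continuity")
  expect_true(is.finite(out0[["log_or"]]))
  expect_error(pair_odds_ratio(0.2, NA, 0.3, 100), "sample sizes")
})

test_that("meta-analysis pools by DerSimonian-Laird with the n>3 rule", {
  # degenerate k=1: pooled = the single pair
  one <- data.frame(log_or = -0.3, se = 0.1, super_region_id = "Z1")
  m1 <- meta_analyze(one)
  ov <- m1[m1$stratum == "overall", ]
  expect_equal(ov$log_or, -0.3)
  expect_equal(ov$se, 0.1)
  # two identical estimates, zero heterogeneity: inverse-variance SE/sqrt(2)
  two <- data.frame(log_or = c(-0.3, -0.3), se = 0.2,
                    super_region_id = "Z1")
  m2 <- meta_analyze(two)
  ov2 <- m2[m2$stratum == "overall", ]
  expect_equal(ov2$log_or, -0.3)
  expect_equal(ov2$se, 0.2 / sqrt(2), tolerance = 1e-9)
  # a super-region with exactly 3 pairs falls back to the overall factor
  pr <- data.frame(log_or = rnorm(8, -0.2, 0.01), se = 0.1,
                   super_region_id = c(rep("Z1", 3), rep("Z2", 5)))
  m3 <- meta_analyze(pr)
  expect_equal(m3$used_level[m3$stratum == "Z1"], "overall")
  expect_equal(m3$used_level[m3$stratum == "Z2"], "super_region")
  # with no heterogeneity the pooled value sits inside the stratum hull
  expect_true(ov2$log_or >= min(two$log_or) - 1e-9 &&
                ov2$log_or <= max(two$log_or) + 1e-9)
  three <- data.frame(log_or = c(-0.5, -0.2, -0.1), se = 0.15,
                      super_region_id = "Z1")
  ovh <- meta_analyze(three)
  ovh <- ovh[ovh$stratum == "overall", ]
  expect_true(ovh$log_or >= -0.5 - 1e-9 && ovh$log_or <= -0.1 + 1e-9)
})

test_that("matched-pair ORs recover injected effects on synthetic surveys", {
  # large-N generation: empirical matched OR near the injected value
  db <- make_fixture("paperlike", seed = 7)
  prep <- prepare_observations(db$observations, db$population2010,
                               db$hierarchy)
  ds <- build_datasets(prep)
  pairs <- exact_match(ds$adjustment, "physical_only", "lifetime")
  pairs$super_region_id <- ipvmeta:::hierarchy_lookup(
    db$hierarchy, pairs$country_code)$super_region_id
  m <- meta_analyze(pairs)
  ov <- m[m$stratum == "overall", ]
  expect_gt(ov$n_matches, 10)
  truth <- db$truth$beta$lifetime[["physical_only"]]
  expect_true(ov$ci_lb <= truth && truth <= ov$ci_ub)
  expect_equal(ov$log_or, truth, tolerance = 0.15)
})

test_that("every exposed observation appears in at most one matched set", {
  db <- make_fixture("paperlike", seed = 8)
  prep <- prepare_observations(db$observations, db$population2010,
                               db$hierarchy)
  ds <- build_datasets(prep)
  for (cov in c("physical_only", "current_recent", "currently_partnered")) {
    m <- exact_match(ds$adjustment, cov, "lifetime")
    expect_equal(anyDuplicated(m$exposed_obs), 0)
    expect_equal(anyDuplicated(m$survey_id), 0)
  }
})

test_that("geographic strata factors recover nulls and injected effects", {
  # surveys where urban = rural = national -> log OR ~ 0
  set.seed(1)
  mk_geo <- function(or_urban, or_rural, n_surv = 12) {
    rows <- list()
    hier <- data.frame(country_code = sprintf("C%d", 1:n_surv),
                       region_id = rep(c("R1", "R2"), length.out = n_surv),
                       super_region_id = rep(c("Z1", "Z2"),
                                             length.out = n_surv))
    for (s in seq_len(n_surv)) {
      p0 <- plogis(rnorm(1, qlogis(0.25), 0.3))
      for (g in c("national", "urban", "rural")) {
        or <- switch(g, national = 1, urban = or_urban, rural = or_rural)
        p <- plogis(qlogis(p0) + log(or))
        n <- 1500
        y <- rbinom(1, n, p)
        rows[[length(rows) + 1]] <- data.frame(
          obs_id = paste0(s, g), study_id = paste0("S", s),
          country_code = sprintf("C%d", s), outcome = "lifetime",
          geo = g, n_eff = n, y = y, prevalence = y / n,
          stringsAsFactors = FALSE)
      }
    }
    list(d = do.call(rbind, rows), h = geo_hierarchy(hier))
  }
  null <- mk_geo(1, 1)
  f0 <- fit_geo_strata_factors(null$d, null$h, "lifetime")
  expect_equal(f0$log_or[f0$stratum == "overall" & f0$covariate == "urban"],
               0, tolerance = 0.1)
  inj <- mk_geo(1, 1.15)
  f1 <- fit_geo_strata_factors(inj$d, inj$h, "lifetime")
  rural <- f1[f1$stratum == "overall" & f1$covariate == "rural", ]
  expect_equal(rural$log_or, log(1.15), tolerance = 2.5 * rural$se)
  # survey missing a stratum is excluded entirely
  part <- null$d[!(null$d$study_id == "S1" & null$d$geo == "urban"), ]
  f2 <- fit_geo_strata_factors(part, null$h, "lifetime")
  expect_equal(unique(f2$n_matches[f2$stratum == "overall"]), 11)
})

test_that("adjustment vectors honor LHS stratification and truncation", {
  fac <- data.frame(covariate = c("current_recent", "severe"),
                    outcome = "lifetime", stratum = "overall",
                    log_or = c(-0.17, -0.9), se = c(0.05, 0.2),
                    n_matches = 10L, used_level = "overall",
                    bound = c(FALSE, TRUE), stringsAsFactors = FALSE)
  dr <- sample_adjustment_vectors(fac, D = 10, seed = 2)
  vals <- sapply(dr$draws, function(t) t$log_or)
  # unbounded factor: LHS empirical mean within 2 se/sqrt(D)
  expect_equal(mean(vals[1, ]), -0.17,
               tolerance = 2 * 0.05 / sqrt(10))
  # bound factor: every draw at or below the null
  expect_true(all(vals[2, ] <= 0))
  # zero SE: degenerate at the point estimate
  fac0 <- fac; fac0$se <- 0
  dr0 <- sample_adjustment_vectors(fac0, D = 5, seed = 3)
  expect_true(all(sapply(dr0$draws, function(t)
    identical(t$log_or, fac0$log_or))))
  expect_error(sample_adjustment_vectors(fac, D = 0), "at least 1")
  # reproducible under seed
  dr2 <- sample_adjustment_vectors(fac, D = 10, seed = 2)
  expect_identical(dr$draws, dr2$draws)
})

test_that("offsets resolve through the super-region rule", {
  h <- geo_hierarchy(data.frame(country_code = c("C1", "C2"),
                                region_id = c("R1", "R2"),
                                super_region_id = c("Z1", "Z2")))
  fac <- data.frame(covariate = "physical_only", outcome = "lifetime",
                    stratum = c("overall", "Z1", "Z2"),
                    log_or = c(-0.15, -0.25, -0.05), se = 0.05,
                    n_matches = c(9L, 5L, 2L),
                    used_level = c("overall", "super_region", "overall"),
                    bound = TRUE, stringsAsFactors = FALSE)
  obs <- adj_obs(2, violence_type = "physical_only",
                 country_code = c("C1", "C2"))
  X <- resolve_offsets(obs, fac, h)
  expect_equal(X, c(-0.25, -0.15))   # Z1 specific; Z2 falls to overall
  # reference-level observations carry zero offset
  X0 <- resolve_offsets(adj_obs(1), fac, h)
  expect_equal(X0, 0)
})
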