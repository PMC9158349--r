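# Desk-scale pipeline shared by the acceptance checks: the 7-super-region,
# 21-region, 40-country synthetic database, its crosswalk factors, and the
# reduced-configuration model fits.

desk_db <- function() cached("desk_db", make_fixture("desk", seed = 42))

desk_pipeline <- function() cached("desk_pipe", {
  db <- desk_db()
  prep <- prepare_observations(db$observations, db$population2010,
                               db$hierarchy)
  ds <- build_datasets(prep)
  fac <- suppressWarnings(crosswalk_factors(ds$adjustment, db$hierarchy))
  mod <- suppressMessages(filter_adjustable(ds$modeling, fac,
                                            db$hierarchy))
  list(db = db, prep = prep, datasets = ds, factors = fac, modeling = mod)
})

desk_fit <- function(outcome = "lifetime") {
  cached(paste0("desk_fit_", outcome), {
    pipe <- desk_pipeline()
    fit_ipv_model(pipe$modeling, pipe$db$hierarchy,
                  pipe$db$population2010, outcome,
                  adjustment = pipe$factors,
                  cfg = mcmc_config(seed = 7), age_knots = 25)
  })
}

# countries to which the joint outcome constraints apply: those with data
# on only one outcome (falling back to the two least-studied countries
# when every country has both)
constraint_countries <- function(modeling) {
  lc <- unique(modeling$country_code[modeling$outcome == "lifetime"])
  pc <- unique(modeling$country_code[modeling$outcome == "past_year"])
  only <- union(setdiff(lc, pc), setdiff(pc, lc))
  if (length(only)) return(only)
  utils::head(names(sort(table(modeling$country_code))), 2)
}
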