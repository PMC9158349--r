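# Shared fixtures, cached across test files (everything is generated in
# code; nothing is read from disk).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_db <- function() cached("tiny_db", make_fixture("tiny", seed = 42))

tiny_prepared <- function() cached("tiny_prep", {
  db <- tiny_db()
  prepare_observations(db$observations, db$population2010, db$hierarchy)
})

tiny_datasets <- function() cached("tiny_ds", build_datasets(tiny_prepared()))

tiny_factors <- function() cached("tiny_fac", suppressWarnings(
  crosswalk_factors(tiny_datasets()$adjustment, tiny_db()$hierarchy)))

tiny_modeling <- function() cached("tiny_mod", suppressMessages(
  filter_adjustable(tiny_datasets()$modeling, tiny_factors(),
                    tiny_db()$hierarchy)))

# short-chain configuration for unit-test fits
tiny_cfg <- function(seed = 5)
  mcmc_config(chains = 2, iterations = 800, warmup = 200, adaptation = 200,
              thin = 2, seed = seed)

tiny_fit <- function(outcome = "lifetime") {
  cached(paste0("tiny_fit_", outcome), {
    db <- tiny_db()
    fit_ipv_model(tiny_modeling(), db$hierarchy, db$population2010,
                  outcome, adjustment = tiny_factors(), cfg = tiny_cfg(),
                  age_knots = 25)
  })
}

# Deterministic fit-shaped object with hand-chosen posterior "draws" for
# exercising prediction/aggregation arithmetic without MCMC.
fake_fit <- function(n_draws = 4, u_g = 0, u_z = c(0, 0), u_r = c(0, 0),
                     u_c = c(0, 0), eta_g = NULL, phi_g = NULL,
                     sigma_c = 0.3, age_knots = 30) {
  Ab <- build_age_spline_basis(age_knots)
  Tb <- build_time_spline_basis(2000:2018, 2011)
  K <- Ab$K; Kt <- Tb$K
  nz <- length(u_z); nr <- length(u_r); nc <- length(u_c)
  eta_g <- eta_g %||% rep(0, K)
  phi_g <- phi_g %||% rep(0, Kt)
  rep_mat <- function(v) matrix(rep(v, each = n_draws), n_draws)
  rep_arr <- function(n2, k) array(0, c(n_draws, n2, k))
  countries <- sprintf("C%02d", seq_len(nc))
  spec <- list(countries = countries,
               regions = sprintf("R%02d", seq_len(nr)),
               supers = sprintf("SR%d", seq_len(nz)),
               country_region = rep_len(seq_len(nr), nc),
               country_super = rep_len(seq_len(nz), nc),
               age_basis = Ab, time_basis = Tb, years = 2000:2018)
  draws <- list(u_g = rep(u_g, n_draws), u_z = rep_mat(u_z),
                u_r = rep_mat(u_r), u_c = rep_mat(u_c),
                eta_g = rep_mat(eta_g), phi_g = rep_mat(phi_g),
                eta_z = rep_arr(nz, K), eta_r = rep_arr(nr, K),
                eta_c = rep_arr(nc, K), phi_z = rep_arr(nz, Kt),
                phi_r = rep_arr(nr, Kt), phi_c = rep_arr(nc, Kt),
                sigma_c = rep(sigma_c, n_draws),
                ups_c = rep_mat(rep(0.1, K)),
                om_c = rep_mat(rep(0.1, Kt)))
  structure(list(draws = draws, spec = spec, n_draws = n_draws,
                 outcome = "lifetime"),
            class = "ipv_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent natural cubic spline construction (truncated power basis,
# Hastie-Tibshirani-Friedman form) used as an oracle for the ns-based
# basis: returns the non-constant basis columns for knots xi (boundary
# knots included in xi).
natural_spline_oracle <- function(x, xi) {
  K <- length(xi)
  d <- function(k) {
    (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
  }
  cols <- cbind(x, sapply(seq_len(K - 2), function(k) d(k) - d(K - 1)))
  colnames(cols) <- NULL
  cols
}

# Population table covering the full age grid for a set of keys.
toy_population <- function(keys, weights = NULL, year = 2010, esp = NULL) {
  do.call(rbind, lapply(keys, function(k) {
    w <- weights %||% rep(100, 11)
    out <- data.frame(region_or_country = k, age = age_grid(), weight = w,
                      reference_year = year, stringsAsFactors = FALSE)
    if (!is.null(esp)) out$ever_sex_proportion <- esp
    out
  }))
}
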