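# Domain types and CSV readers/writers: survey observations, the GBD-style
# geographic hierarchy, and population weight tables.

.outcomes <- c("lifetime", "past_year")
.violence_types <- c("physical_and_or_sexual", "physical_only", "sexual_only")
.severities <- c("all", "severe_only")
.populations <- c("ever_partnered", "all_women", "currently_partnered")
.partner_refs <- c("any_partner", "current_or_most_recent")
.geos <- c("national", "urban", "rural", "mixed_subnational")

# Covariates requiring crosswalk adjustment (geographic strata split into the
# two non-reference levels). Order matters: it is the indicator-vector order.
.covariates <- c("severe", "physical_only", "sexual_only", "all_women",
                 "currently_partnered", "current_recent", "urban", "rural")
# Factors structurally bound at the null (odds ratio <= 1): measuring a
# subset of violence, or a subset of women never exposed, cannot raise odds.
.bound_covariates <- c("severe", "physical_only", "sexual_only", "all_women")

# Open-ended upper age sentinel used at the file boundary.
.open_age_sentinel <- 999

.obs_columns <- c("obs_id", "study_id", "country_code", "year_start",
                  "year_end", "outcome", "violence_type", "severity",
                  "population", "partner_ref", "geo", "age_lower",
                  "age_upper", "prevalence", "denominator", "total_n",
                  "se", "ci_lower", "ci_upper", "publication_year")
.obs_required <- c("obs_id", "study_id", "country_code", "outcome",
                   "violence_type", "severity", "population", "partner_ref",
                   "geo", "age_lower", "prevalence")

#' Construct and validate a geographic hierarchy
#'
#' The pooling tree of the hierarchical model: each country belongs to
#' exactly one region and each region to exactly one super-region (the GBD
#' grouping uses 21 regions in 7 super-regions; any consistent tree is
#' accepted).
#'
#' @param df Data frame with columns \code{country_code}, \code{region_id},
#'   \code{super_region_id}.
#' @return The validated data frame with class \code{geo_hierarchy}.
#' @export
geo_hierarchy <- function(df) {
  need <- c("country_code", "region_id", "super_region_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hierarchy is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df[] <- lapply(df, as.character)
  dup <- unique(df$country_code[duplicated(df$country_code)])
  if (length(dup)) {
    # duplicated identical rows are tolerated; conflicting ones are not
    u <- unique(df)
    if (anyDuplicated(u$country_code))
      stop("country mapped to more than one region: ",
           paste(unique(u$country_code[duplicated(u$country_code)]),
                 collapse = ", "))
    df <- u
  }
  r2z <- unique(df[c("region_id", "super_region_id")])
  if (anyDuplicated(r2z$region_id))
    stop("region mapped to more than one super-region: ",
         paste(unique(r2z$region_id[duplicated(r2z$region_id)]),
               collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("geo_hierarchy", "data.frame")
  df
}

#' Read a geographic hierarchy from CSV
#'
#' @param path CSV file with columns country_code, region_id,
#'   super_region_id.
#' @return A \code{geo_hierarchy}.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  geo_hierarchy(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Resolve region/super-region for a vector of country codes.
hierarchy_lookup <- function(hierarchy, country_code) {
  i <- match(country_code, hierarchy$country_code)
  if (anyNA(i))
    stop("country code(s) not in hierarchy: ",
         paste(unique(country_code[is.na(i)]), collapse = ", "))
  hierarchy[i, , drop = FALSE]
}

#' Read survey observations from CSV
#'
#' One row per age-specific prevalence observation. A column mapping adapts
#' external schemas: a named character vector (or JSON file of one object)
#' whose names are the internal column names and whose values are the
#' external ones. Rows violating invariants are collected and reported
#' together in a single error (never silently dropped). A blank or
#' sentinel (999) upper age is read as an open-ended band and stored as
#' \code{Inf} with \code{age_open = TRUE}.
#'
#' @param path CSV file.
#' @param mapping Optional column mapping (named character vector or path to
#'   a JSON file).
#' @return Data frame of validated observations.
#' @export
read_observations <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
      mapping <- unlist(jsonlite::read_json(mapping))
    hit <- match(names(raw), mapping)
    names(raw)[!is.na(hit)] <- names(mapping)[hit[!is.na(hit)]]
  }
  miss <- setdiff(.obs_required, names(raw))
  if (length(miss))
    stop("observations file is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in setdiff(.obs_columns, names(raw))) raw[[col]] <- NA
  obs <- raw[.obs_columns]
  num <- c("year_start", "year_end", "age_lower", "age_upper", "prevalence",
           "denominator", "total_n", "se", "ci_lower", "ci_upper",
           "publication_year")
  for (col in num) obs[[col]] <- suppressWarnings(as.numeric(obs[[col]]))
  # open-ended upper age: blank or sentinel -> Inf
  open <- is.na(obs$age_upper) | obs$age_upper >= .open_age_sentinel
  obs$age_upper[open] <- Inf
  obs$age_open <- open
  validate_observations(obs)
  rownames(obs) <- NULL
  obs
}

#' Validate survey observations
#'
#' Checks row-level invariants (prevalence in [0,1], age and year ordering,
#' categorical levels) and raises one error listing every offending
#' \code{obs_id}.
#'
#' @param obs Observation data frame.
#' @param hierarchy Optional \code{geo_hierarchy}; when given, country codes
#'   must resolve.
#' @return \code{obs}, invisibly, when valid.
#' @export
validate_observations <- function(obs, hierarchy = NULL) {
  bad <- character()
  note <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    if (any(cond))
      bad <<- c(bad, paste0(msg, ": ", paste(obs$obs_id[cond], collapse = ", ")))
  }
  note(obs$prevalence < 0 | obs$prevalence > 1, "prevalence outside [0,1]")
  note(is.na(obs$prevalence), "unparseable or missing prevalence")
  note(obs$age_lower > obs$age_upper, "age_lower > age_upper")
  note(!is.na(obs$year_start) & !is.na(obs$year_end) &
         obs$year_start > obs$year_end, "year_start > year_end")
  note(!obs$outcome %in% .outcomes, "unknown outcome")
  note(!obs$violence_type %in% .violence_types, "unknown violence_type")
  note(!obs$severity %in% .severities, "unknown severity")
  note(!obs$population %in% .populations, "unknown population")
  note(!obs$partner_ref %in% .partner_refs, "unknown partner_ref")
  note(!obs$geo %in% .geos, "unknown geo")
  if (!is.null(hierarchy))
    note(!obs$country_code %in% hierarchy$country_code,
         "country_code not in hierarchy")
  if (length(bad))
    stop("invalid observation row(s):\n  ", paste(bad, collapse = "\n  "))
  invisible(obs)
}

#' Write survey observations to CSV
#'
#' Inverse of \code{\link{read_observations}}: open-ended upper ages are
#' written back as the 999 sentinel.
#'
#' @param obs Observation data frame.
#' @param path Output CSV path.
#' @export
write_observations <- function(obs, path) {
  out <- obs[intersect(.obs_columns, names(obs))]
  out$age_upper[is.infinite(out$age_upper)] <- .open_age_sentinel
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a population weight table from CSV
#'
#' Female population counts by 5-year age band, keyed by country or region,
#' for a reference year. The 2010 table drives age-standardization and
#' denominator imputation; the 2018 table (with the proportion of women who
#' ever had sex) drives aggregation.
#'
#' @param path CSV with columns region_or_country, age, weight,
#'   reference_year and optionally ever_sex_proportion.
#' @return Validated data frame.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_or_country", "age", "weight", "reference_year")
  miss <- setdiff(need, names(pop))
  if (length(miss))
    stop("population file is missing column(s): ", paste(miss, collapse = ", "))
  if (any(pop$weight < 0, na.rm = TRUE)) stop("negative population weight")
  if ("ever_sex_proportion" %in% names(pop)) {
    esp <- pop$ever_sex_proportion
    if (any(esp < 0 | esp > 1, na.rm = TRUE))
      stop("ever_sex_proportion outside [0,1]")
  }
  pop
}

# Weights of one key (country or region) on the 11-cell age grid,
# in grid order; errors if any grid cell is absent.
population_grid_weights <- function(pop, key) {
  rows <- pop[pop$region_or_country == key, , drop = FALSE]
  if (!nrow(rows)) stop("no population weights for: ", key)
  i <- match(age_grid(), rows$age)
  if (anyNA(i))
    stop("population weights for ", key, " do not cover the age grid (need ",
         paste(age_grid()[is.na(i)], collapse = ", "), ")")
  rows[i, , drop = FALSE]
}

# Normalized population shares over a set of grid cells.
population_shares <- function(pop, key, cells) {
  w <- population_grid_weights(pop, key)$weight[cells]
  w / sum(w)
}
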