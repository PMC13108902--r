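#' @title Observation schema
#' @description Column names and types of the long-format survey observation
#'   table: one row per (country, admin-1 region, contraceptive method,
#'   survey) giving the observed public-sector supply share, the per-sector
#'   sample sizes behind it, and its design-based standard error.
#' @format character vector of required column names.
#' @export
OBS_COLUMNS <- c("country_id", "region_id", "method", "year", "y_public",
                 "n_public", "n_private", "se_prop", "survey_id")

#' Contraceptive methods modelled by default
#'
#' The five modern methods, in the fixed order used for every cross-method
#' covariance matrix.
#' @export
DEFAULT_METHODS <- c("female_sterilization", "implants", "injectables",
                     "iud", "oc_pills")

#' Build the country/region/method hierarchy from observations
#'
#' Derives the nesting used by the hierarchical priors. Region keys are
#' namespaced internally as `country_id:region_id` because admin-1 names
#' repeat across countries. Method order is fixed and shared by every
#' covariance matrix row/column.
#'
#' @param obs observation data frame.
#' @param methods ordered character vector of method labels (length >= 2;
#'   a cross-method covariance needs at least two methods).
#' @param allow_single_method permit M = 1 for degenerate single-series
#'   analyses with fixed covariances (default FALSE).
#' @return object of class `subshare_hierarchy`: list with `countries`,
#'   `regions_by_country` (named list of namespaced region keys), `regions`
#'   (flat vector), `region_country` (country index per region) and
#'   `methods`.
#' @export
build_hierarchy <- function(obs, methods = DEFAULT_METHODS,
                            allow_single_method = FALSE) {
  stopifnot(is.data.frame(obs), is.character(methods))
  if (length(methods) < 2L && !allow_single_method) {
    abort("build_hierarchy(): need at least 2 methods")
  }
  if (anyDuplicated(methods)) abort("build_hierarchy(): duplicated method labels")
  if (nrow(obs) > 0L) {
    unknown <- setdiff(unique(obs$method), methods)
    if (length(unknown)) {
      abort("build_hierarchy(): observation methods not in method list: %s",
            paste(unknown, collapse = ", "))
    }
  }
  countries <- sort(unique(obs$country_id))
  regions_by_country <- lapply(countries, function(cc) {
    sort(unique(region_key(cc, obs$region_id[obs$country_id == cc])))
  })
  names(regions_by_country) <- countries
  regions <- unlist(regions_by_country, use.names = FALSE)
  region_country <- rep(seq_along(countries), lengths(regions_by_country))
  names(region_country) <- regions
  structure(list(countries = countries,
                 regions_by_country = regions_by_country,
                 regions = regions,
                 region_country = region_country,
                 methods = methods),
            class = "subshare_hierarchy")
}

# internal: namespaced region key
region_key <- function(country_id, region_id) paste(country_id, region_id, sep = ":")

#' @export
print.subshare_hierarchy <- function(x, ...) {
  cat(sprintf("Hierarchy: %d countries, %d regions, %d methods\n",
              length(x$countries), length(x$regions), length(x$methods)))
  cat("methods:", paste(x$methods, collapse = ", "), "\n")
  invisible(x)
}

#' Read a survey observation table
#'
#' Parses a plain CSV (UTF-8, "." decimal) with exactly the columns of
#' [OBS_COLUMNS] (extra columns are ignored) and derives the hierarchy from
#' the distinct keys. Rows are returned in the stable order (country, region,
#' method, year, survey).
#'
#' @param path CSV file path.
#' @param methods ordered method labels used for the hierarchy.
#' @return list with `observations` (data frame) and `hierarchy`.
#' @export
read_observations <- function(path, methods = DEFAULT_METHODS) {
  if (!file.exists(path)) abort("read_observations(): no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBS_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort("read_observations(): missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  obs <- raw[, OBS_COLUMNS]
  if (nrow(obs) == 0L) {
    warning("read_observations(): no observation rows in file", call. = FALSE)
    return(list(observations = obs, hierarchy = build_hierarchy(obs, methods)))
  }
  obs <- validate_observations(obs)
  ord <- order(obs$country_id, obs$region_id, obs$method, obs$year, obs$survey_id)
  obs <- obs[ord, , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs, hierarchy = build_hierarchy(obs, methods))
}

#' Validate an observation table against the schema
#'
#' Checks types and value ranges row by row; numeric parse failures and
#' range violations are reported with their row numbers.
#'
#' @param obs data frame with the [OBS_COLUMNS] columns.
#' @return the validated data frame (numeric columns coerced).
#' @export
validate_observations <- function(obs) {
  stopifnot(is.data.frame(obs))
  for (col in c("year", "y_public", "n_public", "n_private", "se_prop")) {
    v <- obs[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort("validate_observations(): non-numeric %s at row(s) %s",
              col, paste(utils::head(bad, 5L), collapse = ", "))
      }
      obs[[col]] <- vn
    }
  }
  bad_y <- which(!is.finite(obs$y_public) | obs$y_public < 0 | obs$y_public > 1)
  if (length(bad_y)) {
    abort("validate_observations(): y_public outside [0, 1] at row(s) %s",
          paste(utils::head(bad_y, 5L), collapse = ", "))
  }
  bad_n <- which(obs$n_public < 0 | obs$n_private < 0 |
                   (obs$n_public + obs$n_private) < 1)
  if (length(bad_n)) {
    abort("validate_observations(): sector sample sizes invalid at row(s) %s",
          paste(utils::head(bad_n, 5L), collapse = ", "))
  }
  obs
}

#' Run configuration
#'
#' Collects every tunable of a model run. MCMC defaults follow the fitting
#' protocol used throughout: 80,000 iterations, burn-in 10,000, thinning 35,
#' hence 2,000 retained samples per chain.
#'
#' @param year_start,year_end inclusive estimation/projection grid.
#' @param spline_degree B-spline degree (default cubic).
#' @param knot_spacing_years interior knot spacing in years.
#' @param n_iter,burn_in,thin,n_chains,seed MCMC settings.
#' @param variant one of `"multivariate_intercept"` (the headline model),
#'   `"multivariate_delta"`, `"zero_covariance"`, `"shrinkage"`,
#'   `"fully_multivariate"`.
#' @param min_sector_n minimum per-sector sample size retained.
#' @param test_cutoff_year validation split year (observations strictly
#'   after it are held out).
#' @return object of class `subshare_config` (a list).
#' @export
run_config <- function(year_start = 1990L, year_end = 2030L,
                       spline_degree = 3L, knot_spacing_years = 5L,
                       n_iter = 80000L, burn_in = 10000L, thin = 35L,
                       n_chains = 4L, seed = 1L,
                       variant = "multivariate_intercept",
                       min_sector_n = 10L, test_cutoff_year = 2015L) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(is_count(year_start), is_count(year_end), year_end > year_start,
            is_count(spline_degree, 0L), is_count(knot_spacing_years, 1L),
            is_count(n_chains, 1L), is_count(min_sector_n, 0L),
            is_count(test_cutoff_year))
  retained_samples(n_iter, burn_in, thin)  # validates the MCMC triple
  structure(list(year_start = as.integer(year_start),
                 year_end = as.integer(year_end),
                 spline_degree = as.integer(spline_degree),
                 knot_spacing_years = as.integer(knot_spacing_years),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), variant = variant,
                 min_sector_n = as.integer(min_sector_n),
                 test_cutoff_year = as.integer(test_cutoff_year)),
            class = "subshare_config")
}

#' @export
print.subshare_config <- function(x, ...) {
  cat(sprintf("subshare run config: variant=%s, grid %d-%d, degree %d, spacing %dy\n",
              x$variant, x$year_start, x$year_end, x$spline_degree,
              x$knot_spacing_years))
  cat(sprintf("  MCMC: %d iter, burn-in %d, thin %d, %d chain(s), seed %d -> %d retained/chain\n",
              x$n_iter, x$burn_in, x$thin, x$n_chains, x$seed,
              retained_samples(x$n_iter, x$burn_in, x$thin)))
  invisible(x)
}

#' Read/write a run configuration as JSON
#'
#' Round-trips bit-exactly: every field is scalar.
#' @param config a `subshare_config`.
#' @param path JSON file path.
#' @return `read_config()` returns a `subshare_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "subshare_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Write trajectory summaries to CSV
#'
#' One row per (region, method, year) with posterior mean, median and the
#' central 95% interval for the public share, plus the private-sector
#' complement of each. Public and private point estimates sum to 1 on every
#' row; the private interval is the mirror image of the public one.
#'
#' @param estimates data frame as produced by [summarize_trajectories()]
#'   (columns `region`, `method`, `year`, `mean`, `median`, `q2.5`, `q97.5`).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  stopifnot(is.data.frame(estimates))
  need <- c("region", "method", "year", "mean", "median", "q2.5", "q97.5")
  missing_cols <- setdiff(need, names(estimates))
  if (length(missing_cols)) {
    abort("write_estimates(): missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(estimates) > 0L) {
    if (any(estimates$q2.5 > estimates$q97.5)) {
      abort("write_estimates(): q2.5 > q97.5 in input")
    }
    if (any(estimates$mean <= 0 | estimates$mean >= 1)) {
      abort("write_estimates(): public mean outside (0, 1)")
    }
  }
  out <- estimates[, need]
  names(out) <- c("region", "method", "year", "public_mean", "public_median",
                  "public_q2.5", "public_q97.5")
  out$private_mean <- 1 - out$public_mean
  out$private_median <- 1 - out$public_median
  out$private_q2.5 <- 1 - out$public_q97.5
  out$private_q97.5 <- 1 - out$public_q2.5
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) abort("read_estimates(): no such file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
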