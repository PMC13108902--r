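#' Generate a country/region hierarchy with deterministic IDs
#'
#' Countries are labelled `c01, c02, ...` and regions `c01:r01, ...`.
#' When `regions_per_country` is a length-2 range, per-country region
#' counts are drawn uniformly from it (seed the session RNG for
#' reproducibility).
#'
#' @param n_countries number of countries.
#' @param regions_per_country a single count or an inclusive range
#'   `c(lo, hi)`.
#' @param methods ordered method labels.
#' @return a `subshare_hierarchy`.
#' @export
generate_hierarchy <- function(n_countries, regions_per_country = c(3L, 6L),
                               methods = DEFAULT_METHODS) {
  stopifnot(is_count(n_countries, 1L))
  counts <- if (length(regions_per_country) == 1L ||
                regions_per_country[1L] == regions_per_country[2L]) {
    rep(as.integer(regions_per_country[1L]), n_countries)
  } else {
    sample(seq.int(regions_per_country[1L], regions_per_country[2L]),
           n_countries, replace = TRUE)
  }
  countries <- sprintf("c%02d", seq_len(n_countries))
  regions_by_country <- lapply(seq_len(n_countries), function(i) {
    region_key(countries[i], sprintf("r%02d", seq_len(counts[i])))
  })
  names(regions_by_country) <- countries
  regions <- unlist(regions_by_country, use.names = FALSE)
  region_country <- rep(seq_len(n_countries), counts)
  names(region_country) <- regions
  structure(list(countries = countries,
                 regions_by_country = regions_by_country,
                 regions = regions, region_country = region_country,
                 methods = methods),
            class = "subshare_hierarchy")
}

#' Default generative truth configuration
#'
#' The conditions the generator emulates by default: a handful of countries
#' with 3-6 admin-1 regions each, the five modern methods, 3-6 surveys per
#' country at irregular 3-7 year gaps between 1990 and 2021, per-cell
#' sample sizes uniform on 10-300 women, and a design-effect multiplier of
#' 1.5 on the binomial standard error. Truth hyperparameters: global method
#' means scattered around logit(0.75) (public-sector dominance at roughly
#' the levels reported for these methods), exchangeable cross-method
#' correlation 0.7 in both intercept covariances (the subnational
#' correlation range reported is 0.6-0.8), and a random-walk increment
#' scale of 0.15 per knot interval.
#'
#' @param n_countries,regions_per_country,methods hierarchy settings.
#' @param n_surveys_range surveys per country (inclusive range).
#' @param gap_range_years between-survey gaps (inclusive range).
#' @param first_year_range window for a country's first survey.
#' @param last_survey_year latest possible survey year.
#' @param n_total_range per-cell total sample-size range.
#' @param design_effect multiplier on the binomial SE.
#' @param theta_all_mean,theta_all_sd global method-mean distribution
#'   (logit scale).
#' @param sd_theta,sd_alpha marginal sds of the intercept covariances.
#' @param rho_theta,rho_alpha exchangeable cross-method correlations.
#' @param sigma_delta true random-walk increment sd.
#' @return a list of class `subshare_sim_config`.
#' @export
sim_config <- function(n_countries = 4L, regions_per_country = c(3L, 6L),
                       methods = DEFAULT_METHODS,
                       n_surveys_range = c(3L, 6L),
                       gap_range_years = c(3L, 7L),
                       first_year_range = c(1990L, 1999L),
                       last_survey_year = 2021L,
                       n_total_range = c(10L, 300L),
                       design_effect = 1.5,
                       theta_all_mean = stats::qlogis(0.75),
                       theta_all_sd = 0.75,
                       sd_theta = 0.5, sd_alpha = 0.4,
                       rho_theta = 0.7, rho_alpha = 0.7,
                       sigma_delta = 0.15) {
  structure(as.list(environment()), class = "subshare_sim_config")
}

# internal: sample() without the scalar-expansion surprise
sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

# internal: exchangeable correlation covariance
exch_cov <- function(sd, rho, M) {
  S <- matrix(rho * sd^2, M, M)
  diag(S) <- sd^2
  S
}

# internal: draw survey years for one country
draw_survey_years <- function(cfg) {
  n <- sample1(seq.int(cfg$n_surveys_range[1L], cfg$n_surveys_range[2L]))
  y <- sample1(seq.int(cfg$first_year_range[1L], cfg$first_year_range[2L]))
  years <- y
  while (length(years) < n) {
    y <- y + sample1(seq.int(cfg$gap_range_years[1L], cfg$gap_range_years[2L]))
    if (y > cfg$last_survey_year) break
    years <- c(years, y)
  }
  years
}

#' Simulate a survey observation table from the generative model
#'
#' Forward-simulates the full model: true process parameters (hierarchical
#' intercepts with exchangeable cross-method covariances, random-walk
#' spline increments), region-specific anchored bases, the latent logit
#' surface, then binomial survey noise: at each (region, method, survey
#' year), `n_total` women are drawn and the design effect is applied as an
#' effective-sample-size reduction (`n_eff = n_total / deff^2`), so the
#' observed share is `Binomial(n_eff, phi) / n_eff` and the reported
#' standard error -- the binomial SE at `n_eff`, computed from the squeezed
#' share so it is always positive -- matches the sampling noise actually
#' simulated, as design-based survey SEs do.
#'
#' @param hierarchy a `subshare_hierarchy` (default generated from `config`).
#' @param config a `subshare_sim_config`.
#' @param run a `subshare_config` (year grid / spline settings).
#' @param seed integer RNG seed.
#' @param truth_params optional list overriding the drawn truth (any of
#'   `theta_all`, `theta_c`, `alpha`, `Sigma_theta`, `Sigma_alpha`,
#'   `sigma_delta`, `delta`).
#' @param survey_years optional named list (by country) of survey years.
#' @return list with `observations` (schema data frame), `truth` (list:
#'   `params`, `surface`, `survey_years`, `hierarchy`, plus per-row
#'   `phi_true`).
#' @export
simulate_dataset <- function(hierarchy = NULL, config = sim_config(),
                             run = run_config(), seed = 1L,
                             truth_params = list(), survey_years = NULL) {
  stopifnot(inherits(config, "subshare_sim_config"))
  set.seed(seed)
  if (is.null(hierarchy)) {
    hierarchy <- generate_hierarchy(config$n_countries,
                                    config$regions_per_country,
                                    config$methods)
  }
  M <- length(hierarchy$methods)
  C <- length(hierarchy$countries)
  P <- length(hierarchy$regions)

  if (is.null(survey_years)) {
    survey_years <- lapply(hierarchy$countries, function(cc) draw_survey_years(config))
    names(survey_years) <- hierarchy$countries
  }

  # --- truth parameters -------------------------------------------------
  tp <- truth_params
  Sigma_theta <- tp$Sigma_theta %||% exch_cov(config$sd_theta, config$rho_theta, M)
  Sigma_alpha <- tp$Sigma_alpha %||% exch_cov(config$sd_alpha, config$rho_alpha, M)
  sigma_delta <- tp$sigma_delta %||% config$sigma_delta
  theta_all <- tp$theta_all %||%
    stats::rnorm(M, config$theta_all_mean, config$theta_all_sd)
  ch_t <- chol(Sigma_theta)
  theta_c <- tp$theta_c %||%
    (matrix(theta_all, C, M, byrow = TRUE) +
       matrix(stats::rnorm(C * M), C, M) %*% ch_t)
  rownames(theta_c) <- hierarchy$countries
  ch_a <- chol(Sigma_alpha)
  alpha <- tp$alpha %||%
    (theta_c[hierarchy$region_country, , drop = FALSE] +
       matrix(stats::rnorm(P * M), P, M) %*% ch_a)
  rownames(alpha) <- hierarchy$regions
  colnames(alpha) <- hierarchy$methods

  # --- bases anchored at each region's last survey year ----------------
  t_last <- vapply(hierarchy$regions, function(rk) {
    cc <- hierarchy$countries[hierarchy$region_country[[rk]]]
    max(survey_years[[cc]])
  }, 0L)
  bases <- lapply(hierarchy$regions, function(rk) {
    spec <- build_basis_spec(rk, t_last[[rk]], run$year_start, run$year_end,
                             run$spline_degree, run$knot_spacing_years)
    list(spec = spec,
         basis = evaluate_basis(spec, seq.int(run$year_start, run$year_end)),
         accum = increment_accumulator(spec$K, spec$k_star))
  })
  names(bases) <- hierarchy$regions

  delta <- tp$delta %||% lapply(hierarchy$regions, function(rk) {
    K <- bases[[rk]]$spec$K
    matrix(stats::rnorm((K - 1L) * M, 0, sigma_delta), K - 1L, M,
           dimnames = list(NULL, hierarchy$methods))
  })
  names(delta) <- hierarchy$regions

  params <- list(theta_all = theta_all, theta_c = theta_c, alpha = alpha,
                 delta = delta, sigma_delta = sigma_delta,
                 Sigma_theta = Sigma_theta, Sigma_alpha = Sigma_alpha)
  surf <- latent_surface(params, bases, methods = hierarchy$methods)

  # --- survey sampling ---------------------------------------------------
  rows <- list()
  for (rk in hierarchy$regions) {
    cc <- hierarchy$countries[hierarchy$region_country[[rk]]]
    ids <- strsplit(rk, ":", fixed = TRUE)[[1L]]
    for (yr in survey_years[[cc]]) {
      ti <- match(yr, surf$years)
      for (m in seq_len(M)) {
        phi <- surf$surface[[rk]]$phi_public[ti, m]
        n_total <- sample1(seq.int(config$n_total_range[1L],
                                   config$n_total_range[2L]))
        # design effect as an effective-sample-size reduction, so the
        # reported SE is consistent with the noise actually simulated
        n_eff <- max(2L, as.integer(round(n_total / config$design_effect^2)))
        y_pub <- stats::rbinom(1L, n_eff, phi) / n_eff
        x_pub <- as.integer(round(y_pub * n_total))
        y_sq <- lemon_squeeze(y_pub, n_eff)
        se <- sqrt(y_sq * (1 - y_sq) / n_eff)
        rows[[length(rows) + 1L]] <- data.frame(
          country_id = ids[1L], region_id = ids[2L],
          method = hierarchy$methods[m], year = yr, y_public = y_pub,
          n_public = x_pub, n_private = n_total - x_pub, se_prop = se,
          survey_id = sprintf("%s_%d", ids[1L], yr), phi_true = phi)
      }
    }
  }
  obs <- do.call(rbind, rows)
  truth <- list(hierarchy = hierarchy, params = params, surface = surf,
                survey_years = survey_years,
                phi_true = obs$phi_true, seed = seed)
  obs$phi_true <- NULL
  list(observations = obs, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sparse-data scenario
#'
#' A simulation configuration plus post-hoc thinning that guarantees at
#' least one single-survey country and at least one region with zero
#' observations for at least one method, mimicking the sparsest countries
#' in real DHS collections (a country with a single survey; a method
#' observed in only one region of a country). Fitting on such data
#' exercises the hierarchical borrowing that fills empty region-method
#' series from their country means.
#'
#' @param hierarchy a `subshare_hierarchy`.
#' @param config a `subshare_sim_config`.
#' @param run a `subshare_config`.
#' @param seed RNG seed.
#' @return as [simulate_dataset()], with the sparsified observation table.
#' @export
scenario_sparse <- function(hierarchy = NULL, config = sim_config(),
                            run = run_config(), seed = 1L) {
  sim <- simulate_dataset(hierarchy, config, run, seed)
  obs <- sim$observations
  hier <- sim$truth$hierarchy
  # country 1: keep only its most recent survey (single-survey country)
  c1 <- hier$countries[1L]
  keep_year <- max(obs$year[obs$country_id == c1])
  drop <- obs$country_id == c1 & obs$year != keep_year
  # region 1: remove every observation of the first method (empty series)
  r1 <- hier$regions[1L]
  ids <- strsplit(r1, ":", fixed = TRUE)[[1L]]
  drop <- drop | (obs$country_id == ids[1L] & obs$region_id == ids[2L] &
                    obs$method == hier$methods[1L])
  sim$observations <- obs[!drop, , drop = FALSE]
  sim$sparse <- list(single_survey_country = c1,
                     empty_series = c(region = r1, method = hier$methods[1L]))
  sim
}

#' Write/read the simulation truth as JSON
#'
#' Persists the drawn truth parameters and survey design alongside the
#' observation table so recovery tests can reload them losslessly.
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param path JSON path.
#' @return `read_truth()` returns the truth list (matrices restored).
#' @export
write_truth <- function(truth, path) {
  out <- list(theta_all = truth$params$theta_all,
              theta_c = truth$params$theta_c,
              alpha = truth$params$alpha,
              delta = truth$params$delta,
              sigma_delta = truth$params$sigma_delta,
              Sigma_theta = truth$params$Sigma_theta,
              Sigma_alpha = truth$params$Sigma_alpha,
              survey_years = truth$survey_years,
              regions = truth$hierarchy$regions,
              countries = truth$hierarchy$countries,
              methods = truth$hierarchy$methods,
              seed = truth$seed)
  jsonlite::write_json(out, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("theta_c", "alpha", "Sigma_theta", "Sigma_alpha")) {
    x[[nm]] <- as.matrix(x[[nm]])
  }
  x$delta <- lapply(x$delta, as.matrix)
  x
}
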