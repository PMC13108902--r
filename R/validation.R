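#' Out-of-sample accuracy and calibration metrics
#'
#' The six-metric battery used to compare model variants on held-out
#' observations: mean absolute relative error (MARE, %), standardized
#' absolute prediction error (SAPE, logit scale), 80%/95% predictive
#' coverage (%), root mean square error (RMSE, %), the median width of the
#' 95% prediction interval (%), and the location (above/below) of the
#' observations missed by the 95% interval.
#'
#' @name validation_metrics
NULL

#' Mean absolute relative error
#'
#' `100 * mean(|y_pred - y_obs| / y_obs)` on the proportion scale, with
#' `y_pred` the posterior-predictive median public share.
#'
#' @param y_obs,y_pred proportion vectors of equal length; `y_obs > 0`
#'   (guaranteed after squeezing).
#' @return percentage.
#' @examples
#' mare(c(0.5, 0.8), c(0.45, 0.9))  # 11.25
#' @export
mare <- function(y_obs, y_pred) {
  check_pair(y_obs, y_pred)
  if (any(y_obs <= 0)) abort("mare(): y_obs must be positive (squeeze first)")
  100 * mean(abs(y_pred - y_obs) / y_obs)
}

#' Root mean square error
#'
#' `100 * sqrt(mean((y_pred - y_obs)^2))` on the proportion scale.
#' @inheritParams mare
#' @return percentage.
#' @export
rmse <- function(y_obs, y_pred) {
  check_pair(y_obs, y_pred)
  100 * sqrt(mean((y_pred - y_obs)^2))
}

check_pair <- function(a, b) {
  if (length(a) != length(b)) abort("metric inputs differ in length")
  if (length(a) < 1L) abort("metric inputs are empty")
  invisible(NULL)
}

#' Standardized absolute prediction error
#'
#' Mean over the test set of `|z_obs - median(draws)| / sd(draws)` on the
#' logit scale, with the predictive draws including observation noise.
#' Values above 1 indicate the data are more dispersed than the predictive
#' distributions. Observations with zero predictive spread are excluded
#' with a warning.
#'
#' @param z_obs logit-scale observations (length n).
#' @param pred_draws predictive draw matrix, draws x n (at least 20 draws).
#' @return scalar.
#' @export
sape <- function(z_obs, pred_draws) {
  pred_draws <- as.matrix(pred_draws)
  if (ncol(pred_draws) != length(z_obs)) abort("sape(): draws/observations mismatch")
  if (nrow(pred_draws) < 20L) abort("sape(): need at least 20 predictive draws")
  med <- apply(pred_draws, 2L, stats::median)
  sd_ <- apply(pred_draws, 2L, stats::sd)
  keep <- sd_ > 0
  if (!all(keep)) {
    warning(sprintf("sape(): excluded %d observation(s) with zero predictive sd",
                    sum(!keep)), call. = FALSE)
  }
  if (!any(keep)) return(NA_real_)
  mean(abs(z_obs[keep] - med[keep]) / sd_[keep])
}

#' Predictive interval coverage
#'
#' Percentage of observations inside the central predictive interval
#' (closed at the endpoints) at the given level.
#'
#' @inheritParams sape
#' @param level 0.80 or 0.95.
#' @return percentage.
#' @export
coverage <- function(z_obs, pred_draws, level = 0.95) {
  pred_draws <- as.matrix(pred_draws)
  if (ncol(pred_draws) != length(z_obs)) abort("coverage(): draws/observations mismatch")
  stopifnot(level > 0, level < 1)
  lo <- apply(pred_draws, 2L, stats::quantile, probs = (1 - level) / 2, names = FALSE)
  hi <- apply(pred_draws, 2L, stats::quantile, probs = 1 - (1 - level) / 2, names = FALSE)
  100 * mean(z_obs >= lo & z_obs <= hi)
}

#' 95% interval width and miss locations
#'
#' Median width of the 95% predictive interval on the proportion scale
#' (x100) and the percentages of observations strictly above / below the
#' interval.
#'
#' @param y_obs proportion-scale observations.
#' @param pred_draws predictive draws on the logit scale, draws x n.
#' @return list `median_width_pct`, `pct_above`, `pct_below`.
#' @export
pi_width_and_misses <- function(y_obs, pred_draws) {
  pred_draws <- as.matrix(pred_draws)
  if (ncol(pred_draws) != length(y_obs)) abort("pi_width_and_misses(): draws/observations mismatch")
  phi <- inv_logit(pred_draws)
  lo <- apply(phi, 2L, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(phi, 2L, stats::quantile, probs = 0.975, names = FALSE)
  list(median_width_pct = 100 * stats::median(hi - lo),
       pct_above = 100 * mean(y_obs > hi),
       pct_below = 100 * mean(y_obs < lo))
}

#' Run the out-of-sample validation protocol
#'
#' Splits the preprocessed observations at the cutoff year (strictly later
#' rows are held out), fits the selected variant on the training rows, forms
#' the posterior predictive for every held-out row (latent draw at its
#' region/method/year plus Normal noise at its own logit-scale standard
#' error), and computes the six metrics.
#'
#' @param obs raw observation table.
#' @param config a `subshare_config` (its `variant` selects the model and
#'   `test_cutoff_year` the split).
#' @param methods method labels.
#' @param quiet suppress sampler output.
#' @return list of class `subshare_validation`: the metrics (`mare_pct`,
#'   `sape`, `coverage80_pct`, `coverage95_pct`, `rmse_pct`,
#'   `median_pi95_width_pct`, `pct_above_pi95`, `pct_below_pi95`,
#'   `n_test`), plus the `fit`.
#' @export
run_validation <- function(obs, config = run_config(),
                           methods = DEFAULT_METHODS, quiet = TRUE) {
  logit_obs <- prepare_observations(obs, config$min_sector_n)
  sp <- split_train_test(logit_obs, config$test_cutoff_year)
  if (nrow(sp$test) == 0L) abort("run_validation(): empty test set (no rows after %d)",
                                 config$test_cutoff_year)
  if (nrow(sp$train) == 0L) abort("run_validation(): empty training set")
  # the hierarchy is defined by the training rows; held-out rows in regions
  # with no training data cannot be predicted and are set aside
  hierarchy <- build_hierarchy(sp$train, methods)
  train_keys <- unique(region_key(sp$train$country_id, sp$train$region_id))
  test_keys <- region_key(sp$test$country_id, sp$test$region_id)
  if (!all(test_keys %in% train_keys)) {
    warning(sprintf("run_validation(): dropped %d held-out row(s) in regions with no training data",
                    sum(!test_keys %in% train_keys)), call. = FALSE)
    sp$test <- sp$test[test_keys %in% train_keys, , drop = FALSE]
    if (nrow(sp$test) == 0L) abort("run_validation(): empty test set after dropping unfitted regions")
  }
  bases <- build_region_bases(sp$train, hierarchy, config)
  fit <- sample_posterior(sp$train, hierarchy, bases, config,
                          model_spec(config$variant), quiet = quiet)
  report <- validation_report(fit, sp$test)
  report$fit <- fit
  report
}

#' Compute the metric battery for a fitted model and held-out rows
#'
#' @param fit a `subshare_fit`.
#' @param test held-out preprocessed rows (with `z`, `se_z`, `y_squeezed`).
#' @return a `subshare_validation` list (without the fit).
#' @export
validation_report <- function(fit, test) {
  stopifnot(nrow(test) >= 1L)
  pred <- posterior_predictive(fit, test, include_noise = TRUE)
  y_pred <- apply(inv_logit(pred), 2L, stats::median)
  w <- pi_width_and_misses(test$y_squeezed, pred)
  structure(list(mare_pct = mare(test$y_squeezed, y_pred),
                 sape = sape(test$z, pred),
                 coverage80_pct = coverage(test$z, pred, 0.80),
                 coverage95_pct = coverage(test$z, pred, 0.95),
                 rmse_pct = rmse(test$y_squeezed, y_pred),
                 median_pi95_width_pct = w$median_width_pct,
                 pct_above_pi95 = w$pct_above,
                 pct_below_pi95 = w$pct_below,
                 n_test = nrow(test)),
            class = "subshare_validation")
}

#' @export
print.subshare_validation <- function(x, ...) {
  cat("Out-of-sample validation (n_test =", x$n_test, ")\n")
  fmt <- function(v) formatC(v, digits = 2, format = "f")
  cat("  MARE (%):              ", fmt(x$mare_pct), "\n")
  cat("  SAPE:                  ", fmt(x$sape), "\n")
  cat("  80% coverage (%):      ", fmt(x$coverage80_pct), "\n")
  cat("  95% coverage (%):      ", fmt(x$coverage95_pct), "\n")
  cat("  RMSE (%):              ", fmt(x$rmse_pct), "\n")
  cat("  median 95% PI width (%):", fmt(x$median_pi95_width_pct), "\n")
  cat("  above / below 95% PI (%):", fmt(x$pct_above_pi95), "/",
      fmt(x$pct_below_pi95), "\n")
  invisible(x)
}

#' Compare all model variants on one dataset
#'
#' Runs the validation protocol once per variant and assembles the metric
#' table (metrics as rows, variants as columns).
#'
#' @param obs raw observation table.
#' @param config base `subshare_config`; the variant field is overridden.
#' @param variants variants to compare (default all five).
#' @param methods method labels.
#' @param quiet suppress sampler output.
#' @return data frame, one row per metric, one column per variant.
#' @export
compare_variants <- function(obs, config = run_config(),
                             variants = MODEL_VARIANTS,
                             methods = DEFAULT_METHODS, quiet = TRUE) {
  metric_names <- c("mare_pct", "sape", "coverage80_pct", "coverage95_pct",
                    "rmse_pct", "median_pi95_width_pct", "pct_above_pi95",
                    "pct_below_pi95")
  cols <- lapply(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    rep_ <- run_validation(obs, cfg, methods, quiet = quiet)
    unlist(rep_[metric_names])
  })
  out <- data.frame(metric = metric_names)
  for (i in seq_along(variants)) out[[variants[i]]] <- as.numeric(cols[[i]])
  out
}
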