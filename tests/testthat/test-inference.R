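test_that("retained-sample arithmetic matches the fitting protocol", {
  expect_identical(retained_samples(80000L, 10000L, 35L), 2000L)
  expect_identical(retained_samples(1000L, 0L, 1L), 1000L)
  expect_identical(retained_samples(1003L, 3L, 7L), 142L)
  expect_error(retained_samples(1000L, 1000L, 10L), "exceed")
})

test_that("split rank-normalized R-hat separates converged from divergent chains", {
  set.seed(1)
  same <- matrix(rnorm(4 * 10000), ncol = 4)
  expect_gt(compute_rhat(same), 0.99)
  expect_lt(compute_rhat(same), 1.01)
  # rank normalization caps the statistic for fully separated chains, but
  # far beyond any convergence threshold
  apart <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(compute_rhat(apart), 1.5)
  const <- matrix(1, nrow = 100, ncol = 3)
  r <- compute_rhat(const)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "zero_variance"))
  expect_error(compute_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("effective sample size tracks independence and autocorrelation", {
  set.seed(2)
  iid <- matrix(rnorm(4000), ncol = 2)
  expect_lt(abs(compute_ess(iid) - 4000) / 4000, 0.10)
  # AR(1) with lag-1 correlation 0.9: ESS ~ n (1 - rho) / (1 + rho)
  n <- 20000L
  ar <- vapply(1:2, function(i) {
    as.numeric(arima.sim(list(ar = 0.9), n = n, sd = sqrt(1 - 0.81)))
  }, numeric(n))
  target <- 2 * n * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(compute_ess(ar) - target) / target, 0.25)
  e <- compute_ess(matrix(2, 50, 2))
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "zero_variance"))
})

test_that("posterior sampling is bit-for-bit reproducible under a fixed seed", {
  sim <- simulate_dataset(config = sim_config(n_countries = 2L,
                                              regions_per_country = 2L),
                          seed = 33L)
  cfg <- fast_config()
  f1 <- fit_supply_share(sim$observations, cfg)
  f2 <- fit_supply_share(sim$observations, cfg)
  expect_identical(lapply(f1$draws, as.matrix), lapply(f2$draws, as.matrix))
  f3 <- fit_supply_share(sim$observations, run_config(n_iter = 1200L,
                                                      burn_in = 400L, thin = 2L,
                                                      n_chains = 2L, seed = 100L))
  expect_false(identical(as.matrix(f1$draws[[1]]), as.matrix(f3$draws[[1]])))
})

test_that("the sampled posterior matches the conjugate normal-normal closed form", {
  # one region, one method, increments pinned at zero, unit fixed prior
  # covariance, a single observation z = 0.4 with se_z = 0.5:
  # posterior alpha ~ N(0.32, 1/sqrt(5))
  toy <- data.frame(country_id = "c01", region_id = "r01", method = "m1",
                    year = 2010L, y_public = 0.6, n_public = 60L,
                    n_private = 40L, se_prop = 0.05, survey_id = "s1")
  lg <- prepare_observations(toy)
  lg$z <- 0.4
  lg$se_z <- 0.5
  hier <- build_hierarchy(lg, methods = "m1", allow_single_method = TRUE)
  cfg <- run_config(n_iter = 80000L, burn_in = 10000L, thin = 35L,
                    n_chains = 1L, seed = 12L)
  bases <- build_region_bases(lg, hier, cfg)
  spec <- model_spec(fixed = list(theta_all = 0, theta_c = matrix(0, 1, 1),
                                  Sigma_theta = matrix(1, 1, 1),
                                  Sigma_alpha = matrix(1, 1, 1),
                                  delta_zero = TRUE))
  fit <- sample_posterior(lg, hier, bases, cfg, spec)
  a <- subshare:::draws_matrix(fit, "alpha[1,1]")
  expect_equal(nrow(a), 2000L)
  post_mean <- 0.4 / 0.25 / (1 + 1 / 0.25)
  post_sd <- sqrt(1 / 5)
  mcse <- post_sd / sqrt(2000)
  expect_lt(abs(mean(a) - post_mean), 3 * mcse)
  expect_lt(abs(sd(a) - post_sd), 3 * post_sd / sqrt(2 * (2000 - 1)))
})

test_that("with no observations the posterior recovers the prior", {
  toy <- data.frame(country_id = "c01", region_id = "r01", method = "m1",
                    year = 2010L, y_public = 0.6, n_public = 60L,
                    n_private = 40L, se_prop = 0.05, survey_id = "s1")
  lg <- prepare_observations(toy)
  hier <- build_hierarchy(lg, methods = "m1", allow_single_method = TRUE)
  cfg <- run_config(n_iter = 42000L, burn_in = 2000L, thin = 20L,
                    n_chains = 1L, seed = 9L)
  bases <- build_region_bases(lg, hier, cfg)
  spec <- model_spec(fixed = list(theta_all = 0, theta_c = matrix(0, 1, 1),
                                  Sigma_theta = matrix(1, 1, 1),
                                  Sigma_alpha = matrix(1, 1, 1),
                                  delta_zero = TRUE))
  fit <- sample_posterior(lg[0, ], hier, bases, cfg, spec)
  a <- subshare:::draws_matrix(fit, "alpha[1,1]")
  expect_lt(abs(mean(a)), 3 / sqrt(length(a)))   # prior mean 0, sd 1
  expect_lt(abs(sd(a) - 1), 0.1)
})

test_that("trajectory summaries respect quantile ordering and monotone transforms", {
  sim <- simulate_dataset(config = sim_config(n_countries = 2L,
                                              regions_per_country = 2L),
                          seed = 5L)
  fit <- fit_supply_share(sim$observations, fast_config())
  tr <- summarize_trajectories(fit)
  expect_true(all(tr$q2.5 <= tr$median & tr$median <= tr$q97.5))
  expect_true(all(tr$mean > 0 & tr$mean < 1))
  expect_equal(nrow(tr), length(fit$hierarchy$regions) * 5 * 41)
  # quantiles on the share equal transformed quantiles of the latent scale
  psi <- subshare:::psi_draws_region_method(fit, 1L, 1L)
  q_psi <- apply(psi, 2, quantile, probs = 0.5, names = FALSE)
  sub <- tr[tr$region == fit$hierarchy$regions[1] &
              tr$method == fit$hierarchy$methods[1], ]
  # interpolated quantiles commute with the monotone transform only up to
  # interpolation error between adjacent order statistics
  expect_equal(sub$median, inv_logit(q_psi), tolerance = 1e-6)
  # degenerate case: identical draws collapse all summaries
  phi1 <- inv_logit(psi[1, 1])
  rep_draws <- matrix(psi[1, 1], 50, 1)
  expect_equal(unname(quantile(inv_logit(rep_draws), c(0.025, 0.5, 0.975))),
               rep(phi1, 3))
})

test_that("convergence diagnostics run over a fitted model", {
  sim <- simulate_dataset(config = sim_config(n_countries = 2L,
                                              regions_per_country = 2L),
                          seed = 5L)
  fit <- fit_supply_share(sim$observations, fast_config())
  dg <- diagnose_fit(fit)
  expect_true(all(is.finite(dg$rhat)))
  expect_true(all(dg$ess >= 0))
  expect_true(is.logical(dg$flagged))
})

test_that("hierarchical borrowing fills an empty region-method series", {
  sim <- scenario_sparse(config = sim_config(n_countries = 3L,
                                             regions_per_country = 3L),
                         seed = 6L)
  fit <- fit_supply_share(sim$observations, fast_config())
  tr <- summarize_trajectories(fit)
  r <- sim$sparse$empty_series[["region"]]
  m <- sim$sparse$empty_series[["method"]]
  sub <- tr[tr$region == r & tr$method == m, ]
  expect_true(all(is.finite(sub$mean)))
  expect_true(all(sub$q97.5 > sub$q2.5))
})

test_that("posterior ranks are uniform under the generative model (SBC)", {
  # simulation-based calibration on a 2-country x 3-region x 2-method toy:
  # truth drawn from the prior, logit-scale data from the data model, rank
  # of the truth among thinned posterior draws must be uniform
  set.seed(77)
  M <- 2L
  hier <- generate_hierarchy(2L, 3L, methods = c("m1", "m2"))
  cfg <- run_config(n_iter = 2900L, burn_in = 400L, thin = 25L,
                    n_chains = 1L, seed = 1L)
  des <- expand.grid(region = hier$regions, method = hier$methods,
                     year = c(1998L, 2005L, 2012L), stringsAsFactors = FALSE)
  ids <- do.call(rbind, strsplit(des$region, ":"))
  lg0 <- data.frame(country_id = ids[, 1], region_id = ids[, 2],
                    method = des$method, year = des$year, se_z = 0.3,
                    z = 0, y_squeezed = 0.5, survey_id = "s")
  bases <- build_region_bases(data.frame(country_id = ids[, 1],
                                         region_id = ids[, 2],
                                         year = des$year), hier, cfg)
  spec <- model_spec("multivariate_intercept")
  n_rep <- 200L
  ranks <- matrix(NA_real_, n_rep, 3L)
  for (r in seq_len(n_rep)) {
    St <- rinvwishart(1L, diag(M), M + 1L)[, , 1L]
    Sa <- rinvwishart(1L, diag(M), M + 1L)[, , 1L]
    th_all <- rnorm(M, 0, 10)
    th_c <- t(sapply(1:2, function(cc) th_all + as.numeric(t(chol(St)) %*% rnorm(M))))
    alpha <- t(sapply(seq_along(hier$regions), function(p) {
      th_c[hier$region_country[p], ] + as.numeric(t(chol(Sa)) %*% rnorm(M))
    }))
    rownames(alpha) <- hier$regions
    sdel <- abs(rnorm(1, 0, 2))
    delta <- lapply(hier$regions, function(rk) {
      matrix(rnorm((bases[[rk]]$spec$K - 1L) * M, 0, sdel), ncol = M)
    })
    names(delta) <- hier$regions
    lg <- lg0
    psi <- subshare:::psi_at_observations(list(alpha = alpha, delta = delta),
                                          lg, bases, hier$methods)
    lg$z <- rnorm(nrow(lg), psi, lg$se_z)
    cfg$seed <- 1000L + r
    fit <- sample_posterior(lg, hier, bases, cfg, spec)
    dm <- subshare:::draws_matrix(fit, c("theta_all[1]", "alpha[1,1]",
                                         "sigma_delta"))
    ranks[r, ] <- colSums(sweep(dm, 2L, c(th_all[1], alpha[1, 1], sdel), "<"))
  }
  n_draws <- retained_samples(cfg$n_iter, cfg$burn_in, cfg$thin)
  for (j in 1:3) {
    bins <- cut(ranks[, j], breaks = seq(-0.5, n_draws + 0.5, length.out = 11))
    expect_gt(chisq.test(table(bins))$p.value, 0.01)
  }
})
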