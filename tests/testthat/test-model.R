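test_that("spline coefficients follow the outward recursion from the anchor", {
  expect_equal(construct_beta(1.0, c(0.2, 0.5), k_star = 2L, K = 3L),
               c(0.8, 1.0, 1.5))
  expect_equal(construct_beta(0.7, rep(0, 5), k_star = 3L, K = 6L), rep(0.7, 6))
  # k_star = 1: beta is alpha plus cumulative sums (explicit oracle)
  delta <- c(0.1, -0.2, 0.4)
  expect_equal(construct_beta(2, delta, k_star = 1L, K = 4L),
               2 + c(0, cumsum(delta)))
  # reconstructed increments equal the input increments for any anchor
  for (k_star in 1:4) {
    beta <- construct_beta(0.3, delta, k_star, 4L)
    expect_equal(diff(beta), delta)
    expect_equal(beta[k_star], 0.3)
  }
  expect_error(construct_beta(1, c(0.1), 2L, 4L), "length")
})

test_that("latent surface is flat when increments vanish", {
  obs <- tiny_obs()
  hier <- build_hierarchy(obs, methods = c("injectables", "oc_pills"))
  cfg <- run_config()
  bases <- build_region_bases(obs, hier, cfg)
  params <- toy_params(hier, bases)
  for (rk in hier$regions) params$delta[[rk]][] <- 0
  params$alpha[] <- 0
  surf <- latent_surface(params, bases, hier$methods)
  expect_equal(unique(as.numeric(surf$surface[[1]]$phi_public)), 0.5)
  params$alpha[] <- logit(0.8)
  surf <- latent_surface(params, bases, hier$methods)
  for (rk in hier$regions) {
    expect_equal(as.numeric(surf$surface[[rk]]$phi_public),
                 rep(0.8, 2 * length(surf$years)), tolerance = 1e-12)
  }
})

test_that("surface reaches an exactly constant steady state after the anchor", {
  # with zero post-anchor increments the spline equals alpha once every
  # coefficient below k* has lost support, i.e. from knot k* + degree on;
  # between t_last and that knot the fitted trend flattens out smoothly
  obs <- tiny_obs()
  hier <- build_hierarchy(obs, methods = c("injectables", "oc_pills"))
  cfg <- run_config()
  bases <- build_region_bases(obs, hier, cfg)
  params <- toy_params(hier, bases, seed = 7)
  for (rk in hier$regions) {
    ks <- bases[[rk]]$spec$k_star
    params$delta[[rk]][ks:nrow(params$delta[[rk]]), ] <- 0
  }
  surf <- latent_surface(params, bases, hier$methods)
  for (rk in hier$regions) {
    sp <- bases[[rk]]$spec
    t_flat <- sp$knots[sp$k_star + sp$degree]
    after <- surf$years >= t_flat
    expect_gt(sum(after), 2)
    psi_after <- surf$surface[[rk]]$psi[after, , drop = FALSE]
    expect_lt(max(apply(psi_after, 2, function(x) diff(range(x)))), 1e-9)
    expect_equal(unname(psi_after[1, ]), unname(params$alpha[rk, ]),
                 tolerance = 1e-9)
  }
})

test_that("log prior equals the sum of independent closed-form terms", {
  obs <- tiny_obs()
  hier <- build_hierarchy(obs, methods = c("injectables", "oc_pills"))
  cfg <- run_config()
  bases <- build_region_bases(obs, hier, cfg)
  params <- toy_params(hier, bases)
  # make covariances diagonal so every term factorises into dnorm calls
  params$Sigma_theta <- diag(c(0.5, 0.8))
  params$Sigma_alpha <- diag(c(0.3, 0.6))
  spec <- model_spec("multivariate_intercept")
  got <- log_prior(params, hier, spec)

  M <- 2L
  expected <- sum(dnorm(params$theta_all, 0, 10, log = TRUE))
  for (ci in 1:2) expected <- expected +
    sum(dnorm(params$theta_c[ci, ], params$theta_all,
              sqrt(diag(params$Sigma_theta)), log = TRUE))
  for (rk in hier$regions) {
    ci <- hier$region_country[[rk]]
    expected <- expected + sum(dnorm(params$alpha[rk, ], params$theta_c[ci, ],
                                     sqrt(diag(params$Sigma_alpha)), log = TRUE))
    expected <- expected + sum(dnorm(params$delta[[rk]], 0, params$sigma_delta,
                                     log = TRUE))
  }
  expected <- expected + log(2) + dnorm(params$sigma_delta, 0, 2, log = TRUE)
  # inverse-Wishart terms for the two diagonal covariances, closed form:
  # IW density at diagonal Sigma with identity scale
  iw_term <- function(S, M, nu) {
    p <- M
    lmg <- sum(lgamma((nu + 1 - seq_len(p)) / 2)) + p * (p - 1) / 4 * log(pi)
    -0.5 * nu * p * log(2) - lmg -
      0.5 * (nu + p + 1) * sum(log(diag(S))) - 0.5 * sum(1 / diag(S))
  }
  expected <- expected + iw_term(params$Sigma_theta, M, 3) +
    iw_term(params$Sigma_alpha, M, 3)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("log prior rejects support violations and off-diagonal zero-covariance", {
  obs <- tiny_obs()
  hier <- build_hierarchy(obs, methods = c("injectables", "oc_pills"))
  bases <- build_region_bases(obs, hier, run_config())
  params <- toy_params(hier, bases)
  bad <- params
  bad$sigma_delta <- -0.1
  expect_identical(log_prior(bad, hier), -Inf)
  npd <- params
  npd$Sigma_alpha <- matrix(c(1, 2, 2, 1), 2, 2)  # not positive definite
  expect_identical(log_prior(npd, hier), -Inf)
  offd <- params
  offd$Sigma_theta <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_error(log_prior(offd, hier, model_spec("zero_covariance")), "diagonal")
})

test_that("likelihood matches Normal closed forms and is additive", {
  obs <- tiny_obs()
  suppressMessages(lg <- prepare_observations(obs))
  hier <- build_hierarchy(lg, methods = c("injectables", "oc_pills"))
  bases <- build_region_bases(lg, hier, run_config())
  params <- toy_params(hier, bases)

  one <- lg[1, , drop = FALSE]
  # zero residual: plant z exactly at psi
  psi1 <- subshare:::psi_at_observations(params, one, bases, hier$methods)
  one$z <- psi1
  expect_equal(log_likelihood(params, one, bases, hier$methods),
               -log(one$se_z * sqrt(2 * pi)))
  expect_equal(log_likelihood(params, lg[0, ], bases, hier$methods), 0)
  two <- rbind(one, one)
  expect_equal(log_likelihood(params, two, bases, hier$methods),
               2 * log_likelihood(params, one, bases, hier$methods))
})

test_that("log posterior is finite across random valid parameter points", {
  obs <- tiny_obs()
  suppressMessages(lg <- prepare_observations(obs))
  hier <- build_hierarchy(lg, methods = c("injectables", "oc_pills"))
  bases <- build_region_bases(lg, hier, run_config())
  set.seed(31)
  for (i in 1:200) {
    params <- toy_params(hier, bases, seed = i)
    params$sigma_delta <- runif(1, 0.01, 3)
    r <- runif(1, -0.9, 0.9)
    s <- runif(2, 0.1, 2)
    params$Sigma_theta <- diag(s) %*% matrix(c(1, r, r, 1), 2) %*% diag(s)
    params$Sigma_alpha <- params$Sigma_theta * runif(1, 0.5, 2)
    lp <- log_posterior(params, hier, lg, bases)
    expect_true(is.finite(lp))
  }
})

test_that("inverse-Wishart identity-scale prior yields uniform marginal correlations", {
  set.seed(5)
  M <- 5L
  draws <- rinvwishart(20000L, diag(M), M + 1L)
  corr <- draws[1, 2, ] / sqrt(draws[1, 1, ] * draws[2, 2, ])
  ks <- suppressWarnings(ks.test(corr, "punif", -1, 1))
  expect_lt(unname(ks$statistic), 0.02)
  # a second, off-diagonal pair behaves the same
  corr2 <- draws[3, 5, ] / sqrt(draws[3, 3, ] * draws[5, 5, ])
  expect_lt(unname(suppressWarnings(ks.test(corr2, "punif", -1, 1))$statistic), 0.02)
})
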