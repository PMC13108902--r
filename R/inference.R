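#' Retained posterior samples per chain
#'
#' `floor((n_iter - burn_in) / thin)`; with the default fitting protocol
#' (80,000 iterations, burn-in 10,000, thinning to every 35th) each chain
#' retains 2,000 samples.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in discarded initial iterations.
#' @param thin thinning interval.
#' @return integer count.
#' @examples
#' retained_samples(80000, 10000, 35)  # 2000
#' @export
retained_samples <- function(n_iter, burn_in, thin) {
  stopifnot(is_count(n_iter, 1L), is_count(burn_in, 0L), is_count(thin, 1L))
  if (n_iter <= burn_in) abort("retained_samples(): n_iter must exceed burn_in")
  as.integer(floor((n_iter - burn_in) / thin))
}

# internal: assemble the JAGS data list
jags_data <- function(logit_obs, hierarchy, bases, spec) {
  M <- length(hierarchy$methods)
  P <- length(hierarchy$regions)
  C <- length(hierarchy$countries)
  Kd <- max(vapply(bases, function(b) b$spec$K, 0L)) - 1L
  dat <- list(M = M, P = P, C = C, Kd = Kd,
              country = as.integer(hierarchy$region_country))
  mv_intercepts <- spec$variant %in% c("multivariate_intercept", "shrinkage",
                                       "fully_multivariate")
  mv_delta <- spec$variant %in% c("multivariate_delta", "fully_multivariate")
  if ((mv_intercepts && is.null(spec$fixed$Sigma_theta)) || mv_delta) {
    dat$IM <- diag(M)
    dat$nu <- M + spec$iw_df_offset
  }
  if (mv_delta) dat$zeroM <- rep(0, M)
  for (nm in c("theta_all", "theta_c", "Sigma_theta", "Sigma_alpha",
               "sigma_delta")) {
    if (!is.null(spec$fixed[[nm]])) dat[[nm]] <- spec$fixed[[nm]]
  }
  if (isTRUE(spec$fixed$delta_zero)) dat$delta <- array(0, c(P, M, Kd))

  n <- nrow(logit_obs)
  if (n > 0L) {
    keys <- region_key(logit_obs$country_id, logit_obs$region_id)
    reg <- match(keys, hierarchy$regions)
    met <- match(logit_obs$method, hierarchy$methods)
    if (anyNA(reg) || anyNA(met)) abort("observations outside the hierarchy")
    X <- matrix(0, nrow = n, ncol = Kd)
    for (i in seq_len(n)) {
      b <- bases[[keys[i]]]
      ti <- match(logit_obs$year[i], b$basis$years)
      if (is.na(ti)) abort("observation year %d not on the year grid", logit_obs$year[i])
      x <- as.numeric(b$basis$values[ti, ] %*% b$accum)
      X[i, seq_along(x)] <- x
    }
    dat$N <- n
    dat$z <- logit_obs$z
    dat$tauz <- 1 / logit_obs$se_z^2
    dat$reg <- reg
    dat$met <- met
    dat$X <- X
  }
  dat
}

#' Sample the posterior by MCMC (Gibbs sampling via JAGS)
#'
#' Compiles the variant's model and draws `n_chains` chains from
#' overdispersed initial points generated from the prior (each chain's RNG
#' is seeded deterministically from `config$seed`, so runs are reproducible
#' bit for bit). Adaptation plus burn-in together consume `burn_in`
#' iterations; the remaining `n_iter - burn_in` are thinned to every
#' `thin`-th draw.
#'
#' @param logit_obs preprocessed observations ([prepare_observations()]);
#'   may have zero rows, in which case the posterior equals the prior.
#' @param hierarchy a `subshare_hierarchy`.
#' @param bases per-region bases ([build_region_bases()]).
#' @param config a `subshare_config`.
#' @param spec a `subshare_model_spec`; defaults to the config's variant.
#' @param quiet suppress JAGS progress output (default TRUE).
#' @return object of class `subshare_fit`: list with `draws` (a
#'   `coda::mcmc.list` over all monitored nodes), `hierarchy`, `bases`,
#'   `config`, `spec`, `logit_obs`, `n_retained_per_chain`.
#' @export
sample_posterior <- function(logit_obs, hierarchy, bases, config,
                             spec = model_spec(config$variant), quiet = TRUE) {
  stopifnot(inherits(config, "subshare_config"),
            inherits(spec, "subshare_model_spec"))
  dat <- jags_data(logit_obs, hierarchy, bases, spec)
  code <- jags_model_string(spec, M = dat$M, has_obs = !is.null(dat$N))
  n_adapt <- min(1000L, config$burn_in)
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (config$seed * 1009L + ch * 7919L) %% 2147483646L + 1L)
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                            n.chains = config$n_chains, n.adapt = n_adapt,
                            quiet = quiet)
    if (config$burn_in > n_adapt) {
      update(jm, n.iter = config$burn_in - n_adapt,
             progress.bar = if (quiet) "none" else "text")
    }
    rjags::coda.samples(jm, variable.names = jags_monitors(spec),
                        n.iter = config$n_iter - config$burn_in,
                        thin = config$thin,
                        progress.bar = if (quiet) "none" else "text")
  }
  draws <- if (quiet) suppressWarnings(run()) else run()
  structure(list(draws = draws, hierarchy = hierarchy, bases = bases,
                 config = config, spec = spec, logit_obs = logit_obs,
                 n_chains = config$n_chains,
                 n_retained_per_chain = retained_samples(config$n_iter,
                                                         config$burn_in,
                                                         config$thin),
                 seed = config$seed),
            class = "subshare_fit")
}

#' @export
print.subshare_fit <- function(x, ...) {
  cat(sprintf("subshare fit: variant %s, %d regions x %d methods, %d obs\n",
              x$spec$variant, length(x$hierarchy$regions),
              length(x$hierarchy$methods), nrow(x$logit_obs)))
  cat(sprintf("  %d chain(s) x %d retained draws (seed %d)\n",
              x$n_chains, x$n_retained_per_chain, x$seed))
  invisible(x)
}

# internal: stacked draw matrix (all chains) for selected columns
draws_matrix <- function(fit, cols = NULL) {
  m <- do.call(rbind, lapply(fit$draws, as.matrix))
  if (is.null(cols)) return(m)
  # JAGS drops the index suffix for single-element nodes ("alpha[1,1]" -> "alpha")
  miss <- setdiff(cols, colnames(m))
  if (length(miss)) {
    bare <- sub("\\[.*\\]$", "", miss)
    ok <- bare %in% colnames(m) & !duplicated(bare)
    if (!all(ok)) abort("draws_matrix(): unknown node(s): %s",
                        paste(utils::head(miss[!ok], 3L), collapse = ", "))
    colnames(m)[match(bare, colnames(m))] <- miss
  }
  m[, cols, drop = FALSE]
}

# internal: per-(region, method) psi draws on the year grid (S x T)
psi_draws_region_method <- function(fit, p, m) {
  b <- fit$bases[[fit$hierarchy$regions[p]]]
  G <- b$basis$values %*% b$accum          # T x (K_p - 1)
  a <- draws_matrix(fit, sprintf("alpha[%d,%d]", p, m))
  if (isTRUE(fit$spec$fixed$delta_zero)) {
    return(matrix(a, nrow = length(a), ncol = nrow(G)))
  }
  dcols <- sprintf("delta[%d,%d,%d]", p, m, seq_len(ncol(G)))
  D <- draws_matrix(fit, dcols)            # S x (K_p - 1)
  sweep(D %*% t(G), 1L, as.numeric(a), "+")
}

#' Summarize posterior trajectories
#'
#' Pushes every retained draw through the latent surface and the inverse
#' logit, then reports mean, median and the central 95% interval of the
#' public share per (region, method, year). Because the inverse logit is
#' monotone, the quantiles of the share equal the transformed quantiles of
#' the latent variable.
#'
#' @param fit a `subshare_fit`.
#' @return data frame with columns `region`, `method`, `year`, `mean`,
#'   `median`, `q2.5`, `q97.5`.
#' @export
summarize_trajectories <- function(fit) {
  stopifnot(inherits(fit, "subshare_fit"))
  hier <- fit$hierarchy
  years <- seq.int(fit$config$year_start, fit$config$year_end)
  rows <- list()
  for (p in seq_along(hier$regions)) {
    for (m in seq_along(hier$methods)) {
      phi <- inv_logit(psi_draws_region_method(fit, p, m))  # S x T
      qs <- apply(phi, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
                  names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        region = hier$regions[p], method = hier$methods[m], year = years,
        mean = colMeans(phi), median = qs[2L, ], q2.5 = qs[1L, ],
        q97.5 = qs[3L, ])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior-predictive draws for observation rows
#'
#' For each supplied row, returns draws of the predicted logit-scale
#' observation: the latent `psi` draw at the row's (region, method, year)
#' plus Normal observation noise at the row's own logit-scale standard
#' error. These predictive draws (not the latent draws) feed the
#' out-of-sample coverage and dispersion metrics.
#'
#' @param fit a `subshare_fit`.
#' @param newdata data frame with `country_id`, `region_id`, `method`,
#'   `year`, `se_z` (e.g. held-out rows from [prepare_observations()]).
#' @param include_noise add observation noise (default TRUE).
#' @return matrix, draws x rows.
#' @export
posterior_predictive <- function(fit, newdata, include_noise = TRUE) {
  stopifnot(inherits(fit, "subshare_fit"), is.data.frame(newdata))
  keys <- region_key(newdata$country_id, newdata$region_id)
  p_idx <- match(keys, fit$hierarchy$regions)
  m_idx <- match(newdata$method, fit$hierarchy$methods)
  if (anyNA(p_idx) || anyNA(m_idx)) abort("posterior_predictive(): rows outside the fitted hierarchy")
  years <- seq.int(fit$config$year_start, fit$config$year_end)
  t_idx <- match(newdata$year, years)
  if (anyNA(t_idx)) abort("posterior_predictive(): year outside the grid")
  out <- vapply(seq_len(nrow(newdata)), function(i) {
    psi <- psi_draws_region_method(fit, p_idx[i], m_idx[i])[, t_idx[i]]
    if (include_noise) psi + stats::rnorm(length(psi), 0, newdata$se_z[i]) else psi
  }, numeric(fit$n_chains * fit$n_retained_per_chain))
  matrix(out, ncol = nrow(newdata))
}

# ---- convergence diagnostics -----------------------------------------------

# internal: coerce chains input (mcmc.list / matrix iterations x chains /
# list of vectors) to a matrix with one column per chain
as_chain_matrix <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    chains <- sapply(chains, as.numeric)
  } else if (is.list(chains)) {
    chains <- do.call(cbind, lapply(chains, as.numeric))
  }
  m <- as.matrix(chains)
  if (ncol(m) < 2L) abort("need at least 2 chains for convergence diagnostics")
  if (nrow(m) < 4L) abort("need at least 4 draws per chain")
  m
}

# internal: split each chain in half and rank-normalize jointly
split_rank_normalize <- function(m) {
  n2 <- floor(nrow(m) / 2)
  sm <- cbind(m[seq_len(n2), , drop = FALSE],
              m[(nrow(m) - n2 + 1L):nrow(m), , drop = FALSE])
  r <- matrix(rank(sm, ties.method = "average"), nrow = nrow(sm))
  stats::qnorm((r - 3 / 8) / (length(sm) + 1 / 4))
}

#' Split rank-normalized R-hat
#'
#' The potential scale reduction factor computed on split, jointly
#' rank-normalized chains. Values above about 1.05 indicate
#' non-convergence. Chains that are exactly constant are reported as 1 with
#' attribute `zero_variance = TRUE`.
#'
#' @param chains draws for one parameter: an `mcmc.list`, a list of
#'   per-chain vectors, or a matrix (iterations x chains).
#' @return scalar R-hat.
#' @export
compute_rhat <- function(chains) {
  m <- as_chain_matrix(chains)
  if (stats::var(as.numeric(m)) == 0) {
    return(structure(1, zero_variance = TRUE))
  }
  zm <- split_rank_normalize(m)
  n <- nrow(zm)
  W <- mean(apply(zm, 2L, stats::var))
  B <- n * stats::var(colMeans(zm))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS on split chains, combining within-chain
#' autocovariances with the between-chain variance and truncating the
#' autocorrelation sum at the first negative paired sum (Geyer's initial
#' positive sequence). Constant chains are reported as 0 with attribute
#' `zero_variance = TRUE`.
#'
#' @inheritParams compute_rhat
#' @return scalar ESS.
#' @export
compute_ess <- function(chains) {
  m <- as_chain_matrix(chains)
  if (stats::var(as.numeric(m)) == 0) {
    return(structure(0, zero_variance = TRUE))
  }
  n2 <- floor(nrow(m) / 2)
  sm <- cbind(m[seq_len(n2), , drop = FALSE],
              m[(nrow(m) - n2 + 1L):nrow(m), , drop = FALSE])
  n <- nrow(sm)
  nch <- ncol(sm)
  W <- mean(apply(sm, 2L, stats::var))
  B <- n * stats::var(colMeans(sm))
  var_plus <- (n - 1) / n * W + B / n
  # mean within-chain autocovariance by lag
  acov <- rowMeans(vapply(seq_len(nch), function(j) {
    x <- sm[, j] - mean(sm[, j])
    stats::acf(x, lag.max = n - 2L, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1L, 1L] * n / (n - 1)
  }, numeric(n - 1L)))
  rho <- 1 - (W - acov) / var_plus  # rho[1] is lag 0
  # Geyer initial monotone positive sequence on paired lags
  n_pairs <- floor(length(rho) / 2)
  pair <- rho[2 * seq_len(n_pairs) - 1L] + rho[2 * seq_len(n_pairs)]
  neg <- which(pair < 0)
  if (length(neg)) pair <- pair[seq_len(neg[1L] - 1L)]
  if (length(pair)) pair <- cummin(pair)
  tau <- max(-1 + 2 * sum(pair), 1 / (n * nch))
  max(n * nch / tau, 0)
}

#' Convergence diagnostics for every monitored node
#'
#' @param fit a `subshare_fit` (needs at least 2 chains).
#' @param rhat_threshold flag threshold (default 1.05).
#' @return data frame with `parameter`, `rhat`, `ess`, `flagged`.
#' @export
diagnose_fit <- function(fit, rhat_threshold = 1.05) {
  stopifnot(inherits(fit, "subshare_fit"))
  pars <- colnames(as.matrix(fit$draws[[1L]]))
  res <- lapply(pars, function(pn) {
    ch <- lapply(fit$draws, function(d) as.matrix(d)[, pn])
    data.frame(parameter = pn,
               rhat = as.numeric(compute_rhat(ch)),
               ess = as.numeric(compute_ess(ch)))
  })
  out <- do.call(rbind, res)
  out$flagged <- out$rhat > rhat_threshold
  out
}

#' Fit the supply-share model to an observation table
#'
#' End-to-end: preprocessing (minimum-sample filter, squeeze, delta-method
#' logit transform), region-specific anchored bases, and MCMC sampling of
#' the selected variant.
#'
#' @param obs raw observation data frame ([read_observations()]).
#' @param config a `subshare_config`.
#' @param methods method labels (default the five modern methods).
#' @param spec optional `subshare_model_spec` override.
#' @param quiet suppress sampler output.
#' @return a `subshare_fit`.
#' @export
fit_supply_share <- function(obs, config = run_config(),
                             methods = DEFAULT_METHODS,
                             spec = model_spec(config$variant),
                             quiet = TRUE) {
  logit_obs <- prepare_observations(obs, config$min_sector_n)
  if (nrow(logit_obs) == 0L) abort("fit_supply_share(): no observations survive preprocessing")
  hierarchy <- build_hierarchy(logit_obs, methods)
  bases <- build_region_bases(logit_obs, hierarchy, config)
  sample_posterior(logit_obs, hierarchy, bases, config, spec, quiet = quiet)
}
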