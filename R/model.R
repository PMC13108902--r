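#' Model variants
#'
#' The headline model (`multivariate_intercept`) places a multivariate
#' normal hierarchy with inverse-Wishart cross-method covariances on the
#' proxy-intercepts and a common random-walk scale on the spline increments.
#' The four comparators alter the prior structure only:
#' \describe{
#'   \item{zero_covariance}{independent per-method intercept hierarchies
#'     (diagonal covariances, half-Normal sd-2 priors on the per-method
#'     standard deviations).}
#'   \item{multivariate_delta}{independent per-method intercepts, but the
#'     inverse-Wishart cross-method covariance moved onto the per-knot
#'     increment vectors.}
#'   \item{fully_multivariate}{inverse-Wishart covariances on both the
#'     intercepts and the increments.}
#'   \item{shrinkage}{as the headline model, but the common increment scale
#'     is replaced by hierarchical per-(region, method) scales under a
#'     common half-Normal sd-2 hyper-scale.}
#' }
#' These comparator parameterizations are reconstructions of the published
#' alternatives from their structural descriptions.
#' @export
MODEL_VARIANTS <- c("multivariate_intercept", "multivariate_delta",
                    "zero_covariance", "shrinkage", "fully_multivariate")

#' Model specification
#'
#' Bundles the variant selector with the hyperprior constants and any nodes
#' held fixed (used for conditional/toy analyses, e.g. the conjugate
#' normal-normal check).
#'
#' @param variant one of [MODEL_VARIANTS].
#' @param theta_all_sd prior sd of the global method means (default 10,
#'   i.e. variance 100).
#' @param iw_df_offset inverse-Wishart degrees of freedom are M +
#'   `iw_df_offset` (default 1, giving uniform marginal correlations).
#' @param halfnorm_sd scale of every half-Normal sd prior (default 2).
#' @param fixed named list of nodes to hold fixed instead of sampling:
#'   any of `theta_all` (M-vector), `theta_c` (C x M), `Sigma_theta`,
#'   `Sigma_alpha` (M x M), `sigma_delta` (scalar) and `delta_zero = TRUE`
#'   (pin all increments at zero, giving the constant-in-time reduction).
#' @return object of class `subshare_model_spec`.
#' @export
model_spec <- function(variant = "multivariate_intercept", theta_all_sd = 10,
                       iw_df_offset = 1L, halfnorm_sd = 2, fixed = list()) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(theta_all_sd > 0, halfnorm_sd > 0, is_count(iw_df_offset, 0L))
  allowed <- c("theta_all", "theta_c", "Sigma_theta", "Sigma_alpha",
               "sigma_delta", "delta_zero")
  if (length(fixed) && !all(names(fixed) %in% allowed)) {
    abort("model_spec(): unknown fixed node(s): %s",
          paste(setdiff(names(fixed), allowed), collapse = ", "))
  }
  structure(list(variant = variant, theta_all_sd = theta_all_sd,
                 iw_df_offset = as.integer(iw_df_offset),
                 halfnorm_sd = halfnorm_sd, fixed = fixed),
            class = "subshare_model_spec")
}

#' Reconstruct spline coefficients from intercept and increments
#'
#' The anchored coefficient `k_star` equals the proxy-intercept
#' `alpha_pm`; moving down from the anchor successive increments are
#' subtracted, moving up they are added, so `delta[k] = beta[k+1] - beta[k]`
#' for every k.
#'
#' @param alpha_pm scalar proxy-intercept.
#' @param delta_pm increment vector, length K - 1.
#' @param k_star anchored coefficient index.
#' @param K number of coefficients.
#' @return numeric vector beta of length K.
#' @examples
#' construct_beta(1, c(0.2, 0.5), k_star = 2, K = 3)  # c(0.8, 1.0, 1.5)
#' @export
construct_beta <- function(alpha_pm, delta_pm, k_star, K) {
  stopifnot(is_count(K, 2L), is_count(k_star, 1L), k_star <= K)
  if (length(delta_pm) != K - 1L) {
    abort("construct_beta(): delta must have length K - 1 = %d (got %d)",
          K - 1L, length(delta_pm))
  }
  beta <- numeric(K)
  beta[k_star] <- alpha_pm
  if (k_star < K) for (k in (k_star + 1L):K) beta[k] <- beta[k - 1L] + delta_pm[k - 1L]
  if (k_star > 1L) for (k in (k_star - 1L):1L) beta[k] <- beta[k + 1L] - delta_pm[k]
  beta
}

#' Latent logit surface from process parameters
#'
#' Pushes the process parameters through the spline: for every region and
#' method, `psi(t) = sum_k beta_k B_k(t)` on the year grid, and
#' `phi_public = logit^{-1}(psi)`.
#'
#' @param params process parameter list: `alpha` (P x M matrix, rownames =
#'   region keys), `delta` (named list by region of (K_p - 1) x M matrices).
#' @param bases per-region bases from [build_region_bases()].
#' @param methods method labels (columns of `alpha`).
#' @return list with `years` and, per region, matrices `psi` and
#'   `phi_public` (years x methods).
#' @export
latent_surface <- function(params, bases, methods = colnames(params$alpha)) {
  stopifnot(is.matrix(params$alpha))
  regions <- rownames(params$alpha)
  out <- lapply(regions, function(rk) {
    b <- bases[[rk]]
    if (is.null(b)) abort("latent_surface(): no basis for region %s", rk)
    B <- b$basis$values
    psi <- vapply(seq_along(methods), function(m) {
      beta <- construct_beta(params$alpha[rk, m], params$delta[[rk]][, m],
                             b$spec$k_star, b$spec$K)
      as.numeric(B %*% beta)
    }, numeric(nrow(B)))
    colnames(psi) <- methods
    list(psi = psi, phi_public = inv_logit(psi))
  })
  names(out) <- regions
  list(years = bases[[regions[1L]]]$basis$years, surface = out)
}

# ---- log densities (closed forms) ------------------------------------------

# multivariate normal log density via Cholesky
ldmvnorm <- function(x, mean, Sigma) {
  p <- length(x)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  r <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

# inverse-Wishart(S, nu) log density at Sigma (p x p)
ldinvwishart <- function(Sigma, S, nu) {
  p <- ncol(S)
  chS <- chol(S)
  chX <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  lmg <- sum(lgamma((nu + 1 - seq_len(p)) / 2)) + p * (p - 1) / 4 * log(pi)
  ldetS <- 2 * sum(log(diag(chS)))
  ldetX <- 2 * sum(log(diag(chX)))
  tr <- sum(diag(S %*% chol2inv(chX)))
  0.5 * nu * ldetS - 0.5 * nu * p * log(2) - lmg -
    0.5 * (nu + p + 1) * ldetX - 0.5 * tr
}

# half-normal (sd scale) log density
ldhalfnorm <- function(x, sd) {
  if (any(x <= 0)) return(-Inf)
  sum(log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

#' Draw from an inverse-Wishart distribution
#'
#' `Sigma ~ IW(S, nu)` via `stats::rWishart` on the inverse scale. With
#' `S = I_M` and `nu = M + 1` the implied marginal correlations are uniform
#' on (-1, 1).
#'
#' @param n number of draws.
#' @param S scale matrix.
#' @param nu degrees of freedom (> ncol(S) - 1).
#' @return array `ncol(S) x ncol(S) x n`.
#' @export
rinvwishart <- function(n, S, nu) {
  W <- stats::rWishart(n, df = nu, Sigma = solve(S))
  out <- array(apply(W, 3L, function(w) chol2inv(chol(w))), dim = dim(W))
  out
}

# ---- joint model density ----------------------------------------------------

#' Log prior density of the process parameters
#'
#' Sums the closed-form log densities of the variant's prior structure. For
#' the multivariate variants the intercept covariances carry
#' \eqn{IW(I_M, M+1)} priors; for `zero_covariance` (and the intercepts of
#' `multivariate_delta`) the supplied covariance matrices must be diagonal
#' and their standard deviations carry half-Normal priors.
#'
#' @param params parameter list; see [latent_surface()] plus `theta_all`,
#'   `theta_c` (C x M, rownames countries), `Sigma_theta`, `Sigma_alpha`
#'   and the variant's increment-scale parameters (`sigma_delta` scalar;
#'   `sigma_delta_pm` P x M plus `sigma_delta0` for shrinkage;
#'   `Sigma_delta` for the multivariate-increment variants).
#' @param hierarchy a `subshare_hierarchy`.
#' @param spec a `subshare_model_spec`.
#' @return scalar log density (`-Inf` outside the support).
#' @export
log_prior <- function(params, hierarchy, spec = model_spec()) {
  stopifnot(inherits(hierarchy, "subshare_hierarchy"),
            inherits(spec, "subshare_model_spec"))
  M <- length(hierarchy$methods)
  IM <- diag(M)
  nu <- M + spec$iw_df_offset
  variant <- spec$variant
  lp <- 0

  mv_intercepts <- variant %in% c("multivariate_intercept", "shrinkage",
                                  "fully_multivariate")
  if (!mv_intercepts && variant %in% c("zero_covariance", "multivariate_delta")) {
    for (nm in c("Sigma_theta", "Sigma_alpha")) {
      S <- params[[nm]]
      if (any(S[upper.tri(S)] != 0) || any(S[lower.tri(S)] != 0)) {
        abort("log_prior(): variant %s requires diagonal %s", variant, nm)
      }
      lp <- lp + ldhalfnorm(sqrt(diag(S)), spec$halfnorm_sd)
    }
  } else {
    lp <- lp + ldinvwishart(params$Sigma_theta, IM, nu) +
      ldinvwishart(params$Sigma_alpha, IM, nu)
  }
  if (!is.finite(lp)) return(-Inf)

  # global means and hierarchical intercepts
  lp <- lp + sum(stats::dnorm(params$theta_all, 0, spec$theta_all_sd, log = TRUE))
  for (ci in seq_along(hierarchy$countries)) {
    lp <- lp + ldmvnorm(params$theta_c[ci, ], params$theta_all, params$Sigma_theta)
  }
  for (rk in hierarchy$regions) {
    ci <- hierarchy$region_country[[rk]]
    lp <- lp + ldmvnorm(params$alpha[rk, ], params$theta_c[ci, ], params$Sigma_alpha)
  }

  # increments
  if (variant %in% c("multivariate_intercept", "zero_covariance")) {
    if (!is.numeric(params$sigma_delta) || params$sigma_delta <= 0) return(-Inf)
    lp <- lp + ldhalfnorm(params$sigma_delta, spec$halfnorm_sd)
    for (rk in hierarchy$regions) {
      lp <- lp + sum(stats::dnorm(params$delta[[rk]], 0, params$sigma_delta,
                                  log = TRUE))
    }
  } else if (variant == "shrinkage") {
    if (params$sigma_delta0 <= 0 || any(params$sigma_delta_pm <= 0)) return(-Inf)
    lp <- lp + ldhalfnorm(params$sigma_delta0, spec$halfnorm_sd) +
      ldhalfnorm(as.numeric(params$sigma_delta_pm), params$sigma_delta0)
    for (rk in hierarchy$regions) {
      sds <- params$sigma_delta_pm[rk, ]
      lp <- lp + sum(stats::dnorm(params$delta[[rk]], 0,
                                  rep(sds, each = nrow(params$delta[[rk]])),
                                  log = TRUE))
    }
  } else {  # multivariate increments
    lp <- lp + ldinvwishart(params$Sigma_delta, IM, nu)
    if (!is.finite(lp)) return(-Inf)
    for (rk in hierarchy$regions) {
      D <- params$delta[[rk]]  # (K-1) x M; rows are the per-knot M-vectors
      for (k in seq_len(nrow(D))) {
        lp <- lp + ldmvnorm(D[k, ], rep(0, M), params$Sigma_delta)
      }
    }
  }
  lp
}

#' Normal log likelihood of logit-scale observations
#'
#' Each observation contributes a Normal log density with mean the latent
#' `psi` at its (region, method, year) and standard deviation its
#' delta-method logit-scale standard error.
#'
#' @param params parameter list (needs `alpha`, `delta`).
#' @param logit_obs data frame from [prepare_observations()] (needs
#'   `country_id`, `region_id`, `method`, `year`, `z`, `se_z`).
#' @param bases per-region bases from [build_region_bases()].
#' @param methods method label order.
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(params, logit_obs, bases,
                           methods = colnames(params$alpha)) {
  if (nrow(logit_obs) == 0L) return(0)
  psi <- psi_at_observations(params, logit_obs, bases, methods)
  sum(stats::dnorm(logit_obs$z, mean = psi, sd = logit_obs$se_z, log = TRUE))
}

# internal: latent psi at each observation row
psi_at_observations <- function(params, logit_obs, bases, methods) {
  keys <- region_key(logit_obs$country_id, logit_obs$region_id)
  vapply(seq_len(nrow(logit_obs)), function(i) {
    b <- bases[[keys[i]]]
    if (is.null(b)) abort("unresolvable region key: %s", keys[i])
    m <- match(logit_obs$method[i], methods)
    if (is.na(m)) abort("unresolvable method: %s", logit_obs$method[i])
    ti <- match(logit_obs$year[i], b$basis$years)
    if (is.na(ti)) abort("year %s outside the grid", logit_obs$year[i])
    beta <- construct_beta(params$alpha[keys[i], m], params$delta[[keys[i]]][, m],
                           b$spec$k_star, b$spec$K)
    sum(b$basis$values[ti, ] * beta)
  }, 0)
}

#' @rdname log_prior
#' @param logit_obs observations for the likelihood term.
#' @param bases per-region bases.
#' @export
log_posterior <- function(params, hierarchy, logit_obs, bases,
                          spec = model_spec()) {
  lp <- log_prior(params, hierarchy, spec)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(params, logit_obs, bases, methods = hierarchy$methods)
}

# ---- JAGS model code --------------------------------------------------------

# Build the JAGS model string for a variant. `M` is the number of methods,
# `has_obs` whether a likelihood block is emitted, `fixed` the model_spec
# fixed-node list. Nodes that are fixed arrive as data, so their prior lines
# are suppressed.
jags_model_string <- function(spec, M, has_obs) {
  fx <- spec$fixed
  variant <- spec$variant
  tau_all <- 1 / spec$theta_all_sd^2
  tau_hn <- 1 / spec$halfnorm_sd^2
  mv_intercepts <- variant %in% c("multivariate_intercept", "shrinkage",
                                  "fully_multivariate")
  mv_delta <- variant %in% c("multivariate_delta", "fully_multivariate")
  if ((mv_intercepts && is.null(fx$Sigma_theta) || mv_delta) && M < 2) {
    abort("multivariate variants need at least 2 methods")
  }
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))

  add("model {")
  if (is.null(fx$theta_all)) {
    add("  for (m in 1:M) { theta_all[m] ~ dnorm(0, %.10g) }", tau_all)
  }

  # intercept hierarchy
  if (mv_intercepts) {
    if (is.null(fx$Sigma_theta)) {
      add("  Omega_theta ~ dwish(IM[,], nu)")
      add("  Sigma_theta <- inverse(Omega_theta)")
    } else if (M >= 2) {
      add("  Omega_theta <- inverse(Sigma_theta[,])")
    }
    if (is.null(fx$Sigma_alpha)) {
      add("  Omega_alpha ~ dwish(IM[,], nu)")
      add("  Sigma_alpha <- inverse(Omega_alpha)")
    } else if (M >= 2) {
      add("  Omega_alpha <- inverse(Sigma_alpha[,])")
    }
    if (M >= 2) {
      if (is.null(fx$theta_c)) {
        add("  for (c in 1:C) { theta_c[c,1:M] ~ dmnorm(theta_all[], Omega_theta) }")
      }
      add("  for (p in 1:P) { alpha[p,1:M] ~ dmnorm(theta_c[country[p],], Omega_alpha) }")
    } else {
      # univariate degenerate case (only reachable with fixed covariances)
      if (is.null(fx$theta_c)) {
        add("  for (c in 1:C) { theta_c[c,1] ~ dnorm(theta_all[1], 1 / Sigma_theta[1,1]) }")
      }
      add("  for (p in 1:P) { alpha[p,1] ~ dnorm(theta_c[country[p],1], 1 / Sigma_alpha[1,1]) }")
    }
  } else {
    add("  for (m in 1:M) {")
    add("    sd_theta[m] ~ dnorm(0, %.10g) T(0,)", tau_hn)
    add("    sd_alpha[m] ~ dnorm(0, %.10g) T(0,)", tau_hn)
    add("  }")
    if (is.null(fx$theta_c)) {
      add("  for (c in 1:C) { for (m in 1:M) { theta_c[c,m] ~ dnorm(theta_all[m], pow(sd_theta[m], -2)) } }")
    }
    add("  for (p in 1:P) { for (m in 1:M) { alpha[p,m] ~ dnorm(theta_c[country[p],m], pow(sd_alpha[m], -2)) } }")
  }

  # increments
  if (is.null(fx$delta_zero)) {
    if (variant %in% c("multivariate_intercept", "zero_covariance")) {
      if (is.null(fx$sigma_delta)) {
        add("  sigma_delta ~ dnorm(0, %.10g) T(0,)", tau_hn)
      }
      add("  tau_delta <- pow(sigma_delta, -2)")
      add("  for (p in 1:P) { for (m in 1:M) { for (k in 1:Kd) { delta[p,m,k] ~ dnorm(0, tau_delta) } } }")
    } else if (variant == "shrinkage") {
      add("  sigma_delta0 ~ dnorm(0, %.10g) T(0,)", tau_hn)
      add("  for (p in 1:P) { for (m in 1:M) {")
      add("    sigma_delta_pm[p,m] ~ dnorm(0, pow(sigma_delta0, -2)) T(0,)")
      add("    for (k in 1:Kd) { delta[p,m,k] ~ dnorm(0, pow(sigma_delta_pm[p,m], -2)) }")
      add("  } }")
    } else {  # multivariate increments
      add("  Omega_delta ~ dwish(IM[,], nu)")
      add("  Sigma_delta <- inverse(Omega_delta)")
      add("  for (p in 1:P) { for (k in 1:Kd) { delta[p,1:M,k] ~ dmnorm(zeroM[], Omega_delta) } }")
    }
  }

  if (has_obs) {
    add("  for (i in 1:N) {")
    add("    psi[i] <- alpha[reg[i], met[i]] + inprod(X[i,1:Kd], delta[reg[i], met[i], 1:Kd])")
    add("    z[i] ~ dnorm(psi[i], tauz[i])")
    add("  }")
  }
  add("}")
  paste(L, collapse = "\n")
}

# Monitored node names for a variant (excluding fixed nodes).
jags_monitors <- function(spec) {
  fx <- spec$fixed
  variant <- spec$variant
  mv_intercepts <- variant %in% c("multivariate_intercept", "shrinkage",
                                  "fully_multivariate")
  mon <- "alpha"
  if (is.null(fx$theta_all)) mon <- c(mon, "theta_all")
  if (is.null(fx$theta_c)) mon <- c(mon, "theta_c")
  if (mv_intercepts) {
    if (is.null(fx$Sigma_theta)) mon <- c(mon, "Sigma_theta")
    if (is.null(fx$Sigma_alpha)) mon <- c(mon, "Sigma_alpha")
  } else {
    mon <- c(mon, "sd_theta", "sd_alpha")
  }
  if (is.null(fx$delta_zero)) {
    mon <- c(mon, "delta")
    if (variant %in% c("multivariate_intercept", "zero_covariance")) {
      if (is.null(fx$sigma_delta)) mon <- c(mon, "sigma_delta")
    } else if (variant == "shrinkage") {
      mon <- c(mon, "sigma_delta0", "sigma_delta_pm")
    } else {
      mon <- c(mon, "Sigma_delta")
    }
  }
  mon
}
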