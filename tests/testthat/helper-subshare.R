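# Shared fixtures and independent oracles for the test suite.

# Independent textbook Cox-de Boor recursion (half-open intervals, closed at
# the right boundary). Deliberately naive; used only as an oracle.
cox_de_boor_basis <- function(knots, x, degree) {
  n_basis <- length(knots) - degree - 1L
  sapply(seq_len(n_basis), function(i) {
    vapply(x, function(xx) cdb_one(knots, i, degree, xx), 0)
  })
}

cdb_one <- function(t, i, d, x) {
  if (d == 0L) {
    hi <- t[i + 1L]
    # closed on the right at the final breakpoint
    if (hi == max(t) && x == hi && t[i] < hi) return(1)
    return(as.numeric(x >= t[i] && x < hi))
  }
  a <- 0
  if (t[i + d] > t[i]) {
    a <- (x - t[i]) / (t[i + d] - t[i]) * cdb_one(t, i, d - 1L, x)
  }
  b <- 0
  if (t[i + d + 1L] > t[i + 1L]) {
    b <- (t[i + d + 1L] - x) / (t[i + d + 1L] - t[i + 1L]) * cdb_one(t, i + 1L, d - 1L, x)
  }
  a + b
}

# A small deterministic observation table: 2 countries x 2 regions x
# 2 methods, surveys spanning the 2015 validation cutoff.
tiny_obs <- function() {
  grid <- expand.grid(country_id = c("AA", "BB"), region_id = c("r1", "r2"),
                      method = c("injectables", "oc_pills"),
                      year = c(2005L, 2012L, 2018L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_pub <- 40L + seq_len(nrow(grid))
  n_priv <- 60L - seq_len(nrow(grid)) %% 7L
  data.frame(grid,
             y_public = n_pub / (n_pub + n_priv),
             n_public = n_pub, n_private = n_priv,
             se_prop = 0.03 + 0.001 * seq_len(nrow(grid)) %% 5,
             survey_id = paste0(grid$country_id, "_", grid$year),
             stringsAsFactors = FALSE)
}

# Reduced MCMC settings for tests that need a sampled posterior.
fast_config <- function(...) {
  run_config(n_iter = 1200L, burn_in = 400L, thin = 2L, n_chains = 2L,
             seed = 99L, ...)
}

# Valid process parameters for a given hierarchy/bases (deterministic).
toy_params <- function(hierarchy, bases, seed = 1L) {
  set.seed(seed)
  M <- length(hierarchy$methods)
  C <- length(hierarchy$countries)
  P <- length(hierarchy$regions)
  delta <- lapply(hierarchy$regions, function(rk) {
    K <- bases[[rk]]$spec$K
    matrix(rnorm((K - 1L) * M, 0, 0.1), K - 1L, M)
  })
  names(delta) <- hierarchy$regions
  list(theta_all = rnorm(M),
       theta_c = matrix(rnorm(C * M), C, M,
                        dimnames = list(hierarchy$countries, NULL)),
       alpha = matrix(rnorm(P * M), P, M,
                      dimnames = list(hierarchy$regions, hierarchy$methods)),
       delta = delta, sigma_delta = 0.2,
       Sigma_theta = diag(M) * 0.5 + 0.1,
       Sigma_alpha = diag(M) * 0.4 + 0.05)
}
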