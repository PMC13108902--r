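#' Squeeze proportions away from the boundary ("lemon-squeezer")
#'
#' Affine shrinkage of observed proportions away from exact 0 and 1 so that
#' the logit transform is finite:
#' \deqn{y' = (y (N - 1) + 1/2) / N}
#' with \eqn{N} the total sample size behind the proportion. The transform is
#' strictly increasing in \eqn{y} for fixed \eqn{N}, preserves relative
#' ordering, and converges to the identity as \eqn{N \to \infty}. It is
#' applied to every observation, not only boundary ones, so all data points
#' are shrunk slightly towards 1/2.
#'
#' @param y proportion(s) in \[0, 1\].
#' @param n_total total sample size(s), integer \eqn{\ge 2}; recycled against
#'   `y`.
#' @return proportion(s) strictly inside (0, 1).
#' @examples
#' lemon_squeeze(0, 100)    # 0.005
#' lemon_squeeze(1, 100)    # 0.995
#' lemon_squeeze(0.5, 100)  # 0.5 (fixed point)
#' @export
lemon_squeeze <- function(y, n_total) {
  stopifnot(is.numeric(y), is.numeric(n_total))
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    abort("lemon_squeeze(): y must lie in [0, 1]")
  }
  if (any(!is.finite(n_total)) || any(n_total < 2)) {
    abort("lemon_squeeze(): n_total must be >= 2")
  }
  (y * (n_total - 1) + 0.5) / n_total
}

#' Minimum-sample filter
#'
#' Retains observations where at least one sector (public or private) has a
#' sample size of at least `min_n` women; rows failing the rule carry too
#' much uncertainty to be informative.
#'
#' @param obs observation data frame (see [read_observations()]).
#' @param min_n minimum per-sector sample size; default 10.
#' @return the filtered data frame, original row order preserved. The number
#'   of dropped rows is reported via `message()` when positive.
#' @export
filter_min_sample <- function(obs, min_n = 10L) {
  stopifnot(is.data.frame(obs), is_count(min_n, min = 0L))
  if (nrow(obs) == 0L) return(obs)
  keep <- pmax(obs$n_public, obs$n_private) >= min_n
  if (any(!keep)) {
    message(sprintf("filter_min_sample(): dropped %d of %d rows (max sector n < %d)",
                    sum(!keep), length(keep), min_n))
  }
  obs[keep, , drop = FALSE]
}

#' Delta-method logit transform
#'
#' Maps a proportion and its standard error onto the logit scale:
#' \eqn{z = \mathrm{logit}(y)} and, by first-order variance propagation,
#' \eqn{se_z = se_y / (y (1 - y))}.
#'
#' @param y proportion(s) strictly in (0, 1) (squeeze first).
#' @param se_prop standard error(s) of `y` on the proportion scale, > 0.
#' @return a list with components `z` and `se_z`.
#' @examples
#' to_logit_scale(0.5, 0.05)  # z = 0, se_z = 0.2
#' @export
to_logit_scale <- function(y, se_prop) {
  if (any(!is.finite(se_prop)) || any(se_prop <= 0)) {
    abort("to_logit_scale(): se_prop must be > 0")
  }
  z <- logit(y)
  list(z = z, se_z = se_prop / (y * (1 - y)))
}

#' Train/test split at a cutoff year
#'
#' Observations strictly after `cutoff_year` form the held-out test set;
#' observations in or before the cutoff year train the model.
#'
#' @param obs observation data frame with a `year` column.
#' @param cutoff_year integer; default 2015.
#' @return list with data frames `train` and `test`.
#' @export
split_train_test <- function(obs, cutoff_year = 2015L) {
  stopifnot(is.data.frame(obs), is_count(cutoff_year, min = 0L))
  train <- obs[obs$year <= cutoff_year, , drop = FALSE]
  test <- obs[obs$year > cutoff_year, , drop = FALSE]
  if (nrow(obs) > 0L && nrow(test) == 0L) {
    warning(sprintf("split_train_test(): no observations after %d; test set empty",
                    cutoff_year), call. = FALSE)
  }
  list(train = train, test = test)
}

#' Prepare observations for model fitting
#'
#' Full preprocessing pipeline: minimum-sample filter, rejection of rows with
#' missing or non-positive standard errors, boundary squeezing of every
#' retained proportion (with \eqn{N} = n_public + n_private), and the
#' delta-method logit transform. Adds columns `y_squeezed`, `z`, `se_z`.
#'
#' @param obs observation data frame from [read_observations()].
#' @param min_n minimum per-sector sample size (default 10).
#' @return data frame of logit-scale observations.
#' @export
prepare_observations <- function(obs, min_n = 10L) {
  obs <- filter_min_sample(obs, min_n)
  bad_se <- !is.finite(obs$se_prop) | obs$se_prop <= 0
  if (any(bad_se)) {
    message(sprintf("prepare_observations(): rejected %d rows with missing/non-positive se_prop",
                    sum(bad_se)))
    obs <- obs[!bad_se, , drop = FALSE]
  }
  if (nrow(obs) == 0L) {
    obs$y_squeezed <- numeric(0)
    obs$z <- numeric(0)
    obs$se_z <- numeric(0)
    return(obs)
  }
  n_total <- obs$n_public + obs$n_private
  obs$y_squeezed <- lemon_squeeze(obs$y_public, n_total)
  lz <- to_logit_scale(obs$y_squeezed, obs$se_prop)
  obs$z <- lz$z
  obs$se_z <- lz$se_z
  obs
}
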