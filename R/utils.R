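#' Logit and inverse-logit
#'
#' Scalar/vector logit transform and its inverse. `logit()` requires inputs
#' strictly inside (0, 1); boundary proportions must be squeezed first (see
#' [lemon_squeeze()]).
#'
#' @param p numeric vector of proportions in (0, 1).
#' @param x numeric vector on the real line.
#' @return numeric vector.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires proportions strictly in (0, 1); squeeze first", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  # numerically stable in both tails
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

# internal: scalar integer check
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

# internal: stop with sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
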