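#' Region-specific B-spline basis specification
#'
#' Each admin-1 region gets its own knot vector: interior knots form an
#' arithmetic sequence (step `spacing` years) passing exactly through that
#' region's most recent survey year `t_last` and covering the whole year
#' grid. Anchoring a knot at `t_last` serves two purposes: it lets the
#' first-order random-walk prior on coefficient increments run outwards in
#' both directions from the anchored coefficient, and it makes projections
#' beyond `t_last` revert to a steady state (the increments beyond the
#' anchor have prior mean zero).
#'
#' The anchored coefficient index `k_star` is the one whose Greville
#' abscissa (the average of its `degree` supporting knots) is nearest
#' `t_last`; that coefficient carries the region-method proxy-intercept.
#'
#' @param region_id region key.
#' @param t_last most recent survey year observed in the region.
#' @param year_start,year_end inclusive year grid.
#' @param degree spline degree (default cubic).
#' @param spacing interior knot spacing in years (default 5).
#' @return object of class `subshare_basis_spec`: list with `region_id`,
#'   `degree`, `knots` (full non-decreasing knot vector, boundary knots at
#'   multiplicity degree + 1), `interior` (the arithmetic sequence),
#'   `K` (number of basis functions), `k_star`, `t_last`, `greville`.
#' @export
build_basis_spec <- function(region_id, t_last, year_start = 1990L,
                             year_end = 2030L, degree = 3L, spacing = 5L) {
  if (!is_count(spacing, 1L)) abort("build_basis_spec(): spacing must be a positive integer")
  stopifnot(is_count(degree, 0L), is_count(t_last), year_end > year_start)
  if (t_last < year_start || t_last > year_end) {
    abort("build_basis_spec(): t_last %d outside year grid [%d, %d]",
          t_last, year_start, year_end)
  }
  n_down <- ceiling((t_last - year_start) / spacing)
  n_up <- ceiling((year_end - t_last) / spacing)
  interior <- t_last + spacing * seq.int(-n_down, n_up)
  knots <- c(rep(interior[1L], degree), interior,
             rep(interior[length(interior)], degree))
  K <- length(knots) - degree - 1L
  # Greville abscissae: mean of the `degree` knots supporting coefficient k
  greville <- if (degree == 0L) {
    (knots[seq_len(K)] + knots[seq_len(K) + 1L]) / 2
  } else {
    vapply(seq_len(K), function(k) mean(knots[(k + 1L):(k + degree)]), 0)
  }
  k_star <- which.min(abs(greville - t_last))
  structure(list(region_id = region_id, degree = as.integer(degree),
                 knots = as.numeric(knots), interior = as.numeric(interior),
                 K = as.integer(K), k_star = as.integer(k_star),
                 t_last = as.integer(t_last), greville = greville,
                 year_start = as.integer(year_start),
                 year_end = as.integer(year_end)),
            class = "subshare_basis_spec")
}

#' @export
print.subshare_basis_spec <- function(x, ...) {
  cat(sprintf("basis spec [%s]: degree %d, K = %d, anchor year %d (k* = %d)\n",
              x$region_id, x$degree, x$K, x$t_last, x$k_star))
  cat("interior knots:", paste(x$interior, collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a B-spline basis on a year vector
#'
#' Standard B-spline basis (Cox--de Boor) of the spec's degree. Rows form a
#' partition of unity over the knot span, so a spline with equal
#' coefficients is constant.
#'
#' @param spec a `subshare_basis_spec`.
#' @param years numeric vector inside the boundary knots.
#' @return list of class `subshare_basis_matrix` with `region_id`, `years`
#'   and `values` (length(years) x K matrix, entries >= 0, rows summing
#'   to 1).
#' @export
evaluate_basis <- function(spec, years) {
  stopifnot(inherits(spec, "subshare_basis_spec"), is.numeric(years))
  lo <- spec$interior[1L]
  hi <- spec$interior[length(spec$interior)]
  if (any(years < lo) || any(years > hi)) {
    abort("evaluate_basis(): year(s) outside knot span [%s, %s]", lo, hi)
  }
  B <- splines::splineDesign(knots = spec$knots, x = years,
                             ord = spec$degree + 1L, outer.ok = FALSE)
  stopifnot(ncol(B) == spec$K)
  structure(list(region_id = spec$region_id, years = years, values = B),
            class = "subshare_basis_matrix")
}

#' Build per-region bases for a fitted hierarchy
#'
#' For every region: the basis spec anchored at that region's most recent
#' survey year, the basis evaluated on the full year grid, and the
#' increment-accumulation matrix used to reconstruct spline coefficients
#' from (proxy-intercept, increments).
#'
#' @param obs observation data frame (needs `country_id`, `region_id`,
#'   `year`).
#' @param hierarchy a `subshare_hierarchy`.
#' @param config a `subshare_config`.
#' @return named list (by region key) of lists with elements `spec`,
#'   `basis` (grid basis matrix) and `accum` (K x (K-1) matrix `A` such
#'   that `beta = alpha + A %*% delta`).
#' @export
build_region_bases <- function(obs, hierarchy, config) {
  stopifnot(inherits(hierarchy, "subshare_hierarchy"),
            inherits(config, "subshare_config"))
  keys <- region_key(obs$country_id, obs$region_id)
  grid <- seq.int(config$year_start, config$year_end)
  out <- lapply(hierarchy$regions, function(rk) {
    yrs <- obs$year[keys == rk]
    if (length(yrs) == 0L) abort("build_region_bases(): region %s has no observations", rk)
    spec <- build_basis_spec(rk, max(yrs), config$year_start, config$year_end,
                             config$spline_degree, config$knot_spacing_years)
    list(spec = spec,
         basis = evaluate_basis(spec, grid),
         accum = increment_accumulator(spec$K, spec$k_star))
  })
  names(out) <- hierarchy$regions
  out
}

#' Increment-accumulation matrix
#'
#' The K x (K-1) matrix `A` with `beta = alpha * 1 + A delta` encoding the
#' outward first-order recursion from the anchored coefficient `k_star`:
#' coefficients above the anchor add successive increments, coefficients
#' below subtract them.
#'
#' @param K number of basis coefficients.
#' @param k_star anchored coefficient index.
#' @return K x (K-1) numeric matrix of 0/±1 entries.
#' @export
increment_accumulator <- function(K, k_star) {
  stopifnot(is_count(K, 2L), is_count(k_star, 1L), k_star <= K)
  A <- matrix(0, nrow = K, ncol = K - 1L)
  for (k in seq_len(K)) {
    if (k > k_star) A[k, k_star:(k - 1L)] <- 1
    if (k < k_star) A[k, k:(k_star - 1L)] <- -1
  }
  A
}
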