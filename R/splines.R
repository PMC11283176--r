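#' Specification of a normalized B-spline basis
#'
#' Describes the basis used to approximate an index function: a polynomial
#' spline of order `order` (cubic by default) over the support `[a, b]` with
#' `n_interior` interior knots, giving `K = n_interior + order` basis
#' functions. Boundary knots are replicated to full multiplicity. The basis is
#' normalized so that the K functions sum to K at every point of the support.
#'
#' @param support Length-2 numeric, the interval `[a, b]`.
#' @param interior Nondecreasing numeric vector of interior knots strictly
#'   inside `(a, b)`; may be empty.
#' @param order Spline order (polynomial degree + 1); 4 = cubic.
#' @return An object of class `spline_spec` with elements `order`, `interior`,
#'   `support`, the padded knot vector `knots` and the basis dimension
#'   `n_basis`.
#' @export
spline_spec <- function(support, interior = numeric(0), order = 4) {
  support <- as.numeric(support)
  interior <- as.numeric(interior)
  if (length(support) != 2 || support[1] >= support[2]) {
    abort("support must be an interval [a, b] with a < b")
  }
  if (is.unsorted(interior)) abort("interior knots must be nondecreasing")
  if (length(interior) &&
      (min(interior) <= support[1] || max(interior) >= support[2])) {
    abort("interior knots must lie strictly inside the support")
  }
  if (order < 1) abort("order must be >= 1")
  structure(
    list(
      order = as.integer(order),
      interior = interior,
      support = support,
      knots = c(rep(support[1], order), interior, rep(support[2], order)),
      n_basis = length(interior) + as.integer(order)
    ),
    class = "spline_spec"
  )
}

# interior knots at equally spaced quantiles of the current index values;
# the knot count is fixed elsewhere (SIC), only the positions adapt
spec_from_index <- function(u, n_interior, order = 4) {
  rng <- range(u)
  if (n_interior > 0) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    interior <- as.numeric(quantile(u, probs, names = FALSE))
    interior <- pmin(pmax(interior, rng[1] + 1e-10), rng[2] - 1e-10)
  } else {
    interior <- numeric(0)
  }
  spline_spec(rng, interior, order)
}

#' Normalized B-spline design matrix
#'
#' Evaluates the K basis functions of `spec` at the index values `u`, scaled
#' so that every row sums to K. Values outside the support are clamped to the
#' boundary. Entries are computed by the Cox-de Boor recursion; at most
#' `order` entries per row are nonzero.
#'
#' @param u Numeric vector of index values.
#' @param spec A [spline_spec()].
#' @return A `length(u)` x `n_basis` matrix.
#' @export
bspline_design <- function(u, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  cpp_bspline(as.numeric(u), spec$knots, spec$order, 0L,
              as.numeric(spec$n_basis))
}

#' First-derivative B-spline design matrix
#'
#' Entrywise derivative of [bspline_design()] with the same K-scaling, used in
#' the Newton update of the index coefficients. Rows sum to zero (derivative
#' of the constant normalization).
#'
#' @inheritParams bspline_design
#' @return A `length(u)` x `n_basis` matrix of derivatives.
#' @export
bspline_deriv_design <- function(u, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  cpp_bspline(as.numeric(u), spec$knots, spec$order, 1L,
              as.numeric(spec$n_basis))
}

#' Candidate grid of interior-knot counts
#'
#' The integer grid from `ceiling(0.5 * Ns)` to
#' `floor(min(5 * Ns, sqrt(n)))` with `Ns = n^(1/(2s+1))`, the neighbourhood
#' of the rate-optimal knot count for an index function with smoothness `s`.
#'
#' @param n Number of subjects.
#' @param s Smoothness parameter (default 2).
#' @return Integer vector of candidate interior-knot counts (possibly empty).
#' @examples
#' knot_grid(200) # 2:14
#' @export
knot_grid <- function(n, s = 2) {
  ns <- n^(1 / (2 * s + 1))
  lo <- ceiling(0.5 * ns)
  hi <- floor(min(5 * ns, sqrt(n)))
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

#' Select the number of interior knots by a Schwarz information criterion
#'
#' Evaluates `SIC(K) = -loglik(K) + log(n) * 2K` over the [knot_grid()] and
#' returns the minimizing interior-knot count, shared by both index
#' functions. `loglik(K)` is the marginal log-likelihood of the model fitted
#' with K interior knots, as produced by `fitter`.
#'
#' @param data A data frame in the long clustered format (see
#'   [as_bvsim_data()]) or a `bvsim_data` object; only the subject count is
#'   used here.
#' @param fitter Function mapping an interior-knot count K to a list with at
#'   least an element `loglik` (the fitted marginal log-likelihood).
#' @param s Smoothness parameter for the candidate grid.
#' @return The selected K (integer) with attribute `"sic_table"`, a tibble of
#'   the K grid, log-likelihoods and SIC values. Ties favour the smaller K.
#'   An empty grid (tiny n) falls back to K = 1 with a warning.
#' @export
select_knots_sic <- function(data, fitter, s = 2) {
  data <- as_bvsim_data(data)
  grid <- knot_grid(data$n, s)
  if (!length(grid)) {
    warn("empty knot grid for this sample size; falling back to K = 1")
    return(structure(1L, sic_table = tibble(
      K = 1L, loglik = NA_real_, sic = NA_real_
    )))
  }
  ll <- vapply(grid, function(K) as.numeric(fitter(K)$loglik), numeric(1))
  sic <- -ll + log(data$n) * 2 * grid
  structure(grid[which.min(sic)],
            sic_table = tibble(K = grid, loglik = ll, sic = sic))
}
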