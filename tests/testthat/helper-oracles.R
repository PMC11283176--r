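# Independent oracles used across the suite. All of these deliberately avoid
# the package's own computational path: plain-R quadrature, stats::integrate,
# splines::splineDesign, optim and explicit loops.

# log K_nu(x) via the integral representation
# K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt
log_bessel_quad <- function(nu, x) {
  nu <- abs(nu)
  # integrate on the log scale relative to the maximum to avoid overflow
  f <- function(t) exp(-x * cosh(t) + x) * cosh(nu * t)
  log(stats::integrate(f, 0, 50, rel.tol = 1e-12,
                       subdivisions = 500L)$value) - x
}

# GIG moments by adaptive quadrature of v^(nu-1) exp(-(a v + b / v)/2),
# integrated on the log scale (v = mode * e^s) so that the extreme spikes at
# very small modes are resolved
gig_quad <- function(a, b, nu) {
  mode <- ((nu - 1) + sqrt((nu - 1)^2 + a * b)) / a
  lf <- function(v) (nu - 1) * log(v) - (a * v + b / v) / 2
  l0 <- lf(mode)
  g <- function(s) { # includes the Jacobian v = mode e^s
    v <- mode * exp(s)
    exp(lf(v) - l0) * v
  }
  z <- stats::integrate(g, -60, 60, rel.tol = 1e-12, subdivisions = 1000L)
  ev <- stats::integrate(function(s) mode * exp(s) * g(s), -60, 60,
                         rel.tol = 1e-12, subdivisions = 1000L)
  evi <- stats::integrate(function(s) g(s) / (mode * exp(s)), -60, 60,
                          rel.tol = 1e-12, subdivisions = 1000L)
  list(ev = ev$value / z$value, evinv = evi$value / z$value)
}

# multivariate normal density via Cholesky (no external packages)
dmvn_chol <- function(y, mu, S, log = FALSE) {
  ch <- chol(S)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  out <- -0.5 * sum(z^2) - sum(log(diag(ch))) -
    0.5 * length(mu) * log(2 * pi)
  if (log) out else exp(out)
}

# SALD density by quadrature of the Exp(1) variance-mean normal mixture
dsald_mixture_quad <- function(y, mu, Sigma, gamma) {
  f <- function(v) {
    vapply(v, function(vv) {
      dmvn_chol(y, mu + vv * gamma, vv * Sigma) * exp(-vv)
    }, numeric(1))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
}

# small clustered dataset for unit tests (fixed design, fast fits)
tiny_data <- function(n = 6, seed = 1) {
  generate_sim1(n, seed = seed)$data
}

# numerical maximization of the expected complete-data objective over one
# parameter block; used to cross-check the CM closed forms
q1_of <- function(data, params, bases, es) {
  bvsim:::q1_value(data, params, bases, es)
}
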