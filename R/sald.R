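#' Parameters of a multivariate shifted asymmetric Laplace distribution
#'
#' Bundles and validates the location vector `mu`, positive-definite scatter
#' matrix `Sigma` and skewness vector `gamma` of a d-dimensional shifted
#' asymmetric Laplace distribution (SALD). The SALD is the normal
#' variance-mean mixture \eqn{Y = \mu + V\gamma + \sqrt{V} Z} with
#' \eqn{V \sim Exp(1)} and \eqn{Z \sim N_d(0, \Sigma)}; it has mean
#' \eqn{\mu + \gamma} and covariance \eqn{\Sigma + \gamma\gamma^T}, and its
#' density involves the modified Bessel function of the third kind of order
#' \eqn{\nu = (2 - d)/2}.
#'
#' @param mu Numeric location vector of length d.
#' @param Sigma d x d symmetric positive-definite scatter matrix.
#' @param gamma Numeric skewness vector of length d (zeros give the symmetric
#'   multivariate Laplace distribution).
#' @return An object of class `sald_params` with elements `mu`, `Sigma`,
#'   `gamma`, the dimension `d` and the Bessel order `nu`.
#' @examples
#' sald_params(c(0, 0), diag(2), c(2, 1.5))
#' @export
sald_params <- function(mu, Sigma, gamma) {
  mu <- as.numeric(mu)
  gamma <- as.numeric(gamma)
  Sigma <- as.matrix(Sigma)
  d <- length(mu)
  if (length(gamma) != d || nrow(Sigma) != d || ncol(Sigma) != d) {
    abort("mu, gamma and Sigma dimensions must agree")
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * (1 + max(abs(Sigma)))) {
    abort("Sigma must be symmetric")
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
    abort("Sigma must be positive definite with condition number below 1e12")
  }
  structure(
    list(mu = mu, Sigma = Sigma, gamma = gamma, d = d, nu = (2 - d) / 2),
    class = "sald_params"
  )
}

#' Logarithm of the modified Bessel function of the third kind
#'
#' Computes \eqn{\log K_\nu(x)} on the log scale so that ratios
#' \eqn{K_{\nu+1}(x) / K_\nu(x)} never overflow, even for the large negative
#' integer orders \eqn{\nu = 1 - m} that arise from clusters with m members.
#' Uses the exponentially scaled Bessel function, falling back to the
#' small-argument expansion \eqn{K_\nu(x) \approx \Gamma(|\nu|)(2/x)^{|\nu|}/2}
#' where the scaled value overflows.
#'
#' @param nu Real order (the function is symmetric in the sign of `nu`).
#' @param x Positive argument; vectorized, recycled against `nu`.
#' @return Numeric vector of \eqn{\log K_\nu(x)} values.
#' @examples
#' log_bessel_k(0.5, 1) # log(sqrt(pi / 2) * exp(-1))
#' @export
log_bessel_k <- function(nu, x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("log_bessel_k: x must be finite and > 0")
  }
  as.numeric(cpp_log_bessel_k(as.numeric(nu), as.numeric(x)))
}

# internal: quadratic forms and density pieces shared by dsald
sald_core <- function(y, p) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  if (ncol(y) != p$d) abort("y must have d columns")
  Sinv <- chol2inv(chol(p$Sigma))
  centred <- sweep(y, 2, p$mu)
  delta <- rowSums((centred %*% Sinv) * centred)
  list(
    Sinv = Sinv,
    cross = as.numeric(centred %*% Sinv %*% p$gamma),
    delta = pmax(delta, 1e-10), # limiting form at y = mu, where K_nu diverges
    a = 2 + as.numeric(crossprod(p$gamma, Sinv %*% p$gamma)),
    logdet = 2 * sum(log(diag(chol(p$Sigma))))
  )
}

#' Density of the multivariate shifted asymmetric Laplace distribution
#'
#' @param y Numeric vector of length d, or a matrix with one point per row.
#' @param params A [sald_params()] object.
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @examples
#' p <- sald_params(c(0, 0), diag(2), c(0, 0))
#' dsald(c(0.3, -0.2), p)
#' @export
dsald <- function(y, params, log = FALSE) {
  stopifnot(inherits(params, "sald_params"))
  q <- sald_core(y, params)
  u <- sqrt(q$a * q$delta)
  out <- base::log(2) + q$cross - (params$d / 2) * log(2 * pi) -
    0.5 * q$logdet +
    (params$nu / 2) * (base::log(q$delta) - base::log(q$a)) +
    log_bessel_k(params$nu, u)
  if (log) out else exp(out)
}

#' Sample from the multivariate shifted asymmetric Laplace distribution
#'
#' Draws via the stochastic representation
#' \eqn{Y = \mu + V\gamma + \sqrt{V}Z}, \eqn{V \sim Exp(1)},
#' \eqn{Z \sim N_d(0, \Sigma)}.
#'
#' @param n Number of draws.
#' @param params A [sald_params()] object.
#' @param seed Optional integer; when supplied the draw is made on a local,
#'   restored RNG stream so repeated calls are bit-identical and the caller's
#'   RNG state is untouched.
#' @return An `n` x `d` matrix, one draw per row.
#' @examples
#' rsald(5, sald_params(c(0, 0), diag(2), c(2, 1.5)), seed = 1)
#' @export
rsald <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "sald_params"), n >= 1)
  draw <- function() {
    v <- rexp(n)
    z <- matrix(rnorm(n * params$d), n, params$d) %*% chol(params$Sigma)
    sweep(outer(v, params$gamma) + sqrt(v) * z, 2, params$mu, `+`)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Mean and covariance of a SALD
#'
#' @param params A [sald_params()] object.
#' @return A list with `mean` (\eqn{\mu + \gamma}) and `cov`
#'   (\eqn{\Sigma + \gamma\gamma^T}).
#' @export
sald_moments <- function(params) {
  stopifnot(inherits(params, "sald_params"))
  list(
    mean = params$mu + params$gamma,
    cov = params$Sigma + tcrossprod(params$gamma)
  )
}

#' Conditional moments of the mixing variable given the observation
#'
#' For a SALD observation y the latent exponential mixing variable V has a
#' generalized inverse Gaussian (GIG) conditional distribution with density
#' proportional to \eqn{v^{\nu - 1} \exp\{-(a v + b / v)/2\}}, where
#' \eqn{a = 2 + \gamma^T\Sigma^{-1}\gamma}, \eqn{b} is the Mahalanobis
#' quadratic form of y, and \eqn{\nu = (2 - d)/2}. Its first and inverse
#' moments, \eqn{E[V | y] = \sqrt{b/a}\, R_\nu(\sqrt{ab})} and
#' \eqn{E[V^{-1} | y] = \sqrt{a/b}\, R_\nu(\sqrt{ab}) - 2\nu/b} with
#' \eqn{R_\nu(u) = K_{\nu+1}(u)/K_\nu(u)}, drive the E-step of the ECM
#' algorithm. `b` is floored at 1e-10, where the small-argument Bessel branch
#' reproduces the GIG small-b limit.
#'
#' @param a Positive scalar or vector.
#' @param b Nonnegative scalar or vector.
#' @param nu Real order (recycled).
#' @return A tibble with columns `a`, `b`, `nu`, `ev` (\eqn{E[V|y]}) and
#'   `evinv` (\eqn{E[V^{-1}|y]}); always `ev * evinv >= 1`.
#' @examples
#' gig_moments(2, 1, -0.5)
#' @export
gig_moments <- function(a, b, nu) {
  if (any(a <= 0)) abort("gig_moments: a must be > 0")
  if (any(b < 0)) abort("gig_moments: b must be >= 0")
  len <- max(length(a), length(b), length(nu))
  a <- rep_len(as.numeric(a), len)
  b <- rep_len(as.numeric(b), len)
  nu <- rep_len(as.numeric(nu), len)
  mom <- cpp_gig_moments(a, b, nu)
  tibble(a = a, b = b, nu = nu, ev = mom$ev, evinv = mom$evinv)
}
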