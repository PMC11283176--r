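#' Control settings for the ECM fit
#'
#' @param max_iter Maximum number of outer ECM iterations.
#' @param tol_param Relative-change convergence tolerance,
#'   `max(|new - old| / (|old| + 1e-4)) < tol_param`.
#' @param tol_loglik Absolute tolerance on the change of the marginal
#'   log-likelihood.
#' @param newton_max Inner Newton-Raphson iterations for the index
#'   coefficients per CM-step 3.
#' @param refresh_knots Track the moving index support: recompute the spline
#'   support and quantile knots after the index-coefficient update (the knot
#'   count never changes), refitting the spline coefficients; the refresh is
#'   accepted only if it does not lower the marginal log-likelihood.
#' @param refresh_every Refresh period in iterations (the first few
#'   iterations, where the index moves most, always refresh).
#' @param seed Optional integer seed for any randomized restart (unused by
#'   the deterministic default path; recorded for reproducibility).
#' @param verbose Print the log-likelihood each iteration?
#' @return A list of class `bvsim_control`.
#' @export
bvsim_control <- function(max_iter = 500, tol_param = 1e-6,
                          tol_loglik = 1e-8, newton_max = 10,
                          refresh_knots = TRUE, refresh_every = 10,
                          seed = NULL, verbose = FALSE) {
  stopifnot(max_iter >= 1, tol_param > 0, tol_loglik > 0, newton_max >= 1,
            refresh_every >= 1)
  structure(
    list(max_iter = as.integer(max_iter), tol_param = tol_param,
         tol_loglik = tol_loglik, newton_max = as.integer(newton_max),
         refresh_knots = isTRUE(refresh_knots),
         refresh_every = as.integer(refresh_every), seed = seed,
         verbose = isTRUE(verbose)),
    class = "bvsim_control"
  )
}

pd_floor_r <- function(M, floor_ev = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor_ev) return(M)
  M <- e$vectors %*% diag(pmax(e$values, floor_ev),
                          length(e$values)) %*% t(e$vectors)
  (M + t(M)) / 2
}

# Per-response Gaussian LMM slopes and random-effect covariances used to
# start the ECM; falls back to ordinary least squares with identity Omega.
init_lmm <- function(data) {
  one <- function(yk, X, Zfree) {
    p <- ncol(X); q <- ncol(Zfree) - 1
    df <- data.frame(.y = yk, X, check.names = FALSE)
    xn <- paste0(".x", seq_len(p)); names(df)[-1] <- xn
    df$.subject <- data$subject_of_row
    zn <- character(0)
    if (q > 0) {
      zn <- paste0(".z", seq_len(q))
      df[zn] <- Zfree[, -1, drop = FALSE]
    }
    re <- if (q > 0) paste("(1 +", paste(zn, collapse = " + "), "| .subject)")
          else "(1 | .subject)"
    form <- stats::as.formula(
      paste(".y ~ 0 +", paste(xn, collapse = " + "), "+", re))
    fallback <- function() {
      list(beta = stats::coef(stats::lm.fit(X, yk)), Om = diag(q + 1),
           fallback = TRUE)
    }
    tryCatch({
      fit <- suppressWarnings(suppressMessages(lme4::lmer(
        form, data = df,
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore"))))
      Om <- as.matrix(lme4::VarCorr(fit)$.subject)
      attributes(Om)[c("stddev", "correlation")] <- NULL
      b <- lme4::fixef(fit)
      if (!all(is.finite(b)) || !all(is.finite(Om))) stop("non-finite")
      list(beta = as.numeric(b), Om = Om, fallback = FALSE)
    }, error = function(e) fallback())
  }
  unitize <- function(b) {
    b[!is.finite(b)] <- 0
    if (sum(b^2) < 1e-12) b <- c(1, rep(0, length(b) - 1))
    b <- b / sqrt(sum(b^2))
    if (b[1] < 0) b <- -b
    if (b[1] < 1e-6) { # keep strictly inside the identifiable region
      b[1] <- 1e-6
      b <- b / sqrt(sum(b^2))
    }
    b
  }
  f1 <- one(data$y[, 1], data$X1, data$Z1)
  f2 <- one(data$y[, 2], data$X2, data$Z2)
  r1 <- ncol(data$Z1); r2 <- ncol(data$Z2)
  Omega0 <- matrix(0, r1 + r2, r1 + r2)
  Omega0[1:r1, 1:r1] <- f1$Om
  Omega0[(r1 + 1):(r1 + r2), (r1 + 1):(r1 + r2)] <- f2$Om
  list(beta1 = unitize(f1$beta), beta2 = unitize(f2$beta),
       Omega = pd_floor_r(Omega0, 1e-4),
       fallback = f1$fallback || f2$fallback)
}

#' Initial parameter values for the ECM algorithm
#'
#' Sets \eqn{\gamma^{(0)} = (0, 0)^T} and \eqn{\Sigma^{(0)} = I_2}; the index
#' coefficients come from per-response Gaussian linear mixed model slopes
#' normalized to unit norm with positive first component, the random-effects
#' covariance from the stacked LMM estimates (cross-response blocks zero),
#' and the spline coefficients from a least-squares regression of each
#' response on its initial spline design.
#'
#' @inheritParams compute_mu
#' @param n_interior Number of interior knots (shared by both functions).
#' @param order Spline order (4 = cubic).
#' @return A list with `params` ([bvsim_params()]) and `bases`.
#' @export
bvsim_init <- function(data, n_interior, order = 4) {
  data <- as_bvsim_data(data)
  lmm <- init_lmm(data)
  build_init(data, lmm, n_interior, order)
}

build_init <- function(data, lmm, n_interior, order) {
  b1 <- spec_from_index(as.numeric(data$X1 %*% lmm$beta1), n_interior, order)
  b2 <- spec_from_index(as.numeric(data$X2 %*% lmm$beta2), n_interior, order)
  ls_theta <- function(spec, u, y) {
    th <- stats::lm.fit(bspline_design(u, spec), y)$coefficients
    th[!is.finite(th)] <- 0
    as.numeric(th)
  }
  th1 <- ls_theta(b1, as.numeric(data$X1 %*% lmm$beta1), data$y[, 1])
  th2 <- ls_theta(b2, as.numeric(data$X2 %*% lmm$beta2), data$y[, 2])
  params <- bvsim_params(lmm$beta1, lmm$beta2, th1, th2,
                         gamma = c(0, 0), Sigma = diag(2),
                         Omega = lmm$Omega)
  list(params = params, bases = list(b1 = b1, b2 = b2),
       init_fallback = lmm$fallback)
}

#' E-step posterior summaries
#'
#' Computes, for every subject, the conditional posterior pieces of the
#' random effect and of the latent exponential mixing variable at the current
#' parameters: \eqn{\Delta_i = (\Omega^{-1} + Z_i\Lambda^{-1}Z_i^T)^{-1}},
#' \eqn{R_{i1} = \Delta_i Z_i \Lambda^{-1}(y_i - W_i^T\theta)},
#' \eqn{R_{i2} = \Delta_i Z_i \Lambda^{-1}\gamma_i^*}, and the GIG moments
#' \eqn{c_i = E[V_i | y_i]}, \eqn{d_i = E[V_i^{-1} | y_i]} with
#' \eqn{a_i = 2 + \gamma^{*T} G_i^{-1}\gamma^*},
#' \eqn{b_i = (y_i - \mu_i)^T G_i^{-1} (y_i - \mu_i)} and order
#' \eqn{\nu = 1 - m_i}. The per-subject marginal SALD log-likelihood falls
#' out of the same computation.
#'
#' @inheritParams compute_mu
#' @param mu Optional precomputed [compute_mu()] result (re-used by the fit
#'   loop).
#' @return A list with `Delta` (r x r x n array), `R1`, `R2` (r x n
#'   matrices), the GIG inputs `a`, `b`, the moments `c`, `d`, and the
#'   per-subject log-likelihood contributions `loglik`.
#' @export
e_step <- function(data, params, bases, mu = NULL) {
  data <- as_bvsim_data(data)
  if (is.null(mu)) mu <- compute_mu(data, params, bases)
  cpp_estep(data$y - mu$mu, data$Z1, data$Z2, data$start0, data$m,
            params$Sigma, params$Omega, params$gamma)
}

#' Conditional-maximization updates
#'
#' The five CM updates of the ECM algorithm, each maximizing the expected
#' complete-data log-likelihood over one block with the others fixed:
#' `cm_update_theta()` solves the generalized least-squares system for the
#' spline coefficients; `cm_update_gamma()` is the closed form for the
#' skewness vector; `cm_update_beta()` runs safeguarded Newton-Raphson on the
#' delete-one-component index coefficients; `cm_update_sigma()` and
#' `cm_update_omega()` are the expected sufficient-statistic updates of the
#' scatter matrices (symmetrized, eigenvalues floored at 1e-8).
#'
#' @inheritParams e_step
#' @param estep The current [e_step()] fields.
#' @param control A [bvsim_control()] (only `newton_max` is used here).
#' @return `cm_update_theta()`: list with `theta1`, `theta2`;
#'   `cm_update_gamma()`: length-2 vector; `cm_update_beta()`: list with
#'   `beta1`, `beta2`, the attained `q1` and inner-iteration diagnostics;
#'   `cm_update_sigma()` / `cm_update_omega()`: the updated matrix.
#' @name cm_updates
NULL

#' @rdname cm_updates
#' @export
cm_update_theta <- function(data, params, bases, estep, mu = NULL) {
  data <- as_bvsim_data(data)
  if (is.null(mu)) mu <- compute_mu(data, params, bases)
  th <- cpp_cm_theta(data$y, mu$B1, mu$B2, data$Z1, data$Z2, data$start0,
                     data$m, params$Sigma, params$gamma, estep$R1, estep$R2,
                     estep$c, estep$d)
  K1 <- bases$b1$n_basis
  list(theta1 = th[seq_len(K1)], theta2 = th[-seq_len(K1)])
}

#' @rdname cm_updates
#' @export
cm_update_gamma <- function(data, params, bases, estep, mu = NULL) {
  data <- as_bvsim_data(data)
  if (is.null(mu)) mu <- compute_mu(data, params, bases)
  as.numeric(cpp_cm_gamma(data$y - mu$mu, data$Z1, data$Z2, data$start0,
                          data$m, estep$R1, estep$R2, estep$c))
}

#' @rdname cm_updates
#' @export
cm_update_beta <- function(data, params, bases, estep,
                           control = bvsim_control()) {
  data <- as_bvsim_data(data)
  res <- cpp_cm_beta(data$y, data$X1, data$X2, data$Z1, data$Z2, data$start0,
                     data$m, params$beta1, params$beta2, params$theta1,
                     params$theta2, bases$b1$knots, bases$b2$knots,
                     bases$b1$order, params$Sigma, params$gamma, estep$Delta,
                     estep$R1, estep$R2, estep$c, estep$d,
                     control$newton_max)
  res$beta1 <- as.numeric(res$beta1)
  res$beta2 <- as.numeric(res$beta2)
  res
}

#' @rdname cm_updates
#' @export
cm_update_sigma <- function(data, params, bases, estep, mu = NULL) {
  data <- as_bvsim_data(data)
  if (is.null(mu)) mu <- compute_mu(data, params, bases)
  cpp_cm_sigma(data$y - mu$mu, data$Z1, data$Z2, data$start0, data$m,
               params$gamma, estep$Delta, estep$R1, estep$R2,
               estep$c, estep$d)
}

#' @rdname cm_updates
#' @export
cm_update_omega <- function(estep) {
  cpp_cm_omega(estep$Delta, estep$R1, estep$R2, estep$c, estep$d)
}

# Expected complete-data objective for the (beta, theta, gamma, Sigma) block,
# exposed for the optimizer cross-checks.
q1_value <- function(data, params, bases, estep, mu = NULL) {
  data <- as_bvsim_data(data)
  if (is.null(mu)) mu <- compute_mu(data, params, bases)
  cpp_q1(data$y - mu$mu, data$Z1, data$Z2, data$start0, data$m, params$Sigma,
         params$gamma, estep$Delta, estep$R1, estep$R2, estep$c, estep$d)
}

q2_value <- function(Omega, estep) {
  cpp_q2(Omega, estep$Delta, estep$R1, estep$R2, estep$c, estep$d)
}

flatten_params <- function(p) {
  c(p$beta1, p$beta2, p$theta1, p$theta2, p$gamma,
    p$Sigma[upper.tri(p$Sigma, diag = TRUE)],
    p$Omega[upper.tri(p$Omega, diag = TRUE)])
}

# Move the spline support/knots to the index values implied by the new beta
# and refit theta; accepted only if the marginal log-likelihood does not
# drop (a basis change alters the approximating model, so the usual ECM
# ascent guarantee does not cover it).
refresh_basis <- function(data, params, bases, estep) {
  order <- bases$b1$order
  nb <- list(
    b1 = spec_from_index(as.numeric(data$X1 %*% params$beta1),
                         length(bases$b1$interior), order),
    b2 = spec_from_index(as.numeric(data$X2 %*% params$beta2),
                         length(bases$b2$interior), order)
  )
  cand <- params
  th <- cm_update_theta(data, params, nb, estep)
  cand$theta1 <- th$theta1; cand$theta2 <- th$theta2
  ll_new <- sum(e_step(data, cand, nb)$loglik)
  ll_old <- sum(e_step(data, params, bases)$loglik)
  if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) {
    list(params = cand, bases = nb)
  } else {
    list(params = params, bases = bases)
  }
}

ecm_run <- function(data, n_interior, order, control, lmm) {
  ini <- build_init(data, lmm, n_interior, order)
  params <- ini$params
  bases <- ini$bases
  trace <- numeric(0)
  converged <- FALSE
  prev_vec <- NULL
  es <- NULL
  for (it in seq_len(control$max_iter)) {
    mu <- compute_mu(data, params, bases)
    es <- e_step(data, params, bases, mu)
    ll <- sum(es$loglik)
    if (length(trace) && ll < trace[length(trace)] - 1e-6) {
      abort(sprintf(
        "ECM divergence: log-likelihood dropped from %.8f to %.8f at iteration %d",
        trace[length(trace)], ll, it), class = "bvsim_divergence")
    }
    ll_prev <- if (length(trace)) trace[length(trace)] else NA_real_
    trace <- c(trace, ll)
    if (control$verbose) message(sprintf("iter %d loglik %.6f", it, ll))

    th <- cm_update_theta(data, params, bases, es, mu)
    params$theta1 <- th$theta1; params$theta2 <- th$theta2
    mu <- compute_mu(data, params, bases)
    params$gamma <- cm_update_gamma(data, params, bases, es, mu)
    bu <- cm_update_beta(data, params, bases, es, control)
    params$beta1 <- bu$beta1; params$beta2 <- bu$beta2
    if (control$refresh_knots &&
        (it <= 5 || it %% control$refresh_every == 0)) {
      rf <- refresh_basis(data, params, bases, es)
      params <- rf$params; bases <- rf$bases
    }
    mu <- compute_mu(data, params, bases)
    params$Sigma <- cm_update_sigma(data, params, bases, es, mu)
    params$Omega <- cm_update_omega(es)

    vec <- flatten_params(params)
    if (!is.null(prev_vec)) {
      rel <- max(abs(vec - prev_vec) / (abs(prev_vec) + 1e-4))
      dll <- abs(ll - ll_prev)
      if (rel < control$tol_param || dll < control$tol_loglik) {
        converged <- TRUE
        break
      }
    }
    prev_vec <- vec
  }
  mu <- compute_mu(data, params, bases)
  es <- e_step(data, params, bases, mu)
  trace <- c(trace, sum(es$loglik))
  structure(
    list(params = params, bases = bases, logLik = sum(es$loglik),
         trace = trace, iterations = length(trace) - 1L,
         converged = converged, K = as.integer(n_interior),
         order = as.integer(order), estep = es, data = data,
         control = control, init_fallback = ini$init_fallback, sic = NULL),
    class = "bvsim_fit"
  )
}

#' Fit the bivariate single-index mixed-effects model
#'
#' Maximum-likelihood estimation by an ECM algorithm: the E-step computes the
#' generalized inverse Gaussian conditional moments of the latent mixing
#' variable and the posterior moments of the random effects; the CM steps
#' update the spline coefficients, the skewness vector, the index
#' coefficients (Newton-Raphson with step-halving), the error scatter matrix
#' and the random-effects covariance in turn. The marginal log-likelihood is
#' non-decreasing across iterations.
#'
#' @param data Long-format data frame (see [as_bvsim_data()]) or a
#'   `bvsim_data` object.
#' @param knots Number of interior knots shared by the two index functions,
#'   or `NULL` to select it once on the initialized fit by the Schwarz
#'   criterion ([select_knots_sic()]).
#' @param order Spline order (4 = cubic).
#' @param s Smoothness parameter for the knot grid when `knots = NULL`.
#' @param control A [bvsim_control()].
#' @return An object of class `bvsim_fit` with the estimated parameters, the
#'   spline bases, the log-likelihood trace, convergence diagnostics, the
#'   final E-step posterior summaries and (when selected) the SIC table.
#'   Supports [tidy()][generics::tidy()], [glance()][generics::glance()],
#'   [predict()], [ggplot2::autoplot()] and [bvsim_bootstrap()].
#' @examples
#' \donttest{
#' sim <- generate_sim1(30, seed = 1)
#' fit <- bvsim(sim$data, knots = 2,
#'              control = bvsim_control(max_iter = 50))
#' glance(fit)
#' }
#' @export
bvsim <- function(data, knots = NULL, order = 4, s = 2,
                  control = bvsim_control()) {
  data <- as_bvsim_data(data)
  lmm <- init_lmm(data)
  if (is.null(knots)) {
    cache <- new.env(parent = emptyenv())
    fitter <- function(K) {
      f <- ecm_run(data, K, order, control, lmm)
      assign(as.character(K), f, envir = cache)
      list(fit = f, loglik = f$logLik)
    }
    Ksel <- select_knots_sic(data, fitter, s)
    fit <- get(as.character(as.integer(Ksel)), envir = cache)
    fit$sic <- attr(Ksel, "sic_table")
    fit
  } else {
    ecm_run(data, knots, order, control, lmm)
  }
}
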