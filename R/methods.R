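#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' @export
print.bvsim_fit <- function(x, ...) {
  cat("Bivariate single-index mixed-effects model (SALD random terms)\n")
  cat(sprintf("  subjects: %d   members: %d   interior knots: %d (order %d)\n",
              x$data$n, x$data$N, x$K, x$order))
  cat(sprintf("  logLik: %.4f after %d ECM iterations (%s)\n", x$logLik,
              x$iterations, if (x$converged) "converged" else "not converged"))
  cat("  beta1: ", paste(sprintf("%.4f", x$params$beta1), collapse = " "), "\n")
  cat("  beta2: ", paste(sprintf("%.4f", x$params$beta2), collapse = " "), "\n")
  cat("  gamma: ", paste(sprintf("%.4f", x$params$gamma), collapse = " "), "\n")
  invisible(x)
}

# scalar parameter vector with stable names; used by tidy(), the bootstrap
# and the simulation report
param_vector <- function(p) {
  vech_names <- function(M, nm) {
    idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
    setNames(M[upper.tri(M, diag = TRUE)],
             paste0(nm, "_", idx[, 1], idx[, 2]))
  }
  c(setNames(p$beta1, paste0("beta1_", seq_along(p$beta1))),
    setNames(p$beta2, paste0("beta2_", seq_along(p$beta2))),
    setNames(p$gamma, paste0("gamma_", seq_along(p$gamma))),
    vech_names(p$Sigma, "Sigma"),
    vech_names(p$Omega, "Omega"))
}

#' Tidy the estimated parameters of a fit
#'
#' @param x A `bvsim_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` covering the index
#'   coefficients, skewness vector and the unique entries of the scatter and
#'   random-effects covariance matrices.
#' @method tidy bvsim_fit
#' @export
tidy.bvsim_fit <- function(x, ...) {
  v <- param_vector(x$params)
  tibble(term = names(v), estimate = as.numeric(v))
}

#' One-row summary of a fit
#'
#' @param x A `bvsim_fit`.
#' @param ... Unused.
#' @return A tibble with the log-likelihood, subject and member counts, knot
#'   count, iteration count and convergence flag.
#' @method glance bvsim_fit
#' @export
glance.bvsim_fit <- function(x, ...) {
  tibble(logLik = x$logLik, n = x$data$n, N = x$data$N, K = x$K,
         iterations = x$iterations, converged = x$converged)
}

# posterior mean of the random effect of each subject, E[b_i | y_i]
posterior_ranef <- function(fit) {
  t(fit$estep$R1 - sweep(fit$estep$R2, 2, fit$estep$c, `*`))
}

# evaluate an estimated index function on new index values (clamped)
eval_g <- function(fit, which, u) {
  spec <- if (which == 1) fit$bases$b1 else fit$bases$b2
  theta <- if (which == 1) fit$params$theta1 else fit$params$theta2
  as.numeric(bspline_design(u, spec) %*% theta)
}

#' Fitted and predicted values
#'
#' `type = "conditional"` adds the estimated subject random effects
#' \eqn{E[b_i | y_i]} (only available for the training subjects);
#' `type = "marginal"` predicts unseen subjects with random effects at their
#' prior mean zero. In both cases the error mean \eqn{\gamma} is added when
#' `include_gamma = TRUE`, since \eqn{E(Y) = \mu + \gamma} under the SALD.
#'
#' @param object A `bvsim_fit`.
#' @param newdata Optional long-format data frame; defaults to the training
#'   data.
#' @param type `"conditional"` or `"marginal"`.
#' @param include_gamma Add the estimated error mean \eqn{\hat\gamma}?
#' @param ... Unused.
#' @return An N x 2 matrix of fitted/predicted response pairs.
#' @export
predict.bvsim_fit <- function(object, newdata = NULL,
                              type = c("conditional", "marginal"),
                              include_gamma = TRUE, ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else as_bvsim_data(newdata)
  mu <- compute_mu(data, object$params, object$bases)$mu
  out <- mu
  if (include_gamma) out <- sweep(out, 2, object$params$gamma, `+`)
  if (type == "conditional") {
    if (!is.null(newdata)) {
      abort("conditional predictions are only defined for the training data")
    }
    b <- posterior_ranef(object)
    r1 <- ncol(data$Z1)
    for (i in seq_len(data$n)) {
      rows <- (data$start0[i] + 1):(data$start0[i] + data$m[i])
      out[rows, 1] <- out[rows, 1] +
        data$Z1[rows, , drop = FALSE] %*% b[i, 1:r1]
      out[rows, 2] <- out[rows, 2] +
        data$Z2[rows, , drop = FALSE] %*% b[i, -(1:r1)]
    }
  }
  out
}

#' Augment the training data with fits and residuals
#'
#' @param x A `bvsim_fit`.
#' @param ... Unused.
#' @return The training tibble plus `.index1`, `.index2`, `.fitted1`,
#'   `.fitted2`, `.resid1`, `.resid2` (conditional fits including the
#'   estimated random effects and error mean).
#' @method augment bvsim_fit
#' @export
augment.bvsim_fit <- function(x, ...) {
  mu <- compute_mu(x$data, x$params, x$bases)
  f <- predict(x)
  dplyr::mutate(x$data$df,
                .index1 = mu$u1, .index2 = mu$u2,
                .fitted1 = f[, 1], .fitted2 = f[, 2],
                .resid1 = x$data$y[, 1] - f[, 1],
                .resid2 = x$data$y[, 2] - f[, 2])
}

#' Plot the estimated index functions
#'
#' Draws \eqn{\hat g_1} and \eqn{\hat g_2} over their index supports, with
#' the member-level partial responses (response minus estimated random
#' effect and error mean) as points.
#'
#' @param object A `bvsim_fit`.
#' @param points Overlay partial residual points?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bvsim_fit
#' @export
autoplot.bvsim_fit <- function(object, points = TRUE, ...) {
  grid_tbl <- purrr::map_dfr(1:2, function(k) {
    spec <- if (k == 1) object$bases$b1 else object$bases$b2
    u <- seq(spec$support[1], spec$support[2], length.out = 200)
    tibble(response = paste0("g", k), u = u, g = eval_g(object, k, u))
  })
  p <- ggplot2::ggplot(grid_tbl, ggplot2::aes(x = .data$u, y = .data$g))
  if (points) {
    mu <- compute_mu(object$data, object$params, object$bases)
    f <- predict(object)
    pts <- dplyr::bind_rows(
      tibble(response = "g1", u = mu$u1,
             g = object$data$y[, 1] - (f[, 1] - mu$mu[, 1])),
      tibble(response = "g2", u = mu$u2,
             g = object$data$y[, 2] - (f[, 2] - mu$mu[, 2]))
    )
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.25, size = 0.6)
  }
  p + ggplot2::geom_line(linewidth = 0.9, colour = "#2166ac") +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = "index u", y = "estimated index function")
}

#' Plot the log-likelihood trace of the ECM iterations
#'
#' @param fit A `bvsim_fit`.
#' @return A ggplot object.
#' @export
plot_trace <- function(fit) {
  tbl <- tibble(iteration = seq_along(fit$trace) - 1, logLik = fit$trace)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$iteration, y = .data$logLik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "ECM iteration", y = "marginal log-likelihood")
}

#' Serialize a fit to a structured text report
#'
#' Writes parameter estimates, the log-likelihood trace, convergence
#' diagnostics and the selected knot count as plain text (JSON).
#'
#' @param fit A `bvsim_fit`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, file) {
  rep <- list(
    estimates = as.list(param_vector(fit$params)),
    theta1 = fit$params$theta1, theta2 = fit$params$theta2,
    knots = list(K = fit$K, order = fit$order,
                 interior1 = fit$bases$b1$interior,
                 interior2 = fit$bases$b2$interior,
                 support1 = fit$bases$b1$support,
                 support2 = fit$bases$b2$support),
    logLik = fit$logLik, trace = fit$trace,
    iterations = fit$iterations, converged = fit$converged
  )
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
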