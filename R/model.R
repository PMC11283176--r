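#' Assemble clustered bivariate data from a long-format data frame
#'
#' The expected columns are `subject`, the paired responses `y1`, `y2`, the
#' index covariates `x1_1 .. x1_p1` and `x2_1 .. x2_p2` for the two
#' responses, and optionally the random-effect covariates `z1_1 .. z1_q1`,
#' `z2_1 .. z2_q2`. A leading intercept column is added internally to each
#' random-effect design (it is never stored in the file/table). Missing
#' values are forbidden: the model supports complete cases only. Rows are
#' grouped by subject in order of first appearance; within-subject order is
#' preserved.
#'
#' @param df A data frame/tibble in the long format above, or an existing
#'   `bvsim_data` object (returned unchanged).
#' @return An object of class `bvsim_data`: the tibble plus the member-level
#'   matrices `y` (N x 2), `X1`, `X2`, `Z1`, `Z2` (with intercept), subject
#'   labels, cluster sizes `m`, and the counts `n`, `N`, `p1`, `p2`, `q1`,
#'   `q2`.
#' @export
as_bvsim_data <- function(df) {
  if (inherits(df, "bvsim_data")) return(df)
  df <- as_tibble(df)
  need <- c("subject", "y1", "y2")
  if (!all(need %in% names(df))) {
    abort("data must contain columns 'subject', 'y1' and 'y2'")
  }
  pick <- function(prefix) {
    nm <- grep(paste0("^", prefix, "_[0-9]+$"), names(df), value = TRUE)
    nm[order(as.integer(sub(paste0(prefix, "_"), "", nm)))]
  }
  x1n <- pick("x1"); x2n <- pick("x2"); z1n <- pick("z1"); z2n <- pick("z2")
  if (!length(x1n) || !length(x2n)) {
    abort("data must contain index covariate columns x1_* and x2_*")
  }
  num_cols <- c("y1", "y2", x1n, x2n, z1n, z2n)
  bad <- num_cols[!vapply(df[num_cols], is.numeric, logical(1))]
  if (length(bad)) abort(paste("non-numeric columns:", toString(bad)))
  if (anyNA(df[c("subject", num_cols)])) {
    abort("missing values are not allowed (complete-case analysis only)")
  }
  df <- df[order(match(df$subject, unique(df$subject))), , drop = FALSE]
  sub <- as.character(df$subject)
  m <- as.integer(table(factor(sub, levels = unique(sub))))
  structure(
    list(
      df = df,
      y = cbind(y1 = df$y1, y2 = df$y2),
      X1 = as.matrix(df[x1n]),
      X2 = as.matrix(df[x2n]),
      Z1 = cbind(`(Intercept)` = 1, as.matrix(df[z1n])),
      Z2 = cbind(`(Intercept)` = 1, as.matrix(df[z2n])),
      subject = unique(sub),
      subject_of_row = sub,
      m = m,
      start0 = as.integer(c(0L, cumsum(m)[-length(m)])),
      n = length(m),
      N = nrow(df),
      p1 = length(x1n), p2 = length(x2n),
      q1 = length(z1n), q2 = length(z2n)
    ),
    class = "bvsim_data"
  )
}

#' @export
print.bvsim_data <- function(x, ...) {
  cat(sprintf(
    "<bvsim_data> %d subjects, %d members (m: %d-%d), p = (%d, %d), q = (%d, %d)\n",
    x$n, x$N, min(x$m), max(x$m), x$p1, x$p2, x$q1, x$q2
  ))
  invisible(x)
}

#' Read / write clustered bivariate data as delimited text
#'
#' Thin wrappers around [readr::read_delim()] / [readr::write_delim()] for the
#' long-format column contract of [as_bvsim_data()]. A header row is
#' required; UTF-8; missing values are rejected.
#'
#' @param file Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @return `read_bvsim_data()` returns a `bvsim_data` object;
#'   `write_bvsim_data()` returns the file path invisibly.
#' @export
read_bvsim_data <- function(file, delim = ",") {
  df <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_bvsim_data(df)
}

#' @param data A `bvsim_data` object or compatible data frame.
#' @rdname read_bvsim_data
#' @export
write_bvsim_data <- function(data, file, delim = ",") {
  df <- if (inherits(data, "bvsim_data")) data$df else as_tibble(data)
  readr::write_delim(df, file, delim = delim)
  invisible(file)
}

#' Delete-one-component parametrization of a unit index vector
#'
#' Reconstructs the unit-norm coefficient vector
#' \eqn{\beta = (\sqrt{1 - \|\beta_{(-1)}\|^2},\ \beta_{(-1)})} from its free
#' last p-1 components, together with the Jacobian
#' \eqn{J = \partial\beta / \partial\beta_{(-1)}} (first row
#' \eqn{-\beta_{(-1)}^T / \sqrt{1 - \|\beta_{(-1)}\|^2}}, identity below).
#' This removes both the norm constraint and the positive-first-component
#' sign constraint from the optimization.
#'
#' @param beta_minus1 Numeric vector of length p - 1 with norm < 1.
#' @return A list with the unit vector `beta` (length p) and the p x (p-1)
#'   matrix `jacobian`.
#' @export
full_beta <- function(beta_minus1) {
  beta_minus1 <- as.numeric(beta_minus1)
  s2 <- sum(beta_minus1^2)
  if (s2 >= 1) abort("||beta_minus1|| must be < 1 (interior of the unit ball)")
  s <- sqrt(1 - s2)
  list(
    beta = c(s, beta_minus1),
    jacobian = rbind(-beta_minus1 / s, diag(length(beta_minus1)))
  )
}

#' Parameters of the bivariate single-index mixed-effects model
#'
#' @param beta1,beta2 Unit-norm index coefficient vectors with positive first
#'   component.
#' @param theta1,theta2 Spline coefficient vectors for the two index
#'   functions.
#' @param gamma Length-2 skewness vector of the error distribution.
#' @param Sigma 2 x 2 positive-definite error scatter matrix.
#' @param Omega Positive-definite covariance matrix of the stacked random
#'   effects, dimension (q1 + q2 + 2).
#' @return An object of class `bvsim_params`.
#' @export
bvsim_params <- function(beta1, beta2, theta1, theta2, gamma, Sigma, Omega) {
  beta1 <- as.numeric(beta1); beta2 <- as.numeric(beta2)
  for (b in list(beta1, beta2)) {
    if (abs(sum(b^2) - 1) > 1e-8) abort("index vectors must have unit norm")
    if (b[1] <= 0) abort("first index component must be positive")
  }
  check_pd <- function(M, nm) {
    M <- as.matrix(M)
    if (max(abs(M - t(M))) > 1e-8 * (1 + max(abs(M)))) {
      abort(paste(nm, "must be symmetric"))
    }
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      abort(paste(nm, "must be positive definite"))
    }
    M
  }
  structure(
    list(
      beta1 = beta1, beta2 = beta2,
      theta1 = as.numeric(theta1), theta2 = as.numeric(theta2),
      gamma = as.numeric(gamma),
      Sigma = check_pd(Sigma, "Sigma"), Omega = check_pd(Omega, "Omega")
    ),
    class = "bvsim_params"
  )
}

#' Member-level index means and spline designs
#'
#' Evaluates \eqn{\mu_{ij} = (B_1(x_{ij}^{(1)T}\beta_1)^T\theta_1,\
#' B_2(x_{ij}^{(2)T}\beta_2)^T\theta_2)} for every cluster member, together
#' with the stacked spline design blocks used throughout the ECM updates.
#'
#' @param data Long-format data frame or `bvsim_data`.
#' @param params A [bvsim_params()] object.
#' @param bases List with spline specs `b1`, `b2` (see [spline_spec()]).
#' @return A list with `mu` (N x 2 matrix), the design matrices `B1`
#'   (N x K1) and `B2` (N x K2), and the index values `u1`, `u2`.
#' @export
compute_mu <- function(data, params, bases) {
  data <- as_bvsim_data(data)
  u1 <- as.numeric(data$X1 %*% params$beta1)
  u2 <- as.numeric(data$X2 %*% params$beta2)
  B1 <- bspline_design(u1, bases$b1)
  B2 <- bspline_design(u2, bases$b2)
  list(
    mu = cbind(as.numeric(B1 %*% params$theta1),
               as.numeric(B2 %*% params$theta2)),
    B1 = B1, B2 = B2, u1 = u1, u2 = u2
  )
}

# internal: r x 2m random-effect design of one subject, column pair per member
subject_Z <- function(data, i) {
  s <- data$start0[i]; mi <- data$m[i]
  r1 <- ncol(data$Z1); r2 <- ncol(data$Z2)
  Z <- matrix(0, r1 + r2, 2 * mi)
  for (j in seq_len(mi)) {
    Z[1:r1, 2 * j - 1] <- data$Z1[s + j, ]
    Z[(r1 + 1):(r1 + r2), 2 * j] <- data$Z2[s + j, ]
  }
  Z
}

#' Marginal log-likelihood of the model
#'
#' Each subject's stacked response is marginally shifted asymmetric Laplace,
#' \eqn{y_i \sim SALD_{2m_i}(\mu_i, G_i, \gamma_i^*)} with
#' \eqn{G_i = Z_i^T \Omega Z_i + I_{m_i} \otimes \Sigma} and
#' \eqn{\gamma_i^* = 1_{m_i} \otimes \gamma}; the marginal log-likelihood is
#' the sum of the corresponding SALD log densities. This reference
#' implementation assembles each \eqn{G_i} explicitly and evaluates
#' [dsald()]; the fitting loop uses an algebraically identical Woodbury form.
#'
#' @inheritParams compute_mu
#' @return The scalar log-likelihood.
#' @export
marginal_loglik <- function(data, params, bases) {
  data <- as_bvsim_data(data)
  mu <- compute_mu(data, params, bases)$mu
  ll <- 0
  for (i in seq_len(data$n)) {
    s <- data$start0[i]; mi <- data$m[i]
    rows <- (s + 1):(s + mi)
    Zi <- subject_Z(data, i)
    Gi <- crossprod(Zi, params$Omega %*% Zi) +
      kronecker(diag(mi), params$Sigma)
    yi <- as.numeric(t(data$y[rows, , drop = FALSE]))
    mui <- as.numeric(t(mu[rows, , drop = FALSE]))
    gi <- rep(params$gamma, mi)
    ll <- ll + dsald(yi, sald_params(mui, Gi, gi), log = TRUE)
  }
  ll
}
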