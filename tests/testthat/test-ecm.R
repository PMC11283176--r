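# fixtures shared by the ECM tests: a small dataset with generic (non-special)
# parameter values so every term of the objective is exercised
ecm_fixture <- function(n = 8, seed = 3) {
  d <- generate_sim1(n, seed = seed)$data
  ini <- bvsim_init(d, n_interior = 1)
  p <- ini$params
  p$gamma <- c(0.5, -0.3)
  p$Sigma <- matrix(c(1.3, 0.3, 0.3, 0.9), 2)
  list(d = d, p = p, b = ini$bases, es = e_step(d, p, ini$bases))
}

test_that("initialization honours the prescribed starting values", {
  d <- tiny_data(8, seed = 2)
  ini <- bvsim_init(d, n_interior = 2)
  expect_equal(ini$params$gamma, c(0, 0))
  expect_equal(ini$params$Sigma, diag(2))
  expect_equal(sum(ini$params$beta1^2), 1, tolerance = 1e-10)
  expect_gt(ini$params$beta1[1], 0)
  expect_gt(ini$params$beta2[1], 0)
  # spline start equals the least-squares solution of the design regression
  u1 <- as.numeric(d$X1 %*% ini$params$beta1)
  B1 <- bspline_design(u1, ini$bases$b1)
  th_ref <- qr.solve(crossprod(B1), crossprod(B1, d$y[, 1]))
  expect_equal(ini$params$theta1, as.numeric(th_ref), tolerance = 1e-8)
})

test_that("initialization recovers the direction of a linear index", {
  # y exactly linear in x' beta with i.i.d. noise: LMM slopes align with beta
  withr::with_seed(11, {
    n <- 60; m <- 4
    sub <- rep(1:n, each = m)
    X <- matrix(runif(n * m * 3), n * m, 3)
    beta <- c(2, 1, 1) / sqrt(6)
    df <- tibble::tibble(
      subject = sub,
      y1 = 3 * as.numeric(X %*% beta) + rnorm(n * m, 0, 0.1),
      y2 = 2 * as.numeric(X %*% beta) + rnorm(n * m, 0, 0.1),
      x1_1 = X[, 1], x1_2 = X[, 2], x1_3 = X[, 3],
      x2_1 = X[, 1], x2_2 = X[, 2], x2_3 = X[, 3],
      z1_1 = rnorm(n * m), z2_1 = rnorm(n * m)
    )
    ini <- bvsim_init(as_bvsim_data(df), n_interior = 1)
    expect_equal(ini$params$beta1, beta, tolerance = 0.05)
    expect_equal(ini$params$beta2, beta, tolerance = 0.05)
  })
})

test_that("E-step fields match their definitions computed in plain R", {
  fx <- ecm_fixture()
  d <- fx$d; p <- fx$p; es <- fx$es
  mu <- compute_mu(d, p, fx$b)$mu
  Omi <- solve(p$Omega)
  Lami_inv1 <- solve(p$Sigma)
  for (i in c(1, d$n)) {
    rows <- (d$start0[i] + 1):(d$start0[i] + d$m[i])
    Zi <- bvsim:::subject_Z(d, i)
    Lam_inv <- kronecker(diag(d$m[i]), Lami_inv1)
    Delta_ref <- solve(Omi + Zi %*% Lam_inv %*% t(Zi))
    expect_equal(es$Delta[, , i], Delta_ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
    ri <- as.numeric(t(d$y[rows, ] - mu[rows, ]))
    gi <- rep(p$gamma, d$m[i])
    expect_equal(es$R1[, i],
                 as.numeric(Delta_ref %*% Zi %*% Lam_inv %*% ri),
                 tolerance = 1e-9)
    expect_equal(es$R2[, i],
                 as.numeric(Delta_ref %*% Zi %*% Lam_inv %*% gi),
                 tolerance = 1e-9)
    # a_i, b_i through the explicit G_i inverse
    Gi <- crossprod(Zi, p$Omega %*% Zi) + kronecker(diag(d$m[i]), p$Sigma)
    expect_equal(es$a[i], 2 + as.numeric(t(gi) %*% solve(Gi, gi)),
                 tolerance = 1e-9)
    expect_equal(es$b[i], as.numeric(t(ri) %*% solve(Gi, ri)),
                 tolerance = 1e-9)
    # c_i, d_i are the GIG conditional moments at (a_i, b_i, 1 - m_i)
    want <- gig_quad(es$a[i], es$b[i], 1 - d$m[i])
    expect_equal(es$c[i], want$ev, tolerance = 1e-8)
    expect_equal(es$d[i], want$evinv, tolerance = 1e-8)
  }
  expect_true(all(es$c * es$d >= 1 - 1e-10))
})

test_that("posterior mixing moments match direct quadrature on a tiny case", {
  # n = 2 subjects, one member each, intercept-only random effects
  df <- generate_sim1(3, seed = 13)$data$df
  df <- df[!duplicated(df$subject), c("subject", "y1", "y2",
                                      "x1_1", "x1_2", "x1_3",
                                      "x2_1", "x2_2", "x2_3")]
  d <- as_bvsim_data(df)
  expect_equal(d$q1, 0)
  ini <- bvsim_init(d, n_interior = 1)
  p <- ini$params
  p$gamma <- c(1, 0.5)
  es <- e_step(d, p, ini$bases)
  for (i in 1:2) {
    want <- gig_quad(es$a[i], es$b[i], 1 - d$m[i])
    expect_equal(es$c[i], want$ev, tolerance = 1e-8)
    expect_equal(es$d[i], want$evinv, tolerance = 1e-8)
  }
})

test_that("a diffuse random-effects prior collapses Delta to the data term", {
  fx <- ecm_fixture()
  p <- fx$p
  p$Omega <- diag(4) * 1e8
  es <- e_step(fx$d, p, fx$b)
  d <- fx$d
  for (i in 1:2) {
    Zi <- bvsim:::subject_Z(d, i)
    Lam_inv <- kronecker(diag(d$m[i]), solve(p$Sigma))
    expect_equal(es$Delta[, , i], solve(Zi %*% Lam_inv %*% t(Zi)),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("each CM closed form maximizes its conditional objective", {
  fx <- ecm_fixture()
  d <- fx$d; p <- fx$p; b <- fx$b; es <- fx$es
  q1 <- function(pp) q1_of(d, pp, b, es)

  # CM-step 1: spline coefficients
  th <- cm_update_theta(d, p, b, es)
  K1 <- length(p$theta1)
  o <- optim(c(p$theta1, p$theta2), function(v) {
    pp <- p; pp$theta1 <- v[1:K1]; pp$theta2 <- v[-(1:K1)]; -q1(pp)
  }, method = "BFGS", control = list(maxit = 3000, reltol = 1e-15))
  expect_equal(c(th$theta1, th$theta2), o$par, tolerance = 1e-5)
  pth <- p; pth$theta1 <- th$theta1; pth$theta2 <- th$theta2
  expect_gte(q1(pth), q1(p) - 1e-10) # ascent
  # Gaussian degenerate case: d = 1, R = 0, gamma = 0 reduces to WLS
  es0 <- es
  es0$d <- rep(1, d$n); es0$R1[] <- 0; es0$R2[] <- 0
  p0 <- p; p0$gamma <- c(0, 0)
  th0 <- cm_update_theta(d, p0, b, es0)
  mu <- compute_mu(d, p, b)
  Sinv <- solve(p$Sigma)
  # WLS normal equations with metric Sigma^-1 across the two responses
  G <- matrix(0, K1 + length(p$theta2), K1 + length(p$theta2))
  rhs <- numeric(nrow(G))
  i1 <- 1:K1; i2 <- (K1 + 1):nrow(G)
  G[i1, i1] <- Sinv[1, 1] * crossprod(mu$B1)
  G[i1, i2] <- Sinv[1, 2] * crossprod(mu$B1, mu$B2)
  G[i2, i1] <- t(G[i1, i2])
  G[i2, i2] <- Sinv[2, 2] * crossprod(mu$B2)
  rhs[i1] <- crossprod(mu$B1, d$y %*% Sinv[, 1])
  rhs[i2] <- crossprod(mu$B2, d$y %*% Sinv[, 2])
  expect_equal(c(th0$theta1, th0$theta2), as.numeric(solve(G, rhs)),
               tolerance = 1e-8)

  # CM-step 2: skewness
  g <- cm_update_gamma(d, p, b, es)
  og <- optim(p$gamma, function(v) {
    pp <- p; pp$gamma <- v; -q1(pp)
  }, method = "BFGS", control = list(reltol = 1e-15))
  expect_equal(g, og$par, tolerance = 1e-6)
  pg <- p; pg$gamma <- g
  expect_gte(q1(pg), q1(p) - 1e-10)

  # CM-step 4: error scatter (3 free entries via log-Cholesky)
  S <- cm_update_sigma(d, p, b, es)
  os <- optim(c(0, 0, 0), function(v) {
    L <- matrix(c(exp(v[1]), v[3], 0, exp(v[2])), 2)
    pp <- p; pp$Sigma <- tcrossprod(L); -q1(pp)
  }, method = "BFGS", control = list(maxit = 3000, reltol = 1e-15))
  L <- matrix(c(exp(os$par[1]), os$par[3], 0, exp(os$par[2])), 2)
  expect_equal(S, tcrossprod(L), tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(S, t(S), tolerance = 1e-12)

  # CM-step 5: random-effects covariance via Q2
  Om <- cm_update_omega(es)
  q2 <- function(O) bvsim:::q2_value(O, es)
  idx <- upper.tri(Om, diag = TRUE)
  ch0 <- chol(Om)
  oo <- optim(ch0[idx], function(v) {
    C <- matrix(0, 4, 4); C[idx] <- v
    O <- crossprod(C)
    if (min(diag(O)) < 1e-10) return(1e10)
    -q2(O)
  }, method = "BFGS", control = list(maxit = 5000, reltol = 1e-15))
  C <- matrix(0, 4, 4); C[idx] <- oo$par
  expect_equal(Om, crossprod(C), tolerance = 1e-5, ignore_attr = TRUE)
  # algebraic reduction: R1 = R2 = 0 gives the mean of the Delta_i
  esr <- es
  esr$R1[] <- 0; esr$R2[] <- 0
  expect_equal(cm_update_omega(esr),
               apply(es$Delta, c(1, 2), mean), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the Newton update maximizes Q1 over the index coefficients", {
  fx <- ecm_fixture()
  d <- fx$d; p <- fx$p; es <- fx$es
  # bases whose support covers every reachable index value (|x' beta| <=
  # ||x|| <= sqrt(3)): no clamping, so Q1 is smooth in beta and the Newton
  # solution must agree with a numerical maximizer
  b <- list(b1 = spline_spec(c(-1.8, 1.8), c(0.4), order = 4),
            b2 = spline_spec(c(-1.8, 1.8), c(0.8), order = 4))
  th <- cm_update_theta(d, p, b, es)
  p$theta1 <- th$theta1; p$theta2 <- th$theta2
  q1 <- function(pp) q1_of(d, pp, b, es)
  up <- cm_update_beta(d, p, b, es, bvsim_control(newton_max = 50))
  pb <- p; pb$beta1 <- up$beta1; pb$beta2 <- up$beta2
  expect_gte(q1(pb), q1(p) - 1e-10) # ascent from the start point
  qfree <- function(v) {
    pp <- p
    pp$beta1 <- c(sqrt(1 - sum(v[1:2]^2)), v[1:2])
    pp$beta2 <- c(sqrt(1 - sum(v[3:4]^2)), v[3:4])
    q1(pp)
  }
  vstar <- c(up$beta1[-1], up$beta2[-1])
  # finite-difference gradient vanishes at the returned point
  h <- 1e-5
  grad <- vapply(1:4, function(j) {
    e <- numeric(4); e[j] <- h
    (qfree(vstar + e) - qfree(vstar - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad)), 1e-3)
  # a numerical optimizer started there cannot improve Q1
  polish <- optim(vstar, function(v) -qfree(v), method = "Nelder-Mead",
                  control = list(maxit = 4000, reltol = 1e-13))
  expect_lte(-polish$value - qfree(vstar), 1e-5)
  expect_equal(vstar, polish$par, tolerance = 1e-3)
  # fixed point: starting at the maximizer, the update stays put
  pstar <- p
  pstar$beta1 <- c(sqrt(1 - sum(polish$par[1:2]^2)), polish$par[1:2])
  pstar$beta2 <- c(sqrt(1 - sum(polish$par[3:4]^2)), polish$par[3:4])
  up2 <- cm_update_beta(d, pstar, b, es, bvsim_control(newton_max = 5))
  expect_equal(up2$beta1, pstar$beta1, tolerance = 1e-4)
  expect_equal(up2$beta2, pstar$beta2, tolerance = 1e-4)
  # construction keeps the unit norm and the sign constraint
  expect_equal(sum(up$beta1^2), 1, tolerance = 1e-12)
  expect_gte(up$beta1[1], 0)
  # under the standard clamped basis the update still ascends
  upc <- cm_update_beta(d, fx$p, fx$b, es, bvsim_control())
  pc <- fx$p
  pc$beta1 <- upc$beta1; pc$beta2 <- upc$beta2
  expect_gte(q1_of(d, pc, fx$b, es), q1_of(d, fx$p, fx$b, es) - 1e-10)
})

test_that("the ECM log-likelihood trace never decreases", {
  for (seed in 1:6) {
    g <- if (seed %% 2) generate_sim1(12, seed = seed)
         else generate_sim2(12, case = (seed %% 4) + 1, seed = seed)
    fit <- bvsim(g$data, knots = 2,
                 control = bvsim_control(max_iter = 40))
    expect_true(all(diff(fit$trace) >= -1e-8),
                label = sprintf("monotone trace (seed %d)", seed))
  }
})

test_that("fitted parameters are invariant to subject relabelling", {
  g <- generate_sim1(12, seed = 21)
  d <- g$data
  ctrl <- bvsim_control(max_iter = 150)
  fit1 <- bvsim(d, knots = 2, control = ctrl)
  perm <- withr::with_seed(99, sample(seq_len(d$n)))
  rows <- unlist(lapply(perm, function(i) {
    (d$start0[i] + 1):(d$start0[i] + d$m[i])
  }))
  fit2 <- bvsim(d$df[rows, ], knots = 2, control = ctrl)
  expect_equal(fit2$params$beta1, fit1$params$beta1, tolerance = 1e-6)
  expect_equal(fit2$params$beta2, fit1$params$beta2, tolerance = 1e-6)
  expect_equal(fit2$params$gamma, fit1$params$gamma, tolerance = 1e-5)
  expect_equal(fit2$logLik, fit1$logLik, tolerance = 1e-6)
})

test_that("fit() selects knots by SIC when none are given", {
  g <- generate_sim1(14, seed = 31)
  fit <- bvsim(g$data, control = bvsim_control(max_iter = 40))
  expect_s3_class(fit$sic, "tbl_df")
  expect_true(fit$K %in% knot_grid(14))
  expect_equal(fit$sic$K[which.min(fit$sic$sic)], fit$K)
  # the chosen K beats both grid endpoints on SIC
  expect_lte(min(fit$sic$sic), fit$sic$sic[1])
  expect_lte(min(fit$sic$sic), fit$sic$sic[nrow(fit$sic)])
})

test_that("fit object methods expose the results coherently", {
  g <- generate_sim1(10, seed = 41)
  fit <- bvsim(g$data, knots = 2, control = bvsim_control(max_iter = 60))
  td <- tidy(fit)
  expect_true(all(c("beta1_1", "beta2_3", "gamma_2", "Sigma_12",
                    "Omega_44") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n, 10)
  expect_equal(gl$K, 2L)
  aug <- augment(fit)
  expect_equal(nrow(aug), fit$data$N)
  expect_equal(aug$.resid1, fit$data$y[, 1] - aug$.fitted1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_trace(fit), "ggplot")
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$knots$K, fit$K)
  expect_length(rep$trace, length(fit$trace))
})
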