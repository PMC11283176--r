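test_that("long-format assembly validates and structures the data", {
  d <- tiny_data(5, seed = 1)
  expect_s3_class(d, "bvsim_data")
  expect_equal(d$n, 5)
  expect_equal(sum(d$m), d$N)
  expect_true(all(d$Z1[, 1] == 1))
  expect_true(all(d$Z2[, 1] == 1))
  expect_equal(ncol(d$X1), 3)
  # idempotent
  expect_identical(as_bvsim_data(d), d)
  # subjects grouped in order of first appearance, within-subject order kept
  shuffled <- d$df[sample(nrow(d$df)), ]
  d2 <- as_bvsim_data(shuffled)
  expect_equal(sort(d2$m), sort(d$m))
  expect_equal(d2$N, d$N)

  bad <- d$df
  bad$y1[3] <- NA
  expect_error(as_bvsim_data(bad), "complete-case")
  expect_error(as_bvsim_data(d$df[, setdiff(names(d$df), "x1_2")]),
               NA) # dropping one x column just lowers p1
  expect_error(as_bvsim_data(d$df[, setdiff(names(d$df), "y2")]), "y2")
})

test_that("delimited round trip preserves the data", {
  d <- tiny_data(4, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_bvsim_data(d, f)
  d2 <- read_bvsim_data(f)
  expect_equal(d2$y, d$y, tolerance = 1e-12)
  expect_equal(d2$X1, d$X1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d2$m, d$m)
})

test_that("delete-one-component map is a unit-norm chart with exact Jacobian", {
  # origin of the unit ball
  fb <- full_beta(c(0, 0))
  expect_equal(fb$beta, c(1, 0, 0))
  expect_equal(fb$jacobian, rbind(0, diag(2)), ignore_attr = TRUE)
  # unit norm everywhere; Jacobian vs central differences
  withr::with_seed(3, {
    for (rep in 1:5) {
      v <- runif(3, -0.4, 0.4)
      fb <- full_beta(v)
      expect_equal(sum(fb$beta^2), 1, tolerance = 1e-12)
      h <- 1e-6
      fd <- vapply(seq_along(v), function(j) {
        e <- numeric(length(v)); e[j] <- h
        (full_beta(v + e)$beta - full_beta(v - e)$beta) / (2 * h)
      }, numeric(length(v) + 1))
      expect_equal(fb$jacobian, fd, tolerance = 1e-6, ignore_attr = TRUE)
    }
  })
  expect_error(full_beta(c(0.9, 0.5)), "unit ball")
})

test_that("index means follow the spline evaluation and W structure", {
  d <- tiny_data(4, seed = 4)
  ini <- bvsim_init(d, n_interior = 2)
  p <- ini$params
  mu <- compute_mu(d, p, ini$bases)
  # pointwise independent evaluation via splineDesign
  B1_ref <- splines::splineDesign(ini$bases$b1$knots, pmin(pmax(mu$u1,
    ini$bases$b1$support[1]), ini$bases$b1$support[2]), ord = 4) *
    ini$bases$b1$n_basis
  expect_equal(mu$mu[, 1], as.numeric(B1_ref %*% p$theta1), tolerance = 1e-10)
  # zero coefficients give zero means
  p0 <- p
  p0$theta1 <- p$theta1 * 0
  p0$theta2 <- p$theta2 * 0
  expect_equal(compute_mu(d, p0, ini$bases)$mu, matrix(0, d$N, 2),
               ignore_attr = TRUE)
  # order-1, single basis function: constant means (theta1, theta2)
  b1 <- spline_spec(range(mu$u1), numeric(0), order = 1)
  b2 <- spline_spec(range(mu$u2), numeric(0), order = 1)
  pc <- p
  pc$theta1 <- 2.5
  pc$theta2 <- -1
  muc <- compute_mu(d, pc, list(b1 = b1, b2 = b2))
  expect_equal(unique(muc$mu[, 1]), 2.5)
  expect_equal(unique(muc$mu[, 2]), -1)
})

test_that("marginal log-likelihood matches its reductions and quadrature", {
  # m_i = 1 throughout, negligible Omega: sum of member-wise SALD densities
  df <- generate_sim1(8, seed = 5)$data$df
  df1 <- df[!duplicated(df$subject), ] # one member per subject
  d1 <- as_bvsim_data(df1)
  ini <- bvsim_init(d1, n_interior = 1)
  p <- ini$params
  p$gamma <- c(0.8, -0.3)
  p$Sigma <- matrix(c(1.2, 0.3, 0.3, 0.9), 2)
  p$Omega <- diag(4) * 1e-10
  mu <- compute_mu(d1, p, ini$bases)$mu
  direct <- sum(vapply(seq_len(d1$N), function(j) {
    dsald(d1$y[j, ], sald_params(mu[j, ], p$Sigma, p$gamma), log = TRUE)
  }, numeric(1)))
  expect_equal(marginal_loglik(d1, p, ini$bases), direct, tolerance = 1e-6)

  # m_i = 2: quadrature over the mixing variable of the hierarchical normal
  df2 <- dplyr::slice_head(dplyr::group_by(df, subject), n = 2)
  d2 <- as_bvsim_data(dplyr::ungroup(df2))
  ini2 <- bvsim_init(d2, n_interior = 1)
  p2 <- ini2$params
  p2$gamma <- c(0.5, 0.2)
  p2$Omega <- sim1_truth()$Omega / 4
  mu2 <- compute_mu(d2, p2, ini2$bases)$mu
  ll_quad <- 0
  for (i in seq_len(d2$n)) {
    rows <- (d2$start0[i] + 1):(d2$start0[i] + d2$m[i])
    Zi <- bvsim:::subject_Z(d2, i)
    Gi <- crossprod(Zi, p2$Omega %*% Zi) + kronecker(diag(d2$m[i]), p2$Sigma)
    yi <- as.numeric(t(d2$y[rows, ]))
    mui <- as.numeric(t(mu2[rows, ]))
    gi <- rep(p2$gamma, d2$m[i])
    f <- function(v) {
      vapply(v, function(vv) {
        dmvn_chol(yi, mui + vv * gi, vv * Gi) * exp(-vv)
      }, numeric(1))
    }
    ll_quad <- ll_quad +
      log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
  }
  expect_equal(marginal_loglik(d2, p2, ini2$bases), ll_quad, tolerance = 1e-6)
})

test_that("marginal log-likelihood is invariant where the model says so", {
  d <- tiny_data(5, seed = 6)
  ini <- bvsim_init(d, n_interior = 1)
  p <- ini$params
  ll <- marginal_loglik(d, p, ini$bases)
  # subject reordering
  perm <- c(3, 1, 5, 2, 4)
  rows <- unlist(lapply(perm, function(i) {
    (d$start0[i] + 1):(d$start0[i] + d$m[i])
  }))
  dperm <- as_bvsim_data(d$df[rows, ])
  expect_equal(marginal_loglik(dperm, p, ini$bases), ll, tolerance = 1e-10)
  # location equivariance: theta + c shifts g by c * K (rows sum to K)
  cshift <- 0.7
  K1 <- ini$bases$b1$n_basis
  p2 <- p
  p2$theta1 <- p$theta1 + cshift
  d2 <- d
  d2$y[, 1] <- d2$y[, 1] + cshift * K1
  expect_equal(marginal_loglik(d2, p2, ini$bases), ll, tolerance = 1e-8)
  # fast Woodbury path in the E-step agrees with the direct assembly
  es <- e_step(d, p, ini$bases)
  expect_equal(sum(es$loglik), ll, tolerance = 1e-8)
})

test_that("subject scatter G_i matches brute-force construction and is p.d.", {
  d <- tiny_data(4, seed = 8)
  tr <- sim1_truth()
  for (i in seq_len(d$n)) {
    Zi <- bvsim:::subject_Z(d, i)
    Gi <- crossprod(Zi, tr$Omega %*% Zi) + kronecker(diag(d$m[i]), tr$Sigma)
    # brute force from the member-level blockdiag definition
    rows <- (d$start0[i] + 1):(d$start0[i] + d$m[i])
    Gref <- kronecker(diag(d$m[i]), tr$Sigma)
    for (j in seq_along(rows)) {
      for (k in seq_along(rows)) {
        Zj <- cbind(c(d$Z1[rows[j], ], 0, 0), c(0, 0, d$Z2[rows[j], ]))
        Zk <- cbind(c(d$Z1[rows[k], ], 0, 0), c(0, 0, d$Z2[rows[k], ]))
        Gref[(2 * j - 1):(2 * j), (2 * k - 1):(2 * k)] <-
          Gref[(2 * j - 1):(2 * j), (2 * k - 1):(2 * k)] +
          t(Zj) %*% tr$Omega %*% Zk
      }
    }
    expect_equal(Gi, Gref, tolerance = 1e-12)
    expect_gt(min(eigen(Gi, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("parameter container enforces the identifiability constraints", {
  tr <- sim1_truth()
  ok <- bvsim_params(tr$beta1, tr$beta2, 1:6, 1:6, tr$gamma, tr$Sigma,
                     tr$Omega)
  expect_s3_class(ok, "bvsim_params")
  expect_error(bvsim_params(c(1, 1, 1), tr$beta2, 1, 1, tr$gamma, tr$Sigma,
                            tr$Omega), "unit norm")
  expect_error(bvsim_params(-tr$beta1, tr$beta2, 1, 1, tr$gamma, tr$Sigma,
                            tr$Omega), "positive")
  expect_error(bvsim_params(tr$beta1, tr$beta2, 1, 1, tr$gamma,
                            matrix(c(1, 2, 2, 1), 2), tr$Omega),
               "positive definite")
})
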