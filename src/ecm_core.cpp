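// Core numerical kernels for the bivariate single-index mixed-effects model:
// normalized B-spline evaluation (Cox-de Boor), log modified Bessel K,
// generalized inverse Gaussian conditional moments, the ECM E-step with
// Woodbury-form SALD marginal log-likelihood, the conditional-maximization
// closed forms, and the Newton update for the index coefficients. Member
// sums are organised as subject-block matrix products.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// log K_nu(x), finite over x in (1e-12, 1e6), |nu| <= 200.
// Exponentially scaled evaluation; when the scaled value overflows (x << nu)
// fall back to the small-argument form K_nu(x) ~ 0.5 * Gamma(nu) * (2/x)^nu.
// ---------------------------------------------------------------------------
static double log_bessel_k_scalar(double nu, double x) {
  nu = std::fabs(nu);
  if (!(x > 0.0)) Rcpp::stop("log_bessel_k: x must be > 0");
  double k = R::bessel_k(x, nu, 2.0); // e^x * K_nu(x)
  if (R_finite(k) && k > 0.0) return std::log(k) - x;
  if (nu > 0.0)
    return -M_LN2 + R::lgammafn(nu) + nu * (M_LN2 - std::log(x));
  // nu == 0, tiny x: K_0(x) ~ -log(x/2) - euler_gamma
  return std::log(-std::log(0.5 * x) - 0.57721566490153286);
}

// [[Rcpp::export]]
NumericVector cpp_log_bessel_k(NumericVector nu, NumericVector x) {
  int n = std::max(nu.size(), x.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = log_bessel_k_scalar(nu[i % nu.size()], x[i % x.size()]);
  return out;
}

// E[V | y] and E[V^-1 | y] for V | y ~ GIG with parameters (a, b, nu):
// density ~ v^(nu-1) exp(-(a v + b / v) / 2).
static void gig_moments_scalar(double a, double b, double nu,
                               double& ev, double& evinv) {
  if (!(a > 0.0)) Rcpp::stop("gig moments: a must be > 0");
  if (b < 1e-10) b = 1e-10; // floor; small-b limit enters through log K branch
  double u = std::sqrt(a * b);
  double lk = log_bessel_k_scalar(nu, u);
  ev = std::sqrt(b / a) * std::exp(log_bessel_k_scalar(nu + 1.0, u) - lk);
  // direct moment form sqrt(a/b) K_{nu-1}/K_nu: identical to the recurrence
  // form sqrt(a/b) K_{nu+1}/K_nu - 2 nu / b but free of its cancellation
  evinv = std::sqrt(a / b) * std::exp(log_bessel_k_scalar(nu - 1.0, u) - lk);
}

// [[Rcpp::export]]
List cpp_gig_moments(NumericVector a, NumericVector b, NumericVector nu) {
  int n = a.size();
  NumericVector ev(n), evinv(n);
  for (int i = 0; i < n; ++i) {
    double e1, e2;
    gig_moments_scalar(a[i], b[i], nu[i % nu.size()], e1, e2);
    ev[i] = e1; evinv[i] = e2;
  }
  return List::create(_["ev"] = ev, _["evinv"] = evinv);
}

// ---------------------------------------------------------------------------
// B-splines. Knot vector t has length K + order with boundary knots
// replicated to full multiplicity: t[0..order-1] = a, t[K..K+order-1] = b.
// ---------------------------------------------------------------------------
static int find_span(double x, const arma::vec& t, int order, int K) {
  if (x >= t(K)) return K - 1;
  if (x <= t(order - 1)) return order - 1;
  int lo = order - 1, hi = K;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (t(mid) <= x) lo = mid; else hi = mid;
  }
  return lo;
}

// de Boor triangular scheme: values of the `ord` basis functions of order
// `ord` that are nonzero on the span `mu`, i.e. indices mu-ord+1 .. mu.
static void basis_funs(int mu, double x, int ord, const arma::vec& t,
                       double* N) {
  double left[16], right[16];
  N[0] = 1.0;
  for (int j = 1; j < ord; ++j) {
    left[j] = x - t(mu + 1 - j);
    right[j] = t(mu + j) - x;
    double saved = 0.0;
    for (int r = 0; r < j; ++r) {
      double den = right[r + 1] + left[j - r];
      double term = (den != 0.0) ? N[r] / den : 0.0;
      N[r] = saved + right[r + 1] * term;
      saved = left[j - r] * term;
    }
    N[j] = saved;
  }
}

// n x K design of order-`ord` B-splines (deriv = 0) or their first
// derivatives (deriv = 1), scaled by `scale` (the K-sum normalization).
// Values of x outside the support are clamped to the boundary.
static arma::mat bspline_mat_core(const arma::vec& x, const arma::vec& t,
                                  int ord, int deriv, double scale) {
  if (ord > 15) Rcpp::stop("spline order too large");
  int K = (int)t.n_elem - ord;
  int n = (int)x.n_elem;
  arma::mat out(n, K, arma::fill::zeros);
  double a = t(0), b = t(K + ord - 1);
  double N[16], Nl[16];
  for (int i = 0; i < n; ++i) {
    // clamped evaluation: constant extension outside the support, so the
    // derivative there is identically zero
    if (deriv == 1 && (x(i) < a || x(i) > b)) continue;
    double xi = std::min(std::max(x(i), a), b);
    int mu = find_span(xi, t, ord, K);
    if (deriv == 0) {
      basis_funs(mu, xi, ord, t, N);
      for (int r = 0; r < ord; ++r) out(i, mu - ord + 1 + r) = scale * N[r];
    } else {
      if (ord == 1) continue; // piecewise constant: derivative 0
      basis_funs(mu, xi, ord - 1, t, Nl);
      // order-(ord-1) nonzero indices: mu-ord+2 .. mu  -> Nl[0..ord-2]
      for (int r = 0; r < ord; ++r) {
        int idx = mu - ord + 1 + r; // basis function index of order `ord`
        double v1 = 0.0, v2 = 0.0;
        int l1 = idx - (mu - ord + 2);       // position of Nl(idx)
        int l2 = l1 + 1;                     // position of Nl(idx + 1)
        if (l1 >= 0 && l1 <= ord - 2) {
          double den = t(idx + ord - 1) - t(idx);
          if (den != 0.0) v1 = Nl[l1] / den;
        }
        if (l2 >= 0 && l2 <= ord - 2) {
          double den = t(idx + ord) - t(idx + 1);
          if (den != 0.0) v2 = Nl[l2] / den;
        }
        out(i, idx) = scale * (ord - 1) * (v1 - v2);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_bspline(const arma::vec& x, const arma::vec& knots, int order,
                      int deriv, double scale) {
  if ((int)knots.n_elem < 2 * order)
    Rcpp::stop("knot vector too short for the requested order");
  return bspline_mat_core(x, knots, order, deriv, scale);
}

// ---------------------------------------------------------------------------
// shared small helpers
// ---------------------------------------------------------------------------
static arma::mat sympd_inv(const arma::mat& S, const char* nm) {
  arma::mat out;
  if (!arma::inv_sympd(out, arma::symmatu(S)))
    Rcpp::stop("%s is not positive definite", nm);
  return out;
}

static double logdet_sym(const arma::mat& S) {
  double v, sign;
  arma::log_det(v, sign, arma::symmatu(S));
  return v;
}

// member-level 2-column matrices Z_ij^T R_i* for all rows
static void zr_mats(const arma::mat& Z1, const arma::mat& Z2,
                    const arma::ivec& start, const arma::ivec& m,
                    const arma::mat& R, arma::mat& out) {
  int n = (int)start.n_elem, r1 = (int)Z1.n_cols, r = r1 + (int)Z2.n_cols;
  out.set_size(Z1.n_rows, 2);
  for (int i = 0; i < n; ++i) {
    int s = start(i), e = start(i) + m(i) - 1;
    out.submat(s, 0, e, 0) = Z1.rows(s, e) * R.col(i).subvec(0, r1 - 1);
    out.submat(s, 1, e, 1) = Z2.rows(s, e) * R.col(i).subvec(r1, r - 1);
  }
}

// expand a per-subject vector to member level
static arma::vec expand_rows(const arma::vec& v, const arma::ivec& start,
                             const arma::ivec& m, int N) {
  arma::vec out(N);
  for (int i = 0; i < (int)start.n_elem; ++i)
    out.subvec(start(i), start(i) + m(i) - 1).fill(v(i));
  return out;
}

// M_i = d_i R1 R1' - R1 R2' - R2 R1' + c_i R2 R2' + Delta_i
static arma::mat subject_M(int i, const arma::cube& Delta, const arma::mat& R1,
                           const arma::mat& R2, const arma::vec& cv,
                           const arma::vec& dv) {
  arma::vec a1 = R1.col(i), a2 = R2.col(i);
  return dv(i) * (a1 * a1.t()) - a1 * a2.t() - a2 * a1.t() +
         cv(i) * (a2 * a2.t()) + Delta.slice(i);
}

// ---------------------------------------------------------------------------
// E-step. Inputs are member-level (one row per cluster member):
//   resid: N x 2, y_ij - W_ij' theta (= y - mu)
//   Z1: N x r1, Z2: N x r2 random-effect designs (leading 1 column included)
//   start, m: subject row offsets (0-based) and cluster sizes
// Returns per-subject Delta (r x r x n), R1, R2 (r x n), a, b, c, d and the
// per-subject SALD marginal log-likelihood computed by Woodbury identities:
//   G_i^-1 = L^-1 - L^-1 Z' Delta Z L^-1,  L = I_m (x) Sigma,
//   log|G_i| = m log|Sigma| + log|Omega| + log|Omega^-1 + Z L^-1 Z'|.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_estep(const arma::mat& resid, const arma::mat& Z1, const arma::mat& Z2,
               const arma::ivec& start, const arma::ivec& m,
               const arma::mat& Sigma, const arma::mat& Omega,
               const arma::vec& gamma) {
  int n = (int)start.n_elem;
  int r1 = (int)Z1.n_cols, r2 = (int)Z2.n_cols, r = r1 + r2;
  arma::mat Siginv = sympd_inv(Sigma, "Sigma");
  arma::mat Omegainv = sympd_inv(Omega, "Omega");
  double ldS = logdet_sym(Sigma), ldO = logdet_sym(Omega);
  arma::vec sg = Siginv * gamma;
  double gSg = arma::dot(gamma, sg);
  arma::mat SE = resid * Siginv;          // rows: Siginv * e_ij
  arma::vec rg = resid * sg;              // rows: e_ij' Siginv gamma
  arma::vec rr = arma::sum(SE % resid, 1);

  arma::cube Delta(r, r, n);
  arma::mat R1(r, n), R2(r, n);
  arma::vec av(n), bv(n), cv(n), dv(n), ll(n);

  arma::mat A(r, r);
  arma::vec t1(r), t2(r);
  for (int i = 0; i < n; ++i) {
    int s = start(i), e = start(i) + m(i) - 1, mi = m(i);
    const arma::mat Z1i = Z1.rows(s, e), Z2i = Z2.rows(s, e);
    A.submat(0, 0, r1 - 1, r1 - 1) = Siginv(0, 0) * (Z1i.t() * Z1i);
    A.submat(0, r1, r1 - 1, r - 1) = Siginv(0, 1) * (Z1i.t() * Z2i);
    A.submat(r1, r1, r - 1, r - 1) = Siginv(1, 1) * (Z2i.t() * Z2i);
    t1.subvec(0, r1 - 1) = Z1i.t() * SE.submat(s, 0, e, 0);
    t1.subvec(r1, r - 1) = Z2i.t() * SE.submat(s, 1, e, 1);
    t2.subvec(0, r1 - 1) = arma::sum(Z1i, 0).t() * sg(0);
    t2.subvec(r1, r - 1) = arma::sum(Z2i, 0).t() * sg(1);
    arma::mat M = arma::symmatu(Omegainv + A);
    arma::mat D = sympd_inv(M, "Omega^-1 + Z Lambda^-1 Z'");
    Delta.slice(i) = D;
    arma::vec Ri1 = D * t1, Ri2 = D * t2;
    R1.col(i) = Ri1;
    R2.col(i) = Ri2;
    double b = arma::accu(rr.subvec(s, e)) - arma::dot(t1, Ri1);
    double a = 2.0 + mi * gSg - arma::dot(t2, Ri2);
    double cross = arma::accu(rg.subvec(s, e)) - arma::dot(t1, Ri2);
    if (b < 1e-10) b = 1e-10;
    double nu = 1.0 - mi;
    double ldG = mi * ldS + ldO + logdet_sym(M);
    ll(i) = M_LN2 + cross - mi * LOG2PI - 0.5 * ldG +
            0.5 * nu * (std::log(b) - std::log(a)) +
            log_bessel_k_scalar(nu, std::sqrt(a * b));
    double ev, evinv;
    gig_moments_scalar(a, b, nu, ev, evinv);
    av(i) = a; bv(i) = b; cv(i) = ev; dv(i) = evinv;
  }
  return List::create(_["Delta"] = Delta, _["R1"] = R1, _["R2"] = R2,
                      _["a"] = av, _["b"] = bv, _["c"] = cv, _["d"] = dv,
                      _["loglik"] = ll);
}

// residual-dependent part of Q1 (the only part that moves in CM-steps 1-3):
// sum_ij -d_i/2 e'Se + d_i e'S zr1 - e'S zr2 + e'S gamma, with S = Siginv
static double q1_resid_part(const arma::mat& resid, const arma::mat& Siginv,
                            const arma::vec& sg, const arma::mat& zr1,
                            const arma::mat& zr2, const arma::vec& drow) {
  arma::mat SE = resid * Siginv;
  double q = -0.5 * arma::accu(drow % arma::sum(SE % resid, 1));
  q += arma::accu(drow % arma::sum(SE % zr1, 1));
  q += -arma::accu(arma::sum(SE % zr2, 1));
  q += arma::accu(resid * sg);
  return q;
}

// ---------------------------------------------------------------------------
// Q1: expected complete-data log-likelihood for (beta, theta, gamma, Sigma)
// given the current E-step fields (up to an additive constant).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_q1(const arma::mat& resid, const arma::mat& Z1, const arma::mat& Z2,
              const arma::ivec& start, const arma::ivec& m,
              const arma::mat& Sigma, const arma::vec& gamma,
              const arma::cube& Delta, const arma::mat& R1, const arma::mat& R2,
              const arma::vec& cv, const arma::vec& dv) {
  int n = (int)start.n_elem;
  int r1 = (int)Z1.n_cols, r = r1 + (int)Z2.n_cols;
  int N = (int)resid.n_rows;
  arma::mat Siginv = sympd_inv(Sigma, "Sigma");
  arma::vec sg = Siginv * gamma;
  double gSg = arma::dot(gamma, sg);
  arma::mat zr1, zr2;
  zr_mats(Z1, Z2, start, m, R1, zr1);
  zr_mats(Z1, Z2, start, m, R2, zr2);
  arma::vec drow = expand_rows(dv, start, m, N);
  double q = -0.5 * N * logdet_sym(Sigma);
  q += q1_resid_part(resid, Siginv, sg, zr1, zr2, drow);
  // gamma-only and trace terms
  q += -arma::accu(zr1 * sg);
  arma::vec crow = expand_rows(cv, start, m, N);
  q += arma::accu(crow % (zr2 * sg));
  arma::mat A(r, r);
  for (int i = 0; i < n; ++i) {
    int s = start(i), e = start(i) + m(i) - 1;
    const arma::mat Z1i = Z1.rows(s, e), Z2i = Z2.rows(s, e);
    A.submat(0, 0, r1 - 1, r1 - 1) = Siginv(0, 0) * (Z1i.t() * Z1i);
    A.submat(0, r1, r1 - 1, r - 1) = Siginv(0, 1) * (Z1i.t() * Z2i);
    A.submat(r1, 0, r - 1, r1 - 1) = Siginv(0, 1) * (Z2i.t() * Z1i);
    A.submat(r1, r1, r - 1, r - 1) = Siginv(1, 1) * (Z2i.t() * Z2i);
    q += -0.5 * cv(i) * m(i) * gSg;
    q += -0.5 * arma::trace(A * subject_M(i, Delta, R1, R2, cv, dv));
  }
  return q;
}

// [[Rcpp::export]]
double cpp_q2(const arma::mat& Omega, const arma::cube& Delta,
              const arma::mat& R1, const arma::mat& R2,
              const arma::vec& cv, const arma::vec& dv) {
  int n = (int)Delta.n_slices;
  arma::mat Omegainv = sympd_inv(Omega, "Omega");
  double q = -0.5 * n * logdet_sym(Omega);
  for (int i = 0; i < n; ++i)
    q += -0.5 * arma::trace(Omegainv * subject_M(i, Delta, R1, R2, cv, dv));
  return q;
}

// ---------------------------------------------------------------------------
// CM-step 1: generalized least squares for the spline coefficients.
// Solves  [sum d_i W_ij Siginv W_ij'] theta =
//         sum W_ij Siginv [d_i (y_ij - Z_ij' R1) + Z_ij' R2 - gamma].
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::vec cpp_cm_theta(const arma::mat& y, const arma::mat& B1,
                       const arma::mat& B2, const arma::mat& Z1,
                       const arma::mat& Z2, const arma::ivec& start,
                       const arma::ivec& m, const arma::mat& Sigma,
                       const arma::vec& gamma, const arma::mat& R1,
                       const arma::mat& R2, const arma::vec& cv,
                       const arma::vec& dv) {
  int K1 = (int)B1.n_cols, K2 = (int)B2.n_cols, K = K1 + K2;
  int N = (int)y.n_rows;
  arma::mat Siginv = sympd_inv(Sigma, "Sigma");
  arma::mat zr1, zr2;
  zr_mats(Z1, Z2, start, m, R1, zr1);
  zr_mats(Z1, Z2, start, m, R2, zr2);
  arma::vec drow = expand_rows(dv, start, m, N);
  arma::mat v = y - zr1;
  v.each_col() %= drow;
  v += zr2;
  v.each_row() -= gamma.t();
  arma::mat SV = v * Siginv;
  arma::mat B1d = B1.each_col() % drow, B2d = B2.each_col() % drow;
  arma::mat G(K, K);
  G.submat(0, 0, K1 - 1, K1 - 1) = Siginv(0, 0) * (B1.t() * B1d);
  G.submat(0, K1, K1 - 1, K - 1) = Siginv(0, 1) * (B1.t() * B2d);
  G.submat(K1, K1, K - 1, K - 1) = Siginv(1, 1) * (B2.t() * B2d);
  G = arma::symmatu(G);
  arma::vec rhs(K);
  rhs.subvec(0, K1 - 1) = B1.t() * SV.col(0);
  rhs.subvec(K1, K - 1) = B2.t() * SV.col(1);
  arma::vec theta;
  if (!arma::solve(theta, G, rhs, arma::solve_opts::likely_sympd))
    Rcpp::stop("spline normal equations are rank deficient (too many knots?)");
  return theta;
}

// CM-step 2: closed form for the skewness vector.
// [[Rcpp::export]]
arma::vec cpp_cm_gamma(const arma::mat& resid, const arma::mat& Z1,
                       const arma::mat& Z2, const arma::ivec& start,
                       const arma::ivec& m, const arma::mat& R1,
                       const arma::mat& R2, const arma::vec& cv) {
  int N = (int)resid.n_rows;
  arma::mat zr1, zr2;
  zr_mats(Z1, Z2, start, m, R1, zr1);
  zr_mats(Z1, Z2, start, m, R2, zr2);
  arma::vec crow = expand_rows(cv, start, m, N);
  arma::mat num = resid - zr1 + (zr2.each_col() % crow);
  return arma::sum(num, 0).t() / arma::accu(crow);
}

static arma::mat pd_floor(arma::mat S, double floor_ev) {
  S = arma::symmatu(0.5 * (S + S.t()));
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, S);
  bool fix = false;
  for (arma::uword k = 0; k < eval.n_elem; ++k)
    if (eval(k) < floor_ev) { eval(k) = floor_ev; fix = true; }
  if (!fix) return S;
  return arma::symmatu(evec * arma::diagmat(eval) * evec.t());
}

// CM-step 4: scatter matrix of the error term, Sigma = S / N with S the
// expected complete-data sum E[ V^-1 (y - mu~ - V gamma)(...)^T | y ].
// [[Rcpp::export]]
arma::mat cpp_cm_sigma(const arma::mat& resid, const arma::mat& Z1,
                       const arma::mat& Z2, const arma::ivec& start,
                       const arma::ivec& m, const arma::vec& gamma,
                       const arma::cube& Delta, const arma::mat& R1,
                       const arma::mat& R2, const arma::vec& cv,
                       const arma::vec& dv) {
  int n = (int)start.n_elem;
  int r1 = (int)Z1.n_cols, r = r1 + (int)Z2.n_cols;
  int N = (int)resid.n_rows;
  arma::mat zr1, zr2;
  zr_mats(Z1, Z2, start, m, R1, zr1);
  zr_mats(Z1, Z2, start, m, R2, zr2);
  arma::vec drow = expand_rows(dv, start, m, N);
  arma::vec crow = expand_rows(cv, start, m, N);
  arma::mat ed = resid.each_col() % drow;
  arma::mat S = ed.t() * resid;                       // sum d e e'
  S += arma::accu(crow) * (gamma * gamma.t());        // sum c gamma gamma'
  arma::mat C1 = ed.t() * zr1;                        // sum d e zr1'
  S += -(C1 + C1.t());
  arma::mat C2 = resid.t() * zr2;                     // sum e zr2'
  S += C2 + C2.t();
  arma::vec esum = arma::sum(resid, 0).t();
  S += -(esum * gamma.t() + gamma * esum.t());
  arma::vec u1sum = arma::sum(zr1, 0).t();
  S += gamma * u1sum.t() + u1sum * gamma.t();
  arma::vec u2c = (zr2.each_col() % crow).t() * arma::ones(N);
  S += -(gamma * u2c.t() + u2c * gamma.t());
  // sum_ij Z_ij' M_i Z_ij
  for (int i = 0; i < n; ++i) {
    int s = start(i), e = start(i) + m(i) - 1;
    const arma::mat Z1i = Z1.rows(s, e), Z2i = Z2.rows(s, e);
    arma::mat Mi = subject_M(i, Delta, R1, R2, cv, dv);
    const arma::mat M11 = Mi.submat(0, 0, r1 - 1, r1 - 1);
    const arma::mat M12 = Mi.submat(0, r1, r1 - 1, r - 1);
    const arma::mat M22 = Mi.submat(r1, r1, r - 1, r - 1);
    S(0, 0) += arma::accu((Z1i * M11) % Z1i);
    S(1, 1) += arma::accu((Z2i * M22) % Z2i);
    double od = arma::accu((Z1i * M12) % Z2i);
    S(0, 1) += od;
    S(1, 0) += od;
  }
  return pd_floor(S / N, 1e-8);
}

// CM-step 5: random-effects covariance, Omega = mean_i M_i.
// [[Rcpp::export]]
arma::mat cpp_cm_omega(const arma::cube& Delta, const arma::mat& R1,
                       const arma::mat& R2, const arma::vec& cv,
                       const arma::vec& dv) {
  int n = (int)Delta.n_slices;
  int r = (int)Delta.n_rows;
  arma::mat S(r, r, arma::fill::zeros);
  for (int i = 0; i < n; ++i) S += subject_M(i, Delta, R1, R2, cv, dv);
  return pd_floor(S / n, 1e-8);
}

// ---------------------------------------------------------------------------
// CM-step 3: Newton-Raphson for the delete-one-component index coefficients,
// with step-halving on Q1 and backtracking into the unit ball. Only the
// residual-dependent part of Q1 is tracked (the rest is constant in beta).
// ---------------------------------------------------------------------------
static arma::vec full_beta_cpp(const arma::vec& bm1) {
  double s2 = arma::dot(bm1, bm1);
  arma::vec beta(bm1.n_elem + 1);
  beta(0) = std::sqrt(std::max(0.0, 1.0 - s2));
  beta.subvec(1, bm1.n_elem) = bm1;
  return beta;
}

// [[Rcpp::export]]
List cpp_cm_beta(const arma::mat& y, const arma::mat& X1, const arma::mat& X2,
                 const arma::mat& Z1, const arma::mat& Z2,
                 const arma::ivec& start, const arma::ivec& m,
                 const arma::vec& beta1_in, const arma::vec& beta2_in,
                 const arma::vec& theta1, const arma::vec& theta2,
                 const arma::vec& knots1, const arma::vec& knots2, int order,
                 const arma::mat& Sigma, const arma::vec& gamma,
                 const arma::cube& Delta, const arma::mat& R1,
                 const arma::mat& R2, const arma::vec& cv, const arma::vec& dv,
                 int newton_max) {
  int p1 = (int)X1.n_cols, p2 = (int)X2.n_cols;
  int K1 = (int)knots1.n_elem - order, K2 = (int)knots2.n_elem - order;
  int N = (int)y.n_rows;
  arma::mat Siginv = sympd_inv(Sigma, "Sigma");
  arma::vec sg = Siginv * gamma;
  arma::mat zr1, zr2;
  zr_mats(Z1, Z2, start, m, R1, zr1);
  zr_mats(Z1, Z2, start, m, R2, zr2);
  arma::vec drow = expand_rows(dv, start, m, N);

  arma::vec b1m1 = beta1_in.subvec(1, p1 - 1);
  arma::vec b2m1 = beta2_in.subvec(1, p2 - 1);

  auto q1_at = [&](const arma::vec& bb1, const arma::vec& bb2) {
    arma::mat resid = y;
    resid.col(0) -= bspline_mat_core(X1 * full_beta_cpp(bb1), knots1, order, 0,
                                     (double)K1) * theta1;
    resid.col(1) -= bspline_mat_core(X2 * full_beta_cpp(bb2), knots2, order, 0,
                                     (double)K2) * theta2;
    return q1_resid_part(resid, Siginv, sg, zr1, zr2, drow);
  };

  double qcur = q1_at(b1m1, b2m1);
  bool halved_out = false;
  int inner = 0;
  int pf = (p1 - 1) + (p2 - 1);
  for (; inner < newton_max; ++inner) {
    arma::vec u1 = X1 * full_beta_cpp(b1m1), u2 = X2 * full_beta_cpp(b2m1);
    arma::mat B1 = bspline_mat_core(u1, knots1, order, 0, (double)K1);
    arma::mat B2 = bspline_mat_core(u2, knots2, order, 0, (double)K2);
    arma::vec g1dot = bspline_mat_core(u1, knots1, order, 1, (double)K1) * theta1;
    arma::vec g2dot = bspline_mat_core(u2, knots2, order, 1, (double)K2) * theta2;
    // J_k' x_k rows: x[,2:p] - x[,1] * bm1' / sqrt(1 - |bm1|^2)
    double s1 = std::sqrt(std::max(1e-12, 1.0 - arma::dot(b1m1, b1m1)));
    double s2 = std::sqrt(std::max(1e-12, 1.0 - arma::dot(b2m1, b2m1)));
    arma::mat Xt1 = X1.cols(1, p1 - 1) - X1.col(0) * (b1m1.t() / s1);
    arma::mat Xt2 = X2.cols(1, p2 - 1) - X2.col(0) * (b2m1.t() / s2);
    arma::mat resid = y;
    resid.col(0) -= B1 * theta1;
    resid.col(1) -= B2 * theta2;
    arma::mat v = resid - zr1;
    v.each_col() %= drow;
    v += zr2;
    v.each_row() -= gamma.t();
    arma::mat SV = v * Siginv;
    arma::vec grad(pf);
    grad.subvec(0, p1 - 2) = Xt1.t() * (g1dot % SV.col(0));
    grad.subvec(p1 - 1, pf - 1) = Xt2.t() * (g2dot % SV.col(1));
    arma::mat H1 = Xt1.each_col() % g1dot;  // rows h1'
    arma::mat H2 = Xt2.each_col() % g2dot;
    arma::mat H1d = H1.each_col() % drow;
    arma::mat GN(pf, pf);
    GN.submat(0, 0, p1 - 2, p1 - 2) = Siginv(0, 0) * (H1d.t() * H1);
    GN.submat(0, p1 - 1, p1 - 2, pf - 1) = Siginv(0, 1) * (H1d.t() * H2);
    GN.submat(p1 - 1, p1 - 1, pf - 1, pf - 1) =
        Siginv(1, 1) * ((H2.each_col() % drow).t() * H2);
    GN = arma::symmatu(GN);
    GN.diag() += 1e-10;
    arma::vec step;
    if (!arma::solve(step, GN, grad, arma::solve_opts::likely_sympd)) break;
    // backtrack into the open unit ball, then step-halve on Q1
    double lam = 1.0;
    arma::vec c1, c2;
    bool ok = false;
    for (int h = 0; h < 30; ++h) {
      c1 = b1m1 + lam * step.subvec(0, p1 - 2);
      c2 = b2m1 + lam * step.subvec(p1 - 1, pf - 1);
      if (arma::dot(c1, c1) < 1.0 && arma::dot(c2, c2) < 1.0) { ok = true; break; }
      lam *= 0.5;
    }
    if (!ok) { halved_out = true; break; }
    double qnew = q1_at(c1, c2);
    bool accepted = false;
    for (int h = 0; h < 30; ++h) {
      if (qnew >= qcur - 1e-10) { accepted = true; break; }
      lam *= 0.5;
      c1 = b1m1 + lam * step.subvec(0, p1 - 2);
      c2 = b2m1 + lam * step.subvec(p1 - 1, pf - 1);
      qnew = q1_at(c1, c2);
    }
    if (!accepted) { halved_out = true; break; }
    double chg = arma::norm(arma::join_cols(c1 - b1m1, c2 - b2m1), 2);
    b1m1 = c1;
    b2m1 = c2;
    qcur = qnew;
    if (chg < 1e-9) break;
  }
  return List::create(_["beta1"] = full_beta_cpp(b1m1),
                      _["beta2"] = full_beta_cpp(b2m1), _["q1"] = qcur,
                      _["iterations"] = inner,
                      _["step_halving_stop"] = halved_out);
}
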