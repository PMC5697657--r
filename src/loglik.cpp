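// Joint likelihood of the growth/rupture model by adaptive Gauss-Hermite
// quadrature. Each subject contributes
//   L_i = int prod_j N(y_ij; m_i(t_ij), s_e^2) * h_i(T_i)^delta_i *
//         exp(-int_0^{T_i} h_i(s) ds) * N(b; 0, Sigma) db,
// with the inner cumulative hazard by Gauss-Legendre quadrature. The
// integrand is log-concave in b (Gaussian terms plus -sum of exponentials
// linear in b), so the conditional mode is found by a damped Newton
// iteration and the quadrature grid is centred and scaled there.

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// association pieces at times s: alpha' f(m(s)) = lin0(s) + linB(s) b
void assoc_pieces(const vec& s, int degree, int q, int kind,
                  const vec& beta, const vec& alpha,
                  vec& lin0, mat& linB) {
  const uword n = s.n_elem;
  vec v0 = beta(0) + beta(1) * s;
  if (degree == 2) v0 += beta(2) * square(s);
  mat vB(n, q);
  vB.col(0).ones();
  if (q == 2) vB.col(1) = s;

  vec s0(n); s0.fill(beta(1));
  if (degree == 2) s0 += 2.0 * beta(2) * s;
  mat sB(n, q, fill::zeros);
  if (q == 2) sB.col(1).ones();

  vec c0 = beta(0) * s + 0.5 * beta(1) * square(s);
  if (degree == 2) c0 += beta(2) * pow(s, 3) / 3.0;
  mat cB(n, q);
  cB.col(0) = s;
  if (q == 2) cB.col(1) = 0.5 * square(s);

  switch (kind) {
  case 0: lin0 = alpha(0) * v0; linB = alpha(0) * vB; break;
  case 1: lin0 = alpha(0) * s0; linB = alpha(0) * sB; break;
  case 2: lin0 = alpha(0) * v0 + alpha(1) * s0;
          linB = alpha(0) * vB + alpha(1) * sB; break;
  default: lin0 = alpha(0) * v0 + alpha(1) * c0;
           linB = alpha(0) * vB + alpha(1) * cB; break;
  }
}

vec log_h0(const vec& s, int baseline_kind, const vec& bl) {
  if (baseline_kind == 0) {
    return vec(s.n_elem, fill::value(bl(0)));
  }
  double k = std::exp(bl(1));
  return bl(0) + bl(1) + (k - 1.0) * log(s);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_joint_loglik(const arma::vec& y, const arma::vec& tobs,
                            const arma::ivec& ni, const arma::vec& Tvec,
                            const arma::ivec& delta, const arma::vec& offsets,
                            int degree, int q, int assoc_kind,
                            int baseline_kind,
                            const arma::vec& beta, double sigma_eps,
                            const arma::mat& Sigma, const arma::vec& alpha,
                            const arma::vec& bl,
                            const arma::vec& gh_x, const arma::vec& gh_w,
                            const arma::vec& gl_x, const arma::vec& gl_w,
                            bool want_modes) {
  const int n = ni.n_elem;
  const double sig2e = sigma_eps * sigma_eps;
  mat Sinv;
  bool ok = inv_sympd(Sinv, Sigma);
  if (!ok) Rcpp::stop("random-effects covariance is not positive definite");
  double ldSigma, sgn;
  log_det(ldSigma, sgn, Sigma);

  // tensor GH grid
  const int m1 = gh_x.n_elem;
  const int M = (q == 1) ? m1 : m1 * m1;
  mat zgrid(M, q);
  vec wgrid(M);
  if (q == 1) {
    zgrid.col(0) = gh_x;
    wgrid = gh_w;
  } else {
    int idx = 0;
    for (int a = 0; a < m1; ++a)
      for (int bb = 0; bb < m1; ++bb, ++idx) {
        zgrid(idx, 0) = gh_x(a);
        zgrid(idx, 1) = gh_x(bb);
        wgrid(idx) = gh_w(a) * gh_w(bb);
      }
  }
  vec z2 = sum(square(zgrid), 1);

  vec ll(n);
  mat modes(n, q, fill::zeros);
  mat mode_cov(n, q * q, fill::zeros);
  const double log2pi = std::log(2.0 * M_PI);

  int pos = 0;
  for (int i = 0; i < n; ++i) {
    const int m = ni(i);
    vec yi = y.subvec(pos, pos + m - 1);
    vec ti = tobs.subvec(pos, pos + m - 1);
    pos += m;
    const double Ti = Tvec(i);
    const int di = delta(i);
    const double off = offsets(i);

    mat Z(m, q);
    Z.col(0).ones();
    if (q == 2) Z.col(1) = ti;
    vec mu0 = beta(0) + beta(1) * ti;               // fixed-effects mean
    if (degree == 2) mu0 += beta(2) * square(ti);
    vec r0 = yi - mu0;                              // residual at b = 0

    // survival pieces at GL nodes on (0, T) and at T
    vec s_nodes = Ti * gl_x;
    vec wgl = Ti * gl_w;
    vec lh0_s = log_h0(s_nodes, baseline_kind, bl);
    vec lin0_s;
    mat linB_s;
    assoc_pieces(s_nodes, degree, q, assoc_kind, beta, alpha, lin0_s, linB_s);
    vec base_s = lh0_s + off + lin0_s;              // log-hazard at b = 0

    double lh0_T = 0.0, lin0_T = 0.0;
    vec linB_T(q, fill::zeros);
    if (di == 1) {
      vec tT(1); tT(0) = Ti;
      vec l0; mat lB;
      assoc_pieces(tT, degree, q, assoc_kind, beta, alpha, l0, lB);
      lh0_T = log_h0(tT, baseline_kind, bl)(0);
      lin0_T = l0(0);
      linB_T = lB.row(0).t();
    }

    const mat ZtZ = Z.t() * Z;
    const double lconst = -0.5 * m * (log2pi + std::log(sig2e))
                          - 0.5 * q * log2pi - 0.5 * ldSigma;

    // g(b) and derivatives
    auto g_fun = [&](const vec& b, vec* grad, mat* nh) -> double {
      vec resid = r0 - Z * b;
      vec eta = base_s + linB_s * b;                // log-hazard at nodes
      vec hs = exp(eta);
      double cumh = dot(wgl, hs);
      double g = lconst - 0.5 * dot(resid, resid) / sig2e - cumh
                 - 0.5 * as_scalar(b.t() * Sinv * b);
      if (di == 1) g += lh0_T + off + lin0_T + dot(linB_T, b);
      if (grad) {
        *grad = Z.t() * resid / sig2e - linB_s.t() * (wgl % hs) - Sinv * b;
        if (di == 1) *grad += linB_T;
      }
      if (nh) {
        *nh = ZtZ / sig2e + Sinv
              + linB_s.t() * (linB_s.each_col() % (wgl % hs));
      }
      return g;
    };

    // damped Newton for the conditional mode (g is strictly concave)
    vec b(q, fill::zeros), grad(q);
    mat nh(q, q);
    double g = g_fun(b, &grad, &nh);
    for (int it = 0; it < 100; ++it) {
      vec step = solve(nh, grad, solve_opts::likely_sympd);
      double stepsz = 1.0;
      vec bnew; double gnew = -datum::inf;
      for (int h = 0; h < 30; ++h) {
        bnew = b + stepsz * step;
        gnew = g_fun(bnew, nullptr, nullptr);
        if (std::isfinite(gnew) && gnew >= g - 1e-12) break;
        stepsz *= 0.5;
      }
      b = bnew;
      double gprev = g;
      g = g_fun(b, &grad, &nh);
      if (norm(grad) < 1e-9 || std::abs(g - gprev) < 1e-12) break;
    }

    // adaptive GH centred at the mode, scaled by the curvature
    mat C;
    ok = inv_sympd(C, nh);
    if (!ok) { ll(i) = datum::nan; continue; }
    mat L = chol(C, "lower");
    double log_jac = 0.5 * q * std::log(2.0) + sum(log(L.diag()));

    double acc = 0.0;
    for (int k = 0; k < M; ++k) {
      vec bk = b + std::sqrt(2.0) * (L * zgrid.row(k).t());
      double gk = g_fun(bk, nullptr, nullptr);
      acc += wgrid(k) * std::exp(gk - g + z2(k));
    }
    ll(i) = g + std::log(acc) + log_jac;
    if (want_modes) {
      modes.row(i) = b.t();
      mode_cov.row(i) = vectorise(C).t();
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loglik") = accu(ll),
    Rcpp::Named("per_subject") = ll);
  if (want_modes) {
    out["modes"] = modes;
    out["mode_cov"] = mode_cov;
  }
  return out;
}
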