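// Joint longitudinal-survival log-likelihood with shared random effects.
//
// The subject-level likelihood integrates the product of the Gaussian
// longitudinal density, the proportional-hazards survival density and
// the random-effects density over b_i. The integral uses pseudo-adaptive
// Gauss-Hermite nodes fixed at each subject's empirical-Bayes posterior
// (precomputed in R and passed in as Bnodes/lw); because the nodes do
// not move with the parameters, the analytic score below is the exact
// gradient of the approximated objective.
//
// Parameter vector layout (all unconstrained):
//   beta (p) | zeta (d(d+1)/2, log-Cholesky of D) | tau (log sigma) |
//   gamma0 | alpha | kappa (kb, log-baseline-hazard B-spline coefs)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat build_L(const vec& zeta, int d) {
  mat L(d, d, fill::zeros);
  int idx = 0;
  for (int j = 0; j < d; j++) {
    for (int i = j; i < d; i++) L(i, j) = zeta(idx++);
  }
  for (int j = 0; j < d; j++) L(j, j) = std::exp(L(j, j));
  return L;
}

// [[Rcpp::export]]
List cpp_jm_loglik(const arma::vec& par, const List& subjects,
                   int p, int d, int kb, bool want_grad) {
  const int nth = d * (d + 1) / 2;
  const vec beta = par.subvec(0, p - 1);
  const vec zeta = par.subvec(p, p + nth - 1);
  const double tau = par(p + nth);
  const double sigma2 = std::exp(2.0 * tau);
  const double gamma0 = par(p + nth + 1);
  const double alpha = par(p + nth + 2);
  const vec kappa = par.subvec(p + nth + 3, p + nth + 2 + kb);

  const mat L = build_L(zeta, d);
  const mat D = L * L.t();
  mat Dinv;
  if (!inv_sympd(Dinv, D)) {
    return List::create(_["loglik"] = NA_REAL);
  }
  double logdetD, signd;
  log_det(logdetD, signd, D);

  const int n = subjects.size();
  double total = 0.0;
  vec lli(n, fill::zeros);
  vec grad(par.n_elem, fill::zeros);
  mat Ssum(d, d, fill::zeros);

  for (int i = 0; i < n; i++) {
    List s = subjects[i];
    const vec y = s["y"];
    const mat X = s["X"];
    const mat Z = s["Z"];
    const double delta = s["delta"];
    const double w = s["w"];
    const rowvec BT = s["BT"];
    const rowvec axT = s["axT"];
    const rowvec azT = s["azT"];
    const vec Wq = s["Wq"];
    const mat Bq = s["Bq"];
    const mat Axq = s["Axq"];
    const mat Azq = s["Azq"];
    const mat Bn = s["Bnodes"];   // K x d
    const vec lw = s["lw"];       // K
    const int K = Bn.n_rows;
    const int ni = y.n_elem;

    // longitudinal factor at each node
    const vec r0 = y - X * beta;
    const mat Ebk = Z * Bn.t();                 // ni x K
    const vec r0Zb = Ebk.t() * r0;              // K
    const vec bZZb = sum(square(Ebk), 0).t();   // K
    const double r0r0 = dot(r0, r0);
    const vec qvec = r0r0 - 2.0 * r0Zb + bZZb;  // K
    const vec ll_y = -(0.5 * ni) * std::log(2.0 * M_PI * sigma2)
      - qvec / (2.0 * sigma2);

    // survival factor: event term + cumulative hazard by quadrature
    const double lh0T = dot(BT, kappa) + gamma0 * w;
    const double mT0 = dot(axT, beta);
    const vec mTb = Bn * azT.t();               // K
    const vec etaT = lh0T + alpha * (mT0 + mTb);
    const vec h0q = Bq * kappa + gamma0 * w;    // qn
    const vec mq0 = Axq * beta;                 // qn
    mat Eta = repmat(h0q + alpha * mq0, 1, K) + alpha * (Azq * Bn.t());
    Eta = clamp(Eta, -60.0, 60.0);
    const mat U = exp(Eta);                     // qn x K
    const vec Hk = U.t() * Wq;                  // K
    const vec ll_T = delta * etaT - Hk;

    // random-effects density at each node
    const mat DinvB = Bn * Dinv;                // K x d
    const vec quadb = sum(DinvB % Bn, 1);
    const vec ll_b = -0.5 * d * std::log(2.0 * M_PI) - 0.5 * logdetD
      - 0.5 * quadb;

    const vec g = lw + ll_y + ll_T + ll_b;
    const double gm = g.max();
    const vec eg = exp(g - gm);
    const double sg = accu(eg);
    const double ll_i = gm + std::log(sg);
    lli(i) = ll_i;
    total += ll_i;

    if (!want_grad) continue;
    const vec pi_k = eg / sg;
    const vec bbar = Bn.t() * pi_k;             // d
    const vec Upi = U * pi_k;                   // qn
    const vec uq = Wq % Upi;                    // qn

    // beta: longitudinal part + hazard dependence through m(t)
    const vec gb = (X.t() * r0 - (X.t() * Z) * bbar) / sigma2
      + delta * alpha * axT.t()
      - alpha * (Axq.t() * uq);
    grad.subvec(0, p - 1) += gb;

    // tau (log sigma)
    grad(p + nth) += dot(pi_k, -double(ni) + qvec / sigma2);

    // gamma0
    const double Hbar = dot(Hk, pi_k);
    grad(p + nth + 1) += w * (delta - Hbar);

    // alpha: event-time m minus hazard-weighted m over time
    const mat Mq = repmat(mq0, 1, K) + Azq * Bn.t();
    const double mhaz = dot(Wq, (U % Mq) * pi_k);
    grad(p + nth + 2) += delta * (mT0 + dot(mTb, pi_k)) - mhaz;

    // kappa
    grad.subvec(p + nth + 3, p + nth + 2 + kb) +=
      delta * BT.t() - Bq.t() * uq;

    // accumulate weighted second moment of b for the D gradient
    Ssum += Bn.t() * (Bn.each_col() % pi_k);
  }

  if (want_grad) {
    mat GL = (-double(n) * Dinv + Dinv * Ssum * Dinv) * L;
    GL.diag() %= L.diag();   // chain rule for log-diagonal entries
    int idx = 0;
    for (int j = 0; j < d; j++) {
      for (int i2 = j; i2 < d; i2++) grad(p + idx++) = GL(i2, j);
    }
  }

  return List::create(_["loglik"] = total, _["lli"] = lli,
                      _["grad"] = grad);
}
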