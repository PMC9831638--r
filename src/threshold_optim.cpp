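// Core numerical kernels: the smooth shrinkage operator and the Rprop
// optimizer of per-neuron thresholds for the three cost variants
// (binary-task symmetrized KL, localization symmetrized KL, ROI
// reconstruction error), each plus the psi-weighted activity term.
//
// Coordinate perturbations reuse cached state: the sparse code is computed
// once per sample and only the cheap nonlinearity and observer arithmetic
// are re-evaluated, which is what makes the numerically estimated gradient
// affordable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double shrink1(double s, double xi, double alpha) {
  if (xi <= 0.0) return s;            // exact identity at xi = 0
  double as = std::fabs(s);
  if (as == 0.0) return 0.0;          // exact zero at s = 0
  double M = std::max(xi, as);
  double t1 = std::exp(alpha * (xi - M));
  double t2 = std::exp(alpha * (as - M));
  double t3 = std::exp(-alpha * M);
  double v = M + std::log((t1 - t3) + t2) / alpha - xi;
  if (v < 0.0) v = 0.0;               // guard tiny negative rounding
  return (s > 0.0) ? v : -v;
}

// [[Rcpp::export]]
arma::mat shrink_cpp(const arma::mat& S, const arma::mat& Xi, double alpha) {
  mat Z(S.n_rows, S.n_cols);
  for (uword j = 0; j < S.n_cols; ++j)
    for (uword i = 0; i < S.n_rows; ++i)
      Z(i, j) = shrink1(S(i, j), Xi(i, j), alpha);
  return Z;
}

// Posteriors are handled on the logit scale, capped at the double-precision
// limit |logit| = 690.78 (probability 1e-300): extreme evidence never yields
// NaN while the guard stays purely numerical and cannot distort the
// divergence at any evidence level the model produces.
static const double LOGIT_CAP = 690.77552789821368;

static inline double clip_logit(double l) {
  if (l > LOGIT_CAP) return LOGIT_CAP;
  if (l < -LOGIT_CAP) return -LOGIT_CAP;
  return l;
}

static inline double sigmoid(double l) { return 1.0 / (1.0 + std::exp(-l)); }

// symmetrized KL between Bernoulli posteriors given their (capped) logits
static inline double sym_kl_logit(double l1, double l0) {
  l1 = clip_logit(l1); l0 = clip_logit(l0);
  return (sigmoid(l1) - sigmoid(l0)) * (l1 - l0);
}

// ---------------------------------------------------------------------------
// Problem interface for Rprop with cached incremental cost evaluation.

struct Problem {
  virtual ~Problem() {}
  virtual void set_state(const vec& xi) = 0;
  virtual double cost() const = 0;
  // Full cost with only coordinate n moved to xi_n (state untouched).
  virtual double cost_perturb(uword n, double xi_n) const = 0;
};

// Binary tasks (detection / orientation estimation).
// measurement m_i = c0 + zeta_i + sum_n w_n g(z_{i,n}),
// g = identity (detection, decoded-image projection folded into w) or
// absolute value (orientation). Posterior vs the xi = 0 posterior from the
// same prior; symmetrized Bernoulli KL averaged over samples.
struct BinaryProblem : Problem {
  const mat& S;          // n x N codes
  vec w;                 // N
  double c0;
  vec zeta;              // n, common random numbers
  double muP, sdP, muA, sdA, prior, psi, alpha;
  bool use_abs;

  mat Z;                 // n x N current responses
  vec xi_cur;
  vec mvec;              // n current measurements
  vec act;               // N column sums of |z|
  vec logit0;            // n logit posterior of the xi = 0 branch
  double logit_prior;
  uword n, N;

  BinaryProblem(const mat& S_, const vec& w_, double c0_, const vec& zeta_,
                double muP_, double sdP_, double muA_, double sdA_,
                double prior_, double psi_, double alpha_, bool use_abs_)
    : S(S_), w(w_), c0(c0_), zeta(zeta_), muP(muP_), sdP(sdP_), muA(muA_),
      sdA(sdA_), prior(prior_), psi(psi_), alpha(alpha_), use_abs(use_abs_) {
    n = S.n_rows; N = S.n_cols;
    double p = std::min(std::max(prior, 1e-12), 1.0 - 1e-12);
    logit_prior = std::log(p / (1.0 - p));
    vec m0 = measurement_of(S);
    logit0.set_size(n);
    for (uword i = 0; i < n; ++i) logit0(i) = logit_post(m0(i));
  }

  vec measurement_of(const mat& ZZ) const {
    vec m(n, fill::value(c0));
    m += zeta;
    for (uword j = 0; j < N; ++j) {
      double wj = w(j);
      if (wj == 0.0) continue;
      for (uword i = 0; i < n; ++i) {
        double z = ZZ(i, j);
        m(i) += wj * (use_abs ? std::fabs(z) : z);
      }
    }
    return m;
  }

  double logit_post(double m) const {
    double lp = -0.5 * std::pow((m - muP) / sdP, 2) - std::log(sdP);
    double la = -0.5 * std::pow((m - muA) / sdA, 2) - std::log(sdA);
    return clip_logit(logit_prior + lp - la);
  }

  void set_state(const vec& xi) override {
    xi_cur = xi;
    Z.set_size(n, N);
    act.set_size(N);
    for (uword j = 0; j < N; ++j) {
      double a = 0.0;
      for (uword i = 0; i < n; ++i) {
        double z = shrink1(S(i, j), xi(j), alpha);
        Z(i, j) = z;
        a += std::fabs(z);
      }
      act(j) = a;
    }
    mvec = measurement_of(Z);
  }

  double kl_of_m(const vec& m) const {
    double acc = 0.0;
    for (uword i = 0; i < n; ++i)
      acc += sym_kl_logit(logit_post(m(i)), logit0(i));
    return acc / n;
  }

  double cost() const override {
    return kl_of_m(mvec) + psi * accu(act) / n;
  }

  double cost_perturb(uword jn, double xi_n) const override {
    double wj = w(jn);
    double acc_kl = 0.0, a_new = 0.0;
    for (uword i = 0; i < n; ++i) {
      double z = shrink1(S(i, jn), xi_n, alpha);
      a_new += std::fabs(z);
      double zc = Z(i, jn);
      double m = mvec(i) +
        wj * ((use_abs ? std::fabs(z) : z) - (use_abs ? std::fabs(zc) : zc));
      acc_kl += sym_kl_logit(logit_post(m), logit0(i));
    }
    return acc_kl / n + psi * (accu(act) - act(jn) + a_new) / n;
  }
};

// Target localization. The decoded image's cross-correlation map with the
// target template is linear in z: M = cc0 + CM z. The measurement is the
// (row, col) of the map's peak (first maximum in row-major order = smallest
// row, then column). Conjugate Gaussian posterior per coordinate; symmetric
// KL between equal-variance Gaussians is (mu1 - mu0)^2 / sigma_post^2.
struct LocalProblem : Problem {
  const mat& S;          // n x N
  const mat& CM;         // P x N per-atom correlation maps
  vec cc0;               // P
  double mu0r, mu0c, var0, sm2, psi, alpha;
  uword W;

  mat Z;                 // n x N
  mat M;                 // P x n current maps
  vec xi_cur, act;       // act: N
  vec post0_r, post0_c;  // posterior means of the xi = 0 branch
  double post_var;
  uword n, N, P;

  LocalProblem(const mat& S_, const mat& CM_, const vec& cc0_,
               double mu0r_, double mu0c_, double var0_, double sm2_,
               double psi_, double alpha_, uword W_)
    : S(S_), CM(CM_), cc0(cc0_), mu0r(mu0r_), mu0c(mu0c_), var0(var0_),
      sm2(sm2_), psi(psi_), alpha(alpha_), W(W_) {
    n = S.n_rows; N = S.n_cols; P = CM.n_rows;
    post_var = var0 * sm2 / (var0 + sm2);
    mat M0 = repmat(cc0, 1, n) + CM * S.t();
    post0_r.set_size(n); post0_c.set_size(n);
    for (uword i = 0; i < n; ++i) {
      double r, c;
      peak_of(M0.colptr(i), r, c);
      post0_r(i) = post_mean(mu0r, r);
      post0_c(i) = post_mean(mu0c, c);
    }
  }

  inline double post_mean(double mu, double m) const {
    return (sm2 * mu + var0 * m) / (var0 + sm2);
  }

  inline void peak_of(const double* col, double& r, double& c) const {
    uword best = 0;
    double bv = col[0];
    for (uword p = 1; p < P; ++p)
      if (col[p] > bv) { bv = col[p]; best = p; }
    r = (double)(best / W) + 1.0;
    c = (double)(best % W) + 1.0;
  }

  void set_state(const vec& xi) override {
    xi_cur = xi;
    Z.set_size(n, N);
    act.set_size(N);
    for (uword j = 0; j < N; ++j) {
      double a = 0.0;
      for (uword i = 0; i < n; ++i) {
        double z = shrink1(S(i, j), xi(j), alpha);
        Z(i, j) = z;
        a += std::fabs(z);
      }
      act(j) = a;
    }
    M = repmat(cc0, 1, n) + CM * Z.t();
  }

  double kl_sample(uword i, double r, double c) const {
    double dr = post_mean(mu0r, r) - post0_r(i);
    double dc = post_mean(mu0c, c) - post0_c(i);
    return (dr * dr + dc * dc) / post_var;
  }

  double cost() const override {
    double acc = 0.0;
    for (uword i = 0; i < n; ++i) {
      double r, c;
      peak_of(M.colptr(i), r, c);
      acc += kl_sample(i, r, c);
    }
    return acc / n + psi * accu(act) / n;
  }

  double cost_perturb(uword jn, double xi_n) const override {
    const double* cmj = CM.colptr(jn);
    double acc_kl = 0.0, a_new = 0.0;
    for (uword i = 0; i < n; ++i) {
      double z = shrink1(S(i, jn), xi_n, alpha);
      a_new += std::fabs(z);
      double dz = z - Z(i, jn);
      const double* col = M.colptr(i);
      uword best = 0;
      double bv = col[0] + dz * cmj[0];
      for (uword p = 1; p < P; ++p) {
        double v = col[p] + dz * cmj[p];
        if (v > bv) { bv = v; best = p; }
      }
      double r = (double)(best / W) + 1.0;
      double c = (double)(best % W) + 1.0;
      acc_kl += kl_sample(i, r, c);
    }
    return acc_kl / n + psi * (accu(act) - act(jn) + a_new) / n;
  }
};

// Static ROI compression: reconstruction error over the ROI pixels of a
// single image on the sparse-coding scale (sum of squares / 2 sigma^2),
// plus the activity term.
struct RoiProblem : Problem {
  const vec& s;          // N code of the image
  const mat& Broi;       // P_roi x N pixel atoms restricted to the ROI
  vec xroi;              // ROI pixels of (x - pca mean)
  double psi, alpha, inv2s2;

  vec z, xi_cur, resid;
  uword N, P;

  RoiProblem(const vec& s_, const mat& Broi_, const vec& xroi_,
             double psi_, double alpha_, double sigma2_)
    : s(s_), Broi(Broi_), xroi(xroi_), psi(psi_), alpha(alpha_),
      inv2s2(1.0 / (2.0 * sigma2_)) {
    N = s.n_elem; P = xroi.n_elem;
  }

  void set_state(const vec& xi) override {
    xi_cur = xi;
    z.set_size(N);
    for (uword j = 0; j < N; ++j) z(j) = shrink1(s(j), xi(j), alpha);
    resid = xroi - Broi * z;
  }

  double cost() const override {
    return dot(resid, resid) * inv2s2 + psi * accu(abs(z));
  }

  double cost_perturb(uword jn, double xi_n) const override {
    double zn = shrink1(s(jn), xi_n, alpha);
    double dz = zn - z(jn);
    const double* bj = Broi.colptr(jn);
    double ss = 0.0;
    for (uword p = 0; p < P; ++p) {
      double r = resid(p) - dz * bj[p];
      ss += r * r;
    }
    return ss * inv2s2 +
      psi * (accu(abs(z)) - std::fabs(z(jn)) + std::fabs(zn));
  }
};

// ---------------------------------------------------------------------------
// Rprop on auxiliary variables a (xi = a^2), numerical central-difference
// gradient, monotone step acceptance: a proposed update is rejected (and all
// step sizes halved) if it does not decrease the cost or yields a non-finite
// value.

static Rcpp::List rprop_drive(Problem& prob, vec a, double h,
                              double step_init, double step_min,
                              double step_max, double eta_plus,
                              double eta_minus, int max_iter,
                              double reltol, int window) {
  const uword N = a.n_elem;
  vec step(N, fill::value(step_init));
  vec g(N), prev_g(N, fill::zeros);
  prob.set_state(square(a));
  double cost = prob.cost();
  std::vector<double> trace;
  trace.push_back(cost);
  int rejects = 0, it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    for (uword nn = 0; nn < N; ++nn) {
      double xp = (a(nn) + h) * (a(nn) + h);
      double xm = (a(nn) - h) * (a(nn) - h);
      g(nn) = (prob.cost_perturb(nn, xp) - prob.cost_perturb(nn, xm)) /
        (2.0 * h);
    }
    for (uword nn = 0; nn < N; ++nn) {
      double sgn = g(nn) * prev_g(nn);
      if (sgn > 0) step(nn) = std::min(step(nn) * eta_plus, step_max);
      else if (sgn < 0) step(nn) = std::max(step(nn) * eta_minus, step_min);
    }
    vec a_new = a;
    for (uword nn = 0; nn < N; ++nn) {
      if (g(nn) > 0) a_new(nn) -= step(nn);
      else if (g(nn) < 0) a_new(nn) += step(nn);
    }
    prob.set_state(square(a_new));
    double cnew = prob.cost();
    if (!std::isfinite(cnew) || cnew > cost) {
      // reject: restore, shrink all steps, reset gradient memory
      step = clamp(step * 0.5, step_min, step_max);
      prev_g.zeros();
      prob.set_state(square(a));
      ++rejects;
      if (all(step <= step_min) || rejects > 50) break;
    } else {
      a = a_new;
      cost = cnew;
      prev_g = g;
      rejects = 0;
      trace.push_back(cost);
      int k = (int)trace.size() - 1;
      if (k >= window) {
        double ref = trace[k - window];
        if (ref - cost <= reltol * std::max(std::fabs(ref), 1e-12)) {
          converged = true;
          break;
        }
      }
    }
  }
  vec xi_out = square(a);
  return Rcpp::List::create(
    Rcpp::Named("xi") = Rcpp::NumericVector(xi_out.begin(), xi_out.end()),
    Rcpp::Named("a") = Rcpp::NumericVector(a.begin(), a.end()),
    Rcpp::Named("cost") = cost,
    Rcpp::Named("trace") = Rcpp::NumericVector(trace.begin(), trace.end()),
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::List rprop_binary_cpp(const arma::mat& S, const arma::vec& w,
                            double c0, const arma::vec& zeta,
                            double muP, double sdP, double muA, double sdA,
                            double prior, double psi, double alpha,
                            bool use_abs, const arma::vec& a0, double h,
                            double step_init, double step_min,
                            double step_max, double eta_plus,
                            double eta_minus, int max_iter, double reltol,
                            int window) {
  BinaryProblem prob(S, w, c0, zeta, muP, sdP, muA, sdA, prior, psi, alpha,
                     use_abs);
  return rprop_drive(prob, a0, h, step_init, step_min, step_max, eta_plus,
                     eta_minus, max_iter, reltol, window);
}

// [[Rcpp::export]]
double cost_binary_cpp(const arma::mat& S, const arma::vec& xi,
                       const arma::vec& w, double c0, const arma::vec& zeta,
                       double muP, double sdP, double muA, double sdA,
                       double prior, double psi, double alpha, bool use_abs) {
  BinaryProblem prob(S, w, c0, zeta, muP, sdP, muA, sdA, prior, psi, alpha,
                     use_abs);
  prob.set_state(xi);
  return prob.cost();
}

// [[Rcpp::export]]
Rcpp::List rprop_local_cpp(const arma::mat& S, const arma::mat& CM,
                           const arma::vec& cc0, double mu0r, double mu0c,
                           double var0, double sm2, double psi, double alpha,
                           int W, const arma::vec& a0, double h,
                           double step_init, double step_min,
                           double step_max, double eta_plus,
                           double eta_minus, int max_iter, double reltol,
                           int window) {
  LocalProblem prob(S, CM, cc0, mu0r, mu0c, var0, sm2, psi, alpha,
                    (uword)W);
  return rprop_drive(prob, a0, h, step_init, step_min, step_max, eta_plus,
                     eta_minus, max_iter, reltol, window);
}

// [[Rcpp::export]]
double cost_local_cpp(const arma::mat& S, const arma::vec& xi,
                      const arma::mat& CM, const arma::vec& cc0,
                      double mu0r, double mu0c, double var0, double sm2,
                      double psi, double alpha, int W) {
  LocalProblem prob(S, CM, cc0, mu0r, mu0c, var0, sm2, psi, alpha,
                    (uword)W);
  prob.set_state(xi);
  return prob.cost();
}

// [[Rcpp::export]]
Rcpp::List rprop_roi_cpp(const arma::vec& s, const arma::mat& Broi,
                         const arma::vec& xroi, double psi, double alpha,
                         double sigma2, const arma::vec& a0, double h,
                         double step_init, double step_min, double step_max,
                         double eta_plus, double eta_minus, int max_iter,
                         double reltol, int window) {
  RoiProblem prob(s, Broi, xroi, psi, alpha, sigma2);
  return rprop_drive(prob, a0, h, step_init, step_min, step_max, eta_plus,
                     eta_minus, max_iter, reltol, window);
}

// Peak (row, col) of a cross-correlation map vector (row-major pixels),
// first maximum in scan order.
// [[Rcpp::export]]
Rcpp::IntegerVector cc_peak_cpp(const arma::vec& map, int W) {
  uword best = 0;
  double bv = map(0);
  for (uword p = 1; p < map.n_elem; ++p)
    if (map(p) > bv) { bv = map(p); best = p; }
  return Rcpp::IntegerVector::create((int)(best / W) + 1,
                                     (int)(best % W) + 1);
}
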