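#include <Rcpp.h>
using namespace Rcpp;

// Adjacent-category logit kernel shared by the whole ERS-GPCM family.
// Categories are scored 0..J-1; for step j = 1..J-1 the log-odds are
//   alpha1[i] * theta(n, subscale[i]) - (beta(i, g) + w_ni * tau(i, j)),
// with the effective threshold weight w_ni = exp(alpha2[i] * logw[n]).
// logw[n] is log(omega_n) for style-class persons and 0 (omega = 1)
// otherwise; alpha2 = 1 gives the plain ERS-GPCM, logw = 0 the GPCM.

static inline double cell_ll(const int y, const double a_th,
                             const double b, const double w,
                             const double *tau, const int Jm1) {
  // cumulative adjacent log-odds, log-sum-exp normalized
  // (rating scales in practice have few categories; 32 is a hard cap)
  double cums[33];
  double mx = 0.0, c = 0.0;
  cums[0] = 0.0;
  for (int j = 0; j < Jm1; ++j) {
    c += a_th - b - w * tau[j];
    cums[j + 1] = c;
    if (c > mx) mx = c;
  }
  double s = 0.0;
  for (int j = 0; j <= Jm1; ++j) s += std::exp(cums[j] - mx);
  return cums[y] - mx - std::log(s);
}

struct Pars {
  const IntegerMatrix &Y;
  const NumericMatrix &theta;
  const IntegerVector &subscale; // 1-based
  const NumericVector &logw;
  const NumericVector &alpha1;
  const NumericVector &alpha2;
  const NumericMatrix &beta;     // I x G
  const IntegerVector &cls;      // 1-based
  const NumericMatrix &tau;      // I x (J-1)
};

static inline double person_item_ll(const Pars &p, int n, int i) {
  const int Jm1 = p.tau.ncol();
  const int g = p.cls[n] - 1;
  const double w = std::exp(p.alpha2[i] * p.logw[n]);
  const double a_th = p.alpha1[i] * p.theta(n, p.subscale[i] - 1);
  std::vector<double> taui(Jm1);
  for (int j = 0; j < Jm1; ++j) taui[j] = p.tau(i, j);
  return cell_ll(p.Y(n, i), a_th, p.beta(i, g), w, taui.data(), Jm1);
}

// [[Rcpp::export]]
NumericVector ll_person_cpp(const IntegerMatrix &Y, const NumericMatrix &theta,
                            const IntegerVector &subscale,
                            const NumericVector &logw,
                            const NumericVector &alpha1,
                            const NumericVector &alpha2,
                            const NumericMatrix &beta,
                            const IntegerVector &cls,
                            const NumericMatrix &tau) {
  const int N = Y.nrow(), I = Y.ncol(), Jm1 = tau.ncol();
  if (Jm1 > 32) stop("at most 33 response categories are supported");
  NumericVector out(N);
  std::vector<double> taui(Jm1);
  for (int i = 0; i < I; ++i) {
    const double a1 = alpha1[i], a2 = alpha2[i];
    const int s = subscale[i] - 1;
    for (int j = 0; j < Jm1; ++j) taui[j] = tau(i, j);
    for (int n = 0; n < N; ++n) {
      const double w = std::exp(a2 * logw[n]);
      out[n] += cell_ll(Y(n, i), a1 * theta(n, s), beta(i, cls[n] - 1), w,
                        taui.data(), Jm1);
    }
  }
  return out;
}

// Sum of log-likelihood over the given items (1-based) and the persons in
// class `class_filter` (0 = all persons).
// [[Rcpp::export]]
double ll_subset_cpp(const IntegerMatrix &Y, const NumericMatrix &theta,
                     const IntegerVector &subscale, const NumericVector &logw,
                     const NumericVector &alpha1, const NumericVector &alpha2,
                     const NumericMatrix &beta, const IntegerVector &cls,
                     const NumericMatrix &tau, const IntegerVector &items,
                     const int class_filter) {
  const int N = Y.nrow(), Jm1 = tau.ncol();
  if (Jm1 > 32) stop("at most 33 response categories are supported");
  double out = 0.0;
  std::vector<double> taui(Jm1);
  for (int k = 0; k < items.size(); ++k) {
    const int i = items[k] - 1;
    const double a1 = alpha1[i], a2 = alpha2[i];
    const int s = subscale[i] - 1;
    for (int j = 0; j < Jm1; ++j) taui[j] = tau(i, j);
    for (int n = 0; n < N; ++n) {
      if (class_filter && cls[n] != class_filter) continue;
      const double w = std::exp(a2 * logw[n]);
      out += cell_ll(Y(n, i), a1 * theta(n, s), beta(i, cls[n] - 1), w,
                     taui.data(), Jm1);
    }
  }
  return out;
}

// In-place random-walk update of the class-specific difficulties under the
// sum-to-zero (per class) identification: item i is paired with the last
// item, so the column mean stays exactly zero.  Prior N(0, prior_var) on
// each difficulty.  Uses R's RNG; returns the number of accepted moves.
// [[Rcpp::export]]
int update_beta_cpp(const IntegerMatrix &Y, const NumericMatrix &theta,
                    const IntegerVector &subscale, const NumericVector &logw,
                    const NumericVector &alpha1, const NumericVector &alpha2,
                    NumericMatrix beta, const IntegerVector &cls,
                    const NumericMatrix &tau, const double step,
                    const double prior_var) {
  const int N = Y.nrow(), I = Y.ncol(), G = beta.ncol(), Jm1 = tau.ncol();
  int acc = 0;
  std::vector<double> tau_i(Jm1), tau_L(Jm1);
  for (int j = 0; j < Jm1; ++j) tau_L[j] = tau(I - 1, j);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < I - 1; ++i) {
      const double delta = R::rnorm(0.0, step);
      const double bi_new = beta(i, g) + delta;
      const double bL_new = beta(I - 1, g) - delta;
      double dll = 0.0;
      for (int j = 0; j < Jm1; ++j) tau_i[j] = tau(i, j);
      const double a1i = alpha1[i], a2i = alpha2[i];
      const double a1L = alpha1[I - 1], a2L = alpha2[I - 1];
      const int si = subscale[i] - 1, sL = subscale[I - 1] - 1;
      for (int n = 0; n < N; ++n) {
        if (cls[n] != g + 1) continue;
        const double wi = std::exp(a2i * logw[n]);
        const double wL = std::exp(a2L * logw[n]);
        dll += cell_ll(Y(n, i), a1i * theta(n, si), bi_new, wi,
                       tau_i.data(), Jm1)
             - cell_ll(Y(n, i), a1i * theta(n, si), beta(i, g), wi,
                       tau_i.data(), Jm1)
             + cell_ll(Y(n, I - 1), a1L * theta(n, sL), bL_new, wL,
                       tau_L.data(), Jm1)
             - cell_ll(Y(n, I - 1), a1L * theta(n, sL), beta(I - 1, g), wL,
                       tau_L.data(), Jm1);
      }
      const double dprior =
        (-0.5 * (bi_new * bi_new + bL_new * bL_new)
         + 0.5 * (beta(i, g) * beta(i, g)
                  + beta(I - 1, g) * beta(I - 1, g))) / prior_var;
      if (std::log(R::runif(0.0, 1.0)) < dll + dprior) {
        beta(i, g) = bi_new;
        beta(I - 1, g) = bL_new;
        ++acc;
      }
    }
  }
  return acc;
}

// In-place update of the step thresholds under the per-item sum-to-zero
// identification (threshold j paired with the last threshold).  When
// `shared` is true a single common tau row is assumed (GRSM/RSM): the move
// is applied to every item's row and the likelihood spans all items.
// [[Rcpp::export]]
int update_tau_cpp(const IntegerMatrix &Y, const NumericMatrix &theta,
                   const IntegerVector &subscale, const NumericVector &logw,
                   const NumericVector &alpha1, const NumericVector &alpha2,
                   const NumericMatrix &beta, const IntegerVector &cls,
                   NumericMatrix tau, const double step,
                   const double prior_var, const bool shared) {
  const int N = Y.nrow(), I = Y.ncol(), Jm1 = tau.ncol();
  if (Jm1 < 2) return 0; // a single threshold is pinned at zero by the
                         // sum constraint
  int acc = 0;
  std::vector<double> cur(Jm1), prop(Jm1);
  const int i_last = Jm1 - 1;
  if (shared) {
    for (int j = 0; j < Jm1 - 1; ++j) {
      const double delta = R::rnorm(0.0, step);
      for (int jj = 0; jj < Jm1; ++jj) cur[jj] = prop[jj] = tau(0, jj);
      prop[j] += delta;
      prop[i_last] -= delta;
      double dll = 0.0;
      for (int i = 0; i < I; ++i) {
        const double a1 = alpha1[i], a2 = alpha2[i];
        const int s = subscale[i] - 1;
        for (int n = 0; n < N; ++n) {
          const double w = std::exp(a2 * logw[n]);
          const double a_th = a1 * theta(n, s);
          const double b = beta(i, cls[n] - 1);
          dll += cell_ll(Y(n, i), a_th, b, w, prop.data(), Jm1)
               - cell_ll(Y(n, i), a_th, b, w, cur.data(), Jm1);
        }
      }
      const double dprior =
        (-0.5 * (prop[j] * prop[j] + prop[i_last] * prop[i_last])
         + 0.5 * (cur[j] * cur[j] + cur[i_last] * cur[i_last])) / prior_var;
      if (std::log(R::runif(0.0, 1.0)) < dll + dprior) {
        for (int i = 0; i < I; ++i) {
          tau(i, j) = prop[j];
          tau(i, i_last) = prop[i_last];
        }
        ++acc;
      }
    }
    return acc;
  }
  for (int i = 0; i < I; ++i) {
    const double a1 = alpha1[i], a2 = alpha2[i];
    const int s = subscale[i] - 1;
    for (int j = 0; j < Jm1 - 1; ++j) {
      const double delta = R::rnorm(0.0, step);
      for (int jj = 0; jj < Jm1; ++jj) cur[jj] = prop[jj] = tau(i, jj);
      prop[j] += delta;
      prop[i_last] -= delta;
      double dll = 0.0;
      for (int n = 0; n < N; ++n) {
        const double w = std::exp(a2 * logw[n]);
        const double a_th = a1 * theta(n, s);
        const double b = beta(i, cls[n] - 1);
        dll += cell_ll(Y(n, i), a_th, b, w, prop.data(), Jm1)
             - cell_ll(Y(n, i), a_th, b, w, cur.data(), Jm1);
      }
      const double dprior =
        (-0.5 * (prop[j] * prop[j] + prop[i_last] * prop[i_last])
         + 0.5 * (cur[j] * cur[j] + cur[i_last] * cur[i_last])) / prior_var;
      if (std::log(R::runif(0.0, 1.0)) < dll + dprior) {
        tau(i, j) = prop[j];
        tau(i, i_last) = prop[i_last];
        ++acc;
      }
    }
  }
  return acc;
}

// In-place update of the target-trait discriminations (log-scale random
// walk, lognormal(0, prior_var) prior).  For CD models (`use_mdp`), a
// proposal exceeding the item's MDP is rejected outright and alpha2 is
// kept in step via alpha2 = sqrt(mdp^2 - alpha1^2).
// [[Rcpp::export]]
int update_alpha_cpp(const IntegerMatrix &Y, const NumericMatrix &theta,
                     const IntegerVector &subscale, const NumericVector &logw,
                     NumericVector alpha1, NumericVector alpha2,
                     const NumericMatrix &beta, const IntegerVector &cls,
                     const NumericMatrix &tau, const double step,
                     const double prior_var, const bool use_mdp,
                     const NumericVector &mdp_item) {
  const int N = Y.nrow(), I = Y.ncol(), Jm1 = tau.ncol();
  int acc = 0;
  std::vector<double> taui(Jm1);
  for (int i = 0; i < I; ++i) {
    const double la_cur = std::log(alpha1[i]);
    const double la_new = la_cur + R::rnorm(0.0, step);
    const double a_new = std::exp(la_new);
    if (use_mdp && a_new >= mdp_item[i]) continue;
    double a2_new = alpha2[i];
    if (use_mdp) {
      a2_new = std::sqrt(mdp_item[i] * mdp_item[i] - a_new * a_new);
    }
    for (int j = 0; j < Jm1; ++j) taui[j] = tau(i, j);
    const int s = subscale[i] - 1;
    double dll = 0.0;
    for (int n = 0; n < N; ++n) {
      const double b = beta(i, cls[n] - 1);
      dll += cell_ll(Y(n, i), a_new * theta(n, s), b,
                     std::exp(a2_new * logw[n]), taui.data(), Jm1)
           - cell_ll(Y(n, i), alpha1[i] * theta(n, s), b,
                     std::exp(alpha2[i] * logw[n]), taui.data(), Jm1);
    }
    // lognormal prior on alpha1 plus the log-scale proposal Jacobian
    const double dprior = -0.5 * (la_new * la_new - la_cur * la_cur)
                          / prior_var;
    if (std::log(R::runif(0.0, 1.0)) < dll + dprior) {
      alpha1[i] = a_new;
      alpha2[i] = a2_new;
      ++acc;
    }
  }
  return acc;
}
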