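#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Emission probability of a binary observation under a Bernoulli state.
static inline double bprob(double e, int o) { return o ? e : 1.0 - e; }

static const double E_FLOOR = 1e-6;

// Baum-Welch for a Q-state hidden Markov chain with Bernoulli emissions on
// binary sequences (rows of `obs`).  Scaled forward-backward; returns the
// re-estimated parameters and the per-iteration total log-likelihood trace
// (log-likelihood of the data under the parameters *entering* each
// iteration, so the trace is non-decreasing).
// [[Rcpp::export(name = ".bw_bernoulli")]]
List bw_bernoulli(IntegerMatrix obs, NumericMatrix A0, NumericVector E0,
                  NumericVector pi0, int max_iter, double tol) {
  const int n = obs.nrow(), T = obs.ncol(), Q = E0.size();
  NumericMatrix A(clone(A0));
  NumericVector E(clone(E0)), pi(clone(pi0));
  std::vector<double> llhist;
  llhist.reserve(max_iter);

  std::vector<double> alpha(T * Q), beta(T * Q), scale(T);
  NumericMatrix A_num(Q, Q);
  NumericVector A_den(Q), E_num(Q), E_den(Q), pi_num(Q);

  double prev_ll = R_NegInf;
  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(A_num.begin(), A_num.end(), 0.0);
    std::fill(A_den.begin(), A_den.end(), 0.0);
    std::fill(E_num.begin(), E_num.end(), 0.0);
    std::fill(E_den.begin(), E_den.end(), 0.0);
    std::fill(pi_num.begin(), pi_num.end(), 0.0);
    double ll = 0.0;

    // cache emission probs for the two observation values and flatten A
    std::vector<double> b0(Q), b1(Q), Af(Q * Q);
    for (int q = 0; q < Q; ++q) { b0[q] = 1.0 - E[q]; b1[q] = E[q]; }
    for (int p = 0; p < Q; ++p)
      for (int q = 0; q < Q; ++q) Af[p * Q + q] = A(p, q);
    std::vector<int> row(T);

    for (int s = 0; s < n; ++s) {
      for (int t = 0; t < T; ++t) row[t] = obs(s, t);
      // forward with scaling
      double c0 = 0.0;
      for (int q = 0; q < Q; ++q) {
        alpha[q] = pi[q] * (row[0] ? b1[q] : b0[q]);
        c0 += alpha[q];
      }
      if (c0 <= 0) c0 = DBL_MIN;
      scale[0] = c0;
      for (int q = 0; q < Q; ++q) alpha[q] /= c0;
      for (int t = 1; t < T; ++t) {
        const double *ap = &alpha[(t - 1) * Q];
        const double *bv = row[t] ? &b1[0] : &b0[0];
        double *an = &alpha[t * Q];
        double ct = 0.0;
        for (int q = 0; q < Q; ++q) {
          double a = 0.0;
          for (int p = 0; p < Q; ++p) a += ap[p] * Af[p * Q + q];
          a *= bv[q];
          an[q] = a;
          ct += a;
        }
        if (ct <= 0) ct = DBL_MIN;
        scale[t] = ct;
        for (int q = 0; q < Q; ++q) an[q] /= ct;
      }
      for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

      // backward with the same scaling
      for (int q = 0; q < Q; ++q) beta[(T - 1) * Q + q] = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        const double *bn = &beta[(t + 1) * Q];
        const double *bv = row[t + 1] ? &b1[0] : &b0[0];
        double *bc = &beta[t * Q];
        const double inv_c = 1.0 / scale[t + 1];
        for (int q = 0; q < Q; ++q) {
          double b = 0.0;
          for (int r = 0; r < Q; ++r) b += Af[q * Q + r] * bv[r] * bn[r];
          bc[q] = b * inv_c;
        }
      }

      // accumulate expected counts (gamma, xi) in one sweep
      for (int t = 0; t < T; ++t) {
        const double *av = &alpha[t * Q];
        const double *bw = &beta[t * Q];
        const int o = row[t];
        for (int q = 0; q < Q; ++q) {
          double g = av[q] * bw[q];
          if (t == 0) pi_num[q] += g;
          E_den[q] += g;
          if (o) E_num[q] += g;
          if (t < T - 1) A_den[q] += g;
        }
        if (t < T - 1) {
          const double *bn = &beta[(t + 1) * Q];
          const double *bv = row[t + 1] ? &b1[0] : &b0[0];
          const double inv_c = 1.0 / scale[t + 1];
          for (int p = 0; p < Q; ++p) {
            const double apv = av[p] * inv_c;
            for (int q = 0; q < Q; ++q)
              A_num(p, q) += apv * Af[p * Q + q] * bv[q] * bn[q];
          }
        }
      }
    }

    llhist.push_back(ll);
    bool converged = (iter > 0) &&
      (ll - prev_ll) < tol * (std::fabs(prev_ll) + 1e-12);
    prev_ll = ll;
    if (converged) break;

    // M step
    for (int p = 0; p < Q; ++p) {
      if (A_den[p] > 0) {
        double rowsum = 0.0;
        for (int q = 0; q < Q; ++q) rowsum += A_num(p, q);
        if (rowsum > 0)
          for (int q = 0; q < Q; ++q) A(p, q) = A_num(p, q) / rowsum;
      }
      if (E_den[p] > 0) {
        double e = E_num[p] / E_den[p];
        E[p] = std::min(1.0 - E_FLOOR, std::max(E_FLOOR, e));
      }
    }
    double pisum = 0.0;
    for (int q = 0; q < Q; ++q) pisum += pi_num[q];
    if (pisum > 0) for (int q = 0; q < Q; ++q) pi[q] = pi_num[q] / pisum;
  }

  return List::create(_["A"] = A, _["E"] = E, _["pi"] = pi,
                      _["loglik"] = prev_ll,
                      _["loglik_trace"] = NumericVector(llhist.begin(),
                                                        llhist.end()),
                      _["n_iter"] = (int)llhist.size());
}

// Viterbi decoding of one binary sequence; 1-based state path.  Ties are
// broken toward the lower-index state (strict improvement required to move
// to a higher index).
// [[Rcpp::export(name = ".viterbi_bernoulli")]]
IntegerVector viterbi_bernoulli(IntegerVector obs, NumericMatrix A,
                                NumericVector E, NumericVector pi) {
  const int T = obs.size(), Q = E.size();
  std::vector<double> delta(T * Q);
  std::vector<int> psi(T * Q);
  for (int q = 0; q < Q; ++q)
    delta[q] = std::log(pi[q]) + std::log(bprob(E[q], obs[0]));
  for (int t = 1; t < T; ++t) {
    for (int q = 0; q < Q; ++q) {
      double best = R_NegInf;
      int arg = 0;
      for (int p = 0; p < Q; ++p) {
        double v = delta[(t - 1) * Q + p] + std::log(A(p, q));
        if (v > best) { best = v; arg = p; }
      }
      delta[t * Q + q] = best + std::log(bprob(E[q], obs[t]));
      psi[t * Q + q] = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int q = 0; q < Q; ++q)
    if (delta[(T - 1) * Q + q] > best) { best = delta[(T - 1) * Q + q]; arg = q; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi[(t + 1) * Q + arg];
    path[t] = arg + 1;
  }
  return path;
}

static inline double norm_pdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// EM for a two-component Gaussian mixture with weights fixed at (0.5, 0.5):
// only the means and SDs are updated.  SDs are floored at `sd_floor`.
// [[Rcpp::export(name = ".em_equal_mixture")]]
List em_equal_mixture(NumericVector x, double mu1, double mu2,
                      double s1, double s2, double sd_floor,
                      int max_iter, double tol) {
  const int n = x.size();
  s1 = std::max(s1, sd_floor);
  s2 = std::max(s2, sd_floor);
  double ll = R_NegInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double new_ll = 0.0, r1s = 0.0, r2s = 0.0, m1 = 0.0, m2 = 0.0;
    std::vector<double> r1(n);
    for (int i = 0; i < n; ++i) {
      double p1 = 0.5 * norm_pdf(x[i], mu1, s1);
      double p2 = 0.5 * norm_pdf(x[i], mu2, s2);
      double tot = p1 + p2;
      if (tot <= 0) { tot = DBL_MIN; p1 = tot / 2; }
      r1[i] = p1 / tot;
      new_ll += std::log(tot);
      r1s += r1[i]; r2s += 1.0 - r1[i];
      m1 += r1[i] * x[i]; m2 += (1.0 - r1[i]) * x[i];
    }
    bool converged = iter > 0 &&
      std::fabs(new_ll - ll) < tol * (std::fabs(ll) + 1e-12);
    ll = new_ll;
    if (converged) break;
    double nmu1 = r1s > 0 ? m1 / r1s : mu1;
    double nmu2 = r2s > 0 ? m2 / r2s : mu2;
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      v1 += r1[i] * (x[i] - nmu1) * (x[i] - nmu1);
      v2 += (1.0 - r1[i]) * (x[i] - nmu2) * (x[i] - nmu2);
    }
    mu1 = nmu1; mu2 = nmu2;
    s1 = std::max(r1s > 0 ? std::sqrt(v1 / r1s) : s1, sd_floor);
    s2 = std::max(r2s > 0 ? std::sqrt(v2 / r2s) : s2, sd_floor);
  }
  // responsibilities and log-likelihood under the final parameters
  NumericVector resp(n);
  double final_ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double p1 = 0.5 * norm_pdf(x[i], mu1, s1);
    double p2 = 0.5 * norm_pdf(x[i], mu2, s2);
    double tot = std::max(p1 + p2, DBL_MIN);
    resp[i] = p1 / tot;
    final_ll += std::log(tot);
  }
  return List::create(_["mu1"] = mu1, _["mu2"] = mu2, _["sigma1"] = s1,
                      _["sigma2"] = s2, _["log_likelihood"] = final_ll,
                      _["responsibilities"] = resp, _["n_iter"] = iter + 1);
}
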