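#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Internal view of a packed population (see pop_pack() on the R side).
// Tuning curves are products over stimulus dimensions of
//   exp((1/w) * (cos(2*pi*(s_j - pref_j)/lambda) - 1))
// scaled by a per-neuron amplitude, plus a shared baseline b.
// cos(2*pi*(s_j - pref_j)/lambda) is expanded as
//   cos(u)*cos(phi) + sin(u)*sin(phi),  u = 2*pi*s_j/lambda, phi = 2*pi*pref_j/lambda
// so that per evaluation only L*D trig calls and one exp per neuron are needed.
struct PopView {
  int N, D, L;
  double w, b;
  const double *a;        // N amplitudes
  const int *module_id;   // N, 0-based
  const double *lambda_m; // L module periods
  const double *cosphi;   // N x D, column-major
  const double *sinphi;   // N x D
};

static PopView unpack(const List &pack) {
  PopView p;
  p.N = as<int>(pack["N"]);
  p.D = as<int>(pack["D"]);
  p.L = as<int>(pack["L"]);
  p.w = as<double>(pack["w"]);
  p.b = as<double>(pack["b"]);
  p.a = REAL(pack["a"]);
  p.module_id = INTEGER(pack["module_id"]);
  p.lambda_m = REAL(pack["lambda_m"]);
  p.cosphi = REAL(pack["cosphi"]);
  p.sinphi = REAL(pack["sinphi"]);
  return p;
}

// Evaluate all N rates at stimulus s (length D). Scratch cu/su are L*D.
static inline void rates_at(const PopView &p, const double *s,
                            std::vector<double> &cu, std::vector<double> &su,
                            std::vector<double> &f) {
  const double twopi = 2.0 * M_PI;
  for (int m = 0; m < p.L; ++m) {
    for (int j = 0; j < p.D; ++j) {
      double u = twopi * s[j] / p.lambda_m[m];
      cu[m + p.L * j] = std::cos(u);
      su[m + p.L * j] = std::sin(u);
    }
  }
  const double invw = 1.0 / p.w;
  for (int i = 0; i < p.N; ++i) {
    int m = p.module_id[i];
    double acc = 0.0;
    for (int j = 0; j < p.D; ++j) {
      acc += cu[m + p.L * j] * p.cosphi[i + p.N * j] +
             su[m + p.L * j] * p.sinphi[i + p.N * j];
    }
    f[i] = p.a[i] * std::exp(invw * (acc - p.D)) + p.b;
  }
}

// Log-likelihood (stimulus-dependent terms): V = sum_i r_i log(T f_i) - T f_i,
// with r given sparsely (idx 0-based, cnt > 0).
static double loglik_at(const PopView &p, const std::vector<int> &idx,
                        const std::vector<double> &cnt, double T, const double *s,
                        std::vector<double> &cu, std::vector<double> &su,
                        std::vector<double> &f) {
  rates_at(p, s, cu, su, f);
  double tot = 0.0;
  for (int i = 0; i < p.N; ++i) tot += f[i];
  double V = -T * tot;
  for (size_t k = 0; k < idx.size(); ++k) {
    double fi = f[idx[k]];
    if (fi <= 0.0) return -std::numeric_limits<double>::infinity();
    V += cnt[k] * std::log(T * fi);
  }
  return V;
}

struct NMResult {
  std::vector<double> x;
  double fval;
  bool converged;
};

// Nelder-Mead maximization of the log-likelihood (minimizes -V).
// Standard coefficients; stops when simplex diameter < ptol and
// function spread < ftol, or after maxit iterations.
static NMResult nelder_mead(const PopView &p, const std::vector<int> &idx,
                            const std::vector<double> &cnt, double T,
                            const double *start, double ptol, double ftol,
                            int maxit, std::vector<double> &cu,
                            std::vector<double> &su, std::vector<double> &f) {
  const int D = p.D;
  const int n = D + 1;
  std::vector<std::vector<double>> X(n, std::vector<double>(D));
  std::vector<double> F(n);
  const double step = 0.02;
  for (int v = 0; v < n; ++v) {
    for (int j = 0; j < D; ++j) X[v][j] = start[j] + (v == j + 1 ? step : 0.0);
    F[v] = -loglik_at(p, idx, cnt, T, X[v].data(), cu, su, f);
  }
  std::vector<double> xc(D), xr(D), xe(D), xk(D);
  int it = 0;
  bool conv = false;
  for (; it < maxit; ++it) {
    // order
    std::vector<int> ord(n);
    for (int v = 0; v < n; ++v) ord[v] = v;
    std::sort(ord.begin(), ord.end(), [&](int a2, int b2) { return F[a2] < F[b2]; });
    std::vector<std::vector<double>> X2(n);
    std::vector<double> F2(n);
    for (int v = 0; v < n; ++v) { X2[v] = X[ord[v]]; F2[v] = F[ord[v]]; }
    X.swap(X2); F.swap(F2);
    // convergence
    double diam = 0.0;
    for (int v = 1; v < n; ++v)
      for (int j = 0; j < D; ++j) diam = std::max(diam, std::fabs(X[v][j] - X[0][j]));
    if (diam < ptol && std::fabs(F[n - 1] - F[0]) < ftol) { conv = true; break; }
    // centroid of best n-1
    for (int j = 0; j < D; ++j) {
      double s2 = 0.0;
      for (int v = 0; v < n - 1; ++v) s2 += X[v][j];
      xc[j] = s2 / (n - 1);
    }
    auto feval = [&](const std::vector<double> &x) {
      return -loglik_at(p, idx, cnt, T, x.data(), cu, su, f);
    };
    for (int j = 0; j < D; ++j) xr[j] = xc[j] + (xc[j] - X[n - 1][j]);
    double fr = feval(xr);
    if (fr < F[0]) {
      for (int j = 0; j < D; ++j) xe[j] = xc[j] + 2.0 * (xc[j] - X[n - 1][j]);
      double fe = feval(xe);
      if (fe < fr) { X[n - 1] = xe; F[n - 1] = fe; }
      else { X[n - 1] = xr; F[n - 1] = fr; }
    } else if (fr < F[n - 2]) {
      X[n - 1] = xr; F[n - 1] = fr;
    } else {
      if (fr < F[n - 1]) { // outside contraction
        for (int j = 0; j < D; ++j) xk[j] = xc[j] + 0.5 * (xr[j] - xc[j]);
        double fk = feval(xk);
        if (fk <= fr) { X[n - 1] = xk; F[n - 1] = fk; }
        else goto shrink;
      } else { // inside contraction
        for (int j = 0; j < D; ++j) xk[j] = xc[j] - 0.5 * (xc[j] - X[n - 1][j]);
        double fk = feval(xk);
        if (fk < F[n - 1]) { X[n - 1] = xk; F[n - 1] = fk; }
        else goto shrink;
      }
      continue;
    shrink:
      for (int v = 1; v < n; ++v) {
        for (int j = 0; j < D; ++j) X[v][j] = X[0][j] + 0.5 * (X[v][j] - X[0][j]);
        F[v] = feval(X[v]);
      }
    }
  }
  // final best
  int best = 0;
  for (int v = 1; v < n; ++v) if (F[v] < F[best]) best = v;
  NMResult res;
  res.x = X[best];
  res.fval = -F[best];
  res.converged = conv;
  return res;
}

static inline double wrap01(double x) {
  double y = x - std::floor(x);
  return (y >= 1.0) ? 0.0 : y;
}

static inline double circ_eps2(double s, double shat) {
  double d = s - shat;
  double e1 = d * d, e2 = (d + 1.0) * (d + 1.0), e3 = (d - 1.0) * (d - 1.0);
  return std::min(e1, std::min(e2, e3));
}

struct DecodeOut {
  std::vector<double> s_hat, s_prewrap, eps2;
  double value;
  int n_converged;
};

// Decode one observation: evaluate V at the candidate starting grid, keep the
// top 4, add the true stimulus, run Nelder-Mead from each of the 5 starts,
// take the best local optimum (ties broken toward the true stimulus), wrap
// componentwise mod 1.
static DecodeOut decode_one(const PopView &p, const std::vector<int> &idx,
                            const std::vector<double> &cnt, double T,
                            const double *s_true, const double *cand, int ncand,
                            double ptol, double ftol, int maxit,
                            std::vector<double> &cu, std::vector<double> &su,
                            std::vector<double> &f) {
  const int D = p.D;
  std::vector<double> Vc(ncand);
  for (int k = 0; k < ncand; ++k) {
    std::vector<double> s(D);
    for (int j = 0; j < D; ++j) s[j] = cand[k + ncand * j];
    Vc[k] = loglik_at(p, idx, cnt, T, s.data(), cu, su, f);
  }
  int keep = std::min(4, ncand);
  std::vector<int> ord(ncand);
  for (int k = 0; k < ncand; ++k) ord[k] = k;
  std::partial_sort(ord.begin(), ord.begin() + keep, ord.end(),
                    [&](int a2, int b2) { return Vc[a2] > Vc[b2]; });
  std::vector<std::vector<double>> starts;
  for (int k = 0; k < keep; ++k) {
    std::vector<double> s(D);
    for (int j = 0; j < D; ++j) s[j] = cand[ord[k] + ncand * j];
    starts.push_back(s);
  }
  starts.push_back(std::vector<double>(s_true, s_true + D));

  double bestV = -std::numeric_limits<double>::infinity();
  std::vector<double> bestx(D, 0.0);
  double best_dist = std::numeric_limits<double>::infinity();
  int n_conv = 0;
  for (size_t k = 0; k < starts.size(); ++k) {
    NMResult r = nelder_mead(p, idx, cnt, T, starts[k].data(), ptol, ftol, maxit,
                             cu, su, f);
    if (!r.converged) continue; // discarded; caller warns via n_converged
    ++n_conv;
    double dist = 0.0;
    for (int j = 0; j < D; ++j) dist += circ_eps2(s_true[j], wrap01(r.x[j]));
    bool better = r.fval > bestV + ftol;
    bool tie = std::fabs(r.fval - bestV) <= ftol && dist < best_dist;
    if (better || tie) {
      bestV = std::max(r.fval, bestV);
      bestx = r.x;
      best_dist = dist;
    }
  }
  if (n_conv == 0)
    Rcpp::stop("maximum-likelihood search failed to converge from every starting point");
  DecodeOut out;
  out.s_prewrap = bestx;
  out.s_hat.resize(D);
  out.eps2.resize(D);
  for (int j = 0; j < D; ++j) {
    out.s_hat[j] = wrap01(bestx[j]);
    out.eps2[j] = circ_eps2(s_true[j], out.s_hat[j]);
  }
  out.value = bestV;
  out.n_converged = n_conv;
  return out;
}

static void sparse_counts(const PopView &p, const std::vector<double> &r,
                          std::vector<int> &idx, std::vector<double> &cnt) {
  idx.clear(); cnt.clear();
  for (int i = 0; i < p.N; ++i)
    if (r[i] > 0) { idx.push_back(i); cnt.push_back(r[i]); }
}

// [[Rcpp::export]]
NumericVector rates_cpp(List pack, NumericVector s) {
  PopView p = unpack(pack);
  std::vector<double> cu(p.L * p.D), su(p.L * p.D), f(p.N);
  rates_at(p, REAL(s), cu, su, f);
  return NumericVector(f.begin(), f.end());
}

// [[Rcpp::export]]
double loglik_cpp(List pack, NumericVector r, NumericVector s, double T) {
  PopView p = unpack(pack);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> idx; std::vector<double> cnt;
  sparse_counts(p, rv, idx, cnt);
  std::vector<double> cu(p.L * p.D), su(p.L * p.D), f(p.N);
  return loglik_at(p, idx, cnt, T, REAL(s), cu, su, f);
}

// [[Rcpp::export]]
NumericVector loglik_grid_cpp(List pack, NumericVector r, NumericMatrix sgrid,
                              double T) {
  PopView p = unpack(pack);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> idx; std::vector<double> cnt;
  sparse_counts(p, rv, idx, cnt);
  std::vector<double> cu(p.L * p.D), su(p.L * p.D), f(p.N);
  int n = sgrid.nrow();
  NumericVector out(n);
  std::vector<double> s(p.D);
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < p.D; ++j) s[j] = sgrid(k, j);
    out[k] = loglik_at(p, idx, cnt, T, s.data(), cu, su, f);
  }
  return out;
}

// [[Rcpp::export]]
List decode_one_cpp(List pack, NumericVector r, double T, NumericVector s_true,
                    NumericMatrix candidates, double ptol, double ftol,
                    int maxit) {
  PopView p = unpack(pack);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> idx; std::vector<double> cnt;
  sparse_counts(p, rv, idx, cnt);
  std::vector<double> cu(p.L * p.D), su(p.L * p.D), f(p.N);
  DecodeOut o = decode_one(p, idx, cnt, T, REAL(s_true), REAL(candidates),
                           candidates.nrow(), ptol, ftol, maxit, cu, su, f);
  return List::create(_["s_hat"] = NumericVector(o.s_hat.begin(), o.s_hat.end()),
                      _["s_prewrap"] = NumericVector(o.s_prewrap.begin(), o.s_prewrap.end()),
                      _["value"] = o.value,
                      _["eps2"] = NumericVector(o.eps2.begin(), o.eps2.end()),
                      _["n_converged"] = o.n_converged);
}

// Run n_trials full decoding trials at decoding window T: draw a uniform
// stimulus, draw Poisson counts r_i ~ Pois(T f_i(s)), decode by ML, record
// the per-dimension squared circular errors. Uses R's RNG stream.
// [[Rcpp::export]]
List mse_trials_cpp(List pack, double T, int n_trials, int n_candidates,
                    double ptol, double ftol, int maxit) {
  PopView p = unpack(pack);
  std::vector<double> cu(p.L * p.D), su(p.L * p.D), f(p.N);
  NumericMatrix eps2(n_trials, p.D);
  NumericVector spikes(n_trials);
  std::vector<double> s_true(p.D), rv(p.N);
  std::vector<double> cand(n_candidates * p.D);
  std::vector<int> idx; std::vector<double> cnt;
  for (int t = 0; t < n_trials; ++t) {
    for (int j = 0; j < p.D; ++j) s_true[j] = unif_rand();
    rates_at(p, s_true.data(), cu, su, f);
    double tot = 0.0;
    for (int i = 0; i < p.N; ++i) { rv[i] = R::rpois(T * f[i]); tot += rv[i]; }
    spikes[t] = tot;
    for (int k = 0; k < n_candidates * p.D; ++k) cand[k] = unif_rand();
    sparse_counts(p, rv, idx, cnt);
    DecodeOut o = decode_one(p, idx, cnt, T, s_true.data(), cand.data(),
                             n_candidates, ptol, ftol, maxit, cu, su, f);
    for (int j = 0; j < p.D; ++j) eps2(t, j) = o.eps2[j];
    if ((t & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["eps2"] = eps2, _["spikes"] = spikes);
}

// Monte-Carlo Fisher information per unit time: for each sampled stimulus,
// J_kl(s) = sum_i (df_i/ds_k)(df_i/ds_l) / f_i(s) for independent Poisson
// spike counts; returns the element-wise average over n_stimuli uniform draws.
// [[Rcpp::export]]
NumericMatrix fisher_mc_cpp(List pack, int n_stimuli) {
  PopView p = unpack(pack);
  const int D = p.D;
  const double twopi = 2.0 * M_PI;
  std::vector<double> cu(p.L * D), su(p.L * D), f(p.N);
  std::vector<double> s(D), g(D);
  NumericMatrix J(D, D);
  const double invw = 1.0 / p.w;
  for (int t = 0; t < n_stimuli; ++t) {
    for (int j = 0; j < D; ++j) s[j] = unif_rand();
    rates_at(p, s.data(), cu, su, f);
    for (int i = 0; i < p.N; ++i) {
      if (f[i] <= 0.0) Rcpp::stop("zero rate with nonzero derivative in Fisher estimate");
      int m = p.module_id[i];
      double evoked = f[i] - p.b;
      for (int j = 0; j < D; ++j) {
        // d/ds_j of cos(2 pi (s_j - pref)/lambda) = -(2 pi/lambda) sin(...)
        double sdiff = su[m + p.L * j] * p.cosphi[i + p.N * j] -
                       cu[m + p.L * j] * p.sinphi[i + p.N * j];
        g[j] = evoked * invw * (-twopi / p.lambda_m[m]) * sdiff;
      }
      for (int k = 0; k < D; ++k)
        for (int l = 0; l <= k; ++l)
          J(k, l) += g[k] * g[l] / f[i];
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < D; ++k)
    for (int l = 0; l <= k; ++l) {
      J(k, l) /= n_stimuli;
      J(l, k) = J(k, l);
    }
  return J;
}
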