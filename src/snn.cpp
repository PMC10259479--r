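#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Two-layer feed-forward LIF network with delta synapses on a fixed dt grid.
// Layer 1 ("tuning" layer, no recurrent connections) receives Poisson input
// whose rate follows a circular tuning curve of the instantaneous stimulus.
// Layer 2 ("readout" layer) receives delayed, tuning-matched EPSPs from layer
// 1 (weight matrix W_EE, N2 x N1), delayed lateral IPSPs from other readout
// neurons (W_I, N2 x N2) and non-specific Poisson background drive.
// Membrane decay between grid points is exact; PSP deliveries are snapped to
// the grid, so the integration is exact up to the grid resolution.
// [[Rcpp::export]]
List simulate_snn_cpp(List cfg, NumericVector stimulus) {
  const int N1 = as<int>(cfg["N1"]);
  const int N2 = as<int>(cfg["N2"]);
  const int L = as<int>(cfg["L"]);
  NumericVector lambda_m = cfg["lambda_m"];
  IntegerVector module_id = cfg["module_id"]; // 0-based, length N1
  NumericVector cosphi = cfg["cosphi"];       // length N1: cos(2 pi pref/lambda)
  NumericVector sinphi = cfg["sinphi"];
  const double a_in = as<double>(cfg["a_in"]);
  const double b_in = as<double>(cfg["b_in"]);
  const double w = as<double>(cfg["w"]);
  const double J_E = as<double>(cfg["J_E"]);
  NumericMatrix W_EE = cfg["W_EE"]; // N2 x N1
  NumericMatrix W_I = cfg["W_I"];   // N2 x N2
  const double tau_mem = as<double>(cfg["tau_mem"]);
  const double V_th = as<double>(cfg["V_th"]);
  const double V_reset = as<double>(cfg["V_reset"]);
  const double V_rest = as<double>(cfg["V_rest"]);
  const double tau_rp = as<double>(cfg["tau_rp"]);
  const double delay = as<double>(cfg["delay"]);
  const double dt = as<double>(cfg["dt"]);
  const double b_ext = as<double>(cfg["b_ext"]);

  const int n_steps = stimulus.size();
  const int delay_steps = (int)std::lround(delay / dt);
  const int refr_steps = (int)std::lround(tau_rp / dt);
  const double decay = std::exp(-dt / tau_mem);
  const double twopi = 2.0 * M_PI;
  const double invw = 1.0 / w;

  std::vector<double> V1(N1, V_rest), V2(N2, V_rest);
  std::vector<int> refr1(N1, 0), refr2(N2, 0);
  const int buflen = delay_steps + 1;
  std::vector<double> buf(buflen * N2, 0.0); // pending PSPs for layer 2
  std::vector<double> cu(L), su(L);

  std::vector<double> t1, t2;
  std::vector<int> id1, id2;

  for (int t = 0; t < n_steps; ++t) {
    const double s = stimulus[t];
    const double tnow = t * dt;
    for (int m = 0; m < L; ++m) {
      double u = twopi * s / lambda_m[m];
      cu[m] = std::cos(u);
      su[m] = std::sin(u);
    }
    const int slot_now = t % buflen;
    const int slot_del = (t + delay_steps) % buflen;
    // layer 1
    for (int i = 0; i < N1; ++i) {
      if (refr1[i] > 0) { --refr1[i]; continue; }
      V1[i] = V_rest + (V1[i] - V_rest) * decay;
      int m = module_id[i];
      double rate = a_in * std::exp(invw * (cu[m] * cosphi[i] + su[m] * sinphi[i] - 1.0)) + b_in;
      int k = (int)R::rpois(rate * dt);
      if (k > 0) V1[i] += J_E * k;
      if (V1[i] >= V_th) {
        t1.push_back(tnow);
        id1.push_back(i + 1);
        V1[i] = V_reset;
        refr1[i] = refr_steps;
        double *col = &W_EE(0, i);
        double *dst = &buf[slot_del * N2];
        for (int n = 0; n < N2; ++n) dst[n] += col[n];
      }
    }
    // layer 2
    double *cur = &buf[slot_now * N2];
    for (int i = 0; i < N2; ++i) {
      if (refr2[i] > 0) { --refr2[i]; cur[i] = 0.0; continue; }
      V2[i] = V_rest + (V2[i] - V_rest) * decay;
      V2[i] += cur[i];
      cur[i] = 0.0;
      int k = (int)R::rpois(b_ext * dt);
      if (k > 0) V2[i] += J_E * k;
      if (V2[i] >= V_th) {
        t2.push_back(tnow);
        id2.push_back(i + 1);
        V2[i] = V_reset;
        refr2[i] = refr_steps;
        double *col = &W_I(0, i);
        double *dst = &buf[slot_del * N2];
        for (int n = 0; n < N2; ++n) dst[n] += col[n];
      }
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t1"] = NumericVector(t1.begin(), t1.end()),
                      _["id1"] = IntegerVector(id1.begin(), id1.end()),
                      _["t2"] = NumericVector(t2.begin(), t2.end()),
                      _["id2"] = IntegerVector(id2.begin(), id2.end()));
}

// Single LIF neuron driven by homogeneous Poisson input (diffusion-oracle
// checks); returns spike count over the simulated duration.
// [[Rcpp::export]]
int lif_poisson_count_cpp(double rate, double J, double duration, double dt,
                          double tau_mem, double V_th, double V_reset,
                          double V_rest, double tau_rp) {
  const int n_steps = (int)std::lround(duration / dt);
  const int refr_steps = (int)std::lround(tau_rp / dt);
  const double decay = std::exp(-dt / tau_mem);
  double V = V_rest;
  int refr = 0, count = 0;
  for (int t = 0; t < n_steps; ++t) {
    if (refr > 0) { --refr; continue; }
    V = V_rest + (V - V_rest) * decay;
    int k = (int)R::rpois(rate * dt);
    if (k > 0) V += J * k;
    if (V >= V_th) {
      ++count;
      V = V_reset;
      refr = refr_steps;
    }
  }
  return count;
}
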