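#include <Rcpp.h>
using namespace Rcpp;

// firing-rate transfer r(x) = (a x - b) / (1 - exp(-d (a x - b)))
// with the removable singularity at a x = b filled by 1/d
static inline double transfer(double x, double a, double b, double d) {
  double u = a * x - b;
  if (std::fabs(u) < 1e-9) return 1.0 / d;
  return u / (1.0 - std::exp(-d * u));
}

// Euler-Maruyama integration of the gating dynamics
//   dS_i = [-S_i/tau_s + gamma (1 - S_i) r(x_i)] dt + sigma_i dW_i
//   x_i  = w_i J S_i + G J sum_j SC_ij S_j + I_i
// S is clamped to [0,1]; clamping events are counted. Noise is drawn from
// R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List mfm_simulate_cpp(NumericVector w, NumericVector I, NumericVector sigma,
                      NumericMatrix sc, double G,
                      double a, double b, double d, double tau_s,
                      double gamma_k, double J,
                      double duration, double dt, double burn_in,
                      double store_dt, NumericVector s0) {
  int N = w.size();
  int n_steps = (int)std::llround((duration + burn_in) / dt);
  int burn_steps = (int)std::llround(burn_in / dt);
  int every = std::max(1, (int)std::llround(store_dt / dt));
  int n_store = (n_steps - burn_steps) / every;
  NumericMatrix S_out(n_store, N);
  std::vector<double> S(N), cpl(N);
  for (int i = 0; i < N; ++i) S[i] = s0[i];
  double sqdt = std::sqrt(dt);
  long clamped = 0;
  int row = 0;
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < N; ++i) {
      double c = 0.0;
      for (int j = 0; j < N; ++j) c += sc(i, j) * S[j];
      cpl[i] = c;
    }
    for (int i = 0; i < N; ++i) {
      double x = w[i] * J * S[i] + G * J * cpl[i] + I[i];
      double drift = -S[i] / tau_s + gamma_k * (1.0 - S[i]) * transfer(x, a, b, d);
      double s_new = S[i] + drift * dt + sigma[i] * sqdt * norm_rand();
      if (!std::isfinite(s_new))
        stop("mean-field integration diverged at step %d, region %d",
             t + 1, i + 1);
      if (s_new < 0.0) { s_new = 0.0; ++clamped; }
      else if (s_new > 1.0) { s_new = 1.0; ++clamped; }
      S[i] = s_new;
    }
    if (t >= burn_steps && (t - burn_steps + 1) % every == 0 && row < n_store) {
      for (int i = 0; i < N; ++i) S_out(row, i) = S[i];
      ++row;
    }
  }
  return List::create(_["S"] = S_out,
                      _["clamp_fraction"] = (double)clamped / ((double)n_steps * N));
}

// Balloon-Windkessel hemodynamic model driven by a gating series S (rows at
// resolution dt), returning BOLD sampled every TR. States per region:
// vasodilatory signal zs, inflow f, volume v, deoxyhemoglobin q.
// [[Rcpp::export]]
NumericMatrix bold_cpp(NumericMatrix S, double dt,
                       double kappa, double gamma_h, double tau,
                       double alpha, double rho, double V0, double TR) {
  int T = S.nrow(), N = S.ncol();
  int every = std::max(1, (int)std::llround(TR / dt));
  int n_out = T / every;
  NumericMatrix B(n_out, N);
  double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * 0.2 - 0.2; // epsilon = 0.2
  for (int i = 0; i < N; ++i) {
    double zs = 0.0, f = 1.0, v = 1.0, q = 1.0;
    int row = 0;
    for (int t = 0; t < T; ++t) {
      double u = S(t, i);
      double dz = u - kappa * zs - gamma_h * (f - 1.0);
      double df = zs;
      double fv = std::pow(v, 1.0 / alpha);
      double dv = (f - fv) / tau;
      double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double dq = (f * Ef / rho - fv * q / v) / tau;
      zs += dz * dt; f += df * dt; v += dv * dt; q += dq * dt;
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      if (!std::isfinite(q) || !std::isfinite(v))
        stop("hemodynamic integration diverged at step %d, region %d",
             t + 1, i + 1);
      if ((t + 1) % every == 0 && row < n_out) {
        B(row, i) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
        ++row;
      }
    }
  }
  return B;
}

// Degree-preserving double-edge swaps within length bins (Maslov-Sneppen).
// edges: m x 2 matrix of 0-based endpoints; bin: bin label per edge;
// weights travel with the edge slot. adjacency is maintained to reject
// swaps creating self- or duplicate edges, and a swap is accepted only if
// both new edges still fall inside the bin being shuffled, so the binned
// edge-length distribution is preserved exactly. Acceptance under the
// length constraint is rare on spatially embedded graphs, hence the large
// default number of attempted swaps per edge in the R wrapper.
// [[Rcpp::export]]
List rewire_swaps_cpp(IntegerMatrix edges, IntegerVector bin, int n_nodes,
                      double passes, NumericMatrix dist,
                      NumericVector breaks) {
  int m = edges.nrow();
  std::vector<int> a(m), b(m);
  for (int e = 0; e < m; ++e) { a[e] = edges(e, 0); b[e] = edges(e, 1); }
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    adj[(size_t)a[e] * n_nodes + b[e]] = 1;
    adj[(size_t)b[e] * n_nodes + a[e]] = 1;
  }
  int n_bins = 0;
  for (int e = 0; e < m; ++e) if (bin[e] + 1 > n_bins) n_bins = bin[e] + 1;
  std::vector<std::vector<int>> by_bin(n_bins);
  for (int e = 0; e < m; ++e) by_bin[bin[e]].push_back(e);
  RNGScope scope;
  long done = 0;
  for (int bb = 0; bb < n_bins; ++bb) {
    std::vector<int>& idx = by_bin[bb];
    int nb = idx.size();
    if (nb < 2) continue;                    // skipped: too few edges to swap
    long attempts = (long)std::ceil(passes * nb);
    for (long t = 0; t < attempts; ++t) {
      int e1 = idx[(int)(unif_rand() * nb)];
      int e2 = idx[(int)(unif_rand() * nb)];
      if (e1 == e2) continue;
      int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
      if (unif_rand() < 0.5) std::swap(x2, y2);   // random orientation
      // proposed: (x1, y2) and (x2, y1)
      if (x1 == y2 || x2 == y1) continue;
      if (adj[(size_t)x1 * n_nodes + y2] || adj[(size_t)x2 * n_nodes + y1])
        continue;
      double lo = breaks[bb], hi = breaks[bb + 1];
      double d1 = dist(x1, y2), d2 = dist(x2, y1);
      if (d1 < lo || d1 > hi || d2 < lo || d2 > hi) continue;
      adj[(size_t)x1 * n_nodes + y1] = adj[(size_t)y1 * n_nodes + x1] = 0;
      adj[(size_t)x2 * n_nodes + y2] = adj[(size_t)y2 * n_nodes + x2] = 0;
      a[e1] = x1; b[e1] = y2;
      a[e2] = x2; b[e2] = y1;
      adj[(size_t)x1 * n_nodes + y2] = adj[(size_t)y2 * n_nodes + x1] = 1;
      adj[(size_t)x2 * n_nodes + y1] = adj[(size_t)y1 * n_nodes + x2] = 1;
      ++done;
    }
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = a[e]; out(e, 1) = b[e]; }
  return List::create(_["edges"] = out, _["n_swaps"] = (double)done);
}
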