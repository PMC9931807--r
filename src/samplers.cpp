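#include <Rcpp.h>
using namespace Rcpp;

// Single-site Metropolis-Hastings for the Ising model with fields.
// One sweep = M proposed single-site flips at uniformly chosen sites;
// acceptance probability min(1, exp(-beta * dU)). A configuration is
// recorded every `thin` sweeps once `burn_in` sweeps have elapsed.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix mh_sample_cpp(IntegerVector x0, NumericVector r, NumericMatrix W,
                            double beta, int n_samples, int burn_in, int thin) {
  const int M = x0.size();
  std::vector<int> x(x0.begin(), x0.end());
  IntegerMatrix out(n_samples, M);
  int kept = 0;
  const long total = (long)burn_in + (long)n_samples * thin;
  for (long s = 0; s < total && kept < n_samples; ++s) {
    for (int p = 0; p < M; ++p) {
      int i = (int)(unif_rand() * M);
      if (i >= M) i = M - 1;
      double field = r[i];
      for (int j = 0; j < M; ++j) field += W(i, j) * x[j]; // W(i,i) == 0
      // flipping x_i changes U by -field (0->1) or +field (1->0)
      double dU = x[i] ? field : -field;
      if (dU <= 0.0 || unif_rand() < std::exp(-beta * dU)) x[i] = 1 - x[i];
    }
    if (s >= burn_in && ((s - burn_in + 1) % thin == 0)) {
      for (int j = 0; j < M; ++j) out(kept, j) = x[j];
      ++kept;
    }
  }
  return out;
}

// Euler integration of a two-population leaky integrate-and-fire network.
// Per frame and neuron: V += dt * (v_rest - V) / tau + sigma * eps / sqrt(tau),
// plus the stimulus increment for group-A neurons on stimulus frames and
// a * (number of parents that spiked on the previous frame) for group-B
// neurons. A spike is emitted when V > threshold, after which V resets to
// v_rest. `parents` holds 0-based A-neuron indices, one row per B neuron.
// [[Rcpp::export]]
IntegerMatrix lif_sim_cpp(int n_frames, NumericVector tau, int n_A,
                          IntegerMatrix parents, LogicalVector stim,
                          double dt, double sigma, double a, double gain,
                          double v_rest, double threshold) {
  const int N = tau.size();
  const int n_B = N - n_A;
  IntegerMatrix spikes(n_frames, N);
  std::vector<double> V(N, v_rest), noise_sd(N);
  for (int i = 0; i < N; ++i) noise_sd[i] = sigma / std::sqrt(tau[i]);
  std::vector<int> prevA(n_A, 0);
  for (int t = 0; t < n_frames; ++t) {
    for (int i = 0; i < N; ++i) {
      double v = V[i] + dt * (v_rest - V[i]) / tau[i];
      if (sigma > 0.0) v += noise_sd[i] * norm_rand();
      if (i < n_A) {
        if (stim[t]) v += gain;
      } else {
        const int b = i - n_A;
        for (int k = 0; k < parents.ncol(); ++k)
          if (prevA[parents(b, k)]) v += a;
      }
      if (v > threshold) {
        spikes(t, i) = 1;
        v = v_rest;
      }
      V[i] = v;
    }
    for (int j = 0; j < n_A; ++j) prevA[j] = spikes(t, j);
  }
  return spikes;
}
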