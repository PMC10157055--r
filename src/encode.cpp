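#include <Rcpp.h>
using namespace Rcpp;

// Ben's Spiking Algorithm core loop. Sequential by construction: the filter is
// subtracted in place whenever a spike is emitted, so later decisions depend on
// earlier ones. Windows running past the signal tail are truncated.
// [[Rcpp::export]]
IntegerVector bsa_encode_cpp(NumericVector signal, NumericVector taps,
                             double threshold) {
  const int L = signal.size();
  const int M = taps.size();
  NumericVector s = clone(signal);
  IntegerVector spikes(L);
  for (int t = 0; t < L; ++t) {
    const int w = std::min(M, L - t);
    double e1 = 0.0, e2 = 0.0;
    for (int k = 0; k < w; ++k) {
      e1 += std::fabs(s[t + k] - taps[k]);
      e2 += std::fabs(s[t + k]);
    }
    if (e1 <= e2 - threshold) {
      spikes[t] = 1;
      for (int k = 0; k < w; ++k) s[t + k] -= taps[k];
    }
  }
  return spikes;
}

// Trace-based STDP over all channels in one shared timestep simulation.
// spikes: L x N binary matrix (rows = timesteps). One exponentially decaying
// trace per channel serves as both the pre- and post-synaptic trace (a single
// time constant tau, in samples). Per-timestep order: decay, weight update,
// trace increment -- so simultaneous spikes contribute nothing, matching the
// all-pairs sum with the Delta t = 0 pairs excluded.
// [[Rcpp::export]]
NumericMatrix stdp_graph_cpp(IntegerMatrix spikes, double a_plus,
                             double a_minus, double tau) {
  const int L = spikes.nrow();
  const int N = spikes.ncol();
  std::vector<double> trace(N, 0.0);
  NumericMatrix W(N, N);
  const double decay = std::exp(-1.0 / tau);
  for (int t = 0; t < L; ++t) {
    for (int n = 0; n < N; ++n) trace[n] *= decay;
    for (int i = 0; i < N; ++i) {
      if (spikes(t, i) == 0) continue;
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        // channel i firing as post-neuron: potentiate j -> i by the pre trace
        W(j, i) += a_plus * trace[j];
        // channel i firing as pre-neuron: depress i -> j by the post trace
        W(i, j) += a_minus * trace[j];
      }
    }
    for (int n = 0; n < N; ++n)
      if (spikes(t, n) != 0) trace[n] += 1.0;
  }
  return W;
}
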