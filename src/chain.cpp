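#include <Rcpp.h>
using namespace Rcpp;

// Single-spin-flip Markov chain on a gene-type (0/1) spin system.
//
// One MC step = one attempted update of one uniformly chosen node. The
// heat-bath kernel resamples the node from its conditional Boltzmann
// distribution P(s_i = 1) = 1 / (1 + exp(-beta * (h + J * sum_nb s_j))),
// independent of the current state; the Metropolis kernel proposes a flip
// and accepts with probability min(1, exp(-beta * dE)). beta may be +Inf
// (T = 0): heat-bath then follows the sign of the local field (ties at
// probability 1/2), Metropolis accepts only strictly downhill moves.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List run_chain_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                   IntegerVector init, double J, double h, double beta,
                   int n_equil, int n_samp, int sample_every, int kernel) {
  const int N = init.size();
  std::vector<int> s(init.begin(), init.end());
  long long ssum = 0;
  for (int i = 0; i < N; ++i) ssum += s[i];

  const int n_rec = n_samp / sample_every;
  NumericVector samples(n_rec);
  const long long total = (long long)n_equil + n_samp;
  long long n_changed = 0, n_accept = 0;
  const bool beta_inf = !R_finite(beta);

  for (long long step = 0; step < total; ++step) {
    int i = (int)(unif_rand() * N);
    if (i >= N) i = N - 1;
    double nb = 0.0;
    for (int p = adj_ptr[i]; p < adj_ptr[i + 1]; ++p) nb += s[adj_idx[p]];
    int snew;
    if (kernel == 0) { // heat bath
      const double lf = h + J * nb;
      double p1;
      if (beta_inf) p1 = lf > 0 ? 1.0 : (lf < 0 ? 0.0 : 0.5);
      else {
        const double x = beta * lf;
        p1 = 1.0 / (1.0 + std::exp(-x));
      }
      snew = (unif_rand() < p1) ? 1 : 0;
      if (snew != s[i]) ++n_accept;
    } else { // metropolis
      const int prop = 1 - s[i];
      const double dE = -(J * nb + h) * (prop - s[i]);
      bool acc;
      if (beta_inf) acc = dE < 0;           // T = 0: ties rejected
      else if (dE <= 0) acc = true;
      else acc = unif_rand() < std::exp(-beta * dE);
      snew = acc ? prop : s[i];
      if (acc) ++n_accept;
    }
    if (snew != s[i]) { ssum += snew - s[i]; s[i] = snew; ++n_changed; }
    if (step >= n_equil) {
      const long long k = step - n_equil + 1;
      if (k % sample_every == 0)
        samples[(int)(k / sample_every) - 1] = (double)ssum / N;
    }
  }

  return List::create(
    _["samples_M"] = samples,
    _["final_state"] = IntegerVector(s.begin(), s.end()),
    _["acceptance_rate"] = total > 0 ? (double)n_accept / total : NA_REAL,
    _["flip_rate"] = total > 0 ? (double)n_changed / total : NA_REAL);
}
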