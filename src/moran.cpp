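#include <Rcpp.h>
using namespace Rcpp;

// Moran-type death-immigration/birth simulation of local communities
// assembled from a shared metacommunity.
//
// Each local community holds exactly N individuals. Per event one
// uniformly chosen individual dies; with probability m the empty slot is
// filled by an immigrant drawn from the metacommunity (taxon k with
// probability p[k]), otherwise by a copy of a uniformly chosen surviving
// local individual. Communities are initialised as multinomial(N, p)
// draws and run for burn_in events before their counts are recorded.
// Uses R's RNG, so results are reproducible under set.seed().

static int draw_categorical(const NumericVector& cum) {
  double u = unif_rand();
  int lo = 0, hi = cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export(name = ".moran_simulate")]]
IntegerMatrix moran_simulate(NumericVector p, int N, double m,
                             int n_samples, double burn_in) {
  int S = p.size();
  NumericVector cum(S);
  double acc = 0.0;
  for (int k = 0; k < S; ++k) { acc += p[k]; cum[k] = acc; }
  cum[S - 1] = 1.0;  // guard against rounding

  IntegerMatrix out(n_samples, S);
  std::vector<int> ind(N);
  long long events = (long long)burn_in;

  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < N; ++i) ind[i] = draw_categorical(cum);
    for (long long e = 0; e < events; ++e) {
      int dying = (int)(unif_rand() * N);
      if (dying == N) dying = N - 1;
      int newtype;
      bool immigrate = unif_rand() < m;
      if (N == 1 && !immigrate) continue;  // no survivor to copy: no-op event
      if (immigrate) {
        newtype = draw_categorical(cum);
      } else {
        // copy a surviving individual: uniform over the N-1 others
        int j = (int)(unif_rand() * (N - 1));
        if (j >= N - 1) j = N - 2;
        if (j >= dying) ++j;
        newtype = ind[j];
      }
      ind[dying] = newtype;
    }
    for (int i = 0; i < N; ++i) out(s, ind[i]) += 1;
    if (s % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
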