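// Reaction-only Gillespie comparator (contact process pinned at the
// nucleation point).  Events: a U site with m modified neighbours gains the
// mark at rate m * k_plus(site); a modified site other than the NP loses it
// at rate k_minus.  Time-weighted occupancies are accumulated after a
// burn-in fraction of events, in contiguous batches so the caller can form
// batch-mean standard errors.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_kmc_engine(int n_sites, NumericVector k_plus_site, double k_minus,
                    double n_events, double burn_frac, int n_batches,
                    bool binary_propensity) {
  const int np = (n_sites - 1) / 2;
  std::vector<int> state(n_sites, 0);
  state[np] = 1;

  const double burn_start = burn_frac * n_events;
  NumericMatrix batch_occ(n_batches, n_sites);
  NumericVector batch_t(n_batches);
  std::vector<double> rate(n_sites);
  bool absorbed = false;
  double t = 0.0;

  for (double ev = 0.0; ev < n_events; ev += 1.0) {
    double total = 0.0;
    for (int s = 0; s < n_sites; ++s) {
      double r = 0.0;
      if (state[s] == 0) {
        int m = 0;
        if (s > 0 && state[s - 1] == 1) ++m;
        if (s < n_sites - 1 && state[s + 1] == 1) ++m;
        if (binary_propensity && m > 1) m = 1;
        r = m * k_plus_site[s];
      } else if (s != np) {
        r = k_minus;
      }
      rate[s] = r;
      total += r;
    }
    if (total <= 0.0) { absorbed = true; break; }

    double u = unif_rand();
    if (u <= 0.0) u = 1e-300;
    double dt = -std::log(u) / total;
    t += dt;

    if (ev >= burn_start) {
      int b = (int)(((ev - burn_start) * n_batches) / (n_events - burn_start));
      if (b >= n_batches) b = n_batches - 1;
      for (int s = 0; s < n_sites; ++s)
        if (state[s] == 1) batch_occ(b, s) += dt;
      batch_t[b] += dt;
    }

    double pick = unif_rand() * total, cum = 0.0;
    int chosen = n_sites - 1;
    for (int s = 0; s < n_sites; ++s) {
      cum += rate[s];
      if (pick <= cum) { chosen = s; break; }
    }
    state[chosen] = 1 - state[chosen];

    if (((long long)ev) % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["batch_occ"] = batch_occ, _["batch_t"] = batch_t,
                      _["absorbed"] = absorbed, _["t_total"] = t,
                      _["final_state"] = IntegerVector(state.begin(),
                                                       state.end()));
}
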