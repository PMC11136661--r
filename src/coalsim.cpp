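#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-site structured coalescent on a species tree, with an optional
// single introgression edge, under an infinite-sites one-mutation model.
//
// Populations are species-tree branches (plus one ancestral population above
// the root).  Time runs backwards from the tips (time 0).  At each speciation
// time the child-branch populations merge into the parent-branch population.
// Within a population k lineages coalesce at rate k(k-1)/2 (coalescent units).
//
// Introgression (looking backwards): with per-site probability gamma, the
// lineage ancestral to tip `mig_tip` relocates at time t_mig into population
// `mig_dest_pop` (the donor branch spanning t_mig).  Forwards in time this is
// gene flow donor -> recipient.
//
// One mutation is placed uniformly on the realised gene tree; the site is
// emitted as the derived (0/1) state of each tip.  Every emitted site is
// segregating because every gene-tree edge subtends a proper tip subset.
//
// RNG: R's unif_rand/exp_rand, so set.seed() in R governs reproducibility.

// [[Rcpp::export]]
IntegerMatrix simulate_msc_sites_cpp(int ntips,
                                     IntegerVector tip_pop,
                                     NumericVector event_time,
                                     List event_from,
                                     IntegerVector event_to,
                                     NumericVector gamma,
                                     double t_mig,
                                     int mig_tip,
                                     int mig_dest_pop,
                                     int n_sites) {
  if (ntips < 2 || ntips > 31) stop("ntips must be in 2..31");
  const int n_events = event_time.size();
  const bool per_site_gamma = gamma.size() > 1;
  if (per_site_gamma && gamma.size() != n_sites)
    stop("gamma must have length 1 or n_sites");

  IntegerMatrix out(n_sites, ntips);
  RNGScope scope;

  std::vector<std::vector<int> > efrom(n_events);
  for (int e = 0; e < n_events; ++e)
    efrom[e] = as<std::vector<int> >(event_from[e]);

  std::vector<int> pop(ntips);
  std::vector<unsigned int> mask(ntips);
  std::vector<double> birth(ntips);
  std::vector<unsigned int> emask(2 * ntips);
  std::vector<double> elen(2 * ntips);

  for (int s = 0; s < n_sites; ++s) {
    const double g = per_site_gamma ? gamma[s] : gamma[0];
    bool mig_pending = (mig_tip >= 0) && (g > 0.0) && (unif_rand() < g);

    int nlin = ntips;
    for (int i = 0; i < ntips; ++i) {
      pop[i] = tip_pop[i];
      mask[i] = (1u << i);
      birth[i] = 0.0;
    }
    int nedge = 0;
    double t = 0.0;
    int next_event = 0;

    while (nlin > 1) {
      // next deterministic boundary: speciation merge or migration
      double tb = R_PosInf;
      int btype = 0;  // 1 = merge, 2 = migration
      if (next_event < n_events) { tb = event_time[next_event]; btype = 1; }
      if (mig_pending && t_mig >= t && t_mig < tb) { tb = t_mig; btype = 2; }

      // total coalescence rate = number of same-population lineage pairs
      double rate = 0.0;
      for (int i = 0; i < nlin; ++i)
        for (int j = i + 1; j < nlin; ++j)
          if (pop[i] == pop[j]) rate += 1.0;

      double tc = R_PosInf;
      if (rate > 0.0) tc = t + exp_rand() / rate;

      if (tc < tb) {
        // pick a same-population pair uniformly
        double u = unif_rand() * rate, acc = 0.0;
        int ci = -1, cj = -1;
        for (int i = 0; i < nlin && ci < 0; ++i)
          for (int j = i + 1; j < nlin; ++j)
            if (pop[i] == pop[j]) {
              acc += 1.0;
              if (acc >= u) { ci = i; cj = j; break; }
            }
        emask[nedge] = mask[ci]; elen[nedge] = tc - birth[ci]; ++nedge;
        emask[nedge] = mask[cj]; elen[nedge] = tc - birth[cj]; ++nedge;
        mask[ci] |= mask[cj];
        birth[ci] = tc;
        pop[cj] = pop[nlin - 1];
        mask[cj] = mask[nlin - 1];
        birth[cj] = birth[nlin - 1];
        --nlin;
        t = tc;
      } else if (btype == 1) {
        t = tb;
        const std::vector<int>& fr = efrom[next_event];
        const int to = event_to[next_event];
        for (int i = 0; i < nlin; ++i)
          for (size_t q = 0; q < fr.size(); ++q)
            if (pop[i] == fr[q]) { pop[i] = to; break; }
        ++next_event;
      } else if (btype == 2) {
        t = tb;
        const unsigned int mb = (1u << mig_tip);
        for (int i = 0; i < nlin; ++i)
          if (mask[i] & mb) { pop[i] = mig_dest_pop; break; }
        mig_pending = false;
      } else {
        stop("coalescent stalled: populations never merge");
      }
    }

    double total = 0.0;
    for (int e = 0; e < nedge; ++e) total += elen[e];
    double u = unif_rand() * total, acc = 0.0;
    unsigned int dm = emask[nedge - 1];
    for (int e = 0; e < nedge; ++e) {
      acc += elen[e];
      if (u <= acc) { dm = emask[e]; break; }
    }
    for (int i = 0; i < ntips; ++i) out(s, i) = (dm >> i) & 1u;
  }
  return out;
}
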