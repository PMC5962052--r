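#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-second stochastic state machine over all nucleation sites.
//
// Phase codes: 0 = empty site, 1 = growing, 2 = shortening.
// Uses R's RNG (unif_rand) so simulations are reproducible via set.seed()
// on the R side.  All MTs in one step see the same growth velocity,
// computed from the free tubulin pool at the start of the step; the pool
// is reconciled once at step end (batch update), so results do not depend
// on site iteration order.

static inline double rate_to_prob(double rate, double dt) {
  return rate > 0.0 ? 1.0 - std::exp(-rate * dt) : 0.0;
}

// [[Rcpp::export(name = ".run_stage_cpp")]]
List run_stage_cpp(NumericVector lengths0, IntegerVector phases0,
                   double budget_uM, int n_steps, double dt,
                   double v_g_mean, double v_s_mean, double v_s_sd,
                   double k_c_mean, double k_r_mean,
                   double nuc_rate, bool nuc_conc_dep, double nuc_slope,
                   double k_on, double c1,
                   double dimers_per_um, double dimers_per_uM_um3,
                   double radius, double volume,
                   bool zones_on, double peripheral_width,
                   double interior_factor,
                   bool vary_v_s, bool vary_k_c, bool vary_k_r,
                   double jitter_max,
                   double pinned_free,   // < 0 => mass balance active
                   int tracked_site,     // 0-based; -1 = assign at first nucleation
                   int tracked_n_mts) {
  const int n = lengths0.size();
  NumericVector len = clone(lengths0);
  IntegerVector ph = clone(phases0);

  // uM of polymer per um of total MT length
  const double polyc_per_um = dimers_per_um / (dimers_per_uM_um3 * volume);

  IntegerVector out_n(n_steps);
  NumericVector out_mlen(n_steps), out_free(n_steps), out_tracked(n_steps);

  double free_c;
  if (pinned_free >= 0.0) {
    free_c = pinned_free;
  } else {
    double s = 0.0;
    for (int i = 0; i < n; ++i) if (ph[i] != 0) s += len[i];
    free_c = budget_uM - s * polyc_per_um;
    if (free_c < 0.0) free_c = 0.0;
  }

  const double interior_limit = zones_on ? (radius - peripheral_width) : -1.0;
  double vs_lo = v_s_mean - v_s_sd, vs_hi = v_s_mean + v_s_sd;
  if (vs_lo < 0.0) vs_lo = 0.0;

  for (int step = 0; step < n_steps; ++step) {
    double eff_r = radius;
    if (jitter_max > 0.0) eff_r = radius - jitter_max * unif_rand();

    const double vg = k_on * free_c + c1;
    const double nr = nuc_conc_dep ? nuc_slope * free_c : nuc_rate;
    const double p_nuc = rate_to_prob(nr, dt);

    for (int i = 0; i < n; ++i) {
      if (ph[i] == 0) {
        // nucleation: the first increment uses the parameter set's
        // measured mean growth rate, concentration-dependent thereafter
        if (p_nuc > 0.0 && unif_rand() < p_nuc) {
          len[i] = v_g_mean * dt;
          ph[i] = 1;
          if (tracked_site < 0) tracked_site = i;
          if (i == tracked_site) ++tracked_n_mts;
        }
      } else if (ph[i] == 1) {
        double nl = len[i] + vg * dt;
        if (nl >= eff_r) {
          // boundary-forced catastrophe; tip clamped to the boundary
          len[i] = eff_r;
          ph[i] = 2;
        } else {
          len[i] = nl;
          double kc = vary_k_c ? 2.0 * k_c_mean * unif_rand() : k_c_mean;
          if (zones_on && len[i] < interior_limit) kc *= interior_factor;
          if (kc > 0.0 && unif_rand() < rate_to_prob(kc, dt)) ph[i] = 2;
        }
      } else {
        double vs = v_s_mean;
        if (vary_v_s) vs = vs_lo + (vs_hi - vs_lo) * unif_rand();
        len[i] -= vs * dt;
        if (len[i] <= 0.0) {
          // complete depolymerization: site re-opens for nucleation at
          // the next step's nucleation pass
          len[i] = 0.0;
          ph[i] = 0;
        } else {
          // a shrunken (jittered) boundary can sit inside an existing MT
          if (len[i] > eff_r) len[i] = eff_r;
          double kr = vary_k_r ? 2.0 * k_r_mean * unif_rand() : k_r_mean;
          if (kr > 0.0 && unif_rand() < rate_to_prob(kr, dt)) ph[i] = 1;
        }
      }
    }

    int cnt = 0;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (ph[i] != 0) { ++cnt; s += len[i]; }
    }
    if (pinned_free < 0.0) {
      free_c = budget_uM - s * polyc_per_um;
      if (free_c < 0.0) free_c = 0.0;
    }
    out_n[step] = cnt;
    out_mlen[step] = cnt > 0 ? s / cnt : NA_REAL;
    out_free[step] = free_c;
    out_tracked[step] =
      (tracked_site >= 0 && ph[tracked_site] != 0) ? len[tracked_site] : 0.0;
  }

  return List::create(
    _["lengths"] = len, _["phases"] = ph,
    _["n_mt"] = out_n, _["mean_length"] = out_mlen,
    _["free_conc"] = out_free, _["tracked_length"] = out_tracked,
    _["tracked_site"] = tracked_site, _["tracked_n_mts"] = tracked_n_mts);
}
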