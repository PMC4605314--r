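#include <Rcpp.h>
using namespace Rcpp;

// Aggregate-count Gillespie simulation of n_sites independent binding sites,
// each a 3-state chain: empty ->(k_on) mono ->(k2) bis, with reverse rates
// k_off1 and k_m2. Equivalent to per-site exponential waiting times; the
// aggregate propensities are count * per-site rate. Returns the site-state
// counts (empty, mono, bis) sampled at the requested (ascending) times.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix gillespie_counts(int n_sites, double k_on, double k_off1,
                               double k2, double k_m2, NumericVector times) {
  const int nt = times.size();
  IntegerMatrix out(nt, 3);
  int n0 = n_sites, n1 = 0, n2 = 0;
  double t = 0.0;
  int idx = 0;
  RNGScope scope;
  while (idx < nt) {
    const double a1 = n0 * k_on;
    const double a2 = n1 * k_off1;
    const double a3 = n1 * k2;
    const double a4 = n2 * k_m2;
    const double atot = a1 + a2 + a3 + a4;
    double tnext;
    if (atot > 0.0) {
      tnext = t + R::rexp(1.0 / atot);
    } else {
      tnext = R_PosInf;  // absorbing configuration: counts frozen
    }
    while (idx < nt && times[idx] < tnext) {
      out(idx, 0) = n0;
      out(idx, 1) = n1;
      out(idx, 2) = n2;
      ++idx;
    }
    if (!R_FINITE(tnext)) break;
    t = tnext;
    const double u = R::runif(0.0, atot);
    if (u < a1) {
      --n0; ++n1;
    } else if (u < a1 + a2) {
      --n1; ++n0;
    } else if (u < a1 + a2 + a3) {
      --n1; ++n2;
    } else {
      --n2; ++n1;
    }
  }
  while (idx < nt) {
    out(idx, 0) = n0;
    out(idx, 1) = n1;
    out(idx, 2) = n2;
    ++idx;
  }
  return out;
}
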