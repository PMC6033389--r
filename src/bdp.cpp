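#include <Rcpp.h>
using namespace Rcpp;

// Discrete-step realisation of the primary/secondary particle populations.
//
// Resting phase (n_rest steps): both populations are simple birth-death
// processes with equal birth and death probabilities x * dt * beta / sigma^2.
// Transient phase (n_trans steps, step index i from 0 at the switch):
//   primary:   p_birth = x * dt * beta / sigma^2
//              p_death = x * dt * (i * dt) / sigma^2
//   secondary: births blocked,
//              p_death = x * dt * (i * dt + beta) / sigma^2
// Per step and population one uniform draw decides a birth (when births are
// possible) and one decides a death, in the fixed order primary-birth,
// primary-death, secondary-birth, secondary-death; an extinct population
// (x = 0) draws nothing and stays extinct.  The step size must keep
// p_birth + p_death below 0.1 at every visited state, otherwise the
// one-jump-per-step contract of the chain is violated and the run aborts.
//
// Both populations are recorded every `record_every` steps (step 0, i.e.
// the start of the resting phase, included; the final step always
// included).
// [[Rcpp::export]]
List bdp_run_cpp(int n0, double sigma, double beta, double dt,
                 int n_rest, int n_trans, int record_every) {
  if (n0 < 1) stop("n0 must be >= 1");
  if (dt <= 0.0) stop("dt must be positive");
  if (record_every < 1) record_every = 1;

  const double s2 = sigma * sigma;
  const double p_rest_rate = beta / s2;   // per particle per unit time
  const int n_steps = n_rest + n_trans;
  const int n_rec = n_steps / record_every + 1 +
                    ((n_steps % record_every) ? 1 : 0);

  IntegerVector xp_out(n_rec), xs_out(n_rec);
  IntegerVector step_out(n_rec);

  int xp = n0, xs = n0;
  int k = 0;
  RNGScope scope;

  auto record = [&](int step) {
    xp_out[k] = xp; xs_out[k] = xs; step_out[k] = step; ++k;
  };
  record(0);

  for (int step = 0; step < n_steps; ++step) {
    bool resting = step < n_rest;
    int i = step - n_rest;              // transient step index (>= 0)

    if (xp > 0) {
      double pb = xp * dt * p_rest_rate;
      double pd = resting ? pb : xp * dt * (i * dt) / s2;
      if (pb + pd >= 0.1)
        stop("transition probabilities reached %.3f at x = %d; "
             "decrease dt", pb + pd, xp);
      if (unif_rand() < pb) ++xp;
      if (unif_rand() < pd) --xp;
    }
    if (xs > 0) {
      double pb = resting ? xs * dt * p_rest_rate : 0.0;
      double pd = resting ? xs * dt * p_rest_rate
                          : xs * dt * (i * dt + beta) / s2;
      if (pb + pd >= 0.1)
        stop("transition probabilities reached %.3f at x = %d; "
             "decrease dt", pb + pd, xs);
      if (!resting) {
        if (unif_rand() < pd) --xs;
      } else {
        if (unif_rand() < pb) ++xs;
        if (unif_rand() < pd) --xs;
      }
    }
    if ((step + 1) % record_every == 0 || step + 1 == n_steps)
      record(step + 1);
  }

  return List::create(_["step"] = head(step_out, k),
                      _["xp"] = head(xp_out, k),
                      _["xs"] = head(xs_out, k));
}
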