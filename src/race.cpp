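#include <Rcpp.h>
using namespace Rcpp;

// Deterministic per-trial integrator for the accelerated race-to-threshold
// model.  All stochastic quantities (build-up rates, afferent delays, ERI
// duration, lapse flag, tie-break uniform) are drawn in R and passed in, so
// this routine is a pure function of its arguments.
//
// Discrete scheme (dt = consts time step): at step k the clock advances to
// t = k*dt; build-up rates are evaluated at t, the activities are then
// incremented (r += b*dt), floored at zero, and finally checked against the
// threshold.  The first crossing triggers the saccade after the efferent
// delay.  Plans cannot build before the go-driven onset (t <= t_go implies
// zero rate for both plans regardless of epoch).
//
// Epochs on the absolute trial clock:
//   epoch 1:  t_go < t <= t_cd            rates (b_c0, b_a0)
//   epoch 2:  t_cd < t <= t_end (ERI)     anti plan halted/suppressed at
//             g_eri*b_a0 throughout; cue plan halted at g_eri*b_c0 for
//             t <= t_rec = t_cd + min(delta_eri, eri), then recovers b_c0
//             and gains a_ex per ms
//   epoch 3:  t > t_end                   anti plan recovers b_a0 and gains
//             a_end per ms; cue plan decelerates from its ERI-final rate by
//             |d_end| per ms.  On lapse trials both rates stay constant
//             (b_a0 and the ERI-final cue rate).
//
// variant: 0 = full, 1 = accel_only (anti plan unperturbed during the ERI),
// 2 = halt_only (cue plan unperturbed, no exogenous acceleration).

// [[Rcpp::export(name = ".race_core")]]
List race_core(NumericVector gap,
               NumericVector b_c0, NumericVector b_a0,
               NumericVector t_go, NumericVector cue_delay,
               NumericVector eri, LogicalVector lapse,
               NumericVector tie_u,
               double g_eri, double delta_eri, double a_ex,
               double d_end, double a_end,
               double threshold, double efferent_delay,
               double dt, double t_max, int variant)
{
  const int n = gap.size();
  NumericVector rt(n);
  IntegerVector winner(n);        // 1 = cue plan (incorrect), 2 = anti plan
  LogicalVector no_response(n);
  const int n_steps = (int) std::ceil(t_max / dt);

  for (int i = 0; i < n; ++i) {
    const double tgo  = t_go[i];
    const double tcd  = gap[i] + cue_delay[i];
    const double win  = std::min(delta_eri, eri[i]);
    const double trec = tcd + win;                 // cue plan recovery time
    const double tend = tcd + eri[i];              // ERI end
    // cue-plan rate at the end of the ERI (carried into epoch 3)
    const double bc_end = (variant == 2) ? b_c0[i]
                          : b_c0[i] + a_ex * (eri[i] - win);
    double rC = 0.0, rA = 0.0;
    double crossed_t = -1.0;
    int    who = 0;

    for (int k = 1; k <= n_steps; ++k) {
      const double t = k * dt;
      double bC, bA;
      if (t <= tgo) {
        bC = 0.0; bA = 0.0;
      } else if (t <= tcd) {                       // epoch 1
        bC = b_c0[i]; bA = b_a0[i];
      } else if (t <= tend) {                      // epoch 2 (ERI)
        bA = (variant == 1) ? b_a0[i] : g_eri * b_a0[i];
        if (variant == 2)
          bC = b_c0[i];
        else
          bC = (t <= trec) ? g_eri * b_c0[i]
                           : b_c0[i] + a_ex * (t - trec);
      } else {                                     // epoch 3
        if (lapse[i]) {
          bC = bc_end;
          bA = b_a0[i];
        } else {
          bC = bc_end + d_end * (t - tend);
          bA = b_a0[i] + a_end * (t - tend);
        }
      }
      rC += bC * dt; if (rC < 0.0) rC = 0.0;
      rA += bA * dt; if (rA < 0.0) rA = 0.0;
      const bool cC = rC >= threshold, cA = rA >= threshold;
      if (cC || cA) {
        crossed_t = t;
        if (cC && cA) {
          if (rC > rA)      who = 1;
          else if (rA > rC) who = 2;
          else              who = (tie_u[i] < 0.5) ? 1 : 2;
        } else who = cC ? 1 : 2;
        break;
      }
    }

    if (who == 0) {
      rt[i] = NA_REAL; winner[i] = NA_INTEGER; no_response[i] = true;
    } else {
      rt[i] = crossed_t + efferent_delay; winner[i] = who;
      no_response[i] = false;
    }
  }

  return List::create(_["rt"] = rt, _["winner"] = winner,
                      _["no_response"] = no_response);
}
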