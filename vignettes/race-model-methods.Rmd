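---
title: "Modeling urgent antisaccades: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling urgent antisaccades: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccRace)
```

## The task and the central quantity

In the compelled antisaccade task a participant is told to respond to a go
signal *before* knowing the correct answer: the go signal (fixation offset)
arrives first, and only after an unpredictable gap does a salient cue appear
to the left or right. The correct response is a saccade *away* from the cue,
within a 450-ms deadline. Because motor planning starts before the cue, the
informative variable is not the reaction time (RT, go signal to saccade) but
the **raw processing time**, rPT = RT − gap: how long the cue was actually
visible before the eyes moved.

Sorting trials by rPT and computing the proportion of correct choices in
sliding bins (15 ms wide, stepping every 1 ms) yields the **tachometric
curve**. For this task it has a characteristic non-monotonic shape: chance
(0.5) at short rPTs where choices are guesses, then a sharp dip toward 0 —
the **vortex**, where the freshly detected cue reflexively captures the
saccade — and then a very fast rise to a near-1 asymptote once voluntary
interpretation of the cue takes over.

## The race model

Two motor plans, one toward the cue (activity $r_C$) and one toward the
opposite location ($r_A$), rise from zero toward a fixed threshold (1000 AU);
the first to cross triggers the saccade after a 20-ms efferent delay.
Integration is Euler with a 1-ms step: build-up rates are set for the new
time, activities integrate, negative activities are floored at zero, and the
threshold is checked. A trial unfolds in three epochs:

1. **Before the cue is detected.** After a go afferent delay (Gaussian,
   sub-20-ms draws rejected), both plans rise linearly with initial build-up
   rates drawn from a bivariate Gaussian (mean $\mu_b$, SD $\sigma_b$,
   correlation $\rho_b$; strongly negative $\rho_b$ makes one plan fast when
   the other is slow). A crossing here is a guess: correct half the time.
2. **The exogenous response interval (ERI).** The cue is detected one cue
   afferent delay after its onset; for a Gaussian duration (negatives
   clipped to zero) the race is biased toward the cue. The anti plan is
   halted (gain $g_{ERI} = 0$) or suppressed ($g_{ERI} < 0$) throughout.
   The cue plan halts for the first $\Delta_{ERI}$ ms, then instantly
   recovers its rate and gains $a_{EX}$ per ms until the ERI ends. Crossings
   here are captured saccades — the vortex.
3. **After the ERI.** The anti plan recovers its rate and accelerates at
   $a_{END}$; the cue plan decelerates at $d_{END}$. With probability
   $\lambda$ the trial is a lapse: neither endogenous term engages and both
   plans continue at their ERI-final rates.

The 15 parameters per luminance condition are bundled in
`luminance_params()`; `pooled_params()` returns the published pooled-data
values for the high, medium, and low cue luminances, whose motor block
(build-up rates and go afferent delay) is shared across conditions.
Restricted variants expose the two exogenous mechanisms separately:
`accel_only` leaves the anti plan unperturbed during the ERI, `halt_only`
leaves the cue plan unperturbed. Their behavioral signatures differ:
acceleration produces the peak in the incorrect-trial rPT distribution,
halting produces the dip in the correct-trial distribution; only the full
model shows both.

### Numerical conventions

The description above leaves a few discrete-time choices open; the package
fixes them as follows, and the test suite cross-checks the compiled core
against an independently written step-by-step integrator under these same
conventions.

* Within a step, rates are updated first, then activities integrate, then
  the threshold is checked; RT is the crossing step plus the efferent delay.
* Epoch boundaries are event times on the absolute trial clock. If a plan
  crosses before cue detection the later epochs never run. Plans cannot
  build before the go-driven onset: if the go afferent delay has not elapsed,
  the rate contribution is zero regardless of epoch.
* If the drawn ERI is shorter than $\Delta_{ERI}$, the acceleration window
  is empty and the cue plan halts for the whole ERI.
* If both plans cross in the same step the larger activity wins; exact ties
  break uniformly at random.
* Build-up rates may be negative (the bivariate Gaussian is unbounded);
  only the activities are floored at zero. Trials with no crossing within
  5000 ms are flagged `no_response` and excluded from analysis.
* Trials beyond the 450-ms deadline are flagged but kept in the analysis;
  the deadline governed feedback, not validity.

## Tachometric estimation and the analytical fit

`compute_tachometric()` counts correct and incorrect trials in inclusive
bins $[c-7, c+7]$ around every 1-ms center. The proportion correct per bin
is a pure count ratio; the common normalization factor recorded for display
provably cancels. Empty bins are flagged `NA` and excluded from fitting
rather than imputed.

`fit_tachometric()` fits the analytical curve
$v(x) = \max(s_L(x), s_R(x), 0)$, two opposed sigmoids sharing a floor $B$:
$s_L$ falls from the chance asymptote $A_L$ (pinned at 0.5, because with no
time to see the cue performance must be at chance) toward $B$ with midpoint
$C_L$ and width $D_L$; $s_R$ rises from $B$ to the asymptote $A_R$ with
midpoint $C_R$ and width $D_R$. The objective is the unweighted mean
absolute error over occupied bins, minimized by Nelder-Mead simplex
search. Because the max-of-sigmoids surface is multimodal, the search runs
from sixteen deterministic start points whose landmarks (floor, asymptote,
midpoints)
are read off a count-pooled version of the curve — pooling counts rather
than averaging proportions keeps sparse edge bins from masquerading as the
vortex — and the incumbent is polished by a restart. Widths are optimized
on the log scale to stay positive; no ordering of $C_L, C_R$ is imposed
(the max composition is well defined either way).

By default the fit uses all occupied bins. A fixed window, typically
$[-100, 400]$ ms, is available and is used for the package's own headline
computations: with many trials at long gaps the observed rPT range grows
far into sparsely populated territory, and in low-luminance conditions with
a high lapse rate the empirical curve genuinely declines again at very long
rPTs (lapse trials concentrate there), which the monotone right sigmoid
cannot and should not chase.

`extract_features()` reads eight quantities off the fitted curve on a 1-ms
grid: asymptote ($A_R$), vortex depth (minimum of $v$), vortex time (its
rPT), extreme slopes (central differences), the left edge (falling branch
midway between 0.5 and the minimum), the centerpoint (rising branch midway
between minimum and asymptote — how soon the participant escapes the
vortex), and the mean perceptual accuracy (average of $v$ over rPT 0–250
ms). Feature uncertainty comes from a percentile bootstrap
(`bootstrap_features()`): resample trials with replacement keeping n,
recompute the curve, refit, re-extract, take 2.5/97.5 percentiles.
Replicate refits warm-start from the point estimate with a looser simplex
tolerance; this tracks the same optimum at a fraction of the cost. Failed
replicate fits are dropped and counted, with a warning beyond 5%.

## Individual differences

`participant_summary()` reduces a trial table to one row per participant ×
luminance (mean observed accuracy over urgent trials, mean RT over all
trials, fitted curve features). `partial_correlation()` quantifies
association between two such measures while removing luminance, coded
ordinally 1/2/3 by default (log-luminance using the printed cd/m² values is
available); Pearson works on least-squares residuals, Spearman on ranks
(reported by default as the more conservative), with p-values from the
t-approximation on $n-3$ degrees of freedom. A permutation-based p is a
possible alternative; the t-approximation is standard at these sample
sizes and is what the package implements. `regression_with_covariate()`
gives the equivalent OLS formulation, whose x-term t-test agrees
numerically with the partial Pearson test.

The model makes a sharp prediction here, which the test suite reproduces:
in a cohort that differs *only* in urgency (how fast plans build up), mean
observed accuracy shows a strong speed–accuracy tradeoff with mean RT while
the curve-based mean perceptual accuracy stays flat — overall accuracy
conflates perception with response-speed sampling of the curve.

## Synthetic experiments

`experiment_design()` encodes the study layout (6 participants, 30 blocks ×
150 trials, gaps {−200, −100, 0, 75, 100, 125, 150, 175, 200, 250, 350} ms
with the negative two being delay trials, three interleaved luminances,
450-ms deadline). Gap, cue side, and luminance are sampled independently
and uniformly per trial; with 4500 trials per participant this puts roughly
1500 (≈1350–1550) trials in each luminance condition, matching the
per-participant counts reported for the study.

Participant heterogeneity is emulated by multiplicative Gaussian jitter
around a template parameter set (`make_cohort()`), default 10% SD on rates,
delays, and endogenous terms, with `rho_b` and `g_eri` held fixed; this
stands in for per-participant fits that are not printed in the source
material and is labeled synthetic throughout. Delay trials (gap < 0) are
outside the mechanistic scope of the race model (which is fitted to urgent
trials only), so `generate_experiment()` emulates them statistically:
correct with probability 0.992 — the reported median accuracy of the easy
task — with lognormal RTs (median 260 ms, log-SD 0.22, a typical
non-urgent latency distribution). This is a declared synthetic convention,
not a mechanistic claim, and such trials carry no simulator diagnostics.

What passing tests on these synthetic cohorts shows is that the *pipeline*
recovers what the generator put in; it cannot show that real data lack
features the generator omits (sequential effects, fatigue, block structure,
eye-tracking artifacts, non-Gaussian delay tails).

## Fitting the model to data

`build_targets()` turns a trial table into the functions the model is
fitted against: per luminance, the tachometric curve plus RT histograms of
correct and incorrect trials at each gap (10-ms bins over 0–600 ms,
normalized so each cell's mass equals its trial fraction).
`race_objective()` simulates trials with matched gap frequencies, bins them
identically, and sums mean absolute errors across all target functions;
a fixed seed gives common random numbers across evaluations so that
candidate comparisons are not dominated by simulation noise. The
Monte-Carlo floor of the objective at the true parameters is measurable by
evaluating twice with different seeds.

`fit_race_model()` searches the 15-dimensional box by iterated random
search: sample candidates uniformly, keep the best (incumbent re-scored
under the round's common random numbers), shrink the box around it by 0.7
per round, repeat from several independent starts. The motor block is
shared across luminance conditions by construction of the parameter vector.
Zero-width bounds pin parameters (the pooled-data convention fixes
$g_{ERI} = 0$). The schedule (8 starts × 40 rounds × 60 candidates at
n_sim = 2×10⁴ by default) is sized so a desk-scale fit runs in minutes;
the test suite uses a reduced schedule (3 × 25 × 40 at n_sim = 8000, one
condition, ~10⁵-trial targets) that reliably recovers the cue afferent
delay to within ±10%. Weakly identified parameters ($\rho_b$,
$\sigma_{ERI}$) are either pinned or reported with wide spread; recovery
claims are limited to the well-identified ones.

## Problem sizes and reproducibility

The package's own headline computations simulate 1.2–2×10⁵ trials per
luminance condition (tachometric features stabilize well below that; the
binomial SE of a vortex bin at these sizes is a few thousandths), 10⁶ draws
for delay/ERI sampling checks, 60 datasets × 100 replicates for bootstrap
coverage, and the reduced fitting schedule above. Every stochastic entry
point takes a seed; given equal seeds, dataset generation is
bit-reproducible, and CLI runs write byte-identical outputs.

## Known limitations

* Delay (gap < 0) trials are emulated, never mechanistically simulated.
* The vortex depth obtained by simulating the published pooled parameters
  is somewhat shallower than the value fitted to the pooled experimental
  data (≈0.07–0.08 vs 0.03 at high luminance): trials whose anti plan is
  frozen just below threshold cross within a few ms of the ERI's end, and
  with the published afferent/ERI SDs these correct crossings smear into
  the vortex bins. The corresponding fitted floor also widens the
  0.10–0.90 rise span. All other placement and shape quantities reproduce.
* The dual-sigmoid family is the only fitted form (no cumulative Gaussian
  or Weibull alternatives), and the curve is never kernel-smoothed.
* Bootstrap intervals are percentile intervals; no BCa correction.
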