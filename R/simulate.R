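#' Simulate urgent antisaccade trials at given gaps
#'
#' Runs the accelerated race-to-threshold model for one luminance condition,
#' one trial per element of `gap`.  Each trial proceeds through three epochs:
#' (1) after the go-signal afferent delay both plans rise linearly at their
#' initial build-up rates; (2) once the cue is detected, the exogenous
#' response interval (ERI) begins, during which the anti plan is halted or
#' suppressed and the cue plan first halts for `delta_eri` ms and then
#' accelerates at `a_ex`; (3) after the ERI, the anti plan accelerates at
#' `a_end` and the cue plan decelerates at `d_end` (on lapse trials neither
#' endogenous term engages).  The first plan to reach the threshold triggers
#' the saccade after the efferent delay.
#'
#' The random draws are made once per quantity, in the order: go-signal
#' afferent delays, build-up rates, cue afferent delays, ERI durations, lapse
#' flags, cue sides, tie-break variates.  Given a prior `set.seed()` call the
#' output is fully reproducible.
#'
#' @param params A [luminance_params()] object.
#' @param gap Numeric vector of gap values (ms, all `>= 0`); one trial per
#'   element.
#' @param consts A [sim_constants()] object.
#' @param variant Model variant: `"full"` applies both ERI mechanisms,
#'   `"accel_only"` leaves the anti plan unperturbed during the ERI,
#'   `"halt_only"` leaves the cue plan unperturbed (no exogenous
#'   acceleration).
#' @param cue_side Optional per-trial cue side (`"left"`/`"right"`); sampled
#'   uniformly when `NULL`.
#' @param rt_deadline Deadline (ms) used to flag late responses; flagged
#'   trials are retained.
#' @return A data frame of trial records with columns `gap_ms`, `cue_side`,
#'   `choice_side`, `correct`, `rt_ms`, `rpt_ms`, `deadline_exceeded`,
#'   `outcome_class` (`guess`, `captured`, `informed`, or `no_response`), and
#'   latent diagnostics `sim_b_c0`, `sim_b_a0`, `sim_go_delay`,
#'   `sim_cue_delay`, `sim_eri`, `sim_lapse`.
#' @export
simulate_trials <- function(params, gap, consts = sim_constants(),
                            variant = "full", cue_side = NULL,
                            rt_deadline = 450) {
  validate_luminance_params(params)
  if (length(gap) < 1L) stop("at least one gap value is required")
  if (any(!is.finite(gap))) stop("gap values must be finite")
  if (any(gap < 0))
    stop("delay trials (gap < 0) are not covered by the race model; ",
         "see generate_experiment() for their statistical emulation")
  n <- length(gap)
  vcode <- variant_code(variant)

  go_delay  <- sample_afferent_delay(n, params$mu_go_aff, params$sigma_go_aff,
                                     consts$afferent_floor)
  rates     <- sample_build_up_rates(params, n)
  cue_delay <- sample_afferent_delay(n, params$mu_cue_aff, params$sigma_cue_aff,
                                     consts$afferent_floor)
  eri       <- sample_eri_duration(n, params$mu_eri, params$sigma_eri)
  lapse     <- stats::runif(n) < params$lambda
  if (is.null(cue_side))
    cue_side <- c("left", "right")[1L + (stats::runif(n) < 0.5)]
  tie_u     <- stats::runif(n)

  res <- .race_core(as.numeric(gap), rates$b_c0, rates$b_a0,
                    go_delay, cue_delay, eri, lapse, tie_u,
                    params$g_eri, params$delta_eri, params$a_ex,
                    params$d_end, params$a_end,
                    consts$threshold, consts$efferent_delay,
                    consts$dt, consts$t_max, vcode)

  correct <- res$winner == 2L                     # anti plan won
  other   <- ifelse(cue_side == "left", "right", "left")
  choice  <- ifelse(correct, other, cue_side)
  rt  <- res$rt
  rpt <- rt - gap
  # crossing happened before the saccade was committed; cue detection at
  # gap + cue_delay on the same clock
  cross_t <- rt - consts$efferent_delay
  oc <- ifelse(res$no_response, "no_response",
        ifelse(cross_t <= gap + cue_delay, "guess",
        ifelse(correct, "informed", "captured")))
  data.frame(
    gap_ms = gap, cue_side = cue_side,
    choice_side = ifelse(res$no_response, NA_character_, choice),
    correct = ifelse(res$no_response, NA, correct),
    rt_ms = rt, rpt_ms = rpt,
    deadline_exceeded = !res$no_response & rt > rt_deadline,
    outcome_class = oc,
    sim_b_c0 = rates$b_c0, sim_b_a0 = rates$b_a0,
    sim_go_delay = go_delay, sim_cue_delay = cue_delay,
    sim_eri = eri, sim_lapse = lapse,
    stringsAsFactors = FALSE)
}

# single-trial integrator with all latent quantities injected (no RNG);
# used for deterministic checks and cross-validation against reference
# integrators
race_trial_given <- function(params, gap, b_c0, b_a0, go_delay, cue_delay,
                             eri, lapse = FALSE, tie_u = 0,
                             consts = sim_constants(), variant = "full") {
  validate_luminance_params(params)
  res <- .race_core(gap, b_c0, b_a0, go_delay, cue_delay, eri, lapse, tie_u,
                    params$g_eri, params$delta_eri, params$a_ex,
                    params$d_end, params$a_end,
                    consts$threshold, consts$efferent_delay,
                    consts$dt, consts$t_max, variant_code(variant))
  list(rt = res$rt[1], winner = c("cue", "anti")[res$winner[1]],
       no_response = res$no_response[1], rpt = res$rt[1] - gap)
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_trials()] for one trial.
#'
#' @inheritParams simulate_trials
#' @param gap Gap value (ms, `>= 0`).
#' @return A one-row trial-record data frame.
#' @export
simulate_trial <- function(params, gap, consts = sim_constants(),
                           variant = "full") {
  if (length(gap) != 1L) stop("simulate_trial() takes a single gap")
  simulate_trials(params, gap, consts = consts, variant = variant)
}

#' Simulate a full multi-condition dataset
#'
#' Batch driver: gap, cue side, and luminance condition are sampled
#' independently and uniformly per trial, then trials are run through the
#' race model.  Records are returned in generation order and the run is
#' bit-reproducible for a given seed.
#'
#' @param params_by_luminance Named list of [luminance_params()], one per
#'   luminance condition (e.g. the result of [pooled_params()]).
#' @param gaps Vector of candidate gap values (ms, all `>= 0`).
#' @param n_trials Total number of trials to simulate.
#' @param consts A [sim_constants()] object.
#' @param variant Model variant (see [simulate_trials()]).
#' @param seed Integer seed; when non-`NULL`, `set.seed(seed)` is called.
#' @param gap_prob Optional sampling probabilities for `gaps` (uniform when
#'   `NULL`).
#' @return A trial-record data frame with a leading `luminance` column.
#' @export
simulate_dataset <- function(params_by_luminance, gaps, n_trials,
                             consts = sim_constants(), variant = "full",
                             seed = NULL, gap_prob = NULL) {
  if (length(gaps) < 1L) stop("gap list must be non-empty")
  if (n_trials < 1L) stop("n_trials must be positive")
  if (is.null(names(params_by_luminance)) ||
      any(!nzchar(names(params_by_luminance))))
    stop("params_by_luminance must be a named list")
  for (p in params_by_luminance) validate_luminance_params(p)
  if (!is.null(seed)) set.seed(seed)

  lum <- sample(names(params_by_luminance), n_trials, replace = TRUE)
  gap <- sample(gaps, n_trials, replace = TRUE, prob = gap_prob)
  out <- vector("list", length(params_by_luminance))
  names(out) <- names(params_by_luminance)
  for (l in names(params_by_luminance)) {
    idx <- which(lum == l)
    if (length(idx) == 0L) next
    rec <- simulate_trials(params_by_luminance[[l]], gap[idx],
                           consts = consts, variant = variant)
    rec$luminance <- l
    rec$.row <- idx
    out[[l]] <- rec
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out <- out[order(out$.row), ]
  out$.row <- NULL
  rownames(out) <- NULL
  out[, c("luminance", setdiff(names(out), "luminance"))]
}
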