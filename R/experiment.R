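#' Design of a synthetic antisaccade experiment
#'
#' Describes the study layout: participants, blocks of interleaved trials,
#' the gap set (negative gaps are delay trials), uniformly interleaved cue
#' luminances, and the response deadline.  Fixation durations are carried as
#' metadata only.
#'
#' @param n_participants Number of participants.
#' @param blocks,trials_per_block Session structure.
#' @param gaps Gap set in ms (negative values denote delay trials).
#' @param luminances Cue luminance levels, sampled uniformly per trial.
#' @param rt_deadline Response deadline (ms).
#' @param fixation_ms Candidate fixation durations (metadata).
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(n_participants = 6L, blocks = 30L,
                              trials_per_block = 150L,
                              gaps = c(-200, -100, 0, 75, 100, 125, 150,
                                       175, 200, 250, 350),
                              luminances = c("high", "medium", "low"),
                              rt_deadline = 450,
                              fixation_ms = c(150, 250, 350)) {
  if (n_participants < 1L || blocks < 0L || trials_per_block < 1L)
    stop("counts must be positive (blocks may be zero)")
  if (length(gaps) < 1L) stop("gap set must be non-empty")
  structure(list(n_participants = as.integer(n_participants),
                 blocks = as.integer(blocks),
                 trials_per_block = as.integer(trials_per_block),
                 gaps = gaps, luminances = luminances,
                 rt_deadline = rt_deadline, fixation_ms = fixation_ms),
            class = "experiment_design")
}

# default multiplicative jitter SDs: 10% on rates, delays, and endogenous
# terms; correlation and ERI gain stay fixed (their bounds are tight)
.default_jitter <- c(mu_b = 0.1, sigma_b = 0.1, rho_b = 0,
                     mu_go_aff = 0.1, sigma_go_aff = 0.1,
                     mu_cue_aff = 0.1, sigma_cue_aff = 0.1,
                     mu_eri = 0.1, sigma_eri = 0.1,
                     g_eri = 0, delta_eri = 0.1,
                     a_ex = 0.1, d_end = 0.1, a_end = 0.1, lambda = 0.1)

#' Generate a cohort of per-participant parameter sets
#'
#' Emulates between-participant heterogeneity by multiplicative Gaussian
#' jitter around a template parameter set: each parameter is multiplied by
#' `1 + N(0, sd)` with the per-parameter SDs in `jitter_sd`.  Draws that
#' violate the parameter invariants after clipping of the bounded entries
#' (`rho_b` to \[-1, 1\], `lambda` to \[0, 1\]) are resampled a bounded
#' number of times.
#'
#' @param design An [experiment_design()].
#' @param template Named list of [luminance_params()] per luminance (e.g.
#'   [pooled_params()]).
#' @param jitter_sd Named vector of multiplicative jitter SDs; defaults to
#'   10 percent on rates, delays, and endogenous terms.
#' @param seed Integer seed.
#' @return A list of length `n_participants`; each element is a named list of
#'   [luminance_params()] with a `participant` attribute.
#' @export
make_cohort <- function(design, template, jitter_sd = .default_jitter,
                        seed = NULL) {
  if (!inherits(design, "experiment_design")) stop("design must be an experiment_design")
  urgent_lums <- design$luminances
  if (!all(urgent_lums %in% names(template)))
    stop("template must provide parameters for: ",
         paste(urgent_lums, collapse = ", "))
  js <- .default_jitter
  js[names(jitter_sd)] <- jitter_sd
  if (!is.null(seed)) set.seed(seed)
  cohort <- vector("list", design$n_participants)
  for (i in seq_len(design$n_participants)) {
    pset <- list()
    for (l in urgent_lums) {
      base <- unlist(template[[l]])
      for (try in 1:100) {
        v <- base * (1 + stats::rnorm(length(base)) * js[names(base)])
        v["rho_b"] <- min(1, max(-1, v["rho_b"]))
        v["lambda"] <- min(1, max(0, v["lambda"]))
        p <- tryCatch(do.call(luminance_params, as.list(v)),
                      error = function(e) NULL)
        if (!is.null(p)) break
      }
      if (is.null(p)) stop("could not draw valid jittered parameters")
      pset[[l]] <- p
    }
    attr(pset, "participant") <- sprintf("P%d", i)
    cohort[[i]] <- pset
  }
  cohort
}

#' Generate a complete synthetic experiment
#'
#' Produces a trial table with the full study design: for each participant,
#' `blocks * trials_per_block` trials with gap, cue side, and luminance
#' sampled independently and uniformly.  Urgent trials (gap >= 0) are run
#' through the race model; delay trials (gap < 0) are emulated statistically
#' — correct with probability `delay_model$p_correct` and RT drawn from a
#' lognormal — since the race model covers urgent trials only.  This delay
#' branch is a synthetic convention, not a mechanistic claim.
#'
#' @param cohort A [make_cohort()] result.
#' @param design An [experiment_design()].
#' @param consts A [sim_constants()] object.
#' @param seed Integer seed.
#' @param variant Model variant for the urgent branch.
#' @param delay_model List with `p_correct`, `meanlog`, `sdlog` for the delay
#'   branch.
#' @return Trial-record data frame with a leading `participant` column.
#' @export
generate_experiment <- function(cohort, design, consts = sim_constants(),
                                seed = NULL, variant = "full",
                                delay_model = list(p_correct = 0.992,
                                                   meanlog = log(260),
                                                   sdlog = 0.22)) {
  if (length(cohort) == 0L) stop("cohort must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  n <- design$blocks * design$trials_per_block
  all_out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    pid <- attr(cohort[[i]], "participant")
    if (is.null(pid)) pid <- sprintf("P%d", i)
    if (n == 0L) {
      all_out[[i]] <- empty_trials()
      next
    }
    gap <- sample(design$gaps, n, replace = TRUE)
    lum <- sample(design$luminances, n, replace = TRUE)
    side <- c("left", "right")[1L + (stats::runif(n) < 0.5)]
    rec <- vector("list", n)
    urgent <- gap >= 0
    for (l in design$luminances) {
      idx <- which(urgent & lum == l)
      if (!length(idx)) next
      r <- simulate_trials(cohort[[i]][[l]], gap[idx], consts = consts,
                           variant = variant, cue_side = side[idx],
                           rt_deadline = design$rt_deadline)
      r$luminance <- l
      r$.row <- idx
      rec[[idx[1]]] <- r
    }
    idx <- which(!urgent)
    if (length(idx)) {
      m <- length(idx)
      corr <- stats::runif(m) < delay_model$p_correct
      rt <- stats::rlnorm(m, delay_model$meanlog, delay_model$sdlog)
      other <- ifelse(side[idx] == "left", "right", "left")
      r <- data.frame(
        gap_ms = gap[idx], cue_side = side[idx],
        choice_side = ifelse(corr, other, side[idx]),
        correct = corr, rt_ms = rt, rpt_ms = rt - gap[idx],
        deadline_exceeded = rt > design$rt_deadline,
        outcome_class = NA_character_,
        sim_b_c0 = NA_real_, sim_b_a0 = NA_real_, sim_go_delay = NA_real_,
        sim_cue_delay = NA_real_, sim_eri = NA_real_, sim_lapse = NA,
        luminance = lum[idx], .row = idx, stringsAsFactors = FALSE)
      rec[[idx[1]]] <- r
    }
    rec <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
    rec <- rec[order(rec$.row), ]
    rec$.row <- NULL
    rec$participant <- pid
    all_out[[i]] <- rec
  }
  out <- do.call(rbind, all_out)
  rownames(out) <- NULL
  out[, c("participant", "luminance",
          setdiff(names(out), c("participant", "luminance")))]
}

# zero-row trial table with the canonical schema
empty_trials <- function() {
  data.frame(participant = character(), luminance = character(),
             gap_ms = numeric(), cue_side = character(),
             choice_side = character(), correct = logical(),
             rt_ms = numeric(), rpt_ms = numeric(),
             deadline_exceeded = logical(), outcome_class = character(),
             sim_b_c0 = numeric(), sim_b_a0 = numeric(),
             sim_go_delay = numeric(), sim_cue_delay = numeric(),
             sim_eri = numeric(), sim_lapse = logical(),
             stringsAsFactors = FALSE)
}
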