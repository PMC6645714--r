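# evaluate one simulated condition against its targets: tachometric MAE over
# jointly occupied bins plus MAE of every RT histogram pair
.condition_error <- function(sim, tgt, rt_breaks, bin_width) {
  half <- (bin_width - 1) / 2
  keep <- !is.na(sim$correct)
  sim <- sim[keep, , drop = FALSE]
  n <- nrow(sim)
  if (n == 0L) return(Inf)
  # tachometric term on the observed centers
  centers <- tgt$tach$rpt_center
  n_c <- .bin_counts(sim$rpt_ms[sim$correct], centers, half)
  n_i <- .bin_counts(sim$rpt_ms[!sim$correct], centers, half)
  tot <- n_c + n_i
  joint <- tot > 0 & !is.na(tgt$tach$p_correct)
  err <- mean(abs(n_c[joint] / tot[joint] - tgt$tach$p_correct[joint]))
  # RT histogram terms
  nb <- length(rt_breaks) - 1L
  for (j in seq_along(tgt$gaps)) {
    g <- sim[sim$gap_ms == tgt$gaps[j], , drop = FALSE]
    cut_rt <- function(rt) {
      idx <- findInterval(rt, rt_breaks, rightmost.closed = TRUE)
      tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
    }
    err <- err + mean(abs(cut_rt(g$rt_ms[g$correct]) / n - tgt$hist_correct[, j]))
    err <- err + mean(abs(cut_rt(g$rt_ms[!g$correct]) / n - tgt$hist_incorrect[, j]))
  }
  err
}

#' Model-fitting objective: summed mean absolute error
#'
#' Simulates `n_sim` trials per luminance condition with gap frequencies
#' matched to the targets, bins the simulated trials on the same grids, and
#' returns the sum over target functions (tachometric curve plus per-gap RT
#' histograms for correct and incorrect trials) of the mean absolute error
#' between simulation and targets.  A fixed seed gives common random numbers
#' across evaluations, which stabilizes comparisons during search.
#'
#' @param params_by_luminance Named list of [luminance_params()] matching the
#'   conditions in `targets`.
#' @param targets A [build_targets()] result.
#' @param n_sim Simulated trials per condition and evaluation.
#' @param seed Integer seed (common random numbers); the caller's RNG state
#'   is restored on exit.
#' @param consts,variant Passed to [simulate_trials()].
#' @return Nonnegative scalar; attribute `no_response_rate` carries the
#'   fraction of simulated trials without a threshold crossing (a warning is
#'   attached above 1 percent).
#' @export
race_objective <- function(params_by_luminance, targets, n_sim = 20000L,
                           seed = 1L, consts = sim_constants(),
                           variant = "full") {
  if (!inherits(targets, "target_set")) stop("targets must come from build_targets()")
  miss <- setdiff(names(targets$luminances), names(params_by_luminance))
  if (length(miss))
    stop("missing parameter sets for condition(s): ", paste(miss, collapse = ", "))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  total <- 0
  n_nr <- 0L
  for (l in names(targets$luminances)) {
    tgt <- targets$luminances[[l]]
    gap <- sample(tgt$gaps, n_sim, replace = TRUE, prob = tgt$gap_prob)
    sim <- simulate_trials(params_by_luminance[[l]], gap, consts = consts,
                           variant = variant)
    n_nr <- n_nr + sum(is.na(sim$correct))
    total <- total + .condition_error(sim, tgt, targets$rt_breaks,
                                      targets$bin_width)
  }
  nr_rate <- n_nr / (n_sim * length(targets$luminances))
  if (nr_rate > 0.01)
    warning(sprintf("no-response rate %.2f%% exceeds 1%%", 100 * nr_rate))
  attr(total, "no_response_rate") <- nr_rate
  total
}

# vector <-> parameter-list codec.  Layout: 5 shared motor entries followed
# by 10 condition-specific entries per luminance.
.motor_names <- c("mu_b", "sigma_b", "rho_b", "mu_go_aff", "sigma_go_aff")
.cond_names <- c("mu_cue_aff", "sigma_cue_aff", "mu_eri", "sigma_eri",
                 "g_eri", "delta_eri", "a_ex", "d_end", "a_end", "lambda")

.decode_theta <- function(theta, lums) {
  out <- list()
  motor <- theta[seq_along(.motor_names)]
  names(motor) <- .motor_names
  for (k in seq_along(lums)) {
    cond <- theta[5L + (k - 1L) * 10L + seq_len(10L)]
    names(cond) <- .cond_names
    out[[lums[k]]] <- do.call(luminance_params, as.list(c(motor, cond)))
  }
  out
}

.encode_bounds <- function(bounds, lums) {
  for (side in c("lower", "upper"))
    if (!all(c(.motor_names, .cond_names) %in% names(bounds[[side]])))
      stop("bounds$", side, " must name all 15 model parameters")
  lo <- c(bounds$lower[.motor_names],
          rep(bounds$lower[.cond_names], times = length(lums)))
  hi <- c(bounds$upper[.motor_names],
          rep(bounds$upper[.cond_names], times = length(lums)))
  if (any(hi < lo)) stop("bounds: upper must be >= lower")
  list(lo = unname(lo), hi = unname(hi))
}

#' Fit the race model by shrinking-box random search
#'
#' Iterated random search over the parameter box: each round draws uniform
#' candidates in the current box, keeps the best (under a common-random-
#' numbers objective), and shrinks the box around the incumbent by a fixed
#' factor; the whole schedule is repeated from several independent starts.
#' Parameters of the motor block (`mu_b`, `sigma_b`, `rho_b`, `mu_go_aff`,
#' `sigma_go_aff`) are shared across luminance conditions by construction.
#' Fixing a parameter (e.g. `g_eri = 0` for pooled data) is done by giving
#' it a zero-width bound.
#'
#' @param targets A [build_targets()] result.
#' @param bounds List with named numeric vectors `lower` and `upper` covering
#'   all 15 parameters (applied to every luminance condition).
#' @param n_starts,n_rounds,n_candidates Search schedule.
#' @param shrink Box shrink factor per round.
#' @param n_sim Simulated trials per objective evaluation.
#' @param seed Base seed; start `s`, round `r` evaluates with seed
#'   `seed + 1000 * s + r` (shared by all candidates of the round).
#' @param consts,variant Passed to the objective.
#' @return An object of class `"race_fit"`: `params_by_luminance`,
#'   `objective`, `theta`, `trace` (start, round, box volume fraction, best
#'   error), `converged`.
#' @export
fit_race_model <- function(targets, bounds, n_starts = 8L, n_rounds = 40L,
                           n_candidates = 60L, shrink = 0.7,
                           n_sim = 20000L, seed = 1L,
                           consts = sim_constants(), variant = "full") {
  lums <- names(targets$luminances)
  bx <- .encode_bounds(bounds, lums)
  d <- length(bx$lo)
  free <- bx$hi > bx$lo
  eval_theta <- function(theta, s) {
    p <- .decode_theta(theta, lums)
    suppressWarnings(as.numeric(
      race_objective(p, targets, n_sim = n_sim, seed = s,
                     consts = consts, variant = variant)))
  }
  best_all <- NULL
  trace <- list()
  improved <- FALSE
  for (s in seq_len(n_starts)) {
    set.seed(seed + s)
    width <- bx$hi - bx$lo
    center <- bx$lo + stats::runif(d) * width
    center[!free] <- bx$lo[!free]
    rseed <- seed + 1000L * s
    best <- list(theta = center, value = eval_theta(center, rseed))
    best_seen <- best$value
    for (r in seq_len(n_rounds)) {
      rseed <- seed + 1000L * s + r
      set.seed(seed + 100000L * s + r)   # candidate-sampling stream
      cand <- matrix(stats::runif(n_candidates * d), ncol = d)
      lo_r <- pmax(bx$lo, center - width / 2)
      hi_r <- pmin(bx$hi, center + width / 2)
      cand <- sweep(sweep(cand, 2, hi_r - lo_r, "*"), 2, lo_r, "+")
      cand[, !free] <- rep(bx$lo[!free], each = n_candidates)
      # incumbent re-scored under this round's common random numbers
      vals <- c(eval_theta(best$theta, rseed),
                apply(cand, 1, eval_theta, s = rseed))
      k <- which.min(vals)
      if (k > 1L) {
        best <- list(theta = cand[k - 1L, ], value = vals[k])
        improved <- TRUE
      } else best$value <- vals[1L]
      center <- best$theta
      width <- width * shrink
      best_seen <- min(best_seen, best$value)
      trace[[length(trace) + 1L]] <-
        data.frame(start = s, round = r,
                   box_fraction = prod((width / (bx$hi - bx$lo))[free])^(1 / sum(free)),
                   best_error = best_seen)
    }
    if (is.null(best_all) || best$value < best_all$value) best_all <- best
  }
  structure(list(params_by_luminance = .decode_theta(best_all$theta, lums),
                 objective = best_all$value,
                 theta = best_all$theta,
                 trace = do.call(rbind, trace),
                 converged = improved,
                 n_sim = n_sim, seed = seed),
            class = "race_fit")
}

#' @export
print.race_fit <- function(x, ...) {
  cat(sprintf("Race-model fit: objective = %.5f (n_sim = %d per evaluation)\n",
              x$objective, x$n_sim))
  for (l in names(x$params_by_luminance)) {
    cat(l, ":\n", sep = "")
    print(round(unlist(x$params_by_luminance[[l]]), 4))
  }
  invisible(x)
}
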