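#' Raw processing time
#'
#' The raw processing time (rPT) is the cue-viewing time of a trial: the
#' interval between cue onset and saccade onset, `rt - gap`.  Delay trials
#' carry negative gaps, so `rt + delay` is the same formula.
#'
#' @param rt Reaction time(s), ms (go signal to saccade onset).
#' @param gap Gap value(s), ms (negative for delay trials).
#' @return rPT in ms.
#' @export
compute_rpt <- function(rt, gap) {
  if (any(!is.finite(rt)) || any(!is.finite(gap)))
    stop("rt and gap must be finite")
  rt - gap
}

#' Tachometric curve in sliding rPT bins
#'
#' Counts correct and incorrect trials in overlapping rPT bins (width
#' `bin_width` ms, centers shifting every `step` ms) and forms the proportion
#' correct per bin,
#' `p = n_correct / (n_correct + n_incorrect)`.
#' The normalized frequency functions `f_c` and `f_i` are the two counts
#' divided by a common display factor (the largest single-bin count); the
#' factor provably cancels in the proportion.
#'
#' @param trials Trial-record data frame with columns `rpt_ms` and `correct`
#'   (non-responses, `correct == NA`, are dropped).
#' @param bin_width Bin width in ms (odd, so bins are centered on the grid).
#' @param step Grid spacing of bin centers in ms.
#' @return An object of class `"tach_curve"`: a list with `rpt_centers`,
#'   `n_correct`, `n_incorrect`, `p_correct` (NA in empty bins), `f_c`,
#'   `f_i`, `norm_factor`, `bin_width`, and `n_trials`.
#' @export
compute_tachometric <- function(trials, bin_width = 15, step = 1) {
  if (!is.data.frame(trials) || !all(c("rpt_ms", "correct") %in% names(trials)))
    stop("trials must be a data frame with columns rpt_ms and correct")
  keep <- !is.na(trials$correct) & is.finite(trials$rpt_ms)
  rpt <- trials$rpt_ms[keep]
  corr <- as.logical(trials$correct[keep])
  if (length(rpt) == 0L) stop("no analyzable trials (all missing)")
  if (bin_width %% 2 != 1) stop("bin_width must be odd so bins center on the grid")
  half <- (bin_width - 1) / 2

  centers <- seq(floor(min(rpt)), ceiling(max(rpt)), by = step)
  count_in_bins <- function(x) {
    x <- sort(x)
    # cumulative counts at bin edges; inclusive on both ends
    hi <- findInterval(centers + half + 1e-9, x)
    lo <- findInterval(centers - half - 1e-9, x)
    hi - lo
  }
  n_c <- count_in_bins(rpt[corr])
  n_i <- count_in_bins(rpt[!corr])
  tot <- n_c + n_i
  p <- ifelse(tot > 0, n_c / tot, NA_real_)
  norm <- max(max(n_c), max(n_i), 1)
  structure(list(rpt_centers = centers, n_correct = n_c, n_incorrect = n_i,
                 p_correct = p, f_c = n_c / norm, f_i = n_i / norm,
                 norm_factor = norm, bin_width = bin_width,
                 n_trials = length(rpt)),
            class = "tach_curve")
}

#' @export
print.tach_curve <- function(x, ...) {
  occ <- sum(x$n_correct + x$n_incorrect > 0)
  cat(sprintf(
    "Tachometric curve: %d trials, rPT %d..%d ms, %d-ms bins, %d occupied\n",
    x$n_trials, min(x$rpt_centers), max(x$rpt_centers), x$bin_width, occ))
  invisible(x)
}

#' @export
as.data.frame.tach_curve <- function(x, ...) {
  data.frame(rpt_center = x$rpt_centers, n_correct = x$n_correct,
             n_incorrect = x$n_incorrect, p_correct = x$p_correct)
}
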