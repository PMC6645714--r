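# shared inclusive sliding-bin counter: number of x in [center - half,
# center + half] for every center (centers need not be contiguous)
.bin_counts <- function(x, centers, half) {
  x <- sort(x)
  findInterval(centers + half + 1e-9, x) - findInterval(centers - half - 1e-9, x)
}

#' Build the target functions for model fitting
#'
#' Converts a trial table into the set of binned functions the model is
#' fitted against: for each luminance condition, the tachometric curve plus,
#' for each urgent gap, the RT histograms of correct and incorrect trials.
#' Histograms use fixed 10-ms bins over \[0, 600\] ms by default and are
#' normalized by the condition's total trial count, so the masses of one
#' gap's pair of histograms sum to that cell's fraction of trials.
#'
#' @param trials Trial table with columns `gap_ms`, `correct`, `rt_ms`,
#'   `rpt_ms`, and optionally `luminance` (a single unnamed condition is
#'   assumed otherwise).
#' @param rt_breaks RT bin edges in ms.
#' @param bin_width Tachometric bin width (ms).
#' @return An object of class `"target_set"`: per luminance a list with the
#'   tachometric data frame, the gap set and observed gap frequencies, the
#'   two histogram matrices (bins x gaps), and the trial count.
#' @export
build_targets <- function(trials, rt_breaks = seq(0, 600, by = 10),
                          bin_width = 15) {
  if (!"luminance" %in% names(trials)) trials$luminance <- "all"
  urgent <- trials[trials$gap_ms >= 0 & !is.na(trials$correct), , drop = FALSE]
  if (nrow(urgent) == 0L) stop("no analyzable urgent trials")
  if (length(unique(urgent$gap_ms)) < 2L)
    warning("fewer than two distinct gaps; the RT targets will be degenerate")
  out <- list()
  for (l in unique(urgent$luminance)) {
    sub <- urgent[urgent$luminance == l, , drop = FALSE]
    gaps <- sort(unique(sub$gap_ms))
    n <- nrow(sub)
    nb <- length(rt_breaks) - 1L
    h_c <- h_i <- matrix(0, nrow = nb, ncol = length(gaps),
                         dimnames = list(NULL, paste0("gap", gaps)))
    for (j in seq_along(gaps)) {
      g <- sub[sub$gap_ms == gaps[j], , drop = FALSE]
      cut_rt <- function(rt) {
        idx <- findInterval(rt, rt_breaks, rightmost.closed = TRUE)
        tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
      }
      h_c[, j] <- cut_rt(g$rt_ms[g$correct]) / n
      h_i[, j] <- cut_rt(g$rt_ms[!g$correct]) / n
    }
    curve <- compute_tachometric(sub, bin_width = bin_width)
    out[[l]] <- list(tach = as.data.frame(curve),
                     gaps = gaps,
                     gap_prob = as.numeric(table(factor(sub$gap_ms,
                                                        levels = gaps))) / n,
                     hist_correct = h_c, hist_incorrect = h_i,
                     n = n)
  }
  structure(list(luminances = out, rt_breaks = rt_breaks,
                 bin_width = bin_width),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  for (l in names(x$luminances)) {
    t <- x$luminances[[l]]
    cat(sprintf("%s: %d trials, %d gaps, %d RT bins\n",
                l, t$n, length(t$gaps), nrow(t$hist_correct)))
  }
  invisible(x)
}
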