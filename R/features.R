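#' Characteristic features of a fitted tachometric curve
#'
#' Computes, on a 1-ms evaluation grid, the eight quantities that summarize
#' a fitted curve: the asymptote (`A_R`), the minimum value (vortex depth),
#' the rPT of the minimum (vortex time), the most negative and most positive
#' slopes (central finite differences), the rPT where the falling branch is
#' midway between chance (0.5) and the minimum (left edge), the rPT where
#' the rising branch is midway between the minimum and the asymptote
#' (centerpoint), and the average of the curve over rPT in \[0, 250\] ms
#' (mean perceptual accuracy).
#'
#' @param fit A `"vfit"` object or [vfit_params()].
#' @param rpt_range Evaluation range in ms; must cover \[0, 250\].
#' @return Named numeric vector of class `"curve_features"` with elements
#'   `asymptote`, `vortex_depth`, `vortex_time`, `slope_min`, `slope_max`,
#'   `left_edge`, `centerpoint`, `mean_perceptual_accuracy`.
#' @export
extract_features <- function(fit, rpt_range = c(-100, 500)) {
  params <- if (inherits(fit, "vfit")) fit$params else fit
  if (!inherits(params, "vfit_params")) stop("fit must carry vfit_params")
  if (rpt_range[1] > 0 || rpt_range[2] < 250)
    stop("rpt_range must cover [0, 250] ms")
  grid <- seq(rpt_range[1], rpt_range[2], by = 1)
  v <- evaluate_v(params, grid)

  i_min <- which.min(v)
  vortex_depth <- v[i_min]
  vortex_time <- grid[i_min]

  slopes <- (v[-(1:2)] - v[1:(length(v) - 2)]) / 2   # central differences

  # falling branch: last grid point at/left of the minimum still at or above
  # the midpoint between chance and the minimum
  m_left <- (0.5 + vortex_depth) / 2
  left_part <- v[1:i_min]
  i_le <- which(left_part >= m_left)
  left_edge <- if (length(i_le)) grid[max(i_le)] else NA_real_

  # rising branch: first grid point at/right of the minimum reaching the
  # midpoint between the minimum and the asymptote
  m_right <- (vortex_depth + params$A_R) / 2
  right_part <- v[i_min:length(v)]
  i_cp <- which(right_part >= m_right)
  centerpoint <- if (length(i_cp)) grid[i_min + min(i_cp) - 1L] else NA_real_

  mpa <- mean(evaluate_v(params, 0:250))

  structure(c(asymptote = params$A_R, vortex_depth = vortex_depth,
              vortex_time = vortex_time,
              slope_min = min(slopes), slope_max = max(slopes),
              left_edge = left_edge, centerpoint = centerpoint,
              mean_perceptual_accuracy = mpa),
            class = "curve_features")
}

#' @export
print.curve_features <- function(x, ...) {
  cat("Tachometric curve features\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for curve features
#'
#' Implements the resampling scheme used for the feature uncertainties:
#' (1) resample the trials with replacement keeping the original n, (2)
#' recompute the tachometric curve, (3) refit the analytical function, (4)
#' re-extract the features, and (5) repeat; the reported interval is the
#' 2.5-97.5 percentile range of each feature's bootstrap distribution.
#' Replicate fits start from the point-estimate solution (plus mild
#' perturbations), which keeps the procedure fast without changing the
#' optimum being tracked.
#'
#' @param trials Trial-record data frame (`rpt_ms`, `correct`).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @param bin_width,step Passed to [compute_tachometric()].
#' @param rpt_window Passed to [fit_tachometric()].
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"feature_ci"`: a data frame with one row per
#'   feature (`point`, `lower`, `upper`), plus attributes `n_boot`,
#'   `n_failed`, and the point fit.
#' @export
bootstrap_features <- function(trials, n_boot = 10000L, seed = NULL,
                               bin_width = 15, step = 1, rpt_window = NULL,
                               conf = 0.95) {
  keep <- !is.na(trials$correct) & is.finite(trials$rpt_ms)
  trials <- trials[keep, , drop = FALSE]
  n <- nrow(trials)
  if (n < 100L) stop("need at least 100 trials to bootstrap the features")
  if (!is.null(seed)) set.seed(seed)

  point_curve <- compute_tachometric(trials, bin_width = bin_width, step = step)
  point_fit <- fit_tachometric(point_curve, rpt_window = rpt_window)
  point_feat <- extract_features(point_fit)

  pf <- point_fit$params
  warm_starts <- list(c(pf$B, pf$A_R, pf$C_L, pf$C_R,
                        log(pf$D_L), log(pf$D_R)))

  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(point_feat))
  colnames(boot) <- names(point_feat)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_feat <- tryCatch({
      cv <- compute_tachometric(trials[idx, , drop = FALSE],
                                bin_width = bin_width, step = step)
      ft <- fit_tachometric(cv, rpt_window = rpt_window, starts = warm_starts,
                            reltol = 1e-5, maxit = 400L, polish = FALSE)
      extract_features(ft)
    }, error = function(e) NULL)
    if (is.null(rep_feat)) n_failed <- n_failed + 1L
    else boot[b, ] <- rep_feat
  }
  if (n_failed > 0.05 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates failed to fit",
                    n_failed, n_boot))
  a <- (1 - conf) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(feature = names(point_feat),
                    point = as.numeric(point_feat),
                    lower = qs[1, ], upper = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "n_failed") <- n_failed
  attr(out, "point_fit") <- point_fit
  attr(out, "boot") <- boot
  class(out) <- c("feature_ci", "data.frame")
  out
}
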