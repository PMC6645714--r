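#' Coefficients of the analytical tachometric function v(x)
#'
#' The fitted tachometric curve is the pointwise maximum of two sigmoids and
#' zero, `v(x) = max(sL(x), sR(x), 0)`, with
#' `sL(x) = B + (A_L - B) / (1 + exp((x - C_L)/D_L))` falling from the chance
#' level `A_L` toward the floor `B`, and
#' `sR(x) = B + (A_R - B) / (1 + exp(-(x - C_R)/D_R))` rising from `B` toward
#' the asymptote `A_R`.  `A_L` is pinned at 0.5: with no time to view the cue
#' performance must be at chance.
#'
#' @param B Floor of the two sigmoids (proportion).
#' @param A_R Right asymptote (proportion).
#' @param C_L,C_R Sigmoid midpoints (ms).
#' @param D_L,D_R Sigmoid widths (ms, strictly positive).
#' @return An object of class `"vfit_params"`.
#' @export
vfit_params <- function(B, A_R, C_L, C_R, D_L, D_R) {
  v <- c(B = B, A_L = 0.5, A_R = A_R, C_L = C_L, C_R = C_R,
         D_L = D_L, D_R = D_R)
  if (any(!is.finite(v))) stop("all coefficients must be finite")
  if (D_L <= 0 || D_R <= 0) stop("D_L and D_R must be strictly positive")
  structure(as.list(v), class = "vfit_params")
}

#' Evaluate the analytical tachometric function
#'
#' @param params A [vfit_params()] object.
#' @param rpt rPT value(s) in ms.
#' @return `v(rpt)`, elementwise `max(sL, sR, 0)`.
#' @export
evaluate_v <- function(params, rpt) {
  if (!inherits(params, "vfit_params")) stop("params must be a vfit_params object")
  sL <- params$B + (params$A_L - params$B) /
    (1 + exp((rpt - params$C_L) / params$D_L))
  sR <- params$B + (params$A_R - params$B) /
    (1 + exp(-(rpt - params$C_R) / params$D_R))
  pmax(sL, sR, 0)
}

# (weighted) mean absolute error between curve proportions and v at the
# occupied centers
vfit_mae <- function(par, x, p, w = NULL) {
  v <- vfit_params(par[1], par[2], par[3], par[4], exp(par[5]), exp(par[6]))
  if (is.null(w)) mean(abs(p - evaluate_v(v, x)))
  else sum(w * abs(p - evaluate_v(v, x))) / sum(w)
}

# deterministic, data-driven start points for the simplex search.  The
# max-of-sigmoids error surface is multimodal, so several starts spanning
# plausible widths and floor/midpoint placements are tried.  Landmarks are
# placed on a count-pooled curve (proportions of summed counts in a sliding
# window) so that sparse edge bins cannot masquerade as the vortex.
vfit_starts <- function(x, p, w = NULL) {
  if (is.null(w)) w <- rep(1, length(p))
  k <- 10L
  pool <- function(v) {
    out <- v
    for (i in seq_along(v)) {
      j <- which(x >= x[i] - k & x <= x[i] + k)
      out[i] <- sum(v[j])
    }
    out
  }
  tot_p <- pool(w)
  num_p <- pool(w * p)
  pp <- num_p / pmax(tot_p, 1e-12)
  # work inside the well-populated core of the rpt range
  core <- tot_p >= max(tot_p) * 0.02
  idx <- which(core)
  i_min <- idx[which.min(pp[idx])]
  B0 <- max(0, pp[i_min])
  right <- idx[x[idx] >= x[i_min]]
  A0 <- min(1, max(pp[right][x[right] >= stats::quantile(x[right], 0.8)], 0.6))
  CL0 <- x[i_min] - 10
  above <- right[pp[right] >= (B0 + A0) / 2]
  CR0 <- if (length(above)) x[above][1] else x[i_min] + 30
  starts <- list()
  for (D in c(3, 8, 15, 30))
    for (shift in c(-10, 0, 10))
      starts[[length(starts) + 1L]] <-
        c(B0, A0, CL0 + shift, CR0 + shift, log(D), log(D))
  # a few floor/asymptote variations
  for (B in c(0, 0.25)) for (A in c(0.8, 1.0))
    starts[[length(starts) + 1L]] <- c(B, A, CL0, CR0, log(8), log(8))
  starts
}

#' Fit the analytical function to a tachometric curve
#'
#' Minimizes the mean absolute error between the per-bin proportions correct
#' and `v(x)` at the occupied bin centers, using a derivative-free
#' Nelder-Mead simplex search from multiple deterministic start points
#' (the surface is multimodal); the best solution is polished by a restart.
#' `A_L` is held at 0.5 throughout.  Widths are optimized on the log scale to
#' keep them positive; final `B` and `A_R` are clamped to `[0, 1]`.
#'
#' @param curve A [compute_tachometric()] result, or a data frame with
#'   columns `rpt_center` and `p_correct`.
#' @param rpt_window Optional `c(lo, hi)` restricting the fitted rPT range.
#' @param starts Optional list of start vectors
#'   `c(B, A_R, C_L, C_R, log D_L, log D_R)`; data-driven defaults otherwise.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param maxit Iteration cap per start.
#' @param polish Restart the simplex once from the incumbent (default);
#'   disable for speed in resampling loops.
#' @param weight_bins Weight each bin's absolute error by its trial count
#'   instead of equally (default unweighted).
#' @return An object of class `"vfit"`: the fitted [vfit_params()] plus
#'   `mae` (objective at the optimum), `n_bins`, `rpt_range`, and
#'   `convergence` (0 = converged).
#' @export
fit_tachometric <- function(curve, rpt_window = NULL, starts = NULL,
                            reltol = 1e-6, maxit = 1000L, polish = TRUE,
                            weight_bins = FALSE) {
  df <- if (inherits(curve, "tach_curve")) as.data.frame(curve)
        else as.data.frame(curve)
  if (!all(c("rpt_center", "p_correct") %in% names(df)))
    stop("curve must provide rpt_center and p_correct")
  keep <- !is.na(df$p_correct)
  if (!is.null(rpt_window))
    keep <- keep & df$rpt_center >= rpt_window[1] & df$rpt_center <= rpt_window[2]
  x <- df$rpt_center[keep]
  p <- df$p_correct[keep]
  w <- if (all(c("n_correct", "n_incorrect") %in% names(df)))
    (df$n_correct + df$n_incorrect)[keep] else NULL
  if (length(x) < 20L)
    stop("need at least 20 occupied bins to fit the curve")
  if (weight_bins && is.null(w))
    stop("weight_bins requires per-bin counts in the curve")
  if (is.null(starts)) starts <- vfit_starts(x, p, w)
  obj <- function(par) vfit_mae(par, x, p, if (weight_bins) w else NULL)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all simplex starts failed")
  if (polish) {
    best2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = maxit))
    if (best2$value < best$value) best <- best2
  }
  par <- best$par
  pars <- vfit_params(B = min(max(par[1], 0), 1), A_R = min(max(par[2], 0), 1),
                      C_L = par[3], C_R = par[4],
                      D_L = exp(par[5]), D_R = exp(par[6]))
  structure(list(params = pars, mae = best$value, n_bins = length(x),
                 rpt_range = range(x), convergence = best$convergence),
            class = "vfit")
}

#' @export
print.vfit <- function(x, ...) {
  cat(sprintf("Analytical tachometric fit: MAE = %.5f over %d bins\n",
              x$mae, x$n_bins))
  print(round(unlist(x$params), 4))
  invisible(x)
}

#' Width of the rising branch between two levels
#'
#' Measures, on a 1-ms grid, the rPT distance between the points where the
#' fitted curve first reaches `lo` and `hi` on its ascending branch (to the
#' right of the curve minimum).
#'
#' @param fit A `"vfit"` object or [vfit_params()].
#' @param lo,hi Proportion levels, `lo < hi`.
#' @param rpt_range Grid range to scan (ms).
#' @return Span in ms (NA if a level is never reached).
#' @export
rise_span <- function(fit, lo = 0.25, hi = 0.75, rpt_range = c(-100, 500)) {
  params <- if (inherits(fit, "vfit")) fit$params else fit
  grid <- seq(rpt_range[1], rpt_range[2], by = 1)
  v <- evaluate_v(params, grid)
  i_min <- which.min(v)
  rise <- v[i_min:length(v)]
  g <- grid[i_min:length(v)]
  i_lo <- which(rise >= lo)[1]
  i_hi <- which(rise >= hi)[1]
  if (is.na(i_lo) || is.na(i_hi)) return(NA_real_)
  g[i_hi] - g[i_lo]
}
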