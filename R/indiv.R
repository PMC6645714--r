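#' Partial correlation controlling for a covariate
#'
#' Pearson: correlates the residuals of `x` and `y` after linearly removing
#' the covariate `z` from each.  Spearman: the same computation on the rank
#' transforms of all three variables.  Significance uses the t approximation
#' with `n - 3` degrees of freedom (two variables plus one covariate).
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param z Covariate vector (e.g. luminance coded ordinally 1/2/3).
#' @param method `"spearman"` (default; generally the most conservative) or
#'   `"pearson"`.
#' @return A list with `rho`, `p_value`, `n`, and `method`.
#' @export
partial_correlation <- function(x, y, z, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("missing values are not supported")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  if (stats::sd(rx) <= 1e-8 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-8 * (stats::sd(y) + 1e-300))
    stop("zero variance after removing the covariate; correlation undefined")
  rho <- stats::cor(rx, ry)
  df <- n - 3
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Linear regression of y on x with a covariate
#'
#' Ordinary least squares of `y` on `x` and `z` (with intercept); the
#' coefficient table for the `x` term carries the association of interest
#' after accounting for the covariate.
#'
#' @inheritParams partial_correlation
#' @return A list with `coefficients` (the full summary table) and `x_term`
#'   (named vector: estimate, std_error, t, p).
#' @export
regression_with_covariate <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  fit <- stats::lm(y ~ x + z)
  if (fit$rank < 3L) {
    ali <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear term(s): ",
         paste(ali, collapse = ", "))
  }
  tab <- summary(fit)$coefficients
  xs <- tab["x", ]
  names(xs) <- c("estimate", "std_error", "t", "p")
  list(coefficients = tab, x_term = xs, fit = fit)
}

#' Per-participant, per-luminance summary table
#'
#' Builds one row per participant and luminance condition from a trial table:
#' mean observed accuracy over urgent trials, mean RT (correct and incorrect
#' trials together), and the perceptual features extracted from the fitted
#' tachometric curve of that cell (notably the mean perceptual accuracy and
#' the centerpoint).
#'
#' @param trials Trial table with columns `participant`, `luminance`,
#'   `gap_ms`, `correct`, `rt_ms`, `rpt_ms`.
#' @param rpt_window Optional fitting window passed to [fit_tachometric()].
#' @return Data frame with columns `participant`, `luminance`,
#'   `mean_observed_accuracy`, `mean_rt`, and the eight curve features.
#' @export
participant_summary <- function(trials, rpt_window = NULL) {
  need <- c("participant", "luminance", "gap_ms", "correct", "rt_ms", "rpt_ms")
  if (!all(need %in% names(trials)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  urgent <- trials[trials$gap_ms >= 0 & !is.na(trials$correct), , drop = FALSE]
  cells <- unique(urgent[, c("participant", "luminance")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- urgent[urgent$participant == cells$participant[i] &
                  urgent$luminance == cells$luminance[i], , drop = FALSE]
    feat <- tryCatch({
      cv <- compute_tachometric(sub)
      extract_features(fit_tachometric(cv, rpt_window = rpt_window))
    }, error = function(e) {
      stats::setNames(rep(NA_real_, 8),
                      c("asymptote", "vortex_depth", "vortex_time",
                        "slope_min", "slope_max", "left_edge", "centerpoint",
                        "mean_perceptual_accuracy"))
    })
    out[[i]] <- data.frame(
      participant = cells$participant[i], luminance = cells$luminance[i],
      mean_observed_accuracy = mean(sub$correct),
      mean_rt = mean(sub$rt_ms),
      as.list(unclass(feat)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Ordinal coding of luminance levels
#'
#' Codes luminance for covariate adjustment: ordinal 1/2/3 (low/medium/high)
#' by default, or the base-10 log of the printed luminances in cd/m^2.
#'
#' @param luminance Character vector with values in
#'   `c("low", "medium", "high")`.
#' @param scale `"ordinal"` (default) or `"log_cd_m2"`.
#' @return Numeric vector.
#' @export
code_luminance <- function(luminance, scale = c("ordinal", "log_cd_m2")) {
  scale <- match.arg(scale)
  lev <- c(low = 1, medium = 2, high = 3)
  cd <- c(low = 0.22, medium = 0.35, high = 17.6)
  if (any(!luminance %in% names(lev)))
    stop("luminance values must be low/medium/high")
  if (scale == "ordinal") unname(lev[luminance]) else unname(log10(cd[luminance]))
}
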