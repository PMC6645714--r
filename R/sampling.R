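#' Draw correlated initial build-up rates
#'
#' The two motor plans start each trial with build-up rates drawn from a
#' bivariate Gaussian with common mean `mu_b`, common SD `sigma_b`, and
#' correlation `rho_b`.  Values may be negative (the activities, not the
#' rates, are floored at zero during integration).
#'
#' @param params A [luminance_params()] object.
#' @param n Number of trials.
#' @return A list with numeric vectors `b_c0` (cue plan) and `b_a0` (anti
#'   plan), each of length `n`.
#' @export
sample_build_up_rates <- function(params, n = 1L) {
  validate_luminance_params(params)
  mu <- params$mu_b; s <- params$sigma_b; rho <- params$rho_b
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  # Cholesky factor of the 2x2 correlation matrix
  b_c0 <- mu + s * z1
  b_a0 <- mu + s * (rho * z1 + sqrt(1 - rho^2) * z2)
  list(b_c0 = b_c0, b_a0 = b_a0)
}

#' Draw afferent delays (rejection-truncated Gaussian)
#'
#' Afferent delays are Gaussian with the given mean and SD, with values below
#' `floor` excluded by resampling (rejection, not clipping), reflecting the
#' minimum conduction time of the visual pathway.
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD (ms).
#' @param floor Minimum admissible delay (ms).
#' @param max_rounds Bound on resampling rounds before giving up.
#' @return Numeric vector of delays, all `>= floor`.
#' @export
sample_afferent_delay <- function(n, mu, sigma, floor = 20, max_rounds = 1000L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) {
    if (mu < floor)
      stop("degenerate afferent delay below the floor is unsatisfiable")
    return(rep(mu, n))
  }
  if (stats::pnorm(floor, mu, sigma, lower.tail = FALSE) < 1e-12)
    stop("the afferent-delay distribution has essentially no mass above the floor")
  out <- stats::rnorm(n, mu, sigma)
  bad <- which(out < floor)
  rounds <- 0L
  while (length(bad) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("afferent-delay rejection sampling failed to terminate")
    out[bad] <- stats::rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < floor]
  }
  out
}

#' Draw ERI durations (Gaussian, negatives reset to zero)
#'
#' The exogenous response interval duration is Gaussian; negative draws are
#' clipped to zero (contrast with the rejection rule for afferent delays).
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD (ms).
#' @return Nonnegative numeric vector.
#' @export
sample_eri_duration <- function(n, mu, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  pmax(0, stats::rnorm(n, mu, sigma))
}
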