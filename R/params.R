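#' Parameter set for one luminance condition of the race model
#'
#' Bundles the 15 parameters that govern the accelerated race-to-threshold
#' model for a single cue-luminance condition: the joint distribution of the
#' two initial build-up rates, the afferent delays of the go signal and of the
#' cue, the exogenous response interval (ERI) and its gain, the exogenous and
#' endogenous accelerations, the endogenous deceleration, and the lapse
#' probability.
#'
#' @param mu_b,sigma_b Mean and SD of the initial build-up rates (AU/ms).
#' @param rho_b Correlation between the two initial build-up rates, in
#'   \[-1, 1\].
#' @param mu_go_aff,sigma_go_aff Mean and SD of the go-signal afferent delay
#'   (ms); draws below the afferent floor are rejected and redrawn.
#' @param mu_cue_aff,sigma_cue_aff Mean and SD of the cue afferent delay (ms);
#'   same rejection rule.
#' @param mu_eri,sigma_eri Mean and SD of the ERI duration (ms); negative
#'   draws are reset to zero.
#' @param g_eri ERI gain factor (dimensionless, must be <= 0): 0 halts the
#'   affected plan, negative values suppress it.
#' @param delta_eri Initial halting window of the cue plan within the ERI
#'   (ms, >= 0); the exogenous acceleration acts only during the remaining
#'   `max(0, ERI - delta_eri)` ms.
#' @param a_ex Exogenous acceleration of the cue plan (AU/ms^2, >= 0).
#' @param d_end Endogenous deceleration of the cue plan after the ERI
#'   (AU/ms^2, must be <= 0).
#' @param a_end Endogenous acceleration of the anti plan after the ERI
#'   (AU/ms^2, >= 0).
#' @param lambda Lapse probability in \[0, 1\]: on lapse trials the endogenous
#'   acceleration/deceleration never engage.
#'
#' @return An object of class `"luminance_params"` (a named list).
#' @seealso [pooled_params()] for the published pooled-data values,
#'   [simulate_trials()] for running the model.
#' @export
luminance_params <- function(mu_b, sigma_b, rho_b,
                             mu_go_aff, sigma_go_aff,
                             mu_cue_aff, sigma_cue_aff,
                             mu_eri, sigma_eri,
                             g_eri, delta_eri,
                             a_ex, d_end, a_end, lambda) {
  p <- list(mu_b = mu_b, sigma_b = sigma_b, rho_b = rho_b,
            mu_go_aff = mu_go_aff, sigma_go_aff = sigma_go_aff,
            mu_cue_aff = mu_cue_aff, sigma_cue_aff = sigma_cue_aff,
            mu_eri = mu_eri, sigma_eri = sigma_eri,
            g_eri = g_eri, delta_eri = delta_eri,
            a_ex = a_ex, d_end = d_end, a_end = a_end, lambda = lambda)
  validate_luminance_params(p)
  structure(p, class = "luminance_params")
}

#' @rdname luminance_params
#' @param x Object to validate.
#' @export
validate_luminance_params <- function(x) {
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num))
    stop("all model parameters must be finite numeric scalars; offending: ",
         paste(names(x)[!num], collapse = ", "))
  if (x$sigma_b < 0 || x$sigma_go_aff < 0 || x$sigma_cue_aff < 0 ||
      x$sigma_eri < 0)
    stop("standard deviations must be nonnegative")
  if (abs(x$rho_b) > 1) stop("rho_b must lie in [-1, 1]")
  if (x$lambda < 0 || x$lambda > 1) stop("lambda must lie in [0, 1]")
  if (x$g_eri > 0) stop("g_eri must be <= 0 (halting or suppression)")
  if (x$d_end > 0) stop("d_end must be <= 0 (deceleration)")
  if (x$a_end < 0) stop("a_end must be >= 0")
  if (x$delta_eri < 0) stop("delta_eri must be >= 0")
  invisible(x)
}

#' Published pooled-data parameters of the race model
#'
#' Returns the best-fitting model parameters for the data pooled across
#' participants, one set per cue-luminance condition.  The motor block
#' (build-up rate distribution and go-signal afferent delay) is shared across
#' conditions; the cue afferent delay, ERI, exogenous/endogenous terms and
#' lapse rate are luminance specific.
#'
#' @param luminance One of `"high"`, `"medium"`, `"low"`, or `"all"` (default)
#'   for a named list of all three.
#' @return A `luminance_params` object, or a named list of the three.
#' @export
pooled_params <- function(luminance = c("all", "high", "medium", "low")) {
  luminance <- match.arg(luminance)
  tab <- list(
    high = luminance_params(
      mu_b = 1.4, sigma_b = 3.74, rho_b = -0.95,
      mu_go_aff = 51, sigma_go_aff = 36,
      mu_cue_aff = 76, sigma_cue_aff = 5,
      mu_eri = 24, sigma_eri = 4, g_eri = 0, delta_eri = 10,
      a_ex = 0.96, d_end = -0.7, a_end = 0.17, lambda = 0.02),
    medium = luminance_params(
      mu_b = 1.4, sigma_b = 3.74, rho_b = -0.95,
      mu_go_aff = 51, sigma_go_aff = 36,
      mu_cue_aff = 104, sigma_cue_aff = 13,
      mu_eri = 24, sigma_eri = 3, g_eri = 0, delta_eri = 14,
      a_ex = 1.15, d_end = -0.54, a_end = 0.17, lambda = 0.02),
    low = luminance_params(
      mu_b = 1.4, sigma_b = 3.74, rho_b = -0.95,
      mu_go_aff = 51, sigma_go_aff = 36,
      mu_cue_aff = 126, sigma_cue_aff = 19,
      mu_eri = 24, sigma_eri = 10, g_eri = 0, delta_eri = 14,
      a_ex = 0.58, d_end = -0.29, a_end = 0.14, lambda = 0.1))
  if (luminance == "all") tab else tab[[luminance]]
}

#' Fixed constants of the simulation
#'
#' @param threshold Saccade-trigger level (arbitrary units).
#' @param efferent_delay Time from threshold crossing to saccade onset (ms).
#' @param dt Integration time step (ms).
#' @param afferent_floor Minimum afferent delay (ms); Gaussian draws below it
#'   are rejected.
#' @param t_max Hard cap on simulated time per trial (ms); trials with no
#'   crossing by then are flagged as non-responses.
#' @return An object of class `"sim_constants"`.
#' @export
sim_constants <- function(threshold = 1000, efferent_delay = 20, dt = 1,
                          afferent_floor = 20, t_max = 5000) {
  v <- c(threshold = threshold, efferent_delay = efferent_delay, dt = dt,
         afferent_floor = afferent_floor, t_max = t_max)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all simulation constants must be strictly positive and finite")
  structure(as.list(v), class = "sim_constants")
}

#' @export
print.luminance_params <- function(x, ...) {
  cat("Race-model parameters (one luminance condition)\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.sim_constants <- function(x, ...) {
  cat("Simulation constants\n")
  print(unlist(x))
  invisible(x)
}

# resolve a model-variant string to the integer code used by the C++ core
variant_code <- function(variant = c("full", "accel_only", "halt_only")) {
  variant <- match.arg(variant)
  c(full = 0L, accel_only = 1L, halt_only = 2L)[[variant]]
}
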