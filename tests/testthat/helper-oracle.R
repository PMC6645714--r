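# Independent reference integrator for the race model, written directly from
# the three-epoch description and kept free of any code shared with the
# package's C++ core.  State (two build-up rates, two activities) is carried
# incrementally step by step; epoch membership is decided on the absolute
# clock.  Conventions match the package's documented scheme: at each step the
# clock advances by dt, rates are set for the new time, activities integrate,
# are floored at zero, and the threshold is checked.
oracle_trial <- function(params, gap, b_c0, b_a0, go_delay, cue_delay, eri,
                         lapse = FALSE, variant = "full",
                         threshold = 1000, efferent_delay = 20, dt = 1,
                         t_max = 5000) {
  t_detect <- gap + cue_delay
  halt_end <- t_detect + min(params$delta_eri, eri)
  eri_end <- t_detect + eri
  bc_final <- if (variant == "halt_only") b_c0 else
    b_c0 + params$a_ex * (eri - min(params$delta_eri, eri))
  rC <- 0; rA <- 0
  t <- 0
  repeat {
    t <- t + dt
    if (t > t_max) return(list(rt = NA_real_, winner = NA_character_))
    if (t <= go_delay) {
      bC <- 0; bA <- 0
    } else if (t <= t_detect) {
      bC <- b_c0; bA <- b_a0
    } else if (t <= eri_end) {
      bA <- if (variant == "accel_only") b_a0 else params$g_eri * b_a0
      if (variant == "halt_only") {
        bC <- b_c0
      } else if (t <= halt_end) {
        bC <- params$g_eri * b_c0
      } else {
        bC <- b_c0 + params$a_ex * (t - halt_end)
      }
    } else {
      if (lapse) {
        bC <- bc_final
        bA <- b_a0
      } else {
        bC <- bc_final + params$d_end * (t - eri_end)
        bA <- b_a0 + params$a_end * (t - eri_end)
      }
    }
    rC <- max(0, rC + bC * dt)
    rA <- max(0, rA + bA * dt)
    if (rC >= threshold || rA >= threshold) {
      winner <- if (rC > rA) "cue" else if (rA > rC) "anti" else "tie"
      return(list(rt = t + efferent_delay, winner = winner))
    }
  }
}

# truncated-normal mean (values below `floor` excluded) by numerical
# integration of the density
truncnorm_mean_quadrature <- function(mu, sigma, floor) {
  z <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                        floor, mu + 12 * sigma)$value
  z / stats::pnorm(floor, mu, sigma, lower.tail = FALSE)
}

# E[max(0, X)] for X ~ N(mu, sigma) by quadrature
relu_normal_mean_quadrature <- function(mu, sigma) {
  stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                   0, mu + 12 * sigma)$value
}
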