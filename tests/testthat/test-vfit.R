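test_that("the dual-sigmoid function obeys its limits and identities", {
  vp <- vfit_params(B = 0.05, A_R = 0.98, C_L = 95, C_R = 140,
                    D_L = 4, D_R = 6)
  # far tails approach the two asymptotes (chance on the left)
  expect_equal(evaluate_v(vp, -1e4), 0.5, tolerance = 1e-10)
  expect_equal(evaluate_v(vp, 1e4), 0.98, tolerance = 1e-10)
  # at the right midpoint the rising sigmoid is exactly halfway
  sR <- vp$B + (vp$A_R - vp$B) / 2
  expect_equal(evaluate_v(vp, vp$C_R), sR, tolerance = 1e-6)
  # a negative floor never drags the curve below zero
  vneg <- vfit_params(B = -0.2, A_R = 0.9, C_L = 50, C_R = 250,
                      D_L = 3, D_R = 3)
  mid <- evaluate_v(vneg, seq(100, 200, 5))
  expect_true(all(mid >= 0))
  expect_true(any(mid == 0))
  expect_error(vfit_params(0.1, 0.9, 50, 100, -1, 5), "positive")
})

test_that("fitting a noiseless curve recovers its own generator", {
  truth <- vfit_params(B = 0.05, A_R = 0.97, C_L = 100, C_R = 145,
                       D_L = 4, D_R = 8)
  grid <- seq(-60, 420, by = 1)
  curve <- data.frame(rpt_center = grid, p_correct = evaluate_v(truth, grid))
  fit <- fit_tachometric(curve)
  expect_lt(fit$mae, 1e-4)
  expect_identical(fit$params$A_L, 0.5)   # pinned at chance, exactly
  fe <- extract_features(fit)
  te <- extract_features(truth)
  expect_equal(fe[["vortex_time"]], te[["vortex_time"]], tolerance = 2)
  expect_equal(fe[["vortex_depth"]], te[["vortex_depth"]], tolerance = 1e-3)
  expect_equal(fe[["mean_perceptual_accuracy"]],
               te[["mean_perceptual_accuracy"]], tolerance = 1e-3)

  # refitting the fit's own curve changes nothing material (idempotence)
  curve2 <- data.frame(rpt_center = grid,
                       p_correct = evaluate_v(fit$params, grid))
  fit2 <- fit_tachometric(curve2)
  expect_equal(unlist(extract_features(fit2)), unlist(fe), tolerance = 1e-3)
})

test_that("the simplex optimum survives a coarse grid-search cross-check on noisy data", {
  truth <- vfit_params(B = 0.08, A_R = 0.95, C_L = 105, C_R = 150,
                       D_L = 5, D_R = 9)
  grid <- seq(-40, 380, by = 2)
  n_per <- 200
  set.seed(31)
  p_obs <- rbinom(length(grid), n_per, evaluate_v(truth, grid)) / n_per
  curve <- data.frame(rpt_center = grid, p_correct = p_obs)
  fit <- fit_tachometric(curve)
  # error no worse than twice the average binomial noise of a bin
  mean_sd <- mean(sqrt(evaluate_v(truth, grid) *
                         (1 - evaluate_v(truth, grid)) / n_per))
  expect_lt(fit$mae, 2 * mean_sd)

  # independent coarse grid search over the six free coefficients
  g <- expand.grid(B = c(0, 0.08, 0.2), A_R = c(0.9, 0.95, 1),
                   C_L = c(95, 105, 115), C_R = c(140, 150, 160),
                   D_L = c(3, 5, 9), D_R = c(5, 9, 14))
  grid_best <- min(apply(g, 1, function(row) {
    v <- vfit_params(row[1], row[2], row[3], row[4], row[5], row[6])
    mean(abs(p_obs - evaluate_v(v, grid)))
  }))
  expect_lte(fit$mae, grid_best + 1e-9)
})

test_that("curve features match a dense brute-force evaluation", {
  vp <- vfit_params(B = 0.05, A_R = 0.98, C_L = 95, C_R = 140,
                    D_L = 4, D_R = 6)
  fe <- extract_features(vp)
  # oracle: direct evaluation at 0.01-ms resolution
  xs <- seq(-100, 500, by = 0.01)
  sL <- vp$B + (vp$A_L - vp$B) / (1 + exp((xs - vp$C_L) / vp$D_L))
  sR <- vp$B + (vp$A_R - vp$B) / (1 + exp(-(xs - vp$C_R) / vp$D_R))
  v <- pmax(sL, sR, 0)
  i <- which.min(v)
  # the package evaluates on a 1-ms grid, so allow the corresponding
  # discretization error around the V-shaped minimum
  expect_equal(fe[["vortex_depth"]], v[i], tolerance = 0.02)
  expect_equal(fe[["vortex_time"]], xs[i], tolerance = 1)
  sl <- diff(v) / 0.01
  expect_equal(fe[["slope_min"]], min(sl), tolerance = 0.02)
  expect_equal(fe[["slope_max"]], max(sl), tolerance = 0.02)
  m_l <- (0.5 + v[i]) / 2
  expect_equal(fe[["left_edge"]], max(xs[seq_len(i)][v[seq_len(i)] >= m_l]),
               tolerance = 1)
  m_r <- (v[i] + vp$A_R) / 2
  right <- seq(i, length(xs))
  expect_equal(fe[["centerpoint"]], xs[right][which(v[right] >= m_r)[1]],
               tolerance = 1)
  expect_equal(fe[["mean_perceptual_accuracy"]],
               mean(v[xs >= 0 & xs <= 250]), tolerance = 1e-3)
})

test_that("feature geometry is internally consistent across random curves", {
  set.seed(32)
  for (k in 1:25) {
    vp <- vfit_params(B = runif(1, 0, 0.4), A_R = runif(1, 0.6, 1),
                      C_L = runif(1, 60, 130), C_R = runif(1, 140, 220),
                      D_L = runif(1, 2, 25), D_R = runif(1, 2, 25))
    fe <- extract_features(vp)
    expect_lte(fe[["left_edge"]], fe[["vortex_time"]])
    expect_lte(fe[["vortex_time"]], fe[["centerpoint"]])
    expect_gte(fe[["vortex_depth"]], 0)
    expect_lte(fe[["vortex_depth"]], fe[["asymptote"]] + 1e-12)
    expect_gte(fe[["mean_perceptual_accuracy"]], 0)
    expect_lte(fe[["mean_perceptual_accuracy"]], 1)
    v <- evaluate_v(vp, seq(-200, 600, 1))
    expect_true(all(v >= 0 & v <= max(0.5, vp$A_R) + 1e-12))
  }
})

test_that("count-weighted fitting agrees with unweighted fitting on clean data", {
  truth <- vfit_params(B = 0.06, A_R = 0.97, C_L = 100, C_R = 150,
                       D_L = 4, D_R = 8)
  set.seed(33)
  rpt <- sample(-30:330, 20000, replace = TRUE)
  tr <- data.frame(rpt_ms = rpt, correct = runif(20000) < evaluate_v(truth, rpt))
  cv <- compute_tachometric(tr)
  f_u <- extract_features(fit_tachometric(cv))
  f_w <- extract_features(fit_tachometric(cv, weight_bins = TRUE))
  vt <- extract_features(truth)[["vortex_time"]]
  expect_equal(f_u[["vortex_time"]], vt, tolerance = 5 / vt)
  expect_equal(f_w[["vortex_time"]], vt, tolerance = 5 / vt)
  expect_error(fit_tachometric(data.frame(rpt_center = 1:30,
                                          p_correct = runif(30)),
                               weight_bins = TRUE), "counts")
})

test_that("a flat curve yields degenerate but well-defined features", {
  vp <- vfit_params(B = 0.5, A_R = 0.5, C_L = 100, C_R = 150,
                    D_L = 5, D_R = 5)
  fe <- extract_features(vp)
  expect_equal(fe[["mean_perceptual_accuracy"]], 0.5)
  expect_equal(fe[["vortex_depth"]], 0.5)
  expect_equal(fe[["slope_max"]], 0, tolerance = 1e-12)
  expect_error(extract_features(vp, rpt_range = c(0, 100)), "250")
})
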