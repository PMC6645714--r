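test_that("a fast anti plan triggers a correct guess before cue onset", {
  # all-deterministic trial: anti plan at 10 AU/ms from t = 50 crosses 1000
  # at t = 150, saccade at 170, before the cue (gap 350) is even shown
  p <- det_params()
  r <- race_trial_given(p, gap = 350, b_c0 = 1, b_a0 = 10,
                        go_delay = 50, cue_delay = 76, eri = 24)
  expect_equal(r$rt, 170)
  expect_equal(r$winner, "anti")
  expect_equal(r$rpt, -180)
})

test_that("exogenous momentum captures a sub-threshold cue plan in the vortex range", {
  # deterministic high-luminance-like trial: sub-threshold at detection
  # (t = 226), 10-ms halt, 14-ms acceleration, post-ERI momentum crosses
  # threshold; compare against the independent reference integrator
  p <- det_params(mu_go_aff = 50)
  r <- race_trial_given(p, gap = 150, b_c0 = 4, b_a0 = 4,
                        go_delay = 50, cue_delay = 76, eri = 24)
  o <- oracle_trial(p, gap = 150, b_c0 = 4, b_a0 = 4,
                    go_delay = 50, cue_delay = 76, eri = 24)
  expect_equal(r$rt, o$rt)
  expect_equal(r$winner, "cue")       # captured, incorrect
  expect_gte(r$rpt, 125)
  expect_lte(r$rpt, 140)
})

test_that("a symmetric lapse race ends in a tie broken at random", {
  # identical plans, no ERI, lapse: both reach threshold at go + 500 steps
  p <- det_params(mu_b = 2, mu_eri = 0, delta_eri = 0, a_ex = 0, lambda = 1)
  rts <- winners <- character(0)
  for (u in c(0.1, 0.9)) {
    r <- race_trial_given(p, gap = 0, b_c0 = 2, b_a0 = 2, go_delay = 50,
                          cue_delay = 76, eri = 0, lapse = TRUE, tie_u = u)
    expect_equal(r$rt, 50 + 500 + 20)
    winners <- c(winners, r$winner)
  }
  expect_setequal(winners, c("cue", "anti"))
})

test_that("the discrete core matches the reference integrator on deterministic configs", {
  set.seed(21)
  for (k in 1:40) {
    p <- det_params(g_eri = -round(runif(1), 2),
                    delta_eri = sample(0:20, 1),
                    a_ex = round(runif(1, 0, 2), 2),
                    d_end = -round(runif(1, 0, 1.5), 2),
                    a_end = round(runif(1, 0.02, 0.5), 2))
    variant <- sample(c("full", "accel_only", "halt_only"), 1)
    gap <- sample(c(0, 75, 150, 250, 350), 1)
    b_c0 <- round(runif(1, -2, 9), 2)
    b_a0 <- round(runif(1, -2, 9), 2)
    go <- sample(20:120, 1)
    cue <- sample(20:140, 1)
    eri <- sample(0:40, 1)
    lapse <- runif(1) < 0.5
    r <- race_trial_given(p, gap, b_c0, b_a0, go, cue, eri, lapse,
                          variant = variant)
    o <- oracle_trial(p, gap, b_c0, b_a0, go, cue, eri, lapse,
                      variant = variant)
    if (is.na(o$rt)) {
      expect_true(r$no_response)
    } else {
      expect_equal(r$rt, o$rt, tolerance = 1e-9,
                   label = sprintf("config %d rt", k))
      if (o$winner != "tie") expect_equal(r$winner, o$winner)
    }
  }
})

test_that("simulated trials satisfy the timing identities and chance floor", {
  tr <- simulate_dataset(pooled_params()["high"], urgent_gaps, 20000, seed = 22)
  ok <- !is.na(tr$correct)
  expect_equal(tr$rpt_ms, tr$rt_ms - tr$gap_ms)
  consts <- sim_constants()
  expect_true(all(tr$rt_ms[ok] >=
    consts$afferent_floor + consts$dt + consts$efferent_delay))
  expect_true(all(tr$correct[ok] ==
    (tr$choice_side[ok] != tr$cue_side[ok])))
  # before the cue can be detected, choices are coin flips
  early <- ok & tr$rpt_ms <= 50
  p_hat <- mean(tr$correct[early])
  se <- sqrt(0.25 / sum(early))
  expect_lt(abs(p_hat - 0.5), 3 * se)
  # guesses precede cue detection by construction
  g <- tr$outcome_class == "guess" & ok
  expect_true(all(tr$rt_ms[g] - consts$efferent_delay <=
                    tr$gap_ms[g] + tr$sim_cue_delay[g]))
})

test_that("dataset generation is seed-reproducible and validates its inputs", {
  a <- simulate_dataset(pooled_params(), urgent_gaps, 500, seed = 23)
  b <- simulate_dataset(pooled_params(), urgent_gaps, 500, seed = 23)
  expect_identical(a, b)
  expect_equal(nrow(simulate_dataset(pooled_params()["high"], 0, 1, seed = 1)), 1L)
  expect_error(simulate_dataset(pooled_params(), urgent_gaps, 0), "positive")
  expect_error(simulate_dataset(pooled_params(), numeric(0), 10), "non-empty")
  expect_error(simulate_trials(pooled_params("high"), -100), "delay trials")
  expect_error(simulate_dataset(unname(pooled_params()), urgent_gaps, 10),
               "named")
})

test_that("gap and luminance assignment is uniform within binomial bounds", {
  tr <- simulate_dataset(pooled_params(), urgent_gaps, 45000, seed = 24)
  counts <- table(tr$gap_ms)
  expect_equal(length(counts), 9L)
  exp_n <- 45000 / 9
  tol <- 3 * sqrt(45000 * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - exp_n) < tol))
  lc <- table(tr$luminance)
  expect_true(all(abs(lc - 15000) < 3 * sqrt(45000 * (1 / 3) * (2 / 3))))
})

test_that("guess-dominated early responses sit at chance with Table-scale parameters", {
  tr <- simulate_trials(pooled_params("high"), rep(350, 30000))
  pre <- !is.na(tr$correct) & tr$rpt_ms <= 0
  expect_gt(sum(pre), 1000)
  expect_lt(abs(mean(tr$correct[pre]) - 0.5), 3 * sqrt(0.25 / sum(pre)))
})

test_that("increasing exogenous acceleration deepens the vortex monotonically", {
  depth <- sapply(c(0.3, 0.96, 2.0), function(aex) {
    tr <- simulate_dataset(
      list(x = mod_params(pooled_params("high"), a_ex = aex)),
      urgent_gaps, 60000, seed = 25)
    cv <- as.data.frame(compute_tachometric(tr))
    core <- cv[cv$n_correct + cv$n_incorrect >= 500, ]
    min(core$p_correct)
  })
  expect_true(all(diff(depth) <= 0.01))   # non-increasing up to binomial noise
  # and the asymptote falls with the lapse rate
  asym <- sapply(c(0, 0.1, 0.3), function(lam) {
    tr <- simulate_dataset(
      list(x = mod_params(pooled_params("high"), lambda = lam)),
      urgent_gaps, 30000, seed = 26)
    mean(tr$correct[tr$rpt_ms >= 220 & !is.na(tr$correct)])
  })
  expect_true(all(diff(asym) < 0))
})
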