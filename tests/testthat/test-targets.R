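test_that("target histograms equal exhaustive counting and conserve mass", {
  # 20-trial hand dataset over two gaps
  tr <- data.frame(
    gap_ms = rep(c(0, 150), each = 10),
    correct = rep(c(TRUE, FALSE), 10),
    rt_ms = c(55, 110, 115, 230, 230, 231, 305, 410, 55, 599,
              60, 60, 61, 155, 155, 290, 305, 410, 555, 599),
    rpt_ms = NA)
  tr$rpt_ms <- tr$rt_ms - tr$gap_ms
  tg <- build_targets(tr)
  t1 <- tg$luminances$all
  expect_equal(t1$n, 20)
  breaks <- tg$rt_breaks
  for (j in 1:2) {
    g <- c(0, 150)[j]
    for (corr in c(TRUE, FALSE)) {
      h <- if (corr) t1$hist_correct[, j] else t1$hist_incorrect[, j]
      for (b in seq_len(length(breaks) - 1L)) {
        inbin <- tr$gap_ms == g & tr$correct == corr &
          tr$rt_ms >= breaks[b] &
          (tr$rt_ms < breaks[b + 1] | (b == length(breaks) - 1L &
                                         tr$rt_ms <= breaks[b + 1]))
        expect_equal(h[b], sum(inbin) / 20)
      }
    }
  }
  # masses per cell sum to the cell's trial fraction
  for (j in 1:2) {
    g <- c(0, 150)[j]
    cell <- sum(t1$hist_correct[, j]) + sum(t1$hist_incorrect[, j])
    expect_equal(cell, mean(tr$gap_ms == g))
  }
})

test_that("a single-gap table still yields one histogram pair plus the curve", {
  tr <- data.frame(gap_ms = 0, correct = c(TRUE, FALSE, TRUE),
                   rt_ms = c(100, 150, 220), rpt_ms = c(100, 150, 220))
  expect_warning(tg <- build_targets(tr), "fewer than two")
  expect_equal(ncol(tg$luminances$all$hist_correct), 1L)
  expect_s3_class(tg, "target_set")
})

test_that("the objective separates truth from perturbed parameters", {
  truth <- list(high = pooled_params("high"))
  tr <- simulate_dataset(truth, c(0, 100, 200, 350), 20000, seed = 61)
  tr$luminance <- "high"
  targets <- build_targets(tr)

  v_self <- as.numeric(race_objective(truth, targets, n_sim = 20000, seed = 62))
  expect_gte(v_self, 0)
  expect_lt(v_self, 0.1)     # at the Monte-Carlo noise floor

  shifted <- list(high = mod_params(truth$high, mu_cue_aff = 106))
  for (s in c(63, 64, 65)) {
    v_s <- as.numeric(race_objective(truth, targets, n_sim = 8000, seed = s))
    v_p <- as.numeric(race_objective(shifted, targets, n_sim = 8000, seed = s))
    expect_gt(v_p, v_s)
  }

  # invariant to the order of trials behind the targets
  targets2 <- build_targets(tr[sample(nrow(tr)), ])
  v2 <- as.numeric(race_objective(truth, targets2, n_sim = 5000, seed = 66))
  v1 <- as.numeric(race_objective(truth, targets, n_sim = 5000, seed = 66))
  expect_equal(v1, v2)

  # the caller's RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(race_objective(truth, targets, n_sim = 2000, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("degenerate search boxes return the pinned parameters", {
  truth <- list(high = pooled_params("high"))
  tr <- simulate_dataset(truth, c(0, 150, 350), 8000, seed = 67)
  tr$luminance <- "high"
  targets <- build_targets(tr)
  th <- unlist(truth$high)
  bounds <- list(lower = th, upper = th)
  fit <- fit_race_model(targets, bounds, n_starts = 1, n_rounds = 2,
                        n_candidates = 3, n_sim = 2000, seed = 68)
  expect_equal(unlist(fit$params_by_luminance$high), th)
  expect_equal(fit$params_by_luminance$high$g_eri, 0)   # pinned exactly
  # best error is non-increasing along the trace within the start
  expect_true(all(diff(fit$trace$best_error) <= 1e-12))
  v <- as.numeric(race_objective(truth, targets, n_sim = 2000,
                                 seed = 68 + 1000 + 2))
  expect_equal(fit$objective, v)
})
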