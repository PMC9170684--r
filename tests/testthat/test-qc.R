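test_that("derandomize inverts arbitrary presentation orders", {
  fps <- 8
  g <- build_condition_grid(3)[1:6, ]
  g$condition_id <- 1:6
  # planted per-condition plateau amplitudes
  amps_true <- c(0.5, 1, 0, 2, 0.25, 1.5)
  for (seed in c(2, 5, 9)) {
    sched <- presentation_schedule(g, n_trials = 4, seed = seed)
    n_t <- 4 * fps + 6 * 8 * fps
    traces <- matrix(0, 4, n_t)
    for (tr in 1:4) {
      s <- sched[sched$trial == tr, ]
      for (k in 1:6) {
        onset <- 4 * fps + (s$epoch_index[k] - 1) * 8 * fps
        traces[tr, (onset + 1):(onset + 4 * fps)] <- amps_true[s$condition_id[k]]
      }
    }
    em <- derandomize(traces, sched, g, fps)
    expect_equal(em$amplitudes, matrix(amps_true, 6, 4), tolerance = 1e-12)
  }
  expect_error(derandomize(matrix(0, 4, 10), sched, g, fps), "mismatch")
})

test_that("baseline drift is removed without distorting clean transients", {
  fps <- 8
  n <- 240 * fps
  # non-negative transients on a zero baseline
  clean <- rep(0, n)
  clean[seq(100, n, by = 300)] <- 1
  clean <- convolve_kernel(clean, calcium_kernel(fps = fps))
  expect_lt(max(abs(preprocess_trace(clean, fps) - clean)), 1e-6)
  # injected linear ramp is removed (residual slope < 5% of injected)
  ramp <- 0.2 * seq_len(n) / n
  corrected <- preprocess_trace(clean + ramp, fps)
  res_slope <- stats::coef(stats::lm(corrected ~ seq_len(n)))[2] * n
  expect_lt(abs(res_slope), 0.05 * 0.2)
  # constant trace maps to zeros
  expect_equal(preprocess_trace(rep(3, n), fps), rep(0, n))
  expect_error(preprocess_trace(rep(NA_real_, 10), fps), "NaN")
})

test_that("responsiveness requires >3 SD for more than 1 s during the stimulus", {
  fps <- 8
  n_win <- 12 * fps  # 4 s pre + 4 s stim + 4 s post
  base <- with_seed(42, array(stats::rnorm(2 * 4 * n_win, 0, 0.05),
                              dim = c(2, 4, n_win)))
  em_flat <- fake_epoch_matrix(base, fps, pre_s = 4, stim_s = 4, post_s = 4)
  r <- is_responsive(em_flat)
  expect_false(r$responsive); expect_false(r$offset_only)
  # 5-SD plateau lasting 1.5 s during the stimulus -> responsive
  em_on <- em_flat
  em_on$epochs[1, , (4 * fps + 8):(4 * fps + 8 + 1.5 * fps)] <-
    em_on$epochs[1, , (4 * fps + 8):(4 * fps + 8 + 1.5 * fps)] + 0.25
  r <- is_responsive(em_on)
  expect_true(r$responsive); expect_false(r$offset_only)
  # plateau of only 0.5 s fails the duration rule
  em_short <- em_flat
  em_short$epochs[1, , (4 * fps + 8):(4 * fps + 8 + 0.5 * fps)] <-
    em_short$epochs[1, , (4 * fps + 8):(4 * fps + 8 + 0.5 * fps)] + 0.25
  r <- is_responsive(em_short)
  expect_false(r$responsive)
  # plateau only after offset -> offset_only
  em_off <- em_flat
  em_off$epochs[1, , (8 * fps + 2):(8 * fps + 2 + 1.5 * fps)] <-
    em_off$epochs[1, , (8 * fps + 2):(8 * fps + 2 + 1.5 * fps)] + 0.25
  r <- is_responsive(em_off)
  expect_false(r$responsive); expect_true(r$offset_only)
  # degenerate zero-variance baseline is signaled
  em_zero <- fake_epoch_matrix(array(0, dim = c(1, 4, n_win)), fps,
                               pre_s = 4, stim_s = 4, post_s = 4)
  expect_warning(r <- is_responsive(em_zero), "degenerate")
  expect_true(is.na(r$responsive))
})

test_that("reliability is the 75th percentile of pairwise trial correlations", {
  # brute-force percentile convention
  expect_equal(stats::quantile(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 0.75,
                               names = FALSE), 0.475)
  fps <- 8
  n_win <- 8 * fps
  # four identical structured trials -> r = 1
  sig <- sin(seq_len(n_win))
  ep <- aperm(array(rep(sig, each = 3 * 4), dim = c(3, 4, n_win)), c(1, 2, 3))
  for (c in 1:3) for (tr in 1:4) ep[c, tr, ] <- sig * c
  em <- fake_epoch_matrix(ep, fps, pre_s = 0, stim_s = 4, post_s = 4)
  expect_equal(reliability_index(em), 1)
  # four independent long white-noise trials -> |r| small
  ep2 <- with_seed(11, array(stats::rnorm(1 * 4 * 10000), dim = c(1, 4, 10000)))
  em2 <- fake_epoch_matrix(ep2, fps = 1250, pre_s = 0, stim_s = 4, post_s = 4)
  expect_lt(abs(reliability_index(em2)), 0.05)
  # zero-variance trial contributes correlation 0
  ep3 <- ep
  ep3[, 4, ] <- 0
  em3 <- fake_epoch_matrix(ep3, fps, pre_s = 0, stim_s = 4, post_s = 4)
  cors <- c(1, 1, 1, 0, 0, 0)  # 3 intact pairs, 3 pairs with the silent trial
  expect_equal(reliability_index(em3),
               stats::quantile(cors, 0.75, names = FALSE))
})

test_that("stimulus-locked neurons exceed the shuffled reliability null", {
  fx <- small_sim()
  ds <- fx$sim$datasets[["1"]]
  qc <- qc_dataset(fx$sim, "1")
  locked <- order(-qc$r)[1]
  em <- derandomize(ds$traces[locked, , ], ds$schedule, ds$grid, fx$sim$fps)
  nl <- reliability_null(em, n_shuffles = 200, seed = 5)
  expect_gt(reliability_index(em), nl$q99_75)
  # a stimulus-independent neuron sits inside the null band
  flat <- with_seed(77, matrix(stats::rnorm(4 * ncol(ds$traces[1, , ]), 0, 0.05),
                               nrow = 4))
  em_flat <- derandomize(flat, ds$schedule, ds$grid, fx$sim$fps)
  nl_flat <- reliability_null(em_flat, n_shuffles = 200, seed = 6)
  expect_lt(reliability_index(em_flat), nl_flat$q97_5)
  # thresholds are seed-reproducible
  nl2 <- reliability_null(em_flat, n_shuffles = 200, seed = 6)
  expect_identical(nl_flat$q99_75, nl2$q99_75)
})

test_that("QC selection is monotone in the threshold and subsets correctly", {
  fx <- small_sim()
  qc <- qc_dataset(fx$sim, "1")
  expect_equal(nrow(qc_filter(qc, 1.01)$qc[qc_filter(qc, 1.01)$qc$selected, ]), 0)
  all_resp <- qc_filter(qc, -1.01)
  expect_equal(all_resp$qc$selected,
               qc$responsive %in% TRUE & !(qc$offset_only %in% TRUE))
  sizes <- vapply(c(0.2, 0.3, 0.4, 0.6), function(th) {
    sum(qc_filter(qc, th)$qc$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  summ <- qc_filter(qc, 0.3)$summary
  expect_true(all(summ$n_selected <= summ$n_responsive))
  expect_true(all(summ$n_responsive <= summ$n_all))
})

test_that("near-noiseless ground truth passes QC iff generatively responsive", {
  fx <- small_sim()
  pop0 <- fx$pop
  pop0$noise_sd <- 0.002; pop0$gain_cv <- 0
  sim0 <- simulate_trial_traces(pop0, fx$grids["1"], fx$schedules["1"],
                                fps = 8, seed = 55)
  qc <- qc_filter(qc_dataset(sim0, "1"))$qc
  drive <- vapply(seq_len(nrow(pop0)), function(i) {
    max(expected_response_grid(pop0[i, ], fx$grids[["1"]]))
  }, numeric(1))
  should <- pop0$responsive & drive > 0.05
  expect_true(all(qc$selected[should]))
  expect_true(all(!qc$selected[!pop0$responsive]))
})

test_that("per-condition reliability mode pools condition-wise correlations", {
  fps <- 8
  n_win <- 8 * fps
  sig <- sin(seq_len(n_win) / 3)
  ep <- array(0, dim = c(3, 4, n_win))
  for (c in 1:3) for (tr in 1:4) ep[c, tr, ] <- sig * c
  em <- fake_epoch_matrix(ep, fps, pre_s = 0, stim_s = 4, post_s = 4)
  expect_equal(reliability_index(em, per_condition = TRUE), 1)
  expect_equal(reliability_index(em, per_condition = FALSE), 1)
  # most conditions unreliable (1 of 6 reliable, below the 75th-percentile
  # mass): the pooled per-condition percentile drops, while the
  # concatenated mode stays dominated by the one strong condition
  ep2 <- with_seed(5, array(stats::rnorm(6 * 4 * n_win, 0, 0.01),
                            dim = c(6, 4, n_win)))
  for (tr in 1:4) ep2[1, tr, ] <- sig
  em2 <- fake_epoch_matrix(ep2, fps, pre_s = 0, stim_s = 4, post_s = 4)
  expect_lt(reliability_index(em2, per_condition = TRUE), 0.5)
  expect_gt(reliability_index(em2, per_condition = FALSE), 0.9)
})
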