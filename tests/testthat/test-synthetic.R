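test_that("population sampling is reproducible and respects the mixture", {
  cfg <- default_population_config(n_mice = 2, areas = c("V1", "AL"),
                                   neurons_per_area_mouse = 2500)
  cfg$area_params$V1$mixture <- c(non_os = 0.3, sharp_os = 0.5, broad_os = 0.2)
  pop <- sample_population(cfg, seed = 7)
  expect_identical(pop, sample_population(cfg, seed = 7))
  fr <- table(pop$cell_type[pop$area == "V1"]) / sum(pop$area == "V1")
  expect_equal(as.numeric(fr[c("non_os", "sharp_os", "broad_os")]),
               c(0.3, 0.5, 0.2), tolerance = 0.02)
  # invariants on generated parameters
  expect_true(all(pop$A >= 0))
  expect_true(all(pop$sigma_sf > 0 & pop$sigma_tf > 0))
  expect_true(all(pop$ori_fwhm >= 10 & pop$ori_fwhm <= 170))
  expect_true(all(pop[, c("gain_inf", "gain_60", "gain_30", "gain_15")] >= 0))
})

test_that("identically configured areas are exchangeable", {
  cfg <- default_population_config(n_mice = 2, areas = c("V1", "AL"),
                                   neurons_per_area_mouse = 100)
  cfg$area_params$AL <- cfg$area_params$V1
  pop <- sample_population(cfg, seed = 21)
  ks <- stats::ks.test(log2(pop$sf0[pop$area == "V1"]),
                       log2(pop$sf0[pop$area == "AL"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid population configurations are rejected", {
  cfg <- default_population_config(n_mice = 1, areas = "V1",
                                   neurons_per_area_mouse = 5)
  bad <- cfg; bad$area_params$V1$mixture <- c(non_os = 0.5, sharp_os = 0.4,
                                              broad_os = 0.2)
  expect_error(sample_population(bad, 1), "sum to 1")
  bad2 <- cfg; bad2$area_params$V1$l2sf0_sd <- -1
  expect_error(sample_population(bad2, 1), "negative SD")
})

test_that("expected responses follow the generative tuning model", {
  nr <- data.frame(A = 2, sf0 = 0.08, tf0 = 2, sigma_sf = 1, sigma_tf = 1,
                   xi = 0, gain_inf = 1, gain_60 = 0.6, gain_30 = 0.3,
                   gain_15 = 0.1, theta_pref = 0, ori_fwhm = 30,
                   responsive = TRUE)
  at <- function(sf, tf, bw = Inf) {
    cond <- data.frame(sf_center = sf, tf_center = tf, ori_bandwidth = bw)
    expected_response(nr, cond)
  }
  expect_equal(at(0.08, 2), 2)                      # peak
  expect_equal(at(0.16, 2), 2 * exp(-0.5))          # one octave off, sigma 1
  expect_equal(at(0.08, 2, bw = 15), 2 * 0.1)       # elongation gain
  # sharp-OS with zero isotropic gain is silent for every dataset-1 condition
  nr$gain_inf <- 0
  g1 <- build_condition_grid(1)
  expect_true(all(expected_response_grid(nr, g1) == 0))
  # non-responsive neurons are silent
  nr$gain_inf <- 1; nr$responsive <- FALSE
  expect_equal(at(0.08, 2), 0)
})

test_that("noiseless epoch means equal expected responses after kernel correction", {
  fx <- small_sim()
  pop0 <- fx$pop
  pop0$noise_sd <- 0; pop0$gain_cv <- 0
  grids <- fx$grids["1"]
  sim0 <- simulate_trial_traces(pop0, grids, fx$schedules["1"], fps = 8,
                                seed = 103)
  amps <- epoch_amplitudes(sim0, "1")
  factor <- kernel_epoch_mean_factor(sim0$kernel, stim_s = 4)
  for (i in which(pop0$responsive)[1:5]) {
    expected <- expected_response_grid(pop0[i, ], grids[["1"]]) * factor
    expect_equal(rowMeans(amps[i, , ]), expected, tolerance = 1e-10)
  }
  # non-responsive neurons give flat traces
  j <- which(!pop0$responsive)[1]
  expect_true(all(sim0$datasets[["1"]]$traces[j, , ] == 0))
})

test_that("trace simulation is seed-reproducible and nested by mouse", {
  fx <- small_sim()
  sim2 <- simulate_trial_traces(fx$pop, fx$grids["1"], fx$schedules["1"],
                                fps = 8, seed = 103)
  expect_identical(sim2$datasets[["1"]]$traces, fx$sim$datasets[["1"]]$traces)
  # between-mouse variance: mouse offsets shift log2(sf0) coherently
  cfg <- default_population_config(n_mice = 8, areas = "V1",
                                   neurons_per_area_mouse = 60)
  cfg$mouse_sd_oct <- 1.5
  pop <- sample_population(cfg, seed = 31)
  f_real <- summary(stats::aov(log2(sf0) ~ mouse_id, pop))[[1]]$`F value`[1]
  pop_sh <- pop
  pop_sh$mouse_id <- with_seed(32, sample(pop$mouse_id))
  f_sh <- summary(stats::aov(log2(sf0) ~ mouse_id, pop_sh))[[1]]$`F value`[1]
  expect_gt(f_real, 5)
  expect_lt(f_sh, 3)
})

test_that("orientation-tuned responses peak when the sweep crosses the preferred angle", {
  pop1 <- data.frame(
    neuron_id = 1, mouse_id = "m1", area = "V1", pos_x_um = 0, pos_y_um = 0,
    A = 1, sf0 = 0.08, tf0 = 2, sigma_sf = 1, sigma_tf = 1, xi = 0,
    theta_pref = 90, ori_fwhm = 30, cell_type = "sharp_os",
    gain_inf = 0, gain_60 = 0.3, gain_30 = 0.6, gain_15 = 1,
    noise_sd = 0, gain_cv = 0, responsive = TRUE
  )
  g2 <- list(`2` = build_condition_grid(2))
  sch <- list(`2` = presentation_schedule(g2[["2"]], seed = 9))
  sim <- simulate_trial_traces(pop1, g2, sch, fps = 8, seed = 11)
  # locate the peak condition epoch in trial 1 and find its peak time
  em <- derandomize(sim$datasets[["2"]]$traces[1, , ], sch[["2"]], g2[["2"]], 8)
  peak_cond <- which.max(rowMeans(em$amplitudes))
  tc <- colMeans(em$epochs[peak_cond, , ])
  stim <- (em$pre_s * 8 + 1):((em$pre_s + em$stim_s) * 8)
  t_peak <- (which.max(tc[stim]) - 0.5) / 8
  lag <- sim$kernel$peak_lag_s
  expect_lt(abs(t_peak - (90 / 45 + lag)), 0.6)
})

test_that("Poisson spike/calcium pairs match their generative statistics", {
  # zero rate: no spikes, flat calcium
  s0 <- simulate_osi_pair(30, 0, rate_scale = 0, seed = 1)
  expect_equal(sum(s0$spikes), 0)
  expect_true(all(s0$calcium == 0))
  expect_error(simulate_osi_pair(30, 0, rate_scale = -1), "rate_scale")
  expect_error(simulate_osi_pair(5, 0), "fwhm")
  # expected count: rate_scale * integral of the tuning along the sweep
  fwhm <- 60; rs <- 50
  th <- seq(0, 180, length.out = 4001)[-4001]
  expected <- rs * mean(orientation_gain(th, 20, fwhm)) * 4
  counts <- vapply(1:10, function(s) {
    sum(simulate_osi_pair(fwhm, 20, rate_scale = rs, seed = s)$spikes)
  }, numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected))
  # determinism
  s1 <- simulate_osi_pair(60, 45, seed = 5)
  s2 <- simulate_osi_pair(60, 45, seed = 5)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("widefield simulation encodes the ground-truth retinotopy", {
  wf <- simulate_widefield_movie(list(nx = 12, ny = 12, n_cycles = 8,
                                      noise_sd = 0), seed = 3)
  # a noiseless pixel peaks at its preferred cycle time plus kernel lag
  i <- 3; j <- 5
  cyc <- matrix(wf$frames[i, j, ], nrow = round(wf$period_s * wf$fps))
  t_peak <- (which.max(rowMeans(cyc)) - 0.5) / wf$fps
  pref <- wf$gt_phase[i, j] / (2 * pi) * wf$period_s
  d <- min(abs(t_peak - (pref + wf$kernel$peak_lag_s)),
           wf$period_s - abs(t_peak - (pref + wf$kernel$peak_lag_s)))
  expect_lt(d, 0.5)
  # anti-phase pixels anticorrelate
  ph <- wf$gt_phase
  pair <- which(abs(((ph - ph[1, 1]) %% (2 * pi)) - pi) < 0.2 &
                  row(ph) + col(ph) > 2)[1]
  expect_lt(stats::cor(wf$frames[1, 1, ], wf$frames[row(ph)[pair], col(ph)[pair], ]),
            0)
})
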