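# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# A small hierarchical population simulated across all three batteries.
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- default_population_config(n_mice = 2, areas = c("V1", "AL"),
                                     neurons_per_area_mouse = 12)
    pop <- sample_population(cfg, seed = 101)
    grids <- list(`1` = build_condition_grid(1),
                  `2` = build_condition_grid(2),
                  `3` = build_condition_grid(3))
    schedules <- lapply(names(grids), function(d) {
      presentation_schedule(grids[[d]], seed = stage_seed(101, d))
    })
    names(schedules) <- names(grids)
    .fixtures$pop <- pop
    .fixtures$grids <- grids
    .fixtures$schedules <- schedules
    .fixtures$sim <- simulate_trial_traces(pop, grids, schedules,
                                           fps = 8, seed = 103)
  }
  .fixtures
}

# Epoch matrix built directly from per-trial epoch traces
# (conditions x trials x samples), with no pre/post segments.
fake_epoch_matrix <- function(epochs, fps = 8, pre_s = 0, stim_s = NULL,
                              post_s = 0) {
  if (is.null(stim_s)) stim_s <- dim(epochs)[3] / fps - pre_s - post_s
  structure(
    list(amplitudes = apply(epochs, c(1, 2), mean), epochs = epochs,
         pre_s = pre_s, stim_s = stim_s, post_s = post_s, fps = fps),
    class = "epoch_matrix"
  )
}

# One mid-grid isotropic condition (0.08 cpd, 2 Hz).
mid_condition <- function(dataset_id = 1) {
  g <- build_condition_grid(dataset_id)
  g[g$sf_center == 0.08 & g$tf_center == 2, ][1, ]
}

# Ground-truth tuning parameter list for evaluate_model.
true_fit <- function(A = 1, sf0 = 0.08, tf0 = 2, sigma_sf = 1,
                     sigma_tf = 1, xi = 0) {
  list(A = A, sf0 = sf0, tf0 = tf0, sigma_sf = sigma_sf,
       sigma_tf = sigma_tf, xi = xi)
}

# Planted three-archetype elongation curves (non-OS / sharp-OS / broad-OS).
planted_curves <- function(n_per = 60, noise = 0.05, seed = 7) {
  arch <- rbind(non = c(1, 0.6, 0.3, 0.1),
                sharp = c(0.1, 0.3, 0.6, 1),
                broad = c(0.7, 0.7, 0.7, 0.7))
  with_seed(seed, {
    lab <- rep(1:3, each = n_per)
    list(curves = arch[lab, ] + matrix(stats::rnorm(3 * n_per * 4, 0, noise),
                                       ncol = 4),
         labels = lab)
  })
}

# Amplitudes of a ground-truth model on the dataset-1 grid (5 x 6 matrix).
model_grid_amplitudes <- function(fit, grid = build_condition_grid(1)) {
  matrix(evaluate_model(fit, grid$sf_center, grid$tf_center),
         5, 6, byrow = TRUE)
}
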