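#!/usr/bin/env Rscript
# Synthetic ground truth: sample the hierarchical population (mice ->
# areas -> neurons) and simulate dF/F trial traces for all three
# stimulus batteries with GCaMP6s-like dynamics and trial noise.

source("analysis/00_config.R")

st <- load_stage("stimuli")
pop <- sample_population(analysis_config$population,
                         seed = stage_seed(ROOT_SEED, "population"))
sim <- simulate_trial_traces(pop, st$grids, st$schedules,
                             fps = analysis_config$fps,
                             seed = stage_seed(ROOT_SEED, "traces"))

write.csv(pop, file.path(OUT_DIR, "population_ground_truth.csv"),
          row.names = FALSE)
save_stage(sim, "sim")

message(sprintf(
  "Simulated %d neurons (%d mice x %d areas), %d/%d/%d-condition batteries at %d Hz; %.0f%% generatively responsive.",
  nrow(pop), analysis_config$population$n_mice,
  length(analysis_config$population$areas),
  nrow(st$grids[["1"]]), nrow(st$grids[["2"]]), nrow(st$grids[["3"]]),
  analysis_config$fps, 100 * mean(pop$responsive)))
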