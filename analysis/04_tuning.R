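#!/usr/bin/env Rscript
# Tuning analysis: 2-D log-Gaussian fits to ISO and ANISO response
# grids, best-fit selection, half-maximum cutoffs and shapes, peak
# speed and speed-tuned flags, the anisotropy preference index, plus
# elongation curves (dataset 3) and orientation selectivity from the
# rotating-stimulus time courses (dataset 2).

source("analysis/00_config.R")

sim <- load_stage("sim")
qc <- load_stage("qc")
pop <- sim$neurons

amps <- lapply(names(sim$datasets), function(d) epoch_amplitudes(sim, d))
names(amps) <- names(sim$datasets)

sel12 <- which(qc[["1"]]$qc$selected | qc[["2"]]$qc$selected)
tuning <- fit_population(amps[["1"]][sel12, , , drop = FALSE],
                         amps[["2"]][sel12, , , drop = FALSE],
                         neuron_ids = pop$neuron_id[sel12])
tuning$mouse_id <- pop$mouse_id[sel12]
tuning$area <- pop$area[sel12]

# parameter recovery against the generator's ground truth
truth <- pop[sel12, ]
ok <- !is.na(tuning$sf0)
recovery <- data.frame(
  n_fitted = sum(ok),
  median_abs_dlog2_sf0 = median(abs(log2(tuning$sf0[ok] / truth$sf0[ok]))),
  median_abs_dlog2_tf0 = median(abs(log2(tuning$tf0[ok] / truth$tf0[ok]))),
  median_abs_dxi = median(abs(tuning$xi[ok] - truth$xi[ok]))
)
write.csv(recovery, file.path(OUT_DIR, "tuning_recovery.csv"),
          row.names = FALSE)

# elongation curves at the preferred spatial frequency (dataset 3)
sel3 <- which(qc[["3"]]$qc$selected)
curves <- t(vapply(sel3, function(i) {
  m <- matrix(rowMeans(amps[["3"]][i, , , drop = FALSE][1, , ]), 4, 4,
              byrow = TRUE)
  elongation_tuning_curve(m)$curve
}, numeric(4)))
colnames(curves) <- c("e_inf", "e_60", "e_30", "e_15")
elong_tbl <- cbind(data.frame(neuron_id = pop$neuron_id[sel3],
                              mouse_id = pop$mouse_id[sel3],
                              area = pop$area[sel3]), curves)
write.csv(elong_tbl, file.path(OUT_DIR, "elongation_curves.csv"),
          row.names = FALSE)

# OSI from the wrap-around orientation time course at the peak ANISO
# condition, for neurons selected on dataset 2
ds2 <- sim$datasets[["2"]]
sel2 <- which(qc[["2"]]$qc$selected)
osi <- vapply(sel2, function(i) {
  em <- derandomize(ds2$traces[i, , ], ds2$schedule, ds2$grid, sim$fps)
  peak_cond <- which.max(rowMeans(em$amplitudes))
  stim_on <- em$pre_s * sim$fps
  seg <- em$epochs[peak_cond, , (stim_on + 1):(stim_on + 8 * sim$fps)]
  seg <- seg - mean(em$epochs[peak_cond, , 1:stim_on])
  otc <- orientation_time_course(seg, sim$fps)
  if (sum(pmax(otc$r_k, 0)) <= 0) return(NA_real_)
  orientation_selectivity_index(otc$r_k, otc$theta_k)
}, numeric(1))
tuning$osi <- osi[match(tuning$neuron_id, pop$neuron_id[sel2])]

write.csv(tuning, file.path(OUT_DIR, "tuning_table.csv"), row.names = FALSE)
save_stage(list(tuning = tuning, amps = amps, curves = elong_tbl), "tuning")

message(sprintf(
  "Fits: %d neurons, %.0f%% accepted; recovery medians |dlog2 sf0| = %.3f oct, |dlog2 tf0| = %.3f oct, |dxi| = %.3f; %d elongation curves; %d OSI estimates.",
  nrow(tuning), 100 * mean(ok), recovery$median_abs_dlog2_sf0,
  recovery$median_abs_dlog2_tf0, recovery$median_abs_dxi,
  nrow(elong_tbl), sum(!is.na(tuning$osi))))
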