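#!/usr/bin/env Rscript
# Cell selection: responsiveness (>3 SD for >1 s), offset-only
# exclusion, and the cross-trial reliability index (75th percentile of
# pairwise correlations, r > 0.3).

source("analysis/00_config.R")

sim <- load_stage("sim")
qc <- lapply(names(sim$datasets), function(d) {
  qc_filter(qc_dataset(sim, d), analysis_config$r_threshold)
})
names(qc) <- names(sim$datasets)

for (d in names(qc)) {
  write.csv(qc[[d]]$qc, file.path(OUT_DIR, paste0("qc_dataset", d, ".csv")),
            row.names = FALSE)
}
summary_tbl <- do.call(rbind, lapply(names(qc), function(d) {
  cbind(dataset = d, qc[[d]]$summary)
}))
write.csv(summary_tbl, file.path(OUT_DIR, "qc_summary.csv"), row.names = FALSE)
save_stage(qc, "qc")

sel <- vapply(qc, function(q) sum(q$qc$selected), 1L)
message("Selected (reliably responsive) neurons per battery: ",
        paste(sprintf("dataset %s: %d", names(sel), sel), collapse = ", "),
        " of ", nrow(sim$neurons), " total.")
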