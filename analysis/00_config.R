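# Shared configuration for the analysis drivers. Each numbered script is
# a thin narrative layer over the package; intermediate state is cached
# under scratch/ and tables land under results/analysis/.

library(vistuning)

ROOT_SEED <- 1
OUT_DIR <- "results/analysis"
CACHE <- "scratch/analysis"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

analysis_config <- default_pipeline_config(seed = ROOT_SEED)

cache_path <- function(name) file.path(CACHE, paste0(name, ".rds"))
load_stage <- function(name) {
  p <- cache_path(name)
  if (!file.exists(p)) stop("run the earlier driver first: missing ", p)
  readRDS(p)
}
save_stage <- function(x, name) saveRDS(x, cache_path(name))
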