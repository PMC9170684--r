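#' Epoch amplitude array for one dataset
#'
#' Mean dF/F over each 4-s stimulus epoch, de-randomized into canonical
#' condition order, for every neuron and trial.
#'
#' @param sim a `simulated_dataset`.
#' @param dataset dataset name.
#' @return numeric array `(neuron, condition, trial)`.
#' @export
epoch_amplitudes <- function(sim, dataset = "1") {
  ds <- sim$datasets[[dataset]]
  fps <- sim$fps
  n_cond <- nrow(ds$grid)
  n_trial <- max(ds$schedule$trial)
  n_neuron <- dim(ds$traces)[1]
  stim_samp <- 4 * fps
  amps <- array(NA_real_, dim = c(n_neuron, n_cond, n_trial))
  for (tr in seq_len(n_trial)) {
    s <- ds$schedule[ds$schedule$trial == tr, ]
    for (k in seq_len(nrow(s))) {
      onset <- 4 * fps + (s$epoch_index[k] - 1) * 8 * fps
      idx <- (onset + 1):(onset + stim_samp)
      amps[, s$condition_id[k], tr] <- rowMeans(ds$traces[, tr, idx])
    }
  }
  amps
}

#' Fit spatiotemporal tuning for a set of neurons
#'
#' Trial-averages the epoch amplitudes and fits the 2-D log-Gaussian
#' model per neuron, for the isotropic and/or anisotropic batteries,
#' returning the per-neuron tuning table (best fit, cutoffs, shapes,
#' speed and API).
#'
#' @param amps1,amps2 amplitude arrays `(neuron, 30, trial)` for
#'   datasets 1 and 2 (either may be `NULL`).
#' @param neuron_ids neuron identifiers (rows of the arrays).
#' @param sf_values,tf_values the tested frequencies.
#' @return data.frame, one row per neuron, with both fits' parameters,
#'   the selected source, cutoffs/shapes, `peak_speed`, `speed_tuned`,
#'   `api` and `api_category`.
#' @export
fit_population <- function(amps1 = NULL, amps2 = NULL, neuron_ids = NULL,
                           sf_values = c(0.02, 0.04, 0.08, 0.16, 0.32),
                           tf_values = c(0.5, 1, 2, 4, 8, 16)) {
  n <- if (!is.null(amps1)) dim(amps1)[1] else dim(amps2)[1]
  if (is.null(neuron_ids)) neuron_ids <- seq_len(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fit_iso <- if (!is.null(amps1)) {
      fit_spatiotemporal(rowMeans(amps1[i, , , drop = FALSE][1, , ]),
                         sf_values, tf_values, source = "ISO")
    } else NULL
    fit_aniso <- if (!is.null(amps2)) {
      fit_spatiotemporal(rowMeans(amps2[i, , , drop = FALSE][1, , ]),
                         sf_values, tf_values, source = "ANISO")
    } else NULL
    best <- select_best_fit(fit_iso, fit_aniso)
    api <- api_cat <- NA
    if (!is.null(fit_iso) && !is.null(fit_aniso) &&
        isTRUE(fit_iso$accepted) && isTRUE(fit_aniso$accepted) &&
        (fit_iso$A > 0 || fit_aniso$A > 0)) {
      a <- anisotropy_preference_index(fit_aniso$A, fit_iso$A)
      api <- a$api; api_cat <- a$category
    }
    cuts <- if (!is.null(best)) frequency_cutoffs(best) else NULL
    f <- function(ft, nm) if (is.null(ft)) NA else ft[[nm]]
    rows[[i]] <- data.frame(
      neuron_id = neuron_ids[i],
      iso_A = f(fit_iso, "A"), iso_nrmse = f(fit_iso, "nrmse"),
      iso_accepted = isTRUE(if (is.null(fit_iso)) NA else fit_iso$accepted),
      aniso_A = f(fit_aniso, "A"), aniso_nrmse = f(fit_aniso, "nrmse"),
      aniso_accepted = isTRUE(if (is.null(fit_aniso)) NA else fit_aniso$accepted),
      source = if (is.null(best)) NA_character_ else best$source,
      A = f(best, "A"), sf0 = f(best, "sf0"), tf0 = f(best, "tf0"),
      sigma_sf = f(best, "sigma_sf"), sigma_tf = f(best, "sigma_tf"),
      xi = f(best, "xi"), nrmse = f(best, "nrmse"),
      sf_low = f(cuts, "sf_low"), sf_high = f(cuts, "sf_high"),
      tf_low = f(cuts, "tf_low"), tf_high = f(cuts, "tf_high"),
      sf_shape = if (is.null(cuts)) NA_character_ else cuts$sf_shape,
      tf_shape = if (is.null(cuts)) NA_character_ else cuts$tf_shape,
      peak_speed = if (is.null(best)) NA_real_ else peak_speed(best),
      speed_tuned = if (is.null(best)) NA else speed_flag(best),
      iso_xi = f(fit_iso, "xi"),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Default end-to-end pipeline configuration
#'
#' Desk-scale defaults for the full synthetic reproduction: 6 mice x 8
#' areas x 30 neurons per area per mouse, 8 Hz traces, the standard
#' QC threshold (r > 0.3), a reduced hierarchical-bootstrap protocol
#' (N = 50, M = 5, L = 200), one speed/iso-speed pair decoded in two
#' areas at pool sizes 2-16, and clustering on 150 sampled neurons per
#' area. Every stage seed derives deterministically from the root seed.
#'
#' @param seed root seed.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    population = default_population_config(n_mice = 6,
                                           neurons_per_area_mouse = 30),
    fps = 8,
    r_threshold = 0.3,
    hb = hb_config(N = 50, M = 5, L = 200),
    decode = list(areas = c("V1", "AL"), sizes = c(2, 8, 16),
                  n_resamples = 20, n_iter = 50, pool_compare = 16),
    elongation = list(n_sub = 5, n_cells = 100),
    cluster = list(n_per_area = 150, k_range = c(4, 8, 12, 16), n_pcs = 12,
                   n_boot = 200, n_cells = 50, n_mice = 4),
    tsne_perplexity = 60,
    map_smoothing_um = 400,
    retinotopy = list(nx = 16, ny = 16, n_cycles = 10, noise_sd = 0.05)
  ), class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage on a synthetic population: stimulus schedules,
#' trace simulation for the three batteries, QC, spatiotemporal fits
#' (ISO and ANISO) with speed and anisotropy indices, elongation typing,
#' hierarchical-bootstrap KS comparisons of peak SF across areas, speed
#' decoding in two areas, functional clustering with composition
#' statistics and t-SNE, retinotopic phase-map recovery and a smoothed
#' cortical parameter map. Writes CSV tables plus a markdown report to
#' `out_dir`; a rerun with the same config and directory produces
#' byte-identical outputs.
#'
#' @param config a [default_pipeline_config()] list.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  seed <- config$seed
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(out_dir, name), row.names = FALSE)

  say("stimulus schedules")
  grids <- list(`1` = build_condition_grid(1), `2` = build_condition_grid(2),
                `3` = build_condition_grid(3))
  schedules <- lapply(names(grids), function(d) {
    presentation_schedule(grids[[d]], n_trials = 4,
                          seed = stage_seed(seed, paste0("schedule-", d)))
  })
  names(schedules) <- names(grids)

  say("population & traces")
  pop <- sample_population(config$population, seed = stage_seed(seed, "population"))
  sim <- simulate_trial_traces(pop, grids, schedules, fps = config$fps,
                               seed = stage_seed(seed, "traces"))
  wcsv(pop, "population.csv")

  say("QC")
  qc <- lapply(names(grids), function(d) qc_filter(qc_dataset(sim, d),
                                                   config$r_threshold))
  names(qc) <- names(grids)
  for (d in names(qc)) wcsv(qc[[d]]$qc, paste0("qc_dataset", d, ".csv"))
  qc_summary <- do.call(rbind, lapply(names(qc), function(d) {
    cbind(dataset = d, qc[[d]]$summary)
  }))
  wcsv(qc_summary, "qc_summary.csv")

  say("spatiotemporal fits")
  amps1 <- epoch_amplitudes(sim, "1")
  amps2 <- epoch_amplitudes(sim, "2")
  amps3 <- epoch_amplitudes(sim, "3")
  sel12 <- which(qc[["1"]]$qc$selected | qc[["2"]]$qc$selected)
  tuning <- fit_population(amps1[sel12, , , drop = FALSE],
                           amps2[sel12, , , drop = FALSE],
                           neuron_ids = pop$neuron_id[sel12])
  tuning$mouse_id <- pop$mouse_id[sel12]
  tuning$area <- pop$area[sel12]
  wcsv(tuning, "tuning_table.csv")

  say("elongation typing")
  sel3 <- which(qc[["3"]]$qc$selected)
  curves <- t(vapply(sel3, function(i) {
    m <- matrix(rowMeans(amps3[i, , , drop = FALSE][1, , ]), 4, 4, byrow = TRUE)
    elongation_tuning_curve(m)$curve
  }, numeric(4)))
  elong <- hb_elongation_fractions(curves, pop$mouse_id[sel3], pop$area[sel3],
                                   n_sub = config$elongation$n_sub,
                                   n_cells = config$elongation$n_cells,
                                   seed = stage_seed(seed, "elongation"))
  wcsv(elong, "elongation_fractions.csv")

  say("area statistics (hierarchical bootstrap KS)")
  ok <- !is.na(tuning$sf0)
  ksm <- hb_ks_matrix(log2(tuning$sf0[ok]), tuning$mouse_id[ok],
                      tuning$area[ok], config$hb,
                      seed = stage_seed(seed, "ks-sf"))
  wcsv(ksm, "ks_peak_sf.csv")

  say("speed decoding")
  pairs <- build_pairs(grids[["1"]])
  sp <- pairs[pairs$kind == "speed", ][1, ]
  iso <- pairs[pairs$kind == "iso-speed" & pairs$pair_id == sp$pair_id, ]
  dec_rows <- list(); deltas <- list()
  results <- list()
  for (a in config$decode$areas) {
    na_idx <- which(pop$area == a & qc[["1"]]$qc$selected)
    for (pr in list(sp, iso)) {
      res <- pool_curve(
        amps1[na_idx, pr$cond_a, , drop = FALSE][, 1, ],
        amps1[na_idx, pr$cond_b, , drop = FALSE][, 1, ],
        sizes = config$decode$sizes,
        n_resamples = config$decode$n_resamples,
        n_iter = config$decode$n_iter,
        seed = stage_seed(seed, paste0("decode-", a, "-", pr$kind))
      )
      results[[paste(a, pr$kind)]] <- res
      dec_rows[[length(dec_rows) + 1L]] <-
        cbind(area = a, pair_kind = pr$kind, res$summary)
    }
    d <- delta_accuracy(results[[paste(a, "speed")]],
                        results[[paste(a, "iso-speed")]],
                        pool_size = config$decode$pool_compare)
    deltas[[length(deltas) + 1L]] <- data.frame(
      area = a, contrast = "speed_vs_iso", delta = d$delta,
      ci_low = d$ci_low, ci_high = d$ci_high, p_value = d$p_value)
  }
  decoding <- do.call(rbind, dec_rows)
  wcsv(decoding, "decoding.csv")
  wcsv(do.call(rbind, deltas), "delta_accuracy.csv")

  say("functional clustering")
  both <- which(qc[["1"]]$qc$selected & qc[["2"]]$qc$selected)
  tm <- build_training_matrix(
    t(vapply(both, function(i) rowMeans(amps1[i, , , drop = FALSE][1, , ]),
             numeric(30))),
    t(vapply(both, function(i) rowMeans(amps2[i, , , drop = FALSE][1, , ]),
             numeric(30))),
    pop$area[both], n_per_area = config$cluster$n_per_area,
    seed = stage_seed(seed, "training"))
  model <- fit_cluster_model(tm$x, k_range = config$cluster$k_range,
                             n_pcs = config$cluster$n_pcs,
                             seed = stage_seed(seed, "kmeans"))
  wcsv(model$validation, "cluster_validation.csv")
  labels <- assign_to_centroids(tm$x, model)
  compo <- hb_cluster_proportions(
    labels, pop$mouse_id[both[tm$manifest$neuron]],
    tm$manifest$area, k = model$k,
    n_boot = config$cluster$n_boot, n_cells = config$cluster$n_cells,
    n_mice = config$cluster$n_mice,
    seed = stage_seed(seed, "composition"))
  wcsv(compo$composition, "cluster_composition.csv")
  simm <- as.data.frame(compo$similarity_mean)
  simm <- cbind(area = rownames(compo$similarity_mean), simm)
  wcsv(simm, "area_similarity.csv")
  emb <- tsne_embed(model$scores, perplexity = config$tsne_perplexity,
                    seed = stage_seed(seed, "tsne"))
  wcsv(data.frame(row = seq_len(nrow(emb)), x = emb[, 1], y = emb[, 2],
                  cluster = model$labels, area = tm$manifest$area),
       "tsne_embedding.csv")

  say("maps")
  wf <- simulate_widefield_movie(config$retinotopy,
                                 seed = stage_seed(seed, "widefield"))
  pm <- phase_map(wf, period_s = wf$period_s)
  retin_rmse <- phase_rmse(pm$phase, wf$gt_phase)
  pmap <- parameter_map(pop$pos_x_um[sel12][ok], pop$pos_y_um[sel12][ok],
                        log2(tuning$sf0[ok]),
                        smoothing_um = config$map_smoothing_um)
  wcsv(data.frame(x_um = rep(pmap$x, times = length(pmap$y)),
                  y_um = rep(pmap$y, each = length(pmap$x)),
                  log2_peak_sf = as.vector(pmap$z)),
       "map_peak_sf.csv")

  say("report")
  rec <- tuning[ok, ]
  truth <- pop[match(rec$neuron_id, pop$neuron_id), ]
  slope <- if (nrow(rec) > 2) {
    stats::coef(stats::lm(log2(rec$sf0) ~ log2(truth$sf0)))[2]
  } else NA
  report <- c(
    "# Synthetic pipeline report", "",
    sprintf("Root seed: %d", seed),
    sprintf("Population: %d neurons, %d mice, %d areas", nrow(pop),
            config$population$n_mice, length(config$population$areas)),
    "", "## QC counts (per dataset)", "",
    utils::capture.output(print(qc_summary, row.names = FALSE)),
    "", "## Tuning", "",
    sprintf("Fitted neurons (dataset 1|2 selected): %d; accepted best fits: %d",
            nrow(tuning), sum(ok)),
    sprintf("Recovered-vs-true log2 peak-SF regression slope: %.3f", slope),
    sprintf("Median |xi| error: %.3f",
            stats::median(abs(rec$xi - truth$xi), na.rm = TRUE)),
    "", "## Decoding (speed vs iso-speed pairs)", "",
    utils::capture.output(print(do.call(rbind, deltas), row.names = FALSE)),
    "", "## Clustering", "",
    sprintf("Selected k = %d (silhouette argmax); 12-PC variance explained: %.1f%%",
            model$k, 100 * model$variance_explained),
    "", "## Retinotopy", "",
    sprintf("Phase-map circular RMSE: %.4f rad (%.2f%% of cycle)",
            retin_rmse, 100 * retin_rmse / (2 * pi))
  )
  writeLines(report, file.path(out_dir, "report.md"))
  say("done")
  invisible(list(pop = pop, sim = sim, qc = qc, tuning = tuning,
                 elongation = elong, ks = ksm, decoding = results,
                 model = model, composition = compo, phase_map = pm,
                 retinotopy_rmse = retin_rmse))
}
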