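#' De-randomize trial traces into a canonical epoch matrix
#'
#' Re-orders the randomized stimulus epochs of each trial into canonical
#' condition order and cuts, for each condition, a window covering the
#' preceding gray (baseline), the 4-s stimulus epoch and the following
#' 4-s gray. Epoch amplitudes are the time-mean dF/F over the stimulus
#' part of the window.
#'
#' @param traces matrix `(trial, time)` of one neuron's dF/F, laid out as
#'   4 s initial gray then one (4 s stimulus + 4 s gray) epoch per
#'   schedule entry.
#' @param schedule a [presentation_schedule()] data.frame.
#' @param grid the matching condition grid.
#' @param fps sampling rate (Hz).
#' @param pre_s,stim_s,post_s window segment durations (s).
#' @return an `epoch_matrix`: list with `amplitudes`
#'   `(condition, trial)`, `epochs` `(condition, trial, time)` and the
#'   window layout (`pre_s`, `stim_s`, `post_s`, `fps`).
#' @export
derandomize <- function(traces, schedule, grid, fps, pre_s = 4, stim_s = 4,
                        post_s = 4) {
  n_cond <- nrow(grid)
  n_trial <- max(schedule$trial)
  epoch_samp <- (stim_s + post_s) * fps
  expected_len <- pre_s * fps + n_cond * epoch_samp
  if (ncol(traces) != expected_len) {
    stop("schedule/trace length mismatch: expected ", expected_len,
         " samples, got ", ncol(traces))
  }
  n_win <- (pre_s + stim_s + post_s) * fps
  epochs <- array(NA_real_, dim = c(n_cond, n_trial, n_win))
  amplitudes <- matrix(NA_real_, n_cond, n_trial)
  for (tr in seq_len(n_trial)) {
    s <- schedule[schedule$trial == tr, ]
    for (k in seq_len(nrow(s))) {
      cid <- s$condition_id[k]
      e <- s$epoch_index[k]
      onset <- pre_s * fps + (e - 1) * epoch_samp  # sample before stim onset
      win <- (onset - pre_s * fps + 1):(onset + (stim_s + post_s) * fps)
      epochs[cid, tr, ] <- traces[tr, win]
      amplitudes[cid, tr] <- mean(traces[tr, (onset + 1):(onset + stim_s * fps)])
    }
  }
  structure(
    list(amplitudes = amplitudes, epochs = epochs,
         pre_s = pre_s, stim_s = stim_s, post_s = post_s, fps = fps),
    class = "epoch_matrix"
  )
}

#' Slow-baseline drift correction of a dF/F trace
#'
#' Estimates the slow baseline as a running low percentile (chunked, then
#' linearly interpolated) and subtracts it, leaving transients on a
#' zero-mean gray-screen baseline.
#'
#' @param trace numeric dF/F vector.
#' @param fps sampling rate (Hz).
#' @param window_s chunk length for the running percentile (s).
#' @param probs baseline percentile.
#' @return the corrected trace.
#' @export
preprocess_trace <- function(trace, fps, window_s = 30, probs = 0.1) {
  if (all(is.na(trace))) stop("all-NaN trace")
  n <- length(trace)
  chunk <- max(2L, round(window_s * fps))
  starts <- seq(1L, n, by = chunk)
  mids <- pmin(starts + chunk / 2, n)
  qs <- vapply(starts, function(s) {
    stats::quantile(trace[s:min(s + chunk - 1L, n)], probs, na.rm = TRUE,
                    names = FALSE)
  }, numeric(1))
  if (length(qs) == 1L) {
    baseline <- rep(qs, n)
  } else {
    baseline <- stats::approx(mids, qs, xout = seq_len(n), rule = 2)$y
  }
  trace - baseline
}

#' Responsiveness of one neuron from its epoch matrix
#'
#' A neuron is responsive if, for at least one condition, the
#' across-trial median time course exceeds the pre-stimulus baseline by
#' more than 3 standard deviations continuously for more than 1 s during
#' the stimulus epoch. The baseline mean and SD come from the final 2 s
#' of the preceding gray. Neurons meeting the criterion only in the 2-s
#' window after stimulus offset are flagged offset-only (and excluded by
#' QC).
#'
#' @param em an `epoch_matrix` from [derandomize()].
#' @param baseline_s baseline length at the end of the preceding gray (s).
#' @param min_run_s minimum supra-threshold duration (s), exceeded
#'   strictly.
#' @param offset_win_s post-offset window used for offset-only detection.
#' @return list with logicals `responsive` and `offset_only` (both `NA`
#'   if every condition has a degenerate zero-variance baseline).
#' @export
is_responsive <- function(em, baseline_s = 2, min_run_s = 1,
                          offset_win_s = 2) {
  fps <- em$fps
  n_cond <- dim(em$epochs)[1]
  pre_idx <- ((em$pre_s - baseline_s) * fps + 1):(em$pre_s * fps)
  stim_idx <- (em$pre_s * fps + 1):((em$pre_s + em$stim_s) * fps)
  off_idx <- ((em$pre_s + em$stim_s) * fps + 1):
    ((em$pre_s + em$stim_s + offset_win_s) * fps)
  min_run <- min_run_s * fps
  any_stim <- FALSE; any_off <- FALSE; any_valid <- FALSE
  for (c in seq_len(n_cond)) {
    med <- col_medians(em$epochs[c, , , drop = FALSE][1, , ])
    b_mean <- mean(med[pre_idx]); b_sd <- stats::sd(med[pre_idx])
    if (!is.finite(b_sd) || b_sd == 0) next
    any_valid <- TRUE
    above <- med > b_mean + 3 * b_sd
    if (longest_run(above[stim_idx]) > min_run) any_stim <- TRUE
    if (longest_run(above[off_idx]) > min_run / 2) any_off <- TRUE
  }
  if (!any_valid) {
    warning("degenerate baseline (zero variance) for every condition")
    return(list(responsive = NA, offset_only = NA))
  }
  list(responsive = any_stim, offset_only = !any_stim && any_off)
}

# Concatenated de-randomized response time course of one trial
# (stimulus + following gray of every condition, canonical order).
trial_time_course <- function(em, trial) {
  fps <- em$fps
  idx <- (em$pre_s * fps + 1):((em$pre_s + em$stim_s + em$post_s) * fps)
  as.numeric(t(em$epochs[, trial, idx]))
}

#' Response reliability index
#'
#' The 75th percentile (linear interpolation between order statistics) of
#' the pairwise Pearson correlations between the concatenated
#' de-randomized response time courses of all trial pairs
#' (C(4,2) = 6 pairs for 4 trials). Pairs involving a zero-variance
#' trial contribute correlation 0, keeping r defined for silent neurons.
#'
#' @param em an `epoch_matrix`.
#' @param per_condition pool the pairwise correlations computed per
#'   condition instead of correlating whole concatenated sessions (the
#'   default).
#' @return reliability `r` in `[-1, 1]`.
#' @export
reliability_index <- function(em, per_condition = FALSE) {
  n_trial <- dim(em$epochs)[2]
  stopifnot(n_trial >= 2)
  pairs <- utils::combn(n_trial, 2)
  pair_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  }
  cors <- if (per_condition) {
    fps <- em$fps
    idx <- (em$pre_s * fps + 1):((em$pre_s + em$stim_s + em$post_s) * fps)
    unlist(lapply(seq_len(dim(em$epochs)[1]), function(c) {
      apply(pairs, 2, function(p) {
        pair_cor(em$epochs[c, p[1], idx], em$epochs[c, p[2], idx])
      })
    }))
  } else {
    tcs <- lapply(seq_len(n_trial), function(tr) trial_time_course(em, tr))
    apply(pairs, 2, function(p) pair_cor(tcs[[p[1]]], tcs[[p[2]]]))
  }
  stats::quantile(cors, 0.75, names = FALSE, type = 7)
}

#' Shuffle-based null distribution of the reliability index
#'
#' Recomputes `r` after randomly permuting condition identity within each
#' trial (breaking stimulus locking while preserving each trial's
#' repertoire of epochs), `n_shuffles` times.
#'
#' @param em an `epoch_matrix`.
#' @param n_shuffles number of shuffles (>= 100).
#' @param seed integer seed.
#' @return list with `null` (vector of shuffled r), `q97_5` and `q99_75`
#'   percentile thresholds.
#' @export
reliability_null <- function(em, n_shuffles = 1000, seed = 1) {
  stopifnot(n_shuffles >= 100)
  n_cond <- dim(em$epochs)[1]
  n_trial <- dim(em$epochs)[2]
  with_seed(seed, {
    null <- vapply(seq_len(n_shuffles), function(s) {
      em2 <- em
      for (tr in seq_len(n_trial)) {
        em2$epochs[, tr, ] <- em$epochs[sample(n_cond), tr, ]
      }
      reliability_index(em2)
    }, numeric(1))
    list(null = null,
         q97_5 = stats::quantile(null, 0.975, names = FALSE),
         q99_75 = stats::quantile(null, 0.9975, names = FALSE))
  })
}

#' Run trace-level QC on a simulated dataset
#'
#' Computes, per neuron, the epoch matrix, responsiveness/offset flags
#' and the reliability index for one stimulus battery.
#'
#' @param sim a `simulated_dataset` from [simulate_trial_traces()].
#' @param dataset dataset name (`"1"`, `"2"` or `"3"`).
#' @return data.frame with one row per neuron: `neuron_id`, `mouse_id`,
#'   `area`, `responsive`, `offset_only`, `r`.
#' @export
qc_dataset <- function(sim, dataset = "1") {
  ds <- sim$datasets[[dataset]]
  if (is.null(ds)) stop("dataset ", dataset, " not present in simulation")
  n <- nrow(sim$neurons)
  out <- data.frame(
    neuron_id = sim$neurons$neuron_id,
    mouse_id = sim$neurons$mouse_id,
    area = sim$neurons$area,
    responsive = NA, offset_only = NA, r = NA_real_
  )
  for (i in seq_len(n)) {
    em <- derandomize(ds$traces[i, , , drop = FALSE][1, , , drop = TRUE],
                      ds$schedule, ds$grid, sim$fps)
    resp <- suppressWarnings(is_responsive(em))
    out$responsive[i] <- resp$responsive
    out$offset_only[i] <- resp$offset_only
    out$r[i] <- reliability_index(em)
  }
  out
}

#' Select reliably responsive neurons
#'
#' Applies the selection rule: responsive during stimulus epochs, not
#' offset-only, and reliability `r` above threshold. Also reports
#' per-area partition counts (all / responsive / selected).
#'
#' @param qc a [qc_dataset()] data.frame.
#' @param r_threshold reliability threshold (default 0.3).
#' @return list with `qc` (input plus `selected` column) and `summary`
#'   (per-area counts).
#' @export
qc_filter <- function(qc, r_threshold = 0.3) {
  sel <- !is.na(qc$responsive) & qc$responsive &
    !is.na(qc$offset_only) & !qc$offset_only &
    !is.na(qc$r) & qc$r > r_threshold
  qc$selected <- sel
  agg <- do.call(rbind, lapply(split(qc, qc$area), function(g) {
    data.frame(area = g$area[1], n_all = nrow(g),
               n_responsive = sum(g$responsive %in% TRUE),
               n_selected = sum(g$selected))
  }))
  rownames(agg) <- NULL
  list(qc = qc, summary = agg, r_threshold = r_threshold)
}
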