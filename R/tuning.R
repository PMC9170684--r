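#' Evaluate the 2-D log-Gaussian spatiotemporal tuning model
#'
#' The tuning surface is an elliptical Gaussian in log2 frequency
#' coordinates with a slant set by the speed-tuning index `xi`:
#' \deqn{R(sf, tf) = A \exp\left(-\frac{(\log_2 sf - \log_2 sf_0)^2}
#'   {2\sigma_{sf}^2}\right) \exp\left(-\frac{(\log_2 tf - g(sf))^2}
#'   {2\sigma_{tf}^2}\right)}
#' with \eqn{g(sf) = \xi(\log_2 sf - \log_2 sf_0) + \log_2 tf_0}.
#' `xi = 0` gives separable SF x TF tuning; `xi = 1` gives tuning that is
#' constant along lines of equal speed `tf/sf` through the peak.
#'
#' @param fit a list (or `st_fit`) with `A`, `sf0`, `tf0`, `sigma_sf`,
#'   `sigma_tf`, `xi`.
#' @param sf,tf spatial (cpd) and temporal (Hz) frequencies, `> 0`,
#'   vectorized.
#' @return model amplitude(s).
#' @export
evaluate_model <- function(fit, sf, tf) {
  stopifnot(all(sf > 0), all(tf > 0))
  dx <- log2(sf) - log2(fit$sf0)
  g <- fit$xi * dx + log2(fit$tf0)
  fit$A * exp(-dx^2 / (2 * fit$sigma_sf^2)) *
    exp(-(log2(tf) - g)^2 / (2 * fit$sigma_tf^2))
}

st_fit <- function(A = NA_real_, sf0 = NA_real_, tf0 = NA_real_,
                   sigma_sf = NA_real_, sigma_tf = NA_real_, xi = NA_real_,
                   nrmse = NA_real_, accepted = FALSE, source = NA_character_) {
  structure(
    list(A = A, sf0 = sf0, tf0 = tf0, sigma_sf = sigma_sf,
         sigma_tf = sigma_tf, xi = xi, nrmse = nrmse,
         accepted = accepted, source = source),
    class = "st_fit"
  )
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf(
    "spatiotemporal fit [%s]: A=%.3g sf0=%.3g cpd tf0=%.3g Hz sigma=(%.2f, %.2f) oct xi=%.2f nRMSE=%.3g (%s)\n",
    ifelse(is.na(x$source), "?", x$source), x$A, x$sf0, x$tf0,
    x$sigma_sf, x$sigma_tf, x$xi, x$nrmse,
    if (isTRUE(x$accepted)) "accepted" else "rejected"
  ))
  invisible(x)
}

#' Fit the spatiotemporal tuning model to a response grid
#'
#' Bounded multi-start least squares on trial-averaged response
#' amplitudes over the SF x TF condition grid. Starts are placed at the
#' observed peak with a small lattice of slant values; each start is
#' refined with `L-BFGS-B`. Fit quality is the normalized RMS error
#' (RMS residual as a fraction of the fitted peak amplitude); fits with
#' `nRMSE < 0.1` are accepted, others are reported but flagged rejected.
#'
#' @param amplitudes numeric matrix `(length(sf_values), length(tf_values))`
#'   of trial-averaged epoch amplitudes (or a vector in sf-major,
#'   tf-minor canonical condition order).
#' @param sf_values,tf_values tested frequencies (defaults: the 5 x 6
#'   battery, 0.02--0.32 cpd and 0.5--16 Hz).
#' @param source label recorded on the fit (`"ISO"` or `"ANISO"`).
#' @param xi_starts slant values used as optimization starts.
#' @param bounds list of parameter bounds; defaults span the tested range
#'   plus or minus 2 octaves.
#' @param nrmse_threshold acceptance gate on the normalized RMS error.
#' @param nrmse_denominator `"fitted_peak"` (noise-robust default) or
#'   `"raw_max"` (observed maximum amplitude).
#' @return an `st_fit` object.
#' @export
fit_spatiotemporal <- function(amplitudes,
                               sf_values = c(0.02, 0.04, 0.08, 0.16, 0.32),
                               tf_values = c(0.5, 1, 2, 4, 8, 16),
                               source = "ISO",
                               xi_starts = c(-1, 0, 1),
                               bounds = list(sf0 = c(0.005, 1.28),
                                             tf0 = c(0.125, 64),
                                             sigma = c(0.3, 10),
                                             xi = c(-3, 3)),
                               nrmse_threshold = 0.1,
                               nrmse_denominator = c("fitted_peak",
                                                     "raw_max")) {
  nrmse_denominator <- match.arg(nrmse_denominator)
  n_sf <- length(sf_values); n_tf <- length(tf_values)
  amp <- if (is.matrix(amplitudes)) {
    amplitudes
  } else {
    # canonical condition order is sf-major, tf-minor
    matrix(amplitudes, n_sf, n_tf, byrow = TRUE)
  }
  stopifnot(nrow(amp) == n_sf, ncol(amp) == n_tf)
  if (!any(is.finite(amp)) || max(amp, na.rm = TRUE) <= 0) {
    return(st_fit(source = source))
  }
  amp[!is.finite(amp)] <- 0
  l2sf <- log2(sf_values); l2tf <- log2(tf_values)
  grid_sf <- matrix(l2sf, n_sf, n_tf)
  grid_tf <- matrix(l2tf, n_sf, n_tf, byrow = TRUE)
  obj <- function(par) {
    # par: A, l2sf0, l2tf0, sigma_sf, sigma_tf, xi
    dx <- grid_sf - par[2]
    g <- par[6] * dx + par[3]
    mdl <- par[1] * exp(-dx^2 / (2 * par[4]^2)) *
      exp(-(grid_tf - g)^2 / (2 * par[5]^2))
    sum((amp - mdl)^2)
  }
  pk <- which(amp == max(amp), arr.ind = TRUE)[1, ]
  a_max <- max(amp)
  lower <- c(1e-9, log2(bounds$sf0[1]), log2(bounds$tf0[1]),
             bounds$sigma[1], bounds$sigma[1], bounds$xi[1])
  upper <- c(4 * a_max, log2(bounds$sf0[2]), log2(bounds$tf0[2]),
             bounds$sigma[2], bounds$sigma[2], bounds$xi[2])
  best <- NULL
  for (xi0 in xi_starts) {
    p0 <- c(a_max, l2sf[pk[1]], l2tf[pk[2]], 1.5, 1.5, xi0)
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) return(st_fit(source = source))
  p <- best$par
  denom <- if (nrmse_denominator == "fitted_peak") p[1] else a_max
  nrmse <- sqrt(best$value / (n_sf * n_tf)) / denom
  st_fit(A = p[1], sf0 = 2^p[2], tf0 = 2^p[3], sigma_sf = p[4],
         sigma_tf = p[5], xi = p[6], nrmse = nrmse,
         accepted = nrmse < nrmse_threshold, source = source)
}

#' Select the fit with the larger peak response
#'
#' Of the accepted ISO and ANISO fits, returns the one with greater
#' fitted peak amplitude; if only one is accepted it wins regardless of
#' amplitude; an exact amplitude tie resolves to the ISO fit. Returns
#' `NULL` when both fits are rejected (the neuron is excluded from SF/TF
#' analyses).
#'
#' @param fit_iso,fit_aniso `st_fit` objects (either may be `NULL`).
#' @return the winning `st_fit`, or `NULL`.
#' @export
select_best_fit <- function(fit_iso, fit_aniso) {
  ok_iso <- !is.null(fit_iso) && isTRUE(fit_iso$accepted)
  ok_aniso <- !is.null(fit_aniso) && isTRUE(fit_aniso$accepted)
  if (!ok_iso && !ok_aniso) return(NULL)
  if (ok_iso && !ok_aniso) return(fit_iso)
  if (!ok_iso && ok_aniso) return(fit_aniso)
  if (fit_aniso$A > fit_iso$A) fit_aniso else fit_iso
}

#' Half-maximum frequency cutoffs and tuning shapes
#'
#' Cutoffs are the half-maximum crossings of the one-dimensional slices
#' `R(sf, tf0)` and `R(sf0, tf)`. Along SF the slant contributes a
#' second exponential, shrinking the effective width:
#' `1/sigma_eff^2 = 1/sigma_sf^2 + xi^2/sigma_tf^2` (closed form).
#' Shapes are assigned against the tested bounds: lowpass if the low
#' cutoff falls below the lowest tested frequency, highpass if the high
#' cutoff exceeds the highest tested, bandpass if both cutoffs are within
#' bounds, and broadband when both fall outside.
#'
#' @param fit an accepted `st_fit`.
#' @param sf_bounds,tf_bounds tested frequency ranges.
#' @return list with `sf_low`, `sf_high` (cpd), `tf_low`, `tf_high` (Hz),
#'   `sf_shape`, `tf_shape` in `{lowpass, bandpass, highpass, broadband}`.
#' @export
frequency_cutoffs <- function(fit, sf_bounds = c(0.02, 0.32),
                              tf_bounds = c(0.5, 16)) {
  sigma_eff <- 1 / sqrt(1 / fit$sigma_sf^2 + fit$xi^2 / fit$sigma_tf^2)
  h_sf <- sigma_eff * sqrt(2 * log(2))
  h_tf <- fit$sigma_tf * sqrt(2 * log(2))
  cut <- list(
    sf_low = fit$sf0 * 2^(-h_sf), sf_high = fit$sf0 * 2^h_sf,
    tf_low = fit$tf0 * 2^(-h_tf), tf_high = fit$tf0 * 2^h_tf
  )
  shape <- function(lo, hi, b) {
    low_out <- lo < b[1]; high_out <- hi > b[2]
    if (low_out && high_out) "broadband"
    else if (low_out) "lowpass"
    else if (high_out) "highpass"
    else "bandpass"
  }
  cut$sf_shape <- shape(cut$sf_low, cut$sf_high, sf_bounds)
  cut$tf_shape <- shape(cut$tf_low, cut$tf_high, tf_bounds)
  cut
}

#' Preferred stimulus speed and speed-tuned flag
#'
#' Speed is the ratio of center temporal over center spatial frequency;
#' a neuron counts as speed-tuned when its slant exceeds 0.5 (strictly),
#' computed from the fit to isotropic responses.
#'
#' @param fit an accepted `st_fit`.
#' @return `peak_speed()`: speed in deg/s; `speed_flag()`: logical.
#' @export
peak_speed <- function(fit) fit$tf0 / fit$sf0

#' @rdname peak_speed
#' @export
speed_flag <- function(fit) fit$xi > 0.5

#' Anisotropy (ANISO/ISO) preference index
#'
#' `API = (R1 - R0) / (R1 + R0)` where `R1` and `R0` are the peak
#' response amplitudes to anisotropic and isotropic stimuli. Categories:
#' ISO-preferring for `API` in `[-1, -1/3]`, ANISO-preferring for
#' `[1/3, 1]`, mixed in between.
#'
#' @param R1,R0 peak ANISO and ISO amplitudes, both `>= 0`, not both 0.
#' @return list with `api` and `category`.
#' @export
anisotropy_preference_index <- function(R1, R0) {
  stopifnot(R1 >= 0, R0 >= 0)
  if (R1 == 0 && R0 == 0) stop("API undefined for R1 = R0 = 0")
  api <- (R1 - R0) / (R1 + R0)
  category <- if (api <= -1 / 3) "ISO-pref"
  else if (api >= 1 / 3) "ANISO-pref"
  else "mixed"
  list(api = api, category = category)
}

#' Elongation tuning curve at the preferred spatial frequency
#'
#' From the dataset-3 amplitude matrix (4 spatial frequencies x 4
#' orientation-bandwidth levels), selects the row containing the global
#' peak (ties broken toward the lower spatial frequency) and returns the
#' 4-element tuning curve over bandwidth levels, widest (isotropic)
#' first.
#'
#' @param amplitudes 4 x 4 matrix, rows = spatial frequencies in
#'   ascending order, columns = orientation bandwidths
#'   `{Inf, 60, 30, 15}` deg.
#' @param sf_values the tested spatial frequencies.
#' @return list with `curve` (length 4), `preferred_sf`,
#'   `ori_bandwidths`.
#' @export
elongation_tuning_curve <- function(amplitudes,
                                    sf_values = c(0.04, 0.08, 0.16, 0.32)) {
  stopifnot(nrow(amplitudes) == length(sf_values), ncol(amplitudes) == 4)
  row_max <- apply(amplitudes, 1, max)
  pref_row <- which(row_max == max(row_max))[1]  # tie -> lower SF
  list(curve = as.numeric(amplitudes[pref_row, ]),
       preferred_sf = sf_values[pref_row],
       ori_bandwidths = c(Inf, 60, 30, 15))
}

#' Orientation-binned response time course with offset wrap-around
#'
#' Converts the trial-averaged calcium time course of one anisotropic
#' epoch into a response-versus-orientation curve. Because calcium decay
#' outlasts the stimulus, activity after stimulus offset is wrapped
#' around: the post-offset samples at time `t` are added to the onset
#' response at `t - stim_s`, so that tails from late-orientation
#' responses land on the orientations that evoked them. The combined
#' time course is binned by the stimulus orientation trajectory
#' `theta(t) = (45 t) mod 180`.
#'
#' @param epoch_traces matrix `(trial, time)` covering the 4-s stimulus
#'   epoch plus at least `wrap_s` of the following gray, baseline near 0.
#' @param fps sampling rate (Hz).
#' @param n_bins number of orientation bins over `[0, 180)`.
#' @param stim_s stimulus epoch duration (s).
#' @param wrap_s length of post-offset gray wrapped onto the onset (s).
#' @return list with `r_k` (binned mean amplitudes), `theta_k`
#'   (bin centers, deg).
#' @export
orientation_time_course <- function(epoch_traces, fps, n_bins = 12,
                                    stim_s = 4, wrap_s = 4) {
  if (is.null(dim(epoch_traces))) epoch_traces <- matrix(epoch_traces, nrow = 1)
  n_stim <- round(stim_s * fps)
  n_wrap <- round(wrap_s * fps)
  if (ncol(epoch_traces) < n_stim + n_wrap) {
    stop("wrap window exceeds the available post-offset trace")
  }
  avg <- colMeans(epoch_traces)
  wrapped <- avg[seq_len(n_stim)]
  if (n_wrap > 0) {
    tail_part <- avg[n_stim + seq_len(n_wrap)]
    idx <- seq_len(n_wrap)  # wrap_s <= stim_s: tail folds onto the onset
    wrapped[idx] <- wrapped[idx] + tail_part
  }
  t_mid <- (seq_len(n_stim) - 0.5) / fps
  theta <- orientation_trajectory(t_mid)
  bin <- pmin(floor(theta / (180 / n_bins)), n_bins - 1) + 1
  r_k <- as.numeric(tapply(wrapped, factor(bin, levels = seq_len(n_bins)), mean))
  r_k[is.na(r_k)] <- 0
  theta_k <- (seq_len(n_bins) - 0.5) * 180 / n_bins
  list(r_k = r_k, theta_k = theta_k)
}

#' Orientation selectivity index (1 - circular variance)
#'
#' `OSI = |sum_k r_k exp(2 i theta_k)| / sum_k r_k` on the doubled
#' orientation angle; 0 for a flat curve, 1 for a single active bin.
#' Negative bin amplitudes are clipped to 0 (amplitudes act as
#' nonnegative weights).
#'
#' @param r_k binned response amplitudes.
#' @param theta_k bin-center orientations (degrees).
#' @return OSI in `[0, 1]`.
#' @export
orientation_selectivity_index <- function(r_k, theta_k) {
  r <- pmax(r_k, 0)
  s <- sum(r)
  if (s <= 0) stop("OSI undefined: total binned response is zero")
  Mod(sum(r * exp(2i * theta_k * pi / 180))) / s
}

#' Validate calcium-based OSI estimates against spike-based estimates
#'
#' Runs the spike/calcium simulation ([simulate_osi_pair()]) over a sweep
#' of orientation tuning widths and preferred orientations, computing the
#' OSI from orientation-binned spike counts (ground-truth route) and from
#' the calcium trace via the wrap-around binning procedure
#' ([orientation_time_course()]).
#'
#' @param fwhm_deg vector of tuning FWHM values (deg).
#' @param theta_pref vector of preferred orientations (deg).
#' @param rate_scale peak firing rate (Hz).
#' @param kernel a [calcium_kernel()].
#' @param seed integer seed.
#' @param n_bins orientation bins.
#' @return data.frame with columns `fwhm`, `theta_pref`, `osi_spike`,
#'   `osi_calc`.
#' @export
validate_osi <- function(fwhm_deg = seq(10, 170, by = 10),
                         theta_pref = c(0, 45, 90, 135),
                         rate_scale = 100, kernel = calcium_kernel(),
                         seed = 1, n_bins = 12) {
  grid <- expand.grid(fwhm = fwhm_deg, theta_pref = theta_pref,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- simulate_osi_pair(
      grid$fwhm[i], grid$theta_pref[i], rate_scale = rate_scale,
      kernel = kernel, seed = stage_seed(seed, paste0("osi-", i))
    )
    stim <- !is.na(sim$theta_deg)
    bin <- pmin(floor(sim$theta_deg[stim] / (180 / n_bins)), n_bins - 1) + 1
    counts <- tapply(sim$spikes[stim], factor(bin, levels = seq_len(n_bins)), sum)
    counts[is.na(counts)] <- 0
    theta_k <- (seq_len(n_bins) - 0.5) * 180 / n_bins
    osi_spike <- if (sum(counts) > 0) {
      orientation_selectivity_index(as.numeric(counts), theta_k)
    } else NA_real_
    otc <- orientation_time_course(matrix(sim$calcium, nrow = 1), fps = sim$fps,
                                   n_bins = n_bins)
    osi_calc <- if (sum(pmax(otc$r_k, 0)) > 0) {
      orientation_selectivity_index(otc$r_k, otc$theta_k)
    } else NA_real_
    data.frame(fwhm = grid$fwhm[i], theta_pref = grid$theta_pref[i],
               osi_spike = osi_spike, osi_calc = osi_calc)
  })
  do.call(rbind, res)
}
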