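#' Stimulus condition grids for the three noise-stimulus batteries
#'
#' Builds the full Cartesian grid of stimulus conditions for one of the
#' three datasets used throughout the pipeline:
#' \describe{
#'   \item{dataset 1}{30 spatially isotropic conditions: 5 center spatial
#'     frequencies (0.02--0.32 cpd) x 6 center temporal frequencies
#'     (0.5--16 Hz), infinite orientation bandwidth.}
#'   \item{dataset 2}{the same 30 frequency combinations with anisotropic,
#'     slowly rotating patterns (15 deg FWHM orientation bandwidth).}
#'   \item{dataset 3}{16 conditions: 4 spatial frequencies
#'     (0.04--0.32 cpd) x 4 orientation bandwidths (infinite, 60, 30,
#'     15 deg FWHM) at a fixed 2 Hz temporal frequency.}
#' }
#' Spatial and temporal bandwidths are 1 octave throughout. Conditions are
#' returned in canonical order: spatial frequency major, then temporal
#' frequency (datasets 1--2) or orientation bandwidth (dataset 3, widest
#' first).
#'
#' @param dataset_id 1, 2 or 3.
#' @return a data.frame with columns `condition_id`, `dataset_id`,
#'   `sf_center` (cpd), `tf_center` (Hz), `ori_bandwidth` (deg FWHM,
#'   `Inf` = isotropic), `sf_bandwidth` and `tf_bandwidth` (octaves).
#' @export
build_condition_grid <- function(dataset_id) {
  if (!dataset_id %in% 1:3) {
    stop("unknown dataset_id: ", dataset_id)
  }
  if (dataset_id %in% c(1L, 2L)) {
    sf <- c(0.02, 0.04, 0.08, 0.16, 0.32)
    tf <- c(0.5, 1, 2, 4, 8, 16)
    grid <- expand.grid(tf_center = tf, sf_center = sf,
                        KEEP.OUT.ATTRS = FALSE)[, c("sf_center", "tf_center")]
    grid$ori_bandwidth <- if (dataset_id == 1L) Inf else 15
  } else {
    sf <- c(0.04, 0.08, 0.16, 0.32)
    bw <- c(Inf, 60, 30, 15)
    grid <- expand.grid(ori_bandwidth = bw, sf_center = sf,
                        KEEP.OUT.ATTRS = FALSE)[, c("sf_center", "ori_bandwidth")]
    grid$tf_center <- 2
  }
  grid <- grid[order(grid$sf_center), ]
  data.frame(
    condition_id = seq_len(nrow(grid)),
    dataset_id = as.integer(dataset_id),
    sf_center = grid$sf_center,
    tf_center = grid$tf_center,
    ori_bandwidth = grid$ori_bandwidth,
    sf_bandwidth = 1,
    tf_bandwidth = 1,
    row.names = NULL
  )
}

#' Center orientation of the rotating anisotropic stimulus
#'
#' The orientation band of anisotropic stimuli rotates clockwise at
#' 45 deg/s; orientation is 180-periodic, so one 4-s epoch sweeps
#' `[0, 180)` exactly once.
#'
#' @param t time in seconds (vectorized), `t >= 0`.
#' @param rate_deg_s rotation rate in deg/s.
#' @return orientation in degrees, in `[0, 180)`.
#' @export
orientation_trajectory <- function(t, rate_deg_s = 45) {
  stopifnot(all(t >= 0))
  (rate_deg_s * t) %% 180
}

#' Spatiotemporal bandpass filter for noise-stimulus synthesis
#'
#' Constructs the spectral amplitude profile used to shape random noise
#' into a stimulus of given center spatial frequency, center temporal
#' frequency and orientation bandwidth. Amplitude profiles are Gaussian in
#' log2 frequency along the radial spatial-frequency and the
#' temporal-frequency axes (FWHM = the condition's 1-octave bandwidths),
#' and Gaussian in orientation angle (wrapped, 180-periodic) with FWHM
#' equal to the condition's orientation bandwidth; an infinite bandwidth
#' omits the orientation factor.
#'
#' @param condition one row of [build_condition_grid()].
#' @return an object of class `bandpass_filter` with amplitude-profile
#'   functions `sf_profile(sf)`, `tf_profile(tf)` and
#'   `ori_profile(theta_deg, center_deg)`.
#' @seealso [filter_mask_array()], [measure_filter_fwhm()]
#' @export
make_bandpass_filter <- function(condition) {
  stopifnot(nrow(condition) == 1L, condition$sf_center > 0, condition$tf_center > 0)
  sigma_sf <- fwhm_to_sigma(condition$sf_bandwidth)   # octaves
  sigma_tf <- fwhm_to_sigma(condition$tf_bandwidth)   # octaves
  sf0 <- condition$sf_center
  tf0 <- condition$tf_center
  ori_bw <- condition$ori_bandwidth
  sigma_ori <- if (is.finite(ori_bw)) fwhm_to_sigma(ori_bw) else Inf

  sf_profile <- function(sf) {
    out <- numeric(length(sf))
    pos <- sf > 0
    out[pos] <- exp(-(log2(sf[pos]) - log2(sf0))^2 / (2 * sigma_sf^2))
    out
  }
  tf_profile <- function(tf) {
    out <- numeric(length(tf))
    pos <- tf > 0
    out[pos] <- exp(-(log2(tf[pos]) - log2(tf0))^2 / (2 * sigma_tf^2))
    out
  }
  ori_profile <- function(theta_deg, center_deg = 0) {
    if (!is.finite(sigma_ori)) return(rep(1, length(theta_deg)))
    # wrapped Gaussian on the 180-periodic orientation circle
    d <- outer(theta_deg - center_deg, 180 * (-2:2), "+")
    rowSums(exp(-d^2 / (2 * sigma_ori^2)))
  }

  structure(
    list(
      condition = condition,
      sf_center = sf0, tf_center = tf0,
      sigma_sf_oct = sigma_sf, sigma_tf_oct = sigma_tf,
      ori_bandwidth = ori_bw, sigma_ori_deg = sigma_ori,
      sf_profile = sf_profile, tf_profile = tf_profile,
      ori_profile = ori_profile
    ),
    class = "bandpass_filter"
  )
}

#' Measure the half-maximum bandwidth of a filter profile
#'
#' Evaluates the filter's amplitude profile on a fine grid and measures
#' its full width at half maximum by linear interpolation of the
#' half-maximum crossings: in octaves (log2 frequency) for the `"sf"` and
#' `"tf"` axes, in degrees for `"ori"`.
#'
#' @param filt a [make_bandpass_filter()] object.
#' @param axis `"sf"`, `"tf"` or `"ori"`.
#' @param n grid resolution.
#' @return the measured FWHM (octaves, or degrees for `"ori"`).
#' @export
measure_filter_fwhm <- function(filt, axis = c("sf", "tf", "ori"), n = 4001) {
  axis <- match.arg(axis)
  if (axis == "ori") {
    if (!is.finite(filt$ori_bandwidth)) return(Inf)
    x <- seq(-90, 90, length.out = n)
    y <- filt$ori_profile(x, center_deg = 0)
  } else {
    center <- if (axis == "sf") log2(filt$sf_center) else log2(filt$tf_center)
    x <- seq(center - 3, center + 3, length.out = n)
    y <- if (axis == "sf") filt$sf_profile(2^x) else filt$tf_profile(2^x)
  }
  half <- max(y) / 2
  above <- y >= half
  idx <- which(above)
  lo_i <- idx[1]; hi_i <- idx[length(idx)]
  interp_cross <- function(i0, i1) {
    # linear interpolation of the half-max crossing between samples i0, i1
    x[i0] + (half - y[i0]) * (x[i1] - x[i0]) / (y[i1] - y[i0])
  }
  x_lo <- if (lo_i > 1) interp_cross(lo_i - 1, lo_i) else x[1]
  x_hi <- if (hi_i < n) interp_cross(hi_i + 1, hi_i) else x[n]
  x_hi - x_lo
}

#' Realize a filter as a spectral mask on an FFT grid
#'
#' @param filt a [make_bandpass_filter()] object.
#' @param n_px spatial resolution (pixels per side, square frame).
#' @param n_t number of frames.
#' @param pitch_deg pixel pitch in degrees per pixel.
#' @param fps frame rate (Hz).
#' @param ori_center_deg center orientation for the (finite-bandwidth)
#'   orientation factor; ignored for isotropic filters.
#' @param include_ori include the orientation factor (set `FALSE` when the
#'   rotating orientation mask is applied per frame instead).
#' @return a 3-D numeric array `(n_px, n_px, n_t)` of spectral amplitudes,
#'   laid out like `stats::fft` output; conjugate-symmetric so a filtered
#'   real movie stays real.
#' @export
filter_mask_array <- function(filt, n_px = 64, n_t = 120, pitch_deg = 100 / 64,
                              fps = 30, ori_center_deg = 0, include_ori = TRUE) {
  nyq_sf <- 1 / (2 * pitch_deg)
  nyq_tf <- fps / 2
  if (filt$sf_center > nyq_sf || filt$tf_center > nyq_tf) {
    stop("center frequency above Nyquist for the chosen resolution")
  }
  if (filt$sf_center * 2^0.5 > nyq_sf || filt$tf_center * 2^0.5 > nyq_tf) {
    warning("1-octave band edge exceeds Nyquist; spectrum will be truncated")
  }
  fx <- fft_freq(n_px, d = pitch_deg)
  fy <- fft_freq(n_px, d = pitch_deg)
  ft <- fft_freq(n_t, d = 1 / fps)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  amp_xy <- matrix(filt$sf_profile(as.vector(fr)), n_px, n_px)
  if (include_ori && is.finite(filt$ori_bandwidth)) {
    theta <- (atan2(rep(fy, each = n_px), rep(fx, times = n_px)) * 180 / pi) %% 180
    amp_xy <- amp_xy * matrix(filt$ori_profile(theta, ori_center_deg), n_px, n_px)
  }
  amp_t <- filt$tf_profile(abs(ft))
  array(outer(as.vector(amp_xy), amp_t), dim = c(n_px, n_px, n_t))
}

# 2-D orientation mask on the spatial FFT grid (used per frame for the
# rotating anisotropic stimuli).
orientation_mask_2d <- function(filt, n_px, pitch_deg, center_deg) {
  fx <- fft_freq(n_px, d = pitch_deg)
  fy <- fft_freq(n_px, d = pitch_deg)
  theta <- (atan2(rep(fy, each = n_px), rep(fx, times = n_px)) * 180 / pi) %% 180
  m <- matrix(filt$ori_profile(theta, center_deg), n_px, n_px)
  m[1, 1] <- 1  # leave DC untouched
  m
}

#' Normalize a movie to a target RMS contrast
#'
#' Rescales fluctuations around the mean so that
#' `100 * sd(frames) / mean(frames)` equals `target_pct`, with the spatial
#' mean pinned at the background luminance (1 in normalized units). The
#' operation is idempotent.
#'
#' @param frames numeric array of luminance values.
#' @param target_pct target RMS contrast in percent.
#' @param mean_luminance background luminance in normalized units.
#' @return the normalized array.
#' @export
normalize_contrast <- function(frames, target_pct = 50, mean_luminance = 1) {
  s <- stats::sd(frames)
  if (s == 0) stop("cannot normalize a constant movie")
  mean_luminance + (frames - mean(frames)) * (target_pct / 100) * mean_luminance / s
}

#' RMS contrast of a stimulus movie
#' @param movie a `stimulus_movie` or a numeric array of luminance frames.
#' @return RMS contrast in percent of mean luminance.
#' @export
movie_rms_contrast <- function(movie) {
  frames <- if (inherits(movie, "stimulus_movie")) movie$frames else movie
  100 * stats::sd(frames) / mean(frames)
}

#' Synthesize a bandpass-filtered noise stimulus movie
#'
#' Generates one 4-s stimulus epoch: white Gaussian noise is shaped to a
#' 1/f spatial amplitude spectrum, bandpass-filtered to the condition's
#' center frequencies (1-octave FWHM in log2 SF and TF), and, for
#' anisotropic conditions, multiplied per frame by an orientation mask
#' whose center rotates at 45 deg/s. The movie is normalized to 50% RMS
#' contrast around a mean luminance of 1. A fixed seed yields a
#' bit-identical movie.
#'
#' @param condition one row of [build_condition_grid()].
#' @param seed integer noise seed (one per trial x epoch in a schedule).
#' @param n_px frame resolution (pixels per side).
#' @param fps frame rate (Hz).
#' @param duration_s epoch duration in seconds.
#' @param field_deg visual field extent covered by the frame (degrees).
#' @param rms_contrast_pct target RMS contrast (percent).
#' @return an object of class `stimulus_movie`: list with `frames`
#'   (`n_px` x `n_px` x frames, mean-1 luminance units), `fps`,
#'   `pixel_pitch_deg`, `rms_contrast`, `condition` and `seed`.
#' @export
synthesize_noise_movie <- function(condition, seed, n_px = 64, fps = 30,
                                   duration_s = 4, field_deg = 100,
                                   rms_contrast_pct = 50) {
  pitch <- field_deg / n_px
  n_t <- round(duration_s * fps)
  filt <- make_bandpass_filter(condition)
  if (condition$sf_center > 1 / (2 * pitch)) {
    stop("resolution too low for requested sf_center")
  }
  # The filter defines the realized spectral envelope directly: the white
  # Gaussian base supplies random phases with flat expected amplitude, so
  # the synthesized spectrum is the mask itself. (Tilting the base by an
  # uncompensated 1/f amplitude would displace the realized spectral peak
  # ~0.13 octave below the nominal center, off the condition's
  # coordinates.)
  mask <- filter_mask_array(filt, n_px = n_px, n_t = n_t, pitch_deg = pitch,
                            fps = fps, include_ori = FALSE)
  shaped <- with_seed(seed, {
    noise <- array(stats::rnorm(n_px * n_px * n_t), dim = c(n_px, n_px, n_t))
    spec <- stats::fft(noise) * mask
    Re(stats::fft(spec, inverse = TRUE)) / length(spec)
  })
  if (is.finite(condition$ori_bandwidth)) {
    # continuous rotation: per-frame orientation mask at the frame midpoint
    for (k in seq_len(n_t)) {
      th <- orientation_trajectory((k - 0.5) / fps)
      m2 <- orientation_mask_2d(filt, n_px, pitch, th)
      f2 <- stats::fft(shaped[, , k]) * m2
      shaped[, , k] <- Re(stats::fft(f2, inverse = TRUE)) / length(f2)
    }
  }
  frames <- normalize_contrast(shaped, target_pct = rms_contrast_pct)
  structure(
    list(frames = frames, fps = fps, pixel_pitch_deg = pitch,
         rms_contrast = movie_rms_contrast(frames),
         condition = condition, seed = seed),
    class = "stimulus_movie"
  )
}

#' Randomized presentation schedule for a condition grid
#'
#' Each of `n_trials` trials presents every condition exactly once, in an
#' independent random order, with a unique noise seed per (trial, epoch):
#' phases vary across trials while frequency spectra stay constant.
#'
#' @param grid a [build_condition_grid()] data.frame.
#' @param n_trials number of trials.
#' @param seed integer seed for order and noise-seed draws.
#' @return a data.frame with columns `trial`, `epoch_index`,
#'   `condition_id`, `noise_seed`.
#' @export
presentation_schedule <- function(grid, n_trials = 4, seed = 1) {
  n <- nrow(grid)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
      data.frame(
        trial = tr,
        epoch_index = seq_len(n),
        condition_id = sample(grid$condition_id),
        noise_seed = sample.int(.Machine$integer.max, n)
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' In-band spectral power fraction of a movie
#'
#' Fraction of (non-DC) spectral power lying within a log2-frequency band
#' around a center spatial frequency; used to validate spectral fidelity
#' of synthesized stimuli.
#'
#' @param movie a `stimulus_movie`.
#' @param sf_center center spatial frequency (cpd); default from the
#'   movie's condition.
#' @param halfwidth_oct half width of the band in octaves.
#' @return fraction in `[0, 1]`.
#' @export
spatial_band_power_fraction <- function(movie, sf_center = NULL,
                                        halfwidth_oct = 1) {
  if (is.null(sf_center)) sf_center <- movie$condition$sf_center
  frames <- movie$frames - mean(movie$frames)
  n_px <- dim(frames)[1]
  fx <- fft_freq(n_px, d = movie$pixel_pitch_deg)
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  pw <- apply(abs(stats::fft(frames))^2, c(1, 2), sum)
  pw[1, 1] <- 0
  in_band <- fr > 0 & abs(log2(fr / sf_center)) <= halfwidth_oct
  sum(pw[in_band]) / sum(pw)
}

#' Peak of a movie's radial spatial amplitude spectrum
#' @param movie a `stimulus_movie`.
#' @param n_bins number of log2-frequency bins.
#' @return peak spatial frequency (cpd) of the binned radial spectrum.
#' @export
spectral_peak_sf <- function(movie, n_bins = 48) {
  frames <- movie$frames - mean(movie$frames)
  n_px <- dim(frames)[1]
  fx <- fft_freq(n_px, d = movie$pixel_pitch_deg)
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- sqrt(apply(abs(stats::fft(frames))^2, c(1, 2), sum))
  ok <- fr > 0
  bins <- cut(log2(fr[ok]), breaks = n_bins)
  prof <- tapply(amp[ok], bins, mean)
  centers <- tapply(log2(fr[ok]), bins, mean)
  2^centers[which.max(prof)]
}
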