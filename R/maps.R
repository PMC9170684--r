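#' Retinotopic phase map from a widefield movie
#'
#' Averages the movie across stimulus cycles and takes, per pixel, the
#' phase of the cycle time evoking the maximal response
#' (`phase = argmax_t / period * 2 pi`); amplitude is the cycle-averaged
#' peak-to-trough range. Pixels whose modulation amplitude falls below
#' `amp_threshold` times the map's median amplitude are flagged
#' unreliable. A `"fourier"` mode (phase of the first harmonic) is
#' available for noisy data.
#'
#' @param movie list with `frames` `(nx, ny, time)` and `fps` (e.g. from
#'   [simulate_widefield_movie()]).
#' @param period_s stimulus cycle period (s).
#' @param method `"argmax"` (cycle-averaged peak time) or `"fourier"`.
#' @param amp_threshold reliability threshold relative to the median
#'   amplitude.
#' @return a `phase_map`: list with `phase` (radians in `[0, 2 pi)`),
#'   `amplitude`, `reliable` (logical matrix), `period_s`.
#' @export
phase_map <- function(movie, period_s = 20, method = c("argmax", "fourier"),
                      amp_threshold = 0.1) {
  method <- match.arg(method)
  frames <- movie$frames
  fps <- movie$fps
  n_cycle_t <- round(period_s * fps)
  n_t <- dim(frames)[3]
  if (n_t %% n_cycle_t != 0) stop("movie length is not an integer number of cycles")
  n_cycles <- n_t %/% n_cycle_t
  dims <- dim(frames)[1:2]
  cyc <- array(frames, dim = c(dims[1], dims[2], n_cycle_t, n_cycles))
  avg <- apply(cyc, c(1, 2, 3), mean)
  amplitude <- apply(avg, c(1, 2), function(v) max(v) - min(v))
  phase <- if (method == "argmax") {
    apply(avg, c(1, 2), function(v) {
      ((which.max(v) - 0.5) / n_cycle_t) * 2 * pi
    })
  } else {
    apply(avg, c(1, 2), function(v) {
      h <- sum(v * exp(-2i * pi * (seq_along(v) - 0.5) / n_cycle_t))
      (Arg(Conj(h))) %% (2 * pi)
    })
  }
  structure(
    list(phase = phase %% (2 * pi), amplitude = amplitude,
         reliable = amplitude > amp_threshold * stats::median(amplitude),
         period_s = period_s),
    class = "phase_map"
  )
}

#' Circular RMS error between two phase maps
#' @param phase_a,phase_b matrices of phases in radians.
#' @param align remove the best common offset (e.g. kernel lag) first.
#' @return RMS circular distance in radians.
#' @export
phase_rmse <- function(phase_a, phase_b, align = TRUE) {
  d <- (phase_a - phase_b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  if (align) {
    offset <- Arg(mean(exp(1i * d)))
    d <- (d - offset + pi) %% (2 * pi) - pi
  }
  sqrt(mean(d^2))
}

#' Smoothed cortical map of a per-neuron parameter
#'
#' Gaussian-weighted local average of neuron values on a regular spatial
#' grid (kernel sigma = `smoothing_um`); grid cells with negligible
#' total weight are masked `NA`. Linear in the value vector.
#'
#' @param x_um,y_um neuron positions (micrometers).
#' @param values per-neuron values.
#' @param smoothing_um Gaussian kernel width in micrometers, interpreted
#'   as the kernel sigma by default.
#' @param grid_step_um grid spacing.
#' @param min_weight mask threshold on the summed kernel weight.
#' @param width_is_fwhm interpret `smoothing_um` as the kernel FWHM
#'   instead of sigma.
#' @return list with `x`, `y` (grid coordinates) and `z` (matrix of
#'   smoothed values, `NA` where masked).
#' @export
parameter_map <- function(x_um, y_um, values, smoothing_um = 400,
                          grid_step_um = 100, min_weight = 1e-3,
                          width_is_fwhm = FALSE) {
  stopifnot(length(x_um) == length(values), length(y_um) == length(values))
  if (width_is_fwhm) smoothing_um <- fwhm_to_sigma(smoothing_um)
  gx <- seq(min(x_um) - smoothing_um, max(x_um) + smoothing_um,
            by = grid_step_um)
  gy <- seq(min(y_um) - smoothing_um, max(y_um) + smoothing_um,
            by = grid_step_um)
  z <- matrix(NA_real_, length(gx), length(gy))
  s2 <- 2 * smoothing_um^2
  for (i in seq_along(gx)) {
    wx <- exp(-(x_um - gx[i])^2 / s2)
    for (j in seq_along(gy)) {
      w <- wx * exp(-(y_um - gy[j])^2 / s2)
      sw <- sum(w)
      if (sw > min_weight) z[i, j] <- sum(w * values) / sw
    }
  }
  list(x = gx, y = gy, z = z)
}
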