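#' Double-exponential GCaMP6s-like calcium kernel
#'
#' Impulse response `exp(-t/decay) - exp(-t/rise)`, sampled at the trace
#' frame rate and normalized to unit integral so a sustained rate
#' converges to its own steady-state amplitude.
#'
#' @param rise_s rise time constant (s); GCaMP6s-typical 0.2 s.
#' @param decay_s decay time constant (s); GCaMP6s-typical 0.56 s.
#' @param fps sampling rate (Hz).
#' @param duration_s kernel support (s).
#' @return a `calcium_kernel` object: list with `weights` (per-sample,
#'   summing to 1), `fps`, `rise_s`, `decay_s`, `peak_lag_s`.
#' @export
calcium_kernel <- function(rise_s = 0.2, decay_s = 0.56, fps = 8,
                           duration_s = 5 * decay_s) {
  stopifnot(rise_s < decay_s, rise_s > 0)
  t <- seq(0, duration_s, by = 1 / fps)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  w <- k / sum(k)
  structure(
    list(weights = w, fps = fps, rise_s = rise_s, decay_s = decay_s,
         peak_lag_s = t[which.max(k)]),
    class = "calcium_kernel"
  )
}

#' Epoch-mean attenuation of a boxcar response under the calcium kernel
#'
#' Closed-form mean of the kernel's step response over a stimulus epoch:
#' a constant rate `a` sustained for `stim_s` seconds yields an
#' epoch-mean calcium amplitude `a * kernel_epoch_mean_factor(...)`
#' (the rise eats into the epoch onset). Used to compare simulated
#' epoch means against generative amplitudes exactly.
#'
#' @param kernel a [calcium_kernel()].
#' @param stim_s epoch duration (s).
#' @return attenuation factor in `(0, 1]`.
#' @export
kernel_epoch_mean_factor <- function(kernel, stim_s = 4) {
  n <- round(stim_s * kernel$fps)
  step <- cumsum(kernel$weights)
  s <- c(step, rep(1, max(0, n - length(step))))[seq_len(n)]
  mean(s)
}

#' Causal convolution of a rate or spike vector with the calcium kernel
#'
#' The initial partial-overlap samples (NA from `stats::filter`) are
#' zero-padded, so the output has the length of the input.
#' @param x numeric vector (firing rate or spike counts per sample).
#' @param kernel a [calcium_kernel()] sampled at the same rate.
#' @return the convolved trace, same length as `x`.
#' @export
convolve_kernel <- function(x, kernel) {
  y <- as.numeric(stats::filter(c(numeric(length(kernel$weights) - 1), x),
                                kernel$weights, method = "convolution",
                                sides = 1))
  y[length(kernel$weights) - 1 + seq_along(x)]
}

#' Orientation tuning gain (wrapped Gaussian on the orientation circle)
#'
#' Wrapped-Gaussian tuning on the 180-periodic orientation circle,
#' peak-normalized to 1 at `theta_pref` and parameterized by FWHM. A
#' wrapped Gaussian keeps wide tuning genuinely flat: at 170 deg FWHM
#' its selectivity is near zero, unlike a FWHM-matched von Mises whose
#' fat tails retain appreciable modulation.
#'
#' @param theta_deg orientation(s) in degrees.
#' @param theta_pref preferred orientation (deg).
#' @param fwhm_deg tuning full width at half maximum (deg).
#' @return gain(s) in `(0, 1]`.
#' @export
orientation_gain <- function(theta_deg, theta_pref, fwhm_deg) {
  sigma <- fwhm_to_sigma(fwhm_deg)
  d <- outer((theta_deg - theta_pref) %% 180, 180 * (-3:3), "+")
  g <- rowSums(exp(-d^2 / (2 * sigma^2)))
  peak <- sum(exp(-(180 * (-3:3))^2 / (2 * sigma^2)))
  as.numeric(g / peak)
}

# Mean of the orientation gain over [0, 180).
orientation_gain_mean <- function(fwhm_deg, n = 720) {
  mean(orientation_gain(seq(0, 180, length.out = n + 1)[-(n + 1)], 0, fwhm_deg))
}

#' Default configuration of the synthetic population generator
#'
#' Defines the study conditions the generator emulates: 10 mice, 8 visual
#' areas (V1, LM, AL, RL, AM, PM, LI, POR/P), 150 neurons per area per
#' mouse, with area-specific tuning biases (anterior dorsal areas prefer
#' low SF / high TF and speed tuning; ventral areas the opposite), nested
#' mouse-level variability, a three-way cell-type mixture for elongation
#' tuning (non-OS / sharp-OS / broad-OS), and trial noise (additive
#' sigma = 0.05 dF/F per frame, multiplicative gain CV = 0.15 per epoch)
#' chosen so the reliability distribution straddles the r = 0.3
#' selection threshold.
#'
#' @param n_mice number of mice.
#' @param areas character vector of area labels.
#' @param neurons_per_area_mouse neurons sampled per area per mouse.
#' @return a named list accepted by [sample_population()].
#' @export
default_population_config <- function(n_mice = 10,
                                      areas = c("V1", "LM", "AL", "RL",
                                                "AM", "PM", "LI", "POR/P"),
                                      neurons_per_area_mouse = 150) {
  base <- list(
    l2sf0_mean = log2(0.04), l2sf0_sd = 1.0,
    l2tf0_mean = log2(2),    l2tf0_sd = 1.0,
    xi_mean = 0.2, xi_sd = 0.5,
    mixture = c(non_os = 0.40, sharp_os = 0.30, broad_os = 0.30)
  )
  tweak <- function(dsf, dtf, xi_mean, mixture) {
    p <- base
    p$l2sf0_mean <- p$l2sf0_mean + dsf
    p$l2tf0_mean <- p$l2tf0_mean + dtf
    p$xi_mean <- xi_mean
    p$mixture <- mixture
    p
  }
  dorsal_mix  <- c(non_os = 0.20, sharp_os = 0.50, broad_os = 0.30)
  ventral_mix <- c(non_os = 0.55, sharp_os = 0.18, broad_os = 0.27)
  mid_mix     <- c(non_os = 0.40, sharp_os = 0.30, broad_os = 0.30)
  area_params <- list(
    "V1"    = tweak( 0.0, -0.5, 0.0,  mid_mix),
    "LM"    = tweak( 0.5,  0.0, 0.25, mid_mix),
    "AL"    = tweak(-0.5,  1.0, 0.55, dorsal_mix),
    "RL"    = tweak(-0.5,  1.2, 0.65, dorsal_mix),
    "AM"    = tweak(-0.3,  1.0, 0.60, dorsal_mix),
    "PM"    = tweak( 0.8, -0.8, 0.35, dorsal_mix),
    "LI"    = tweak( 1.0, -1.0, 0.30, ventral_mix),
    "POR/P" = tweak( 1.0, -1.2, 0.30, ventral_mix)
  )
  list(
    n_mice = n_mice,
    areas = areas,
    neurons_per_area_mouse = neurons_per_area_mouse,
    area_params = area_params[areas],
    mouse_sd_oct = 0.3,      # per-mouse log2 offset shared within mouse
    mouse_sd_xi = 0.1,
    sigma_log_mean = log(1.5), sigma_log_sd = 0.25,  # tuning widths (oct)
    amp_log_mean = log(0.6), amp_log_sd = 0.5,       # peak dF/F
    responsive_prob = 0.85,
    noise = list(additive_sd = 0.05, gain_cv = 0.15, drift_per_min = 0),
    area_spacing_um = 1200, area_scatter_um = 250
  )
}

#' Sample a hierarchical ground-truth neuron population
#'
#' Draws mice, then neurons nested in mice and areas, from the
#' configuration's per-area tuning distributions. Mouse-level random
#' offsets (log2 SF/TF and speed-index shifts) are shared by all neurons
#' of a mouse, producing genuinely nested variability. Cell types set the
#' elongation-gain profile over orientation-bandwidth levels
#' (infinite, 60, 30, 15 deg): non-OS decreasing, sharp-OS increasing,
#' broad-OS flat.
#'
#' @param config a [default_population_config()]-style list.
#' @param seed integer seed.
#' @return a data.frame (one row per neuron) with identifiers, cortical
#'   position (um), tuning parameters `A`, `sf0`, `tf0`, `sigma_sf`,
#'   `sigma_tf`, `xi`, orientation preference/width, cell type, the
#'   elongation gains `gain_inf`, `gain_60`, `gain_30`, `gain_15`, noise
#'   parameters and a `responsive` flag.
#' @export
sample_population <- function(config = default_population_config(), seed = 1) {
  for (a in config$areas) {
    p <- config$area_params[[a]]
    if (is.null(p)) stop("missing area_params for area ", a)
    if (abs(sum(p$mixture) - 1) > 1e-8) stop("cell-type mixture must sum to 1")
    if (p$l2sf0_sd < 0 || p$l2tf0_sd < 0 || p$xi_sd < 0) {
      stop("negative SD in area_params")
    }
  }
  with_seed(seed, {
    rows <- list()
    area_centers <- cbind(
      x = ((seq_along(config$areas) - 1) %% 4) * config$area_spacing_um,
      y = ((seq_along(config$areas) - 1) %/% 4) * config$area_spacing_um
    )
    nid <- 0L
    for (m in seq_len(config$n_mice)) {
      off_sf <- stats::rnorm(1, 0, config$mouse_sd_oct)
      off_tf <- stats::rnorm(1, 0, config$mouse_sd_oct)
      off_xi <- stats::rnorm(1, 0, config$mouse_sd_xi)
      for (ai in seq_along(config$areas)) {
        a <- config$areas[ai]
        p <- config$area_params[[a]]
        n <- config$neurons_per_area_mouse
        ct <- sample(names(p$mixture), n, replace = TRUE, prob = p$mixture)
        fwhm <- ifelse(
          ct == "sharp_os", pmin(pmax(stats::rnorm(n, 30, 8), 10), 170),
          ifelse(ct == "broad_os", pmin(pmax(stats::rnorm(n, 80, 20), 10), 170),
                 pmin(pmax(stats::rnorm(n, 120, 25), 10), 170))
        )
        gains <- t(vapply(seq_len(n), function(i) {
          base <- switch(ct[i],
            non_os   = c(1, 0.6, 0.3, 0.1),
            sharp_os = c(0.1, 0.3, 0.6, 1),
            broad_os = c(1, 1, 1, 1)
          )
          pmax(base * exp(stats::rnorm(4, 0, 0.08)), 0)
        }, numeric(4)))
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = nid + seq_len(n),
          mouse_id = paste0("m", sprintf("%02d", m)),
          area = a,
          pos_x_um = area_centers[ai, "x"] + stats::rnorm(n, 0, config$area_scatter_um),
          pos_y_um = area_centers[ai, "y"] + stats::rnorm(n, 0, config$area_scatter_um),
          A = exp(stats::rnorm(n, config$amp_log_mean, config$amp_log_sd)),
          sf0 = 2^(stats::rnorm(n, p$l2sf0_mean + off_sf, p$l2sf0_sd)),
          tf0 = 2^(stats::rnorm(n, p$l2tf0_mean + off_tf, p$l2tf0_sd)),
          sigma_sf = exp(stats::rnorm(n, config$sigma_log_mean, config$sigma_log_sd)),
          sigma_tf = exp(stats::rnorm(n, config$sigma_log_mean, config$sigma_log_sd)),
          xi = stats::rnorm(n, p$xi_mean + off_xi, p$xi_sd),
          theta_pref = stats::runif(n, 0, 180),
          ori_fwhm = fwhm,
          cell_type = ct,
          gain_inf = gains[, 1], gain_60 = gains[, 2],
          gain_30 = gains[, 3], gain_15 = gains[, 4],
          noise_sd = config$noise$additive_sd,
          gain_cv = config$noise$gain_cv,
          responsive = stats::runif(n) < config$responsive_prob,
          stringsAsFactors = FALSE
        )
        nid <- nid + n
      }
    }
    # clamp preferred frequencies into the generative support used by fits
    pop <- do.call(rbind, rows)
    pop$sf0 <- pmin(pmax(pop$sf0, 0.005), 1.28)
    pop$tf0 <- pmin(pmax(pop$tf0, 0.125), 64)
    rownames(pop) <- NULL
    pop
  })
}

# Elongation gain for a condition's orientation-bandwidth level.
elongation_gain <- function(neuron, ori_bandwidth) {
  ifelse(!is.finite(ori_bandwidth), neuron$gain_inf,
         ifelse(ori_bandwidth == 60, neuron$gain_60,
                ifelse(ori_bandwidth == 30, neuron$gain_30, neuron$gain_15)))
}

#' Expected (epoch-mean) response of a ground-truth neuron
#'
#' Evaluates the generative tuning model: a 2-D log-Gaussian over
#' (SF, TF) with slant given by the speed-tuning index, multiplied by the
#' neuron's elongation gain at the condition's orientation-bandwidth
#' level. Because anisotropic epochs sweep orientation through the full
#' `[0, 180)` range, the epoch-mean amplitude is independent of the
#' neuron's preferred orientation and the elongation gains encode the
#' orientation-averaged drive directly.
#'
#' @param neuron one row (or several rows) of [sample_population()].
#' @param condition one row of [build_condition_grid()].
#' @return expected epoch-mean dF/F amplitude(s); 0 for non-responsive
#'   neurons.
#' @export
expected_response <- function(neuron, condition) {
  amp <- evaluate_model(
    list(A = neuron$A, sf0 = neuron$sf0, tf0 = neuron$tf0,
         sigma_sf = neuron$sigma_sf, sigma_tf = neuron$sigma_tf,
         xi = neuron$xi),
    condition$sf_center, condition$tf_center
  )
  amp * elongation_gain(neuron, condition$ori_bandwidth) *
    ifelse(neuron$responsive, 1, 0)
}

#' Expected responses of one neuron to every condition of a grid
#' @param neuron one row of [sample_population()].
#' @param grid a [build_condition_grid()] data.frame.
#' @return numeric vector of epoch-mean amplitudes in canonical order.
#' @export
expected_response_grid <- function(neuron, grid) {
  vapply(seq_len(nrow(grid)), function(i) {
    expected_response(neuron, grid[i, ])
  }, numeric(1))
}

#' Simulate trial dF/F traces for a population and stimulus battery
#'
#' For each neuron and trial, builds the underlying rate time course
#' (epoch-mean amplitude from [expected_response()], modulated within
#' anisotropic epochs by the neuron's orientation tuning along the
#' 45 deg/s trajectory, normalized to preserve the epoch mean), convolves
#' it with the calcium kernel, and adds epoch-wise multiplicative gain
#' noise, per-frame additive Gaussian noise and optional slow linear
#' drift. Trials start with 4 s of gray, then one 4-s stimulus + 4-s gray
#' epoch per condition in the schedule's randomized order.
#'
#' @param population a [sample_population()] data.frame.
#' @param grids named list of condition grids (names `"1"`, `"2"`, `"3"`).
#' @param schedules named list of [presentation_schedule()] data.frames,
#'   same names as `grids`.
#' @param fps trace sampling rate (Hz).
#' @param kernel a [calcium_kernel()] (rebuilt at `fps` if rates differ).
#' @param seed integer seed.
#' @param noise optional override list (`additive_sd`, `gain_cv`,
#'   `drift_per_min`); default uses each neuron's own noise columns.
#' @return a `simulated_dataset`: list with `neurons`, `fps`, `kernel`
#'   and `datasets`, where `datasets[[d]]` holds `grid`, `schedule` and a
#'   `traces` array `(neuron, trial, time)`.
#' @export
simulate_trial_traces <- function(population, grids, schedules, fps = 8,
                                  kernel = calcium_kernel(fps = fps),
                                  seed = 1, noise = NULL) {
  stopifnot(identical(sort(names(grids)), sort(names(schedules))))
  if (kernel$fps != fps) kernel <- calcium_kernel(kernel$rise_s, kernel$decay_s, fps)
  if (1 / fps * length(kernel$weights) > 4) {
    # kernel tail longer than the gray epoch: spillover into the next
    # epoch is intended (it is what the OSI wrap-around corrects for)
  }
  n_neuron <- nrow(population)
  epoch_samp <- 8 * fps
  stim_samp <- 4 * fps
  out <- list(neurons = population, fps = fps, kernel = kernel,
              datasets = list())
  for (d in names(grids)) {
    grid <- grids[[d]]
    sched <- schedules[[d]]
    n_cond <- nrow(grid)
    n_trial <- max(sched$trial)
    n_t <- 4 * fps + n_cond * epoch_samp
    traces <- array(0, dim = c(n_neuron, n_trial, n_t))
    # per-condition within-epoch orientation modulation (shared by neurons
    # only through theta_pref/fwhm, so computed per neuron below); the
    # orientation sweep itself is condition-independent
    t_in_stim <- (seq_len(stim_samp) - 0.5) / fps
    theta_t <- orientation_trajectory(t_in_stim)
    ds_seed <- stage_seed(seed, paste0("traces-", d))
    with_seed(ds_seed, {
      for (i in seq_len(n_neuron)) {
        nr <- population[i, ]
        amps <- expected_response_grid(nr, grid)
        nz <- if (is.null(noise)) {
          list(additive_sd = nr$noise_sd, gain_cv = nr$gain_cv, drift_per_min = 0)
        } else noise
        finite_bw <- is.finite(grid$ori_bandwidth)
        if (any(finite_bw & amps > 0)) {
          og <- orientation_gain(theta_t, nr$theta_pref, nr$ori_fwhm)
          og_mean <- orientation_gain_mean(nr$ori_fwhm)
          mod <- og / og_mean
        } else {
          mod <- rep(1, stim_samp)
        }
        for (tr in seq_len(n_trial)) {
          s <- sched[sched$trial == tr, ]
          s <- s[order(s$epoch_index), ]
          rate <- numeric(n_t)
          gain_noise <- 1 + stats::rnorm(n_cond, 0, nz$gain_cv)
          for (e in seq_len(n_cond)) {
            cid <- s$condition_id[e]
            a <- amps[cid] * max(gain_noise[e], 0)
            if (a > 0) {
              idx <- 4 * fps + (e - 1) * epoch_samp + seq_len(stim_samp)
              rate[idx] <- a * (if (finite_bw[cid]) mod else 1)
            }
          }
          tracev <- convolve_kernel(rate, kernel) + stats::rnorm(n_t, 0, nz$additive_sd)
          if (!is.null(nz$drift_per_min) && nz$drift_per_min != 0) {
            tracev <- tracev + nz$drift_per_min * (seq_len(n_t) / fps / 60)
          }
          traces[i, tr, ] <- tracev
        }
      }
    })
    out$datasets[[d]] <- list(grid = grid, schedule = sched, traces = traces)
  }
  class(out) <- "simulated_dataset"
  out
}

#' Simulate a paired spike train and calcium trace for OSI validation
#'
#' An inhomogeneous Poisson neuron with zero spontaneous rate and an
#' orientation tuning curve (von Mises on the doubled angle, given FWHM)
#' is driven along the 45 deg/s orientation trajectory for 4 s, followed
#' by 4 s of silence; the spike train convolved with the GCaMP6s-like
#' kernel gives the calcium trace (whose tail spills past stimulus
#' offset, motivating the wrap-around in the OSI estimator).
#'
#' @param fwhm_deg orientation tuning FWHM in degrees, in `[10, 170]`.
#' @param theta_pref preferred orientation (deg).
#' @param rate_scale peak firing rate (Hz), `> 0` (0 allowed: no spikes).
#' @param kernel a [calcium_kernel()]; rebuilt at `1/dt_s` Hz.
#' @param seed integer seed.
#' @param dt_s simulation time step (s).
#' @param stim_s,gray_s stimulus and post-stimulus durations (s).
#' @return list with `time_s`, `theta_deg` (NA after offset), `spikes`
#'   (counts per bin), `calcium`, `fps`.
#' @export
simulate_osi_pair <- function(fwhm_deg, theta_pref = 0, rate_scale = 30,
                              kernel = calcium_kernel(), seed = 1,
                              dt_s = 0.01, stim_s = 4, gray_s = 4) {
  stopifnot(fwhm_deg >= 10, fwhm_deg <= 170)
  if (rate_scale < 0) stop("nonpositive rate_scale")
  fps <- 1 / dt_s
  kernel <- calcium_kernel(kernel$rise_s, kernel$decay_s, fps = fps)
  n_stim <- round(stim_s / dt_s)
  n_tot <- round((stim_s + gray_s) / dt_s)
  t <- (seq_len(n_tot) - 0.5) * dt_s
  theta <- rep(NA_real_, n_tot)
  theta[seq_len(n_stim)] <- orientation_trajectory(t[seq_len(n_stim)])
  rate <- numeric(n_tot)
  rate[seq_len(n_stim)] <-
    rate_scale * orientation_gain(theta[seq_len(n_stim)], theta_pref, fwhm_deg)
  spikes <- with_seed(seed, stats::rpois(n_tot, rate * dt_s))
  calc <- convolve_kernel(spikes, kernel)
  list(time_s = t, theta_deg = theta, spikes = spikes, calcium = calc, fps = fps)
}

#' Simulate a widefield retinotopy movie with known phase map
#'
#' Every pixel responds with a Gaussian bump (in circular cycle time)
#' centered at its preferred phase of a 20-s stimulus cycle, convolved
#' with the calcium kernel, over `n_cycles` repetitions plus noise. The
#' ground-truth phase map is smooth with one reversal across the field,
#' emulating the mirror-image retinotopy at an area border.
#'
#' @param config list: `nx`, `ny` (pixels), `period_s`, `n_cycles`,
#'   `fps`, `bump_sigma_s`, `noise_sd`.
#' @param seed integer seed.
#' @return list with `frames` `(nx, ny, time)`, `fps`, `period_s`,
#'   `gt_phase` (radians in `[0, 2*pi)`), `kernel`.
#' @export
simulate_widefield_movie <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(nx = 24, ny = 24, period_s = 20, n_cycles = 20, fps = 5,
         bump_sigma_s = 1, noise_sd = 0.05),
    config
  )
  kernel <- calcium_kernel(fps = cfg$fps)
  n_cycle_t <- round(cfg$period_s * cfg$fps)
  n_t <- n_cycle_t * cfg$n_cycles
  xs <- (seq_len(cfg$nx) - 0.5) / cfg$nx
  ys <- (seq_len(cfg$ny) - 0.5) / cfg$ny
  # triangular map in x (reversal at midline) plus a small y gradient
  frac <- outer(abs(2 * xs - 1), 0.2 * ys, "+") %% 1
  gt_phase <- 2 * pi * frac
  t_cycle <- (seq_len(n_cycle_t) - 0.5) / cfg$fps
  frames <- array(0, dim = c(cfg$nx, cfg$ny, n_t))
  with_seed(seed, {
    for (i in seq_len(cfg$nx)) {
      for (j in seq_len(cfg$ny)) {
        pref <- frac[i, j] * cfg$period_s
        d <- pmin(abs(t_cycle - pref), cfg$period_s - abs(t_cycle - pref))
        r1 <- exp(-d^2 / (2 * cfg$bump_sigma_s^2))
        rate <- rep(r1, cfg$n_cycles)
        tr <- convolve_kernel(rate, kernel)
        frames[i, j, ] <- tr + stats::rnorm(n_t, 0, cfg$noise_sd)
      }
    }
  })
  list(frames = frames, fps = cfg$fps, period_s = cfg$period_s,
       gt_phase = gt_phase, kernel = kernel)
}
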