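#' Derive a stage-specific seed from a root seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from a single root seed and a stage name, so that re-running any stage
#' with the same configuration is bit-reproducible while stages stay
#' decorrelated.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
stage_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(root_seed) * 7919 + h * 104729) %% (2^31 - 2) + 1)
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# FFT sample frequencies, matching the layout of stats::fft output.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# FWHM (full width at half maximum) <-> Gaussian sigma.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# Column medians of a small matrix; vectorized fast paths for the
# common 3- and 4-row (trial) cases.
col_medians <- function(m) {
  if (is.null(dim(m))) return(m)
  n <- nrow(m)
  if (n == 4L) {
    as.numeric(colSums(m) - do.call(pmax, asplit(m, 1)) -
                 do.call(pmin, asplit(m, 1))) / 2
  } else if (n == 3L) {
    as.numeric(colSums(m) - do.call(pmax, asplit(m, 1)) -
                 do.call(pmin, asplit(m, 1)))
  } else {
    apply(m, 2, stats::median)
  }
}

# Longest run of TRUE in a logical vector.
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
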