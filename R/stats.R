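#' Hierarchical bootstrap configuration
#'
#' Resampling sizes for the nested (animal, then cell) bootstrap: `N`
#' cells per animal, `M` animals per resample, `L` resamples. The default
#' mirrors the cluster-composition protocol (150 cells, 5 animals, 1000
#' resamples).
#'
#' @param N cells per animal.
#' @param M animals per resample.
#' @param L number of resamples.
#' @return an `hb_config` list.
#' @export
hb_config <- function(N = 150, M = 5, L = 1000) {
  stopifnot(N >= 1, M >= 1, L >= 1)
  structure(list(N = N, M = M, L = L), class = "hb_config")
}

#' Hierarchical (animal, then cell) bootstrap resampling
#'
#' Each resample draws `M` animals with replacement, then `N` values with
#' replacement within each drawn animal, giving `L` resampled datasets of
#' size `N * M` that respect the nested variance structure.
#'
#' @param values numeric vector.
#' @param animals grouping factor/vector, same length as `values`.
#' @param config an [hb_config()].
#' @param seed integer seed.
#' @return numeric matrix `(L, N * M)`.
#' @export
hierarchical_resample <- function(values, animals, config = hb_config(),
                                  seed = 1) {
  stopifnot(length(values) == length(animals), length(values) >= 1)
  by_animal <- split(values, animals)
  by_animal <- by_animal[vapply(by_animal, length, 1L) > 0]
  if (length(by_animal) == 0) stop("empty group")
  with_seed(seed, {
    t(vapply(seq_len(config$L), function(l) {
      picked <- sample(length(by_animal), config$M, replace = TRUE)
      unlist(lapply(picked, function(a) {
        v <- by_animal[[a]]
        v[sample.int(length(v), config$N, replace = TRUE)]
      }), use.names = FALSE)
    }, numeric(config$N * config$M)))
  })
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the empirical CDFs of two samples.
#'
#' @param x,y nonempty numeric vectors.
#' @return `D` in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  z <- sort(unique(c(x, y)))
  fx <- findInterval(z, sort(x)) / length(x)
  fy <- findInterval(z, sort(y)) / length(y)
  max(abs(fx - fy))
}

#' Asymptotic KS critical value
#'
#' `D_alpha = c(alpha) * sqrt((n1 + n2) / (n1 * n2))` with
#' `c(alpha) = 1.36, 1.63, 1.95` for `alpha = 0.05, 0.01, 0.001`.
#'
#' @param n1,n2 sample sizes.
#' @param alpha one of 0.05, 0.01, 0.001.
#' @return the critical value `D_alpha`.
#' @export
ks_critical_value <- function(n1, n2, alpha) {
  stopifnot(n1 >= 1, n2 >= 1)
  coefs <- c(`0.05` = 1.36, `0.01` = 1.63, `0.001` = 1.95)
  key <- as.character(alpha)
  if (!key %in% names(coefs)) {
    stop("unsupported alpha: ", alpha, " (use 0.05, 0.01 or 0.001)")
  }
  coefs[[key]] * sqrt((n1 + n2) / (n1 * n2))
}

#' Hierarchical bootstrap two-sample KS test
#'
#' Draws `L` paired hierarchical resamples of the two groups, computes
#' the KS statistic for each pair, and forms, for each significance
#' level, the confidence interval of `D` at the `alpha/2` and
#' `1 - alpha/2` percentiles. A level is attained when its lower CI bound
#' exceeds the asymptotic critical value `D_alpha` computed at the
#' resampled sizes `n1 = n2 = N * M`; the most stringent attained level
#' is reported (`"ns"` if none).
#'
#' @param x,y numeric vectors for the two groups.
#' @param animals_x,animals_y animal labels, matching `x` and `y`.
#' @param config an [hb_config()].
#' @param alphas significance levels to test (subset of 0.05/0.01/0.001).
#' @param seed integer seed.
#' @return an `hb_ks` list: `D` (length-`L` distribution), `ci_low`,
#'   `ci_high` (at the 0.05 level), `per_alpha` (data.frame of CI bounds,
#'   critical values and attainment per level), `significance`
#'   (`"ns"`, `"0.05"`, `"0.01"` or `"0.001"`), `n1`, `n2`.
#' @export
hb_ks_test <- function(x, animals_x, y, animals_y, config = hb_config(),
                       alphas = c(0.05, 0.01, 0.001), seed = 1) {
  rx <- hierarchical_resample(x, animals_x, config, seed = stage_seed(seed, "hbks-x"))
  ry <- hierarchical_resample(y, animals_y, config, seed = stage_seed(seed, "hbks-y"))
  D <- vapply(seq_len(config$L), function(l) ks_statistic(rx[l, ], ry[l, ]),
              numeric(1))
  n <- config$N * config$M
  alphas <- sort(alphas, decreasing = TRUE)
  per_alpha <- do.call(rbind, lapply(alphas, function(a) {
    data.frame(
      alpha = a,
      ci_low = stats::quantile(D, a / 2, names = FALSE),
      ci_high = stats::quantile(D, 1 - a / 2, names = FALSE),
      d_crit = ks_critical_value(n, n, a)
    )
  }))
  per_alpha$attained <- per_alpha$ci_low > per_alpha$d_crit
  sig <- if (any(per_alpha$attained)) {
    as.character(min(per_alpha$alpha[per_alpha$attained]))
  } else "ns"
  structure(
    list(D = D,
         ci_low = stats::quantile(D, 0.025, names = FALSE),
         ci_high = stats::quantile(D, 0.975, names = FALSE),
         per_alpha = per_alpha, significance = sig, n1 = n, n2 = n),
    class = "hb_ks"
  )
}

#' Cohen's d between two bootstrap distributions
#'
#' Standardized mean difference
#' `d = |M_a - M_b| / sqrt((SD_a^2 + SD_b^2) / 2)`, categorized as small
#' (`d < 0.2`), median (`0.2 <= d <= 2`) or large (`d > 2`).
#'
#' @param boot_a,boot_b numeric vectors (length >= 2).
#' @return list with `d` and `category`.
#' @export
cohens_d <- function(boot_a, boot_b) {
  stopifnot(length(boot_a) >= 2, length(boot_b) >= 2)
  sda <- stats::sd(boot_a); sdb <- stats::sd(boot_b)
  if (sda == 0 && sdb == 0) stop("Cohen's d undefined: both SDs are zero")
  d <- abs(mean(boot_a) - mean(boot_b)) / sqrt((sda^2 + sdb^2) / 2)
  category <- if (d < 0.2) "small" else if (d <= 2) "median" else "large"
  list(d = d, category = category)
}

#' Gaussian kernel density estimate on a stated grid
#'
#' @param values numeric vector (nonempty).
#' @param bandwidth Gaussian kernel SD (the analysis uses 0.05 or 0.1
#'   depending on the parameter's scale).
#' @param n grid size.
#' @param from,to grid range (defaults: data range padded by 5
#'   bandwidths, so the grid captures the kernel mass to < 1e-3).
#' @return data.frame with `x` and density `y` (integrating to ~1).
#' @export
kde <- function(values, bandwidth, n = 512, from = NULL, to = NULL) {
  stopifnot(length(values) >= 1, bandwidth > 0)
  if (is.null(from)) from <- min(values) - 5 * bandwidth
  if (is.null(to)) to <- max(values) + 5 * bandwidth
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian", n = n,
                      from = from, to = to)
  data.frame(x = d$x, y = d$y)
}

#' Pairwise hierarchical-bootstrap KS comparison across groups
#'
#' Convenience wrapper producing the machine-readable significance grid:
#' one row per unordered group pair for one tuning parameter.
#'
#' @param values numeric vector of the parameter.
#' @param animals animal labels.
#' @param groups group (area) labels.
#' @param config an [hb_config()].
#' @param seed integer seed.
#' @return data.frame `(group_i, group_j, ci_low, ci_high, significance)`.
#' @export
hb_ks_matrix <- function(values, animals, groups, config = hb_config(),
                         seed = 1) {
  gs <- unique(groups)
  out <- list()
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (j <= i) next
      sel_i <- groups == gs[i]; sel_j <- groups == gs[j]
      res <- hb_ks_test(values[sel_i], animals[sel_i],
                        values[sel_j], animals[sel_j], config,
                        seed = stage_seed(seed, paste(gs[i], gs[j])))
      out[[length(out) + 1L]] <- data.frame(
        group_i = gs[i], group_j = gs[j],
        ci_low = res$ci_low, ci_high = res$ci_high,
        significance = res$significance
      )
    }
  }
  do.call(rbind, out)
}
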