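#' Speed and iso-speed stimulus pairs on the isotropic grid
#'
#' Speed pairs are neighboring conditions lying orthogonally to the
#' iso-speed lines: `((sf, tf), (2 sf, tf/2))`, a 4-fold difference in
#' speed `tf/sf`. Swapping the frequency combination gives the matched
#' iso-speed pair `((sf, tf/2), (2 sf, tf))`, identical speeds. On the
#' full 5 x 6 grid this yields 20 pairs of each kind, matched one-to-one.
#'
#' @param grid the dataset-1 condition grid.
#' @return data.frame with `pair_id`, `kind` (`"speed"`/`"iso-speed"`),
#'   condition ids and frequencies of both members, and `speed_ratio`.
#' @export
build_pairs <- function(grid = build_condition_grid(1)) {
  key <- function(sf, tf) {
    m <- match(paste(signif(sf, 8), signif(tf, 8)),
               paste(signif(grid$sf_center, 8), signif(grid$tf_center, 8)))
    m
  }
  out <- list()
  pid <- 0L
  for (i in seq_len(nrow(grid))) {
    sf <- grid$sf_center[i]; tf <- grid$tf_center[i]
    a2 <- key(2 * sf, tf / 2)
    if (is.na(a2)) next
    pid <- pid + 1L
    speed_a <- tf / sf; speed_b <- (tf / 2) / (2 * sf)
    out[[length(out) + 1L]] <- data.frame(
      pair_id = pid, kind = "speed",
      cond_a = grid$condition_id[i], cond_b = grid$condition_id[a2],
      sf_a = sf, tf_a = tf, sf_b = 2 * sf, tf_b = tf / 2,
      speed_ratio = speed_a / speed_b
    )
    iso_a <- key(sf, tf / 2); iso_b <- key(2 * sf, tf)
    out[[length(out) + 1L]] <- data.frame(
      pair_id = pid, kind = "iso-speed",
      cond_a = grid$condition_id[iso_a], cond_b = grid$condition_id[iso_b],
      sf_a = sf, tf_a = tf / 2, sf_b = 2 * sf, tf_b = tf,
      speed_ratio = 1
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Train/test one iteration of the pairwise linear-SVM decoder.
svm_iteration <- function(amp_a, amp_b, pool, train_tr, test_tr) {
  xtr <- rbind(t(amp_a[pool, train_tr, drop = FALSE]),
               t(amp_b[pool, train_tr, drop = FALSE]))
  xte <- rbind(t(amp_a[pool, test_tr, drop = FALSE]),
               t(amp_b[pool, test_tr, drop = FALSE]))
  y <- factor(rep(c("a", "b"), each = length(train_tr)))
  # z-score with training-split statistics only
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(xtr, y, kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, xte)
  mean(pred == factor(rep(c("a", "b"), each = length(test_tr))))
}

#' Pairwise linear-SVM decoding of one stimulus pair
#'
#' Trains a linear support vector machine (C = 1, features z-scored with
#' training-split statistics) to discriminate the two conditions of a
#' stimulus pair from a pool of neurons' epoch amplitudes. Each
#' iteration splits the 4 trials half-half into training and testing
#' (drawn without replacement); accuracy is the fraction of correct
#' decisions on the 4 test presentations.
#'
#' @param amp_a,amp_b numeric matrices `(neuron, trial)` of epoch
#'   amplitudes for the two conditions.
#' @param pool integer vector of neuron row indices forming the decoding
#'   pool (nonempty).
#' @param n_iter number of train/test iterations.
#' @param seed integer seed.
#' @return numeric vector of per-iteration accuracies in `[0, 1]`.
#' @export
decode_pair <- function(amp_a, amp_b, pool, n_iter = 100, seed = 1) {
  if (length(pool) == 0) stop("empty decoding pool")
  n_trial <- ncol(amp_a)
  stopifnot(ncol(amp_b) == n_trial, n_trial >= 2)
  with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      train_tr <- sample(n_trial, n_trial %/% 2)
      test_tr <- setdiff(seq_len(n_trial), train_tr)
      svm_iteration(amp_a, amp_b, pool, train_tr, test_tr)
    }, numeric(1))
  })
}

#' Decoding accuracy as a function of pool size
#'
#' For each pool size, repeats the decoding `n_resamples` times with
#' random resampling of neurons (with replacement, equalizing pool
#' availability across areas), each resample averaging `n_iter`
#' train/test iterations; reports the mean and the 95% CI over
#' resamples. Pool sizes exceeding the population are dropped with a
#' warning.
#'
#' @param amp_a,amp_b `(neuron, trial)` amplitude matrices.
#' @param sizes pool sizes (default log-spaced 2..512).
#' @param n_resamples neuron resamples per size.
#' @param n_iter train/test iterations per resample.
#' @param seed integer seed.
#' @return a `decoding_result`: list with `per_resample` (data.frame
#'   `pool_size`, `resample`, `accuracy` in %) and `summary`
#'   (`pool_size`, `mean_accuracy`, `ci_low`, `ci_high`).
#' @export
pool_curve <- function(amp_a, amp_b, sizes = 2^(1:9), n_resamples = 50,
                       n_iter = 100, seed = 1) {
  n <- nrow(amp_a)
  if (any(sizes > n)) {
    warning("pool sizes exceeding the population (", n, ") were dropped")
    sizes <- sizes[sizes <= n]
  }
  rows <- list()
  for (s in sizes) {
    accs <- vapply(seq_len(n_resamples), function(r) {
      rs <- stage_seed(seed, paste0("pool-", s, "-", r))
      pool <- with_seed(rs, sample.int(n, s, replace = TRUE))
      mean(decode_pair(amp_a, amp_b, pool, n_iter = n_iter,
                       seed = stage_seed(rs, "iter")))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      pool_size = s, resample = seq_len(n_resamples), accuracy = 100 * accs
    )
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, per$pool_size), function(g) {
    data.frame(pool_size = g$pool_size[1],
               mean_accuracy = mean(g$accuracy),
               ci_low = stats::quantile(g$accuracy, 0.025, names = FALSE),
               ci_high = stats::quantile(g$accuracy, 0.975, names = FALSE))
  }))
  rownames(summ) <- NULL
  structure(list(per_resample = per, summary = summ,
                 n_resamples = n_resamples, n_iter = n_iter),
            class = "decoding_result")
}

#' Difference in decoding accuracy between two results
#'
#' Compares two [pool_curve()] results at a given pool size (default 16,
#' where differences between small ensembles are most discernible):
#' reports the mean difference, a 95% CI from the paired resample
#' distributions, and a two-sample t-test over the resample accuracy
#' sets.
#'
#' @param result_a,result_b `decoding_result` objects.
#' @param pool_size pool size at which to compare.
#' @return list with `delta` (%), `ci_low`, `ci_high`, `p_value`,
#'   `significant` (p < 0.05).
#' @export
delta_accuracy <- function(result_a, result_b, pool_size = 16) {
  ga <- result_a$per_resample[result_a$per_resample$pool_size == pool_size, ]
  gb <- result_b$per_resample[result_b$per_resample$pool_size == pool_size, ]
  if (nrow(ga) == 0 || nrow(gb) == 0 || nrow(ga) != nrow(gb)) {
    stop("mismatched pool size or resample counts")
  }
  diffs <- ga$accuracy - gb$accuracy
  tt <- if (stats::sd(ga$accuracy) == 0 && stats::sd(gb$accuracy) == 0) {
    list(p.value = 1)
  } else {
    stats::t.test(ga$accuracy, gb$accuracy)
  }
  list(delta = mean(ga$accuracy) - mean(gb$accuracy),
       ci_low = stats::quantile(diffs, 0.025, names = FALSE),
       ci_high = stats::quantile(diffs, 0.975, names = FALSE),
       p_value = tt$p.value,
       significant = tt$p.value < 0.05)
}
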