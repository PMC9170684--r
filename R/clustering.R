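#' Ward clustering of elongation tuning curves into three types
#'
#' Ward-linkage (squared-Euclidean) hierarchical clustering of 4-element
#' elongation tuning curves, cut at 3 clusters, with clusters named by
#' the slope of their mean curve over orientation-bandwidth levels
#' (widest to narrowest): decreasing -> non-OS, increasing -> sharp-OS,
#' flat -> broad-OS. Naming depends only on the mean curves, so it is
#' invariant to cluster index permutations.
#'
#' @param curves numeric matrix `(neuron, 4)` of elongation curves over
#'   `{Inf, 60, 30, 15}` deg bandwidth.
#' @param k number of clusters.
#' @param flat_tol relative slope below which a mean curve counts as
#'   flat.
#' @return list with `labels` (integer), `type` (character per neuron),
#'   `cluster_types` (name per cluster index), `mean_curves`.
#' @export
cluster_elongation <- function(curves, k = 3, flat_tol = 0.15) {
  curves <- as.matrix(curves)
  stopifnot(ncol(curves) == 4)
  if (nrow(unique(curves)) < k) stop("fewer than ", k, " distinct curves")
  hc <- stats::hclust(stats::dist(curves), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  mean_curves <- t(vapply(seq_len(k), function(c) colMeans(curves[labels == c, , drop = FALSE]),
                          numeric(4)))
  x <- seq_len(4)  # bandwidth level index, widest (isotropic) first
  slope <- apply(mean_curves, 1, function(m) {
    stats::coef(stats::lm(m ~ x))[2] / max(mean(m), .Machine$double.eps)
  })
  cluster_types <- ifelse(slope < -flat_tol, "non-OS",
                          ifelse(slope > flat_tol, "sharp-OS", "broad-OS"))
  list(labels = labels, type = cluster_types[labels],
       cluster_types = cluster_types, mean_curves = mean_curves)
}

#' Hierarchically bootstrapped elongation-type fractions per area
#'
#' Builds `n_sub` sub-datasets per area, each of `n_cells` reliable
#' cells sampled hierarchically (mice with replacement, then cells
#' within mice), pools all sub-datasets, ward-clusters the pooled curves
#' into three named types, and reports per-area type fractions averaged
#' over sub-datasets with their s.e.m.
#'
#' @param curves matrix `(neuron, 4)` of elongation curves.
#' @param mouse,area per-neuron labels.
#' @param n_sub sub-datasets per area.
#' @param n_cells cells per sub-dataset.
#' @param seed integer seed.
#' @return data.frame `(area, type, fraction, sem)`.
#' @export
hb_elongation_fractions <- function(curves, mouse, area, n_sub = 10,
                                    n_cells = 500, seed = 1) {
  curves <- as.matrix(curves)
  areas <- unique(area)
  draws <- list()
  with_seed(seed, {
    for (a in areas) {
      idx_a <- which(area == a)
      mice <- unique(mouse[idx_a])
      for (s in seq_len(n_sub)) {
        picked_mice <- sample(mice, length(mice), replace = TRUE)
        per_mouse <- ceiling(n_cells / length(picked_mice))
        idx <- unlist(lapply(picked_mice, function(m) {
          cand <- idx_a[mouse[idx_a] == m]
          cand[sample.int(length(cand), per_mouse, replace = TRUE)]
        }))[seq_len(n_cells)]
        draws[[length(draws) + 1L]] <- data.frame(area = a, sub = s, idx = idx)
      }
    }
  })
  pool <- do.call(rbind, draws)
  cl <- cluster_elongation(curves[pool$idx, , drop = FALSE])
  pool$type <- cl$type
  types <- c("non-OS", "sharp-OS", "broad-OS")
  out <- list()
  for (a in areas) {
    fr <- vapply(seq_len(n_sub), function(s) {
      g <- pool$type[pool$area == a & pool$sub == s]
      vapply(types, function(tp) mean(g == tp), numeric(1))
    }, numeric(length(types)))
    out[[length(out) + 1L]] <- data.frame(
      area = a, type = types,
      fraction = rowMeans(fr),
      sem = apply(fr, 1, stats::sd) / sqrt(n_sub)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Training matrix of joint ISO/ANISO responses
#'
#' Concatenates each neuron's 30 isotropic and 30 anisotropic epoch
#' amplitudes into a 60-condition response vector, min-max normalizes
#' each row to `[0, 1]` (constant rows are dropped with a warning), and
#' samples `n_per_area` rows per area with replacement.
#'
#' @param amp_iso,amp_aniso matrices `(neuron, 30)` of trial-averaged
#'   amplitudes.
#' @param area per-neuron area labels.
#' @param n_per_area rows sampled per area.
#' @param seed integer seed.
#' @return list with `x` (matrix `(rows, 60)`), `manifest` (data.frame
#'   `row`, `neuron`, `area` allowing exact reconstruction).
#' @export
build_training_matrix <- function(amp_iso, amp_aniso, area, n_per_area = 2000,
                                  seed = 1) {
  x <- cbind(as.matrix(amp_iso), as.matrix(amp_aniso))
  rng <- apply(x, 1, function(r) diff(range(r)))
  keep <- which(rng > 0 & is.finite(rng))
  if (length(keep) < nrow(x)) {
    warning(nrow(x) - length(keep), " constant-response rows dropped")
  }
  if (length(keep) == 0) stop("no usable rows")
  xn <- t(apply(x[keep, , drop = FALSE], 1, function(r) {
    (r - min(r)) / (max(r) - min(r))
  }))
  area <- area[keep]
  areas <- unique(area)
  if (any(vapply(areas, function(a) sum(area == a), 1L) == 0)) {
    stop("area with zero eligible neurons")
  }
  with_seed(seed, {
    picks <- unlist(lapply(areas, function(a) {
      cand <- which(area == a)
      cand[sample.int(length(cand), n_per_area, replace = TRUE)]
    }))
    list(
      x = xn[picks, , drop = FALSE],
      manifest = data.frame(row = seq_along(picks),
                            neuron = keep[picks],
                            area = rep(areas, each = n_per_area))
    )
  })
}

# Internal cluster-validation indices on a score matrix.
davies_bouldin <- function(x, labels, centers) {
  k <- nrow(centers)
  s <- vapply(seq_len(k), function(c) {
    d <- sqrt(rowSums((x[labels == c, , drop = FALSE] -
                         matrix(centers[c, ], sum(labels == c), ncol(x),
                                byrow = TRUE))^2))
    mean(d)
  }, numeric(1))
  m <- as.matrix(stats::dist(centers))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) (s[i] + s[j]) / m[i, j],
               numeric(1)))
  }, numeric(1)))
}

calinski_harabasz <- function(x, labels, centers) {
  n <- nrow(x); k <- nrow(centers)
  grand <- colMeans(x)
  b <- sum(vapply(seq_len(k), function(c) {
    sum(labels == c) * sum((centers[c, ] - grand)^2)
  }, numeric(1)))
  w <- sum(vapply(seq_len(k), function(c) {
    sum((x[labels == c, , drop = FALSE] -
           matrix(centers[c, ], sum(labels == c), ncol(x), byrow = TRUE))^2)
  }, numeric(1)))
  (b / (k - 1)) / (w / (n - k))
}

#' Fit the PCA + k-means functional cluster model
#'
#' Projects the training matrix onto its first `n_pcs` principal
#' components and runs seeded multi-restart k-means for every `k` in
#' `k_range`, scoring each solution with the mean silhouette coefficient
#' (on squared-Euclidean distances, matching the clustering metric), the
#' Davies-Bouldin index and the Calinski-Harabasz index. The selected
#' `k` is the silhouette argmax.
#'
#' @param x training matrix from [build_training_matrix()].
#' @param k_range candidate cluster counts (`k >= 2`).
#' @param n_pcs number of principal components.
#' @param n_starts k-means restarts.
#' @param seed integer seed.
#' @return a `cluster_model`: list with `pca` (prcomp), `n_pcs`,
#'   `variance_explained`, `scores`, `k`, `centers` (in PC space),
#'   `labels`, `validation` (data.frame of indices per k).
#' @export
fit_cluster_model <- function(x, k_range = 2:20, n_pcs = 12, n_starts = 20,
                              seed = 1) {
  stopifnot(all(k_range >= 2), nrow(x) >= max(k_range) * 10)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (any(pca$sdev[seq_len(n_pcs)] == 0)) stop("degenerate principal components")
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  varexp <- sum(pca$sdev[seq_len(n_pcs)]^2) / sum(pca$sdev^2)
  d2 <- stats::dist(scores)^2
  fits <- list()
  val <- do.call(rbind, lapply(k_range, function(k) {
    km <- with_seed(stage_seed(seed, paste0("kmeans-", k)),
                    stats::kmeans(scores, centers = k, nstart = n_starts,
                                  iter.max = 100))
    fits[[as.character(k)]] <<- km
    sil <- mean(cluster::silhouette(km$cluster, d2)[, "sil_width"])
    data.frame(k = k, silhouette = sil,
               davies_bouldin = davies_bouldin(scores, km$cluster, km$centers),
               calinski_harabasz = calinski_harabasz(scores, km$cluster,
                                                     km$centers))
  }))
  best_k <- val$k[which.max(val$silhouette)]
  km <- fits[[as.character(best_k)]]
  structure(
    list(pca = pca, n_pcs = n_pcs, variance_explained = varexp,
         scores = scores, k = best_k, centers = km$centers,
         labels = km$cluster, validation = val),
    class = "cluster_model"
  )
}

#' Assign response vectors to the nearest cluster centroid
#'
#' Projects new (row-normalized) response vectors into the model's PC
#' space and assigns each to the nearest centroid (squared-Euclidean;
#' exact ties resolve to the lowest-index centroid). Deterministic and
#' row-order invariant.
#'
#' @param x matrix `(neuron, 60)` of min-max-normalized responses, or a
#'   matrix of PC scores when `is_scores = TRUE`.
#' @param model a `cluster_model`.
#' @param is_scores set `TRUE` if `x` is already in PC space.
#' @return integer cluster labels.
#' @export
assign_to_centroids <- function(x, model, is_scores = FALSE) {
  scores <- if (is_scores) {
    as.matrix(x)
  } else {
    sweep(as.matrix(x), 2, model$pca$center) %*%
      model$pca$rotation[, seq_len(model$n_pcs), drop = FALSE]
  }
  d <- vapply(seq_len(nrow(model$centers)), function(c) {
    rowSums(sweep(scores, 2, model$centers[c, ])^2)
  }, numeric(nrow(scores)))
  if (nrow(scores) == 1) d <- matrix(d, nrow = 1)
  apply(d, 1, which.min)  # which.min resolves ties to the lowest index
}

#' Hierarchically bootstrapped cluster composition per area
#'
#' For each area and bootstrap draw, samples `n_mice` mice with
#' replacement and `n_cells` labeled neurons per mouse with replacement,
#' and tallies cluster proportions. Reports per-area mean proportions,
#' the ratio to the uniform chance level `1/k`, 95% CIs,
#' over/under-representation flags (CI excluding chance), the area-pair
#' Pearson similarity of composition vectors (mean and s.e.m. over
#' bootstraps) and Cohen's d contrasts of the similarity distributions.
#'
#' @param labels integer cluster labels.
#' @param mouse,area per-neuron labels.
#' @param k number of clusters (default `max(labels)`).
#' @param n_boot bootstrap draws.
#' @param n_cells neurons per mouse per draw.
#' @param n_mice mice per draw.
#' @param seed integer seed.
#' @return a `cluster_composition`: list with `composition` (data.frame
#'   `area`, `cluster`, `proportion`, `ratio_to_chance`, `ci_low`,
#'   `ci_high`, `flag`), `similarity_mean`, `similarity_sem` (area x
#'   area matrices), `similarity_boot` (3-D array), `chance`.
#' @export
hb_cluster_proportions <- function(labels, mouse, area, k = max(labels),
                                   n_boot = 1000, n_cells = 150, n_mice = 5,
                                   seed = 1) {
  areas <- unique(area)
  n_area <- length(areas)
  props <- array(NA_real_, dim = c(n_area, k, n_boot),
                 dimnames = list(areas, NULL, NULL))
  with_seed(seed, {
    for (ai in seq_len(n_area)) {
      idx_a <- which(area == areas[ai])
      mice <- unique(mouse[idx_a])
      for (b in seq_len(n_boot)) {
        picked <- sample(mice, n_mice, replace = TRUE)
        lab <- unlist(lapply(picked, function(m) {
          cand <- idx_a[mouse[idx_a] == m]
          labels[cand[sample.int(length(cand), n_cells, replace = TRUE)]]
        }))
        props[ai, , b] <- tabulate(lab, nbins = k) / length(lab)
      }
    }
  })
  chance <- 1 / k
  comp <- do.call(rbind, lapply(seq_len(n_area), function(ai) {
    do.call(rbind, lapply(seq_len(k), function(c) {
      p <- props[ai, c, ]
      lo <- stats::quantile(p, 0.025, names = FALSE)
      hi <- stats::quantile(p, 0.975, names = FALSE)
      data.frame(area = areas[ai], cluster = c, proportion = mean(p),
                 ratio_to_chance = mean(p) / chance,
                 ci_low = lo / chance, ci_high = hi / chance,
                 flag = if (lo > chance) "over" else if (hi < chance) "under"
                 else "ns")
    }))
  }))
  sim_boot <- array(NA_real_, dim = c(n_area, n_area, n_boot),
                    dimnames = list(areas, areas, NULL))
  for (b in seq_len(n_boot)) {
    sim_boot[, , b] <- stats::cor(t(props[, , b]))
  }
  structure(
    list(composition = comp,
         similarity_mean = apply(sim_boot, c(1, 2), mean),
         similarity_sem = apply(sim_boot, c(1, 2), stats::sd) / sqrt(n_boot),
         similarity_boot = sim_boot, chance = chance),
    class = "cluster_composition"
  )
}

#' t-SNE embedding of the training PC scores
#'
#' Two-dimensional t-SNE with a large perplexity (default 120, favoring
#' global structure) and learning rate `n/10`.
#'
#' @param scores matrix of PC scores.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < nrow(scores) / 3`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return matrix `(n, 2)` of embedding coordinates.
#' @export
tsne_embed <- function(scores, perplexity = 120, seed = 1, max_iter = 500) {
  n <- nrow(scores)
  if (perplexity >= n / 3) {
    stop("perplexity (", perplexity, ") must be below n/3 = ", round(n / 3, 1))
  }
  with_seed(seed, {
    Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                 eta = n / 10, max_iter = max_iter, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE)$Y
  })
}
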