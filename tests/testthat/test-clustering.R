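test_that("ward-3 typing recovers planted elongation archetypes with stable names", {
  p <- planted_curves()
  cl <- cluster_elongation(p$curves)
  ari <- mclust::adjustedRandIndex(cl$labels, p$labels)
  expect_gte(ari, 0.95)
  # names derive from mean-curve slopes, independent of index permutation
  maj <- function(planted) names(which.max(table(cl$type[p$labels == planted])))
  expect_equal(maj(1), "non-OS")
  expect_equal(maj(2), "sharp-OS")
  expect_equal(maj(3), "broad-OS")
  expect_error(cluster_elongation(matrix(1, 10, 4)), "distinct")
})

test_that("bootstrapped elongation fractions recover generator mixtures", {
  with_seed(17, {
    n <- 1200
    mouse <- sample(paste0("m", 1:4), n, replace = TRUE)
    area <- rep(c("X", "Y"), each = n / 2)
    # area X: 70% non-OS; area Y: 70% sharp-OS
    mk <- function(kind) switch(kind,
      non = c(1, 0.6, 0.3, 0.1), sharp = c(0.1, 0.3, 0.6, 1),
      broad = c(0.7, 0.7, 0.7, 0.7))
    kind <- ifelse(stats::runif(n) < ifelse(area == "X", 0.7, 0.15), "non",
                   ifelse(stats::runif(n) < ifelse(area == "X", 0.5, 0.82),
                          "sharp", "broad"))
    curves <- t(vapply(kind, mk, numeric(4))) +
      matrix(stats::rnorm(n * 4, 0, 0.05), n, 4)
  })
  fr <- hb_elongation_fractions(curves, mouse, area, n_sub = 8, n_cells = 300,
                                seed = 5)
  expect_equal(sum(fr$fraction[fr$area == "X"]), 1, tolerance = 1e-12)
  expect_equal(sum(fr$fraction[fr$area == "Y"]), 1, tolerance = 1e-12)
  expect_equal(fr$fraction[fr$area == "X" & fr$type == "non-OS"],
               0.7, tolerance = 0.05)
  fr2 <- hb_elongation_fractions(curves, mouse, area, n_sub = 8, n_cells = 300,
                                 seed = 5)
  expect_identical(fr, fr2)
})

test_that("training matrices are row-normalized with a faithful manifest", {
  with_seed(23, {
    amp_iso <- matrix(stats::runif(40 * 30), 40, 30)
    amp_aniso <- matrix(stats::runif(40 * 30), 40, 30)
    amp_iso[5, ] <- 0.3; amp_aniso[5, ] <- 0.3  # constant row
    area <- rep(c("A", "B"), each = 20)
  })
  expect_warning(tm <- build_training_matrix(amp_iso, amp_aniso, area,
                                             n_per_area = 30, seed = 2),
                 "constant-response")
  expect_equal(nrow(tm$x), 60)
  expect_true(all(abs(apply(tm$x, 1, max) - 1) < 1e-12))
  expect_true(all(abs(apply(tm$x, 1, min)) < 1e-12))
  # manifest reconstructs the sample exactly
  full <- cbind(amp_iso, amp_aniso)
  rebuilt <- t(apply(full[tm$manifest$neuron, ], 1, function(r) {
    (r - min(r)) / (max(r) - min(r))
  }))
  expect_equal(unname(tm$x), unname(rebuilt))
  expect_false(5 %in% tm$manifest$neuron)
})

test_that("k-means with silhouette validation recovers planted archetypes", {
  with_seed(29, {
    k_true <- 6
    arch <- matrix(stats::runif(k_true * 60), k_true, 60)
    lab <- rep(seq_len(k_true), each = 40)
    x <- arch[lab, ] + matrix(stats::rnorm(240 * 60, 0, 0.03), 240, 60)
  })
  model <- fit_cluster_model(x, k_range = 2:10, n_pcs = 12, seed = 3)
  expect_equal(model$k, k_true)
  expect_gte(mclust::adjustedRandIndex(model$labels, lab), 0.9)
  expect_true(all(diff(model$pca$sdev) <= 1e-8 + 0))  # decreasing variance
  expect_true(model$variance_explained > 0 && model$variance_explained <= 1)
  # centroid assignment is consistent with training labels and tie-stable
  expect_equal(assign_to_centroids(x, model), unname(model$labels))
  expect_equal(assign_to_centroids(model$scores, model, is_scores = TRUE),
               unname(model$labels))
  perm <- with_seed(5, sample(nrow(x)))
  expect_equal(assign_to_centroids(x[perm, ], model),
               unname(model$labels)[perm])
})

test_that("composition statistics are honest under the null and detect planted bias", {
  with_seed(37, {
    n <- 4000
    area <- sample(c("P", "Q", "R"), n, replace = TRUE)
    mouse <- sample(paste0("m", 1:6), n, replace = TRUE)
    labels <- sample(1:12, n, replace = TRUE)  # uniform: no structure
  })
  comp <- hb_cluster_proportions(labels, mouse, area, k = 12, n_boot = 300,
                                 n_cells = 60, n_mice = 4, seed = 8)
  # proportions sum to 1 within areas
  sums <- tapply(comp$composition$proportion, comp$composition$area, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # uniform labels: the vast majority of CIs include chance
  expect_gte(mean(comp$composition$flag == "ns"), 0.9)
  expect_true(isSymmetric(comp$similarity_mean))
  expect_true(all(abs(diag(comp$similarity_mean) - 1) < 1e-12))
  # planted bias: areas sharing a mixture correlate, opposing mixtures do not
  with_seed(38, {
    bias <- ifelse(area %in% c("P", "Q"),
                   sample(1:3, n, replace = TRUE),
                   sample(10:12, n, replace = TRUE))
    keep <- stats::runif(n) < 0.8
    labels2 <- ifelse(keep, bias, labels)
  })
  comp2 <- hb_cluster_proportions(labels2, mouse, area, k = 12, n_boot = 300,
                                  n_cells = 60, n_mice = 4, seed = 9)
  expect_gt(comp2$similarity_mean["P", "Q"], 0.9)
  expect_lt(comp2$similarity_mean["P", "R"], 0)
  # effect size of the similarity contrast via the bootstrap distributions
  d <- cohens_d(comp2$similarity_boot["P", "Q", ],
                comp2$similarity_boot["P", "R", ])
  expect_equal(d$category, "large")
  over <- comp2$composition[comp2$composition$area == "P" &
                              comp2$composition$cluster %in% 1:3, ]
  expect_true(all(over$flag == "over"))
})

test_that("t-SNE embeds duplicates together, reproducibly, with guarded perplexity", {
  with_seed(43, {
    x <- matrix(stats::rnorm(300 * 5), 300, 5)
    x[2, ] <- x[1, ]  # exact duplicate
  })
  e1 <- tsne_embed(x, perplexity = 20, seed = 4, max_iter = 300)
  e2 <- tsne_embed(x, perplexity = 20, seed = 4, max_iter = 300)
  expect_identical(e1, e2)
  d_dup <- sqrt(sum((e1[1, ] - e1[2, ])^2))
  d_typ <- stats::median(as.matrix(stats::dist(e1))[1, -1])
  expect_lt(d_dup, 0.05 * d_typ)
  expect_error(tsne_embed(x, perplexity = 120), "perplexity")
})
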