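#!/usr/bin/env Rscript
# Functional clustering: ward-3 elongation typing with hierarchically
# bootstrapped per-area type fractions; PCA + k-means on joint
# ISO/ANISO response vectors with silhouette / Davies-Bouldin /
# Calinski-Harabasz validation; per-area cluster composition vs the
# 1/k chance level; area-similarity matrix; t-SNE embedding.

source("analysis/00_config.R")

sim <- load_stage("sim")
qc <- load_stage("qc")
tu <- load_stage("tuning")
pop <- sim$neurons

# elongation typing
ec <- tu$curves
fr <- hb_elongation_fractions(as.matrix(ec[, c("e_inf", "e_60", "e_30", "e_15")]),
                              ec$mouse_id, ec$area,
                              n_sub = analysis_config$elongation$n_sub,
                              n_cells = analysis_config$elongation$n_cells,
                              seed = stage_seed(ROOT_SEED, "elongation"))
write.csv(fr, file.path(OUT_DIR, "elongation_type_fractions.csv"),
          row.names = FALSE)

# joint ISO/ANISO clustering
both <- which(qc[["1"]]$qc$selected & qc[["2"]]$qc$selected)
tm <- build_training_matrix(
  t(vapply(both, function(i) rowMeans(tu$amps[["1"]][i, , , drop = FALSE][1, , ]),
           numeric(30))),
  t(vapply(both, function(i) rowMeans(tu$amps[["2"]][i, , , drop = FALSE][1, , ]),
           numeric(30))),
  pop$area[both], n_per_area = analysis_config$cluster$n_per_area,
  seed = stage_seed(ROOT_SEED, "training"))
model <- fit_cluster_model(tm$x, k_range = analysis_config$cluster$k_range,
                           n_pcs = analysis_config$cluster$n_pcs,
                           seed = stage_seed(ROOT_SEED, "kmeans"))
write.csv(model$validation, file.path(OUT_DIR, "cluster_validation.csv"),
          row.names = FALSE)

labels <- assign_to_centroids(tm$x, model)
compo <- hb_cluster_proportions(labels, pop$mouse_id[both[tm$manifest$neuron]],
                                tm$manifest$area, k = model$k,
                                n_boot = analysis_config$cluster$n_boot,
                                n_cells = analysis_config$cluster$n_cells,
                                n_mice = analysis_config$cluster$n_mice,
                                seed = stage_seed(ROOT_SEED, "composition"))
write.csv(compo$composition, file.path(OUT_DIR, "cluster_composition.csv"),
          row.names = FALSE)
simm <- cbind(area = rownames(compo$similarity_mean),
              as.data.frame(compo$similarity_mean))
write.csv(simm, file.path(OUT_DIR, "area_similarity.csv"), row.names = FALSE)

emb <- tsne_embed(model$scores, perplexity = analysis_config$tsne_perplexity,
                  seed = stage_seed(ROOT_SEED, "tsne"))
write.csv(data.frame(row = seq_len(nrow(emb)), x = emb[, 1], y = emb[, 2],
                     cluster = model$labels, area = tm$manifest$area),
          file.path(OUT_DIR, "tsne_embedding.csv"), row.names = FALSE)

over <- sum(compo$composition$flag == "over")
under <- sum(compo$composition$flag == "under")
message(sprintf(
  "Elongation types per area written; k-means selected k = %d (silhouette argmax), 12-PC variance %.0f%%; composition: %d over- and %d under-represented area-cluster cells.",
  model$k, 100 * model$variance_explained, over, under))
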