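#!/usr/bin/env Rscript
# Stage 5: representational geometry — per-layer PCA, meta-RDM, MDS layer
# trajectories, between/within category separation by depth, and the
# PC-space projection of probe stimuli with selective-unit tuning vectors.

library(selunit)
w <- load_results("results/world.rds")
loc <- load_results("results/localizer.rds")
seed <- w$seed

# The default world plants the same fraction of selective units at every
# depth. Emergent categorical structure — the hierarchy's later stages
# separating categories more than its early stages — needs the fraction of
# selective units to grow with depth, which is also the depth trend the
# trained models show; the trajectory analysis therefore runs on that
# variant of the world.
st_e <- generate_stimulus_set(stimulus_config(), derive_seed(seed, "geo_stim"))
m_e <- build_planted_model(st_e, planted_model_config(rho = c(0.02, 0.05, 0.10)),
                           derive_seed(seed, "geo_model"))
store_e <- forward_activations(m_e, st_e)

traj <- meta_rdm_trajectories(store_e, config = geometry_config())
sep <- embedding_separation(traj$coords)
cat("between/within category distance ratio by layer (emergence world):\n")
print(round(sep, 3))
cat(sprintf("separation %s from layer 1 (%.2f) to layer 3 (%.2f)\n",
            if (sep$ratio[3] > sep$ratio[1]) "grows" else "does not grow",
            sep$ratio[1], sep$ratio[3]))

proj <- pc_projection_map(w$store, w$store, loc$map,
                          domains = c("face", "scene"), layer = 3,
                          config = geometry_config())
cat(sprintf("tuning vectors drawn: %d (domains: %s)\n", nrow(proj$arrows),
            paste(unique(proj$arrows$domain), collapse = ", ")))

persist_results(traj$coords, "results/mds_trajectories.tsv")
persist_results(sep, "results/embedding_separation.tsv")
persist_results(proj$scores, "results/pc_projection_scores.tsv")
persist_results(proj$arrows, "results/pc_projection_arrows.tsv")
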