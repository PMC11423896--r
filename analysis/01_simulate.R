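#!/usr/bin/env Rscript
# Stage 1: build the synthetic world — category-structured stimuli, a
# planted-selectivity hierarchy, its activations, and simulated ROI voxels.
# Later stages load results/world.rds.

library(selunit)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

stimuli <- generate_stimulus_set(stimulus_config(), derive_seed(seed, "stimuli"))
model <- build_planted_model(stimuli, planted_model_config(),
                             derive_seed(seed, "model"))
store <- forward_activations(model, stimuli)
voxels <- simulate_voxel_dataset(store, model$planted[[2]], voxel_config(),
                                 derive_seed(seed, "voxels"))

print(stimuli); print(model); print(voxels)

counts <- as.data.frame(table(split = stimuli$split, category = stimuli$category))
persist_results(counts, "results/stimulus_counts.tsv")
planted <- do.call(rbind, lapply(seq_along(model$planted), function(l)
  data.frame(layer = l, domain = names(model$planted[[l]]),
             n_planted = lengths(model$planted[[l]]))))
persist_results(planted, "results/planted_units.tsv")
persist_results(list(stimuli = stimuli, model = model, store = store,
                     voxels = voxels, seed = seed), "results/world.rds")

cat(sprintf("world built: %d stimuli, %d layers, %d planted units/layer, %d voxels\n",
            nrow(stimuli$features), length(model$layers),
            sum(lengths(model$planted[[1]])), ncol(voxels$responses)))
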