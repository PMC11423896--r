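# Canonical synthetic worlds, built once per test session and cached.
.world_cache <- new.env(parent = emptyenv())

default_world <- function(seed = 1L) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]])) {
    stimuli <- generate_stimulus_set(stimulus_config(), derive_seed(seed, "stim"))
    model <- build_planted_model(stimuli, planted_model_config(),
                                 derive_seed(seed, "model"))
    store <- forward_activations(model, stimuli)
    map <- localize_selective_units(store, localizer_design())
    .world_cache[[key]] <- list(stimuli = stimuli, model = model,
                                store = store, map = map)
  }
  .world_cache[[key]]
}

trained_world <- function(seed = 1L) {
  key <- paste0("t", seed)
  if (is.null(.world_cache[[key]])) {
    w <- default_world(seed)
    rcfg <- readout_config(epochs = 150L, batch_size = 64L, max_lr = 10,
                           initial_lr = 0.2, k = 1L,
                           seed = derive_seed(seed, "readout"))
    feats <- activations(w$store, 3, "post", split = "readout_train")
    labels <- droplevels(w$store$category[w$store$split == "readout_train"])
    w$head <- train_sparse_readout(feats, labels, rcfg)
    .world_cache[[key]] <- w
  }
  .world_cache[[key]]
}

# hand-built activation store for unit tests that need exact control
fake_store <- function(acts, category, split = rep("localizer", length(category))) {
  structure(list(layers = list(list(pre = acts, post = pmax(acts, 0))),
                 category = factor(category),
                 split = factor(split), id = seq_len(nrow(acts)),
                 n_layers = 1L, lesion = NULL),
            class = "activation_store")
}

# brute-force oracle for the non-negative lasso (p <= 3): dense grid search
# over [0, w_max]^p with the intercept profiled out (its optimum given w is
# the mean residual). Vectorized over grid cells.
nnlasso_grid_oracle <- function(X, y, alpha, w_max, n_grid = 41L) {
  grid <- seq(0, w_max, length.out = n_grid)
  cells <- as.matrix(do.call(expand.grid, rep(list(grid), ncol(X))))
  R0 <- y - X %*% t(cells)                    # n x m residuals before intercept
  R0 <- sweep(R0, 2, colMeans(R0))
  obj <- colSums(R0^2) / (2 * nrow(X)) + alpha * rowSums(cells)
  i <- which.min(obj)
  list(objective = obj[i], w = cells[i, ], step = grid[2] - grid[1])
}
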