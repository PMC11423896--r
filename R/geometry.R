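#' Geometry / visualization configuration
#'
#' @param n_comp principal components kept per layer for the meta-RDM
#'   (reference 10).
#' @param mds_dim MDS embedding dimension (reference 2).
#' @param n_pc projection components for the PC-space map (reference 2).
#' @param n_top_units tuning vectors drawn per domain (reference 25).
#' @param scale constant scaling of tuning vectors (reference 2.5e4);
#'   changes arrow lengths only, never their angles.
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(n_comp = 10L, mds_dim = 2L, n_pc = 2L,
                            n_top_units = 25L, scale = 2.5e4) {
  if (n_comp < mds_dim || mds_dim < 1) stop("need n_comp >= mds_dim >= 1")
  if (scale <= 0) stop("scale must be > 0")
  structure(list(n_comp = as.integer(n_comp), mds_dim = as.integer(mds_dim),
                 n_pc = as.integer(n_pc), n_top_units = as.integer(n_top_units),
                 scale = scale),
            class = "geometry_config")
}

# PCA scores with a fixed sign convention: the largest-magnitude loading of
# each component is forced positive, so embeddings are reproducible.
pca_scores_signed <- function(A, n_comp) {
  k <- min(n_comp, ncol(A), nrow(A) - 1L)
  pc <- stats::prcomp(A, center = TRUE, scale. = FALSE, rank. = k)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  list(scores = sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*"),
       rotation = sweep(rot, 2, flip, "*"),
       center = pc$center)
}

#' Meta-RDM MDS trajectories across layers
#'
#' Per layer, probe activations are reduced to `n_comp` principal
#' components; the per-layer score matrices are stacked into an
#' `(n_images * n_layers) x n_comp` matrix whose Pearson-dissimilarity
#' matrix (the meta-RDM) is embedded with classical (Torgerson) MDS. Each
#' image then traces a trajectory through the layers in the embedding.
#' Layers with fewer units than `n_comp` are reduced to their unit count
#' and zero-padded (flagged).
#'
#' @param store an `activation_store` containing the probe split.
#' @param layers >= 2 layer indices.
#' @param config a [geometry_config()].
#' @param stage activation stage.
#' @param split stimulus split embedded (default `"probe"`).
#' @return list: `coords` (data.frame image id, category, layer, and
#'   `mds_dim` coordinate columns), `meta_rdm`, `flagged_layers`.
#' @export
meta_rdm_trajectories <- function(store, layers = seq_len(store$n_layers),
                                  config = geometry_config(), stage = "post",
                                  split = "probe") {
  if (length(layers) < 2) stop("need >= 2 layers")
  keep <- store$split %in% split
  n_img <- sum(keep)
  if (n_img < config$n_comp + 1) stop("probe size must exceed n_comp")
  flagged <- integer(0)
  blocks <- list()
  for (l in layers) {
    A <- activations(store, l, stage, split = split)
    sc <- pca_scores_signed(A, config$n_comp)$scores
    if (ncol(sc) < config$n_comp) {
      flagged <- c(flagged, l)
      sc <- cbind(sc, matrix(0, nrow(sc), config$n_comp - ncol(sc)))
    }
    blocks[[as.character(l)]] <- sc
  }
  stacked <- do.call(rbind, blocks)
  meta <- compute_rdm(stacked)
  emb <- stats::cmdscale(stats::as.dist(meta), k = config$mds_dim)
  coords <- data.frame(image = rep(store$id[keep], length(layers)),
                       category = rep(as.character(store$category[keep]),
                                      length(layers)),
                       layer = rep(layers, each = n_img))
  for (d in seq_len(config$mds_dim)) coords[[paste0("dim", d)]] <- emb[, d]
  list(coords = coords, meta_rdm = meta, flagged_layers = flagged)
}

#' Between/within category separation in an MDS embedding
#'
#' @param coords the `coords` data.frame from [meta_rdm_trajectories()].
#' @return data.frame (layer, within, between, ratio): mean pairwise
#'   embedded distance between categories over mean distance within.
#' @export
embedding_separation <- function(coords) {
  dims <- grep("^dim", names(coords), value = TRUE)
  rows <- lapply(sort(unique(coords$layer)), function(l) {
    cc <- coords[coords$layer == l, ]
    D <- as.matrix(stats::dist(cc[, dims]))
    same <- outer(cc$category, cc$category, "==")
    lt <- lower.tri(D)
    data.frame(layer = l, within = mean(D[lt & same]),
               between = mean(D[lt & !same]),
               ratio = mean(D[lt & !same]) / mean(D[lt & same]))
  })
  do.call(rbind, rows)
}

#' Project probe stimuli and selective-unit tuning vectors into PC space
#'
#' Fits a 2-component PCA on reference activations at one layer, projects
#' the probe activations, and maps each of a domain's `n_top_units` most
#' selective units (by mean contrast t) through the component matrix: a
#' unit's one-hot vector times the `(units x 2)` rotation, scaled by
#' `config$scale`, gives an arrow endpoint from the origin.
#'
#' @param ref_store `activation_store` for the reference split (disjoint
#'   from the probe split).
#' @param probe_store `activation_store` containing the probe split.
#' @param map a `selectivity_map` (t-test method, for the t ranking).
#' @param domains domains whose tuning vectors are drawn.
#' @param layer layer used.
#' @param config a [geometry_config()].
#' @param stage activation stage.
#' @param ref_split,probe_split split tags.
#' @return list: `scores` (probe image id, category, pc1, pc2), `arrows`
#'   (domain, unit, x, y), `flagged` (domains with fewer than
#'   `n_top_units` selective units).
#' @export
pc_projection_map <- function(ref_store, probe_store, map, domains, layer,
                              config = geometry_config(), stage = "post",
                              ref_split = "localizer", probe_split = "probe") {
  ref_ids <- ref_store$id[ref_store$split %in% ref_split]
  probe_ids <- probe_store$id[probe_store$split %in% probe_split]
  if (length(intersect(ref_ids, probe_ids)))
    stop("reference and probe sets must be disjoint")
  A_ref <- activations(ref_store, layer, stage, split = ref_split)
  pca <- pca_scores_signed(A_ref, config$n_pc)
  A_probe <- activations(probe_store, layer, stage, split = probe_split)
  scores <- sweep(A_probe, 2, pca$center) %*% pca$rotation
  sc <- data.frame(image = probe_ids,
                   category = as.character(store_labels(probe_store, probe_split)),
                   pc1 = scores[, 1], pc2 = scores[, 2])
  arrows <- list(); flagged <- character(0)
  for (dn in domains) {
    e <- map$sel[[layer]][[stage]][[dn]]
    idx <- e$indices
    if (length(idx) == 0) { flagged <- c(flagged, dn); next }
    if (length(idx) < config$n_top_units) flagged <- c(flagged, dn)
    top <- idx[order(-e$t_mean)][seq_len(min(config$n_top_units, length(idx)))]
    arrows[[dn]] <- data.frame(domain = dn, unit = top,
                               x = config$scale * pca$rotation[top, 1],
                               y = config$scale * pca$rotation[top, 2])
  }
  list(scores = sc, arrows = do.call(rbind, arrows), flagged = flagged,
       rotation = pca$rotation)
}
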