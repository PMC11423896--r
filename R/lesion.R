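#' Build a lesion spec from a selectivity map
#'
#' @param map a `selectivity_map`.
#' @param domain domain whose selective units are zeroed.
#' @param layers layer indices to lesion (default all).
#' @param stage stage of the map entries used.
#' @param top_fraction optionally lesion only the top fraction of each
#'   layer's selective units, ranked by mean contrast t (e.g. 0.05 or 0.01).
#' @return a [lesion_spec()].
#' @export
domain_lesion <- function(map, domain, layers = seq_along(map$sel),
                          stage = "post", top_fraction = NULL) {
  units <- list()
  for (l in layers) {
    e <- map$sel[[l]][[stage]][[domain]]
    idx <- e$indices
    if (!is.null(top_fraction) && length(idx)) {
      n_keep <- max(1L, ceiling(top_fraction * length(idx)))
      idx <- idx[order(-e$t_mean)][seq_len(min(n_keep, length(idx)))]
    }
    units[[as.character(l)]] <- idx
  }
  lesion_spec(units, provenance = if (is.null(top_fraction)) "domain" else "top_fraction")
}

#' Per-category recognition cost of a lesion
#'
#' Evaluates the frozen readout on unlesioned versus lesioned forward
#' passes (downstream activations recomputed under the lesion) and returns
#' the per-category drop in top-k accuracy in percentage points
#' (baseline - lesioned, so deficits are positive). No retraining occurs.
#'
#' @param model a `planted_model`.
#' @param head a `readout_head` trained on unlesioned features.
#' @param eval_set a `stimulus_set`.
#' @param spec a [lesion_spec()].
#' @param k top-k.
#' @param readout_layer layer feeding the readout (default: last layer).
#' @param split evaluation split (default `"readout_eval"`).
#' @return object of class `cost_profile`: `cost` (named, percentage
#'   points), `baseline`, `lesioned`, `split`.
#' @export
lesion_cost_profile <- function(model, head, eval_set, spec, k = head$config$k,
                                readout_layer = length(model$layers),
                                split = "readout_eval") {
  ev <- stimulus_subset(eval_set, split)
  base <- forward_activations(model, ev)
  les <- forward_activations(model, ev, lesion = spec)
  labels <- ev$category
  acc_b <- topk_accuracy_per_category(head, activations(base, readout_layer, "post"),
                                      labels, k)
  acc_l <- topk_accuracy_per_category(head, activations(les, readout_layer, "post"),
                                      labels, k)
  structure(list(cost = 100 * (acc_b - acc_l), baseline = 100 * acc_b,
                 lesioned = 100 * acc_l, k = k, split = split,
                 provenance = spec$provenance),
            class = "cost_profile")
}

#' @export
print.cost_profile <- function(x, ...) {
  cat("<cost_profile> deficit (percentage points):\n")
  print(round(x$cost, 2))
  invisible(x)
}

#' Cross-validated quantification of the most-affected categories
#'
#' Splits the evaluation stimuli into stratified halves: the `n_top` most
#' affected categories are identified on half A and their mean deficit is
#' quantified on held-out half B, guarding against circularity. Odd
#' per-category counts put the larger half in the identification split.
#'
#' @inheritParams lesion_cost_profile
#' @param n_top number of categories selected.
#' @param seed seed for the stratified split.
#' @return list with `categories` (selected on half A), `holdout_mean_deficit`
#'   (their mean deficit on half B), and both half profiles.
#' @export
crossval_top_affected <- function(model, head, eval_set, spec, n_top,
                                  k = head$config$k, seed = 1L,
                                  readout_layer = length(model$layers),
                                  split = "readout_eval") {
  ev <- stimulus_subset(eval_set, split)
  if (any(table(ev$category) < 2)) stop("need >= 2 eval stimuli per category")
  halves <- with_seed(seed, {
    a <- logical(length(ev$id))
    for (cat_k in levels(ev$category)) {
      ix <- which(ev$category == cat_k)
      n_a <- ceiling(length(ix) / 2)
      a[sample(ix, n_a)] <- TRUE
    }
    a
  })
  subset_rows <- function(keep) {
    out <- ev
    out$features <- ev$features[keep, , drop = FALSE]
    out$category <- ev$category[keep]
    out$split <- ev$split[keep]
    out$id <- ev$id[keep]
    out
  }
  prof_a <- lesion_cost_profile(model, head, subset_rows(halves), spec, k,
                                readout_layer, split)
  prof_b <- lesion_cost_profile(model, head, subset_rows(!halves), spec, k,
                                readout_layer, split)
  sel_cats <- names(sort(prof_a$cost, decreasing = TRUE))[seq_len(min(n_top, length(prof_a$cost)))]
  list(categories = sel_cats,
       holdout_mean_deficit = mean(prof_b$cost[sel_cats]),
       profile_a = prof_a, profile_b = prof_b)
}

#' Pearson similarity of two cost profiles
#'
#' @param p1,p2 `cost_profile`s over the same category set.
#' @return list with `r` (Pearson correlation of per-category deficits) and
#'   `undefined` (TRUE when either profile has zero variance, in which case
#'   `r` is NA rather than NaN).
#' @export
compare_cost_profiles <- function(p1, p2) {
  if (!setequal(names(p1$cost), names(p2$cost)))
    stop("cost profiles cover different category sets")
  a <- p1$cost; b <- p2$cost[names(a)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, undefined = TRUE))
  list(r = stats::cor(a, b), undefined = FALSE)
}

#' Correlation between pre-lesion activation and lesioning cost
#'
#' Correlates the per-category mean pre-lesion activation within a unit set
#' at one layer with the per-category accuracy change (lesioned - baseline,
#' so deficits are negative); categories the lesion hurts most are those
#' the units respond to most, making the expected correlation negative.
#'
#' @param store pre-lesion `activation_store` over the evaluation split.
#' @param units integer unit indices at `layer`.
#' @param cost a `cost_profile`.
#' @param layer layer of the activation profile.
#' @param stage activation stage.
#' @param split split over which the profile is averaged.
#' @return list with `r` and `undefined` (empty unit set or constant
#'   profile).
#' @export
activation_cost_correlation <- function(store, units, cost, layer,
                                        stage = "post", split = "readout_eval") {
  if (length(units) == 0) return(list(r = NA_real_, undefined = TRUE))
  A <- activations(store, layer, stage, split = split)[, units, drop = FALSE]
  labels <- store_labels(store, split)
  cats <- names(cost$cost)
  act_profile <- vapply(cats, function(k) mean(A[labels == k, , drop = FALSE]),
                        numeric(1))
  delta <- -cost$cost  # lesioned - baseline
  if (stats::sd(act_profile) == 0 || stats::sd(delta) == 0)
    return(list(r = NA_real_, undefined = TRUE))
  list(r = stats::cor(act_profile, delta), undefined = FALSE)
}

#' Size-matched random-lesion null distribution
#'
#' Each draw zeroes a uniformly random unit set per layer, size-matched to
#' a reference domain's selective-unit counts, and records the resulting
#' cost profile.
#'
#' @inheritParams lesion_cost_profile
#' @param map a `selectivity_map` giving the size reference.
#' @param reference_domain domain whose per-layer counts are matched.
#' @param n_draws number of random lesions (>= 1).
#' @param seed integer seed (fixed seed -> reproducible draws).
#' @param layers layers to lesion.
#' @param stage map stage.
#' @return list with `profiles` (list of `cost_profile`s), `mean_cost`,
#'   and `sd_cost` (per-category spread across draws).
#' @export
random_lesion_null <- function(model, head, eval_set, map, reference_domain,
                               n_draws, seed, k = head$config$k,
                               layers = seq_along(map$sel), stage = "post",
                               readout_layer = length(model$layers),
                               split = "readout_eval") {
  if (n_draws < 1) stop("n_draws must be >= 1")
  sizes <- vapply(layers, function(l)
    length(map$sel[[l]][[stage]][[reference_domain]]$indices), 1L)
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      units <- list()
      for (j in seq_along(layers)) {
        l <- layers[j]
        n_l <- nrow(model$layers[[l]]$W)
        units[[as.character(l)]] <- sample.int(n_l, min(sizes[j], n_l))
      }
      spec <- lesion_spec(units, provenance = "random")
      list(spec = spec,
           profile = lesion_cost_profile(model, head, eval_set, spec, k,
                                         readout_layer, split))
    })
  })
  profiles <- lapply(draws, `[[`, "profile")
  M <- do.call(rbind, lapply(profiles, function(p) p$cost))
  list(profiles = profiles, specs = lapply(draws, `[[`, "spec"),
       mean_cost = colMeans(M), sd_cost = apply(M, 2, stats::sd))
}

#' Downstream selectivity change after early-layer lesions
#'
#' Lesions a domain's selective units in early layers only and measures the
#' change in mean activation (lesioned - baseline) per probe category
#' within the target layer's domain-selective units.
#'
#' @param model a `planted_model`.
#' @param map a `selectivity_map`.
#' @param domain lesioned / measured domain.
#' @param probe a `stimulus_set` (probe split used).
#' @param early_layers layers receiving the lesion.
#' @param target_layer strictly downstream layer measured.
#' @param stage stage.
#' @param split probe split tag.
#' @param top_fraction optional top-fraction restriction of the lesion.
#' @return named per-category activation delta.
#' @export
downstream_selectivity_change <- function(model, map, domain, probe,
                                          early_layers, target_layer,
                                          stage = "post", split = "probe",
                                          top_fraction = NULL) {
  if (target_layer %in% early_layers)
    stop("target layer must not be among the lesioned early layers")
  if (any(early_layers >= target_layer))
    stop("target layer must be strictly downstream of all early layers")
  spec <- domain_lesion(map, domain, layers = early_layers, stage = stage,
                        top_fraction = top_fraction)
  pr <- stimulus_subset(probe, split)
  base <- forward_activations(model, pr)
  les <- forward_activations(model, pr, lesion = spec)
  units <- selected_units(map, target_layer, domain, stage)
  if (length(units) == 0) stop("no selective units at the target layer")
  labels <- pr$category
  vapply(levels(labels), function(k) {
    ix <- labels == k
    mean(activations(les, target_layer, stage)[ix, units, drop = FALSE]) -
      mean(activations(base, target_layer, stage)[ix, units, drop = FALSE])
  }, numeric(1))
}
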