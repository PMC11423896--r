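#' Localizer design
#'
#' Specifies the in-silico localizer: which domains are mapped to which
#' preferred stimulus category, which categories enter the pairwise
#' contrasts, and the FDR level q applied per contrast.
#'
#' @param domains named character vector, domain label -> preferred category.
#' @param contrast_categories categories entering contrasts (must contain
#'   every preferred category); default: all of them plus object/scrambled
#'   analogs present in the data.
#' @param q FDR level in (0, 1); default 0.05.
#' @return list of class `localizer_design`.
#' @export
localizer_design <- function(domains = c(face = "face", body = "body",
                                         scene = "scene", word = "word"),
                             contrast_categories = NULL, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (!is.null(contrast_categories) && !all(domains %in% contrast_categories))
    stop("every domain's preferred category must be a contrast category")
  structure(list(domains = domains, contrast_categories = contrast_categories, q = q),
            class = "localizer_design")
}

design_contrasts <- function(design, labels) {
  cats <- design$contrast_categories %||% levels(labels)
  missing <- setdiff(cats, levels(labels))
  if (length(missing)) stop(sprintf("contrast categories absent from labels: %s",
                                    paste(missing, collapse = ",")))
  cats
}

#' Per-unit two-sample t contrast
#'
#' Pooled-variance (Student) two-sample t statistic per unit, preferred
#' minus other, with two-sided p values — the classic contrast used by fMRI
#' localizers. Units with zero pooled variance and zero mean difference get
#' t = 0, p = 1; zero pooled variance with a nonzero difference gives a
#' signed infinite t with p = 0.
#'
#' @param acts stimulus x unit activation matrix.
#' @param labels category label per stimulus.
#' @param preferred,other the two categories contrasted.
#' @return list with per-unit `t`, `p`, and the degrees of freedom `df`.
#' @export
contrast_tmap <- function(acts, labels, preferred, other) {
  labels <- as.character(labels)
  i1 <- labels == preferred; i2 <- labels == other
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 == 0) stop(sprintf("category '%s' absent from labels", preferred))
  if (n2 == 0) stop(sprintf("category '%s' absent from labels", other))
  if (n1 < 2 || n2 < 2) stop("need >= 2 stimuli in each contrasted category")
  X1 <- acts[i1, , drop = FALSE]; X2 <- acts[i2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2, m1)^2); v2 <- colSums(sweep(X2, 2, m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  p[t == 0 & se == 0] <- 1
  list(t = t, p = p, df = df)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up BH procedure at level q over one layer-contrast's units; returns
#' the units passing (all hypotheses up to the largest passing rank).
#'
#' @param pvals p values in `[0, 1]`.
#' @param q FDR level.
#' @return logical mask, same length as `pvals` (empty input -> empty mask).
#' @export
bh_fdr_mask <- function(pvals, q) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Localize category-selective units (t contrast + FDR intersection)
#'
#' For each layer, stage, and domain: the preferred category is contrasted
#' against every other contrast category with [contrast_tmap()], each
#' contrast is FDR-masked with [bh_fdr_mask()], and a unit is selective iff
#' it passes FDR with t > 0 in ALL contrasts. Pre- and post-rectification
#' stages are localized separately; preference requirements make domain
#' sets within a layer/stage pairwise disjoint by construction.
#'
#' @param store an `activation_store` containing the localizer split.
#' @param design a [localizer_design()].
#' @param stages stages to localize (default post-rectification only; pass
#'   `c("pre","post")` for both).
#' @param split stimulus split used (default `"localizer"`).
#' @return object of class `selectivity_map`: `sel[[layer]][[stage]][[domain]]`
#'   holds `indices`, per-selected-unit `t_contrasts` (unit x contrast) and
#'   their mean `t_mean`; `unit_t[[layer]][[stage]][[domain]]` holds the
#'   mean-contrast t for every unit (used for selectivity ranking).
#' @export
localize_selective_units <- function(store, design, stages = "post",
                                     split = "localizer") {
  stopifnot(inherits(store, "activation_store"), inherits(design, "localizer_design"))
  if (is.null(store$split) || !any(store$split %in% split))
    stop("localizer split absent from the activation store")
  labels <- store_labels(store, split)
  cats <- design_contrasts(design, labels)
  sel <- list(); unit_t <- list()
  for (l in seq_len(store$n_layers)) {
    sel_l <- list(); ut_l <- list()
    for (st in stages) {
      A <- activations(store, l, st, split = split)
      sel_s <- list(); ut_s <- list()
      for (dn in names(design$domains)) {
        pref <- design$domains[[dn]]
        others <- setdiff(cats, pref)
        tmat <- matrix(NA_real_, ncol(A), length(others),
                       dimnames = list(NULL, others))
        pass <- rep(TRUE, ncol(A))
        for (oc in others) {
          tp <- contrast_tmap(A, labels, pref, oc)
          tmat[, oc] <- tp$t
          pass <- pass & bh_fdr_mask(tp$p, design$q) & (tp$t > 0)
        }
        idx <- unname(which(pass))
        sel_s[[dn]] <- list(indices = idx,
                            t_contrasts = tmat[idx, , drop = FALSE],
                            t_mean = unname(rowMeans(tmat[idx, , drop = FALSE])))
        ut_s[[dn]] <- unname(rowMeans(tmat))
      }
      sel_l[[st]] <- sel_s; ut_l[[st]] <- ut_s
    }
    sel[[l]] <- sel_l; unit_t[[l]] <- ut_l
  }
  structure(list(sel = sel, unit_t = unit_t, design = design,
                 stages = stages, method = "ttest_fdr",
                 n_units = vapply(seq_len(store$n_layers),
                                  function(l) ncol(store$layers[[l]]$post), 1L)),
            class = "selectivity_map")
}

#' @export
print.selectivity_map <- function(x, ...) {
  cat(sprintf("<selectivity_map> method=%s, %d layers, stages: %s\n",
              x$method, length(x$sel), paste(x$stages, collapse = "/")))
  for (l in seq_along(x$sel)) {
    st <- x$stages[length(x$stages)]
    n <- vapply(x$sel[[l]][[st]], function(e) length(e$indices), 1L)
    cat(sprintf("  layer %d (%s): %s\n", l, st,
                paste(sprintf("%s=%d", names(n), n), collapse = " ")))
  }
  invisible(x)
}

#' Selected unit indices for one layer/stage/domain
#' @param map a `selectivity_map`.
#' @param layer layer index.
#' @param domain domain label.
#' @param stage stage (default `"post"`).
#' @return integer unit indices.
#' @export
selected_units <- function(map, layer, domain, stage = "post") {
  e <- map$sel[[layer]][[stage]][[domain]]
  if (is.null(e)) stop(sprintf("no entry for layer %d stage %s domain %s",
                               layer, stage, domain))
  e$indices
}

#' Localize selective units by the 2:1 response-ratio method
#'
#' A unit is selective for a domain iff its mean response to the preferred
#' category is at least `ratio` times its mean response to EACH non-preferred
#' contrast category. Only valid on post-rectification stages where mean
#' responses are non-negative; denominators are floored at `eps` and a unit
#' whose preferred mean is 0 is never selected.
#'
#' @inheritParams localize_selective_units
#' @param ratio required preference ratio (default 2).
#' @param eps denominator floor.
#' @return a `selectivity_map` with method tag `"ratio"`.
#' @export
ratio_localize <- function(store, design, ratio = 2.0, eps = 1e-8,
                           stages = "post", split = "localizer") {
  stopifnot(inherits(store, "activation_store"))
  if (any(stages != "post"))
    stop("ratio method is defined only for post-rectification stages")
  labels <- store_labels(store, split)
  cats <- design_contrasts(design, labels)
  sel <- list()
  for (l in seq_len(store$n_layers)) {
    A <- activations(store, l, "post", split = split)
    means <- vapply(cats, function(k) colMeans(A[labels == k, , drop = FALSE]),
                    numeric(ncol(A)))
    sel_s <- list()
    for (dn in names(design$domains)) {
      pref <- design$domains[[dn]]
      others <- setdiff(cats, pref)
      mp <- means[, pref]
      pass <- mp > 0
      for (oc in others) pass <- pass & (mp >= ratio * pmax(means[, oc], eps))
      idx <- unname(which(pass))
      sel_s[[dn]] <- list(indices = idx,
                          t_contrasts = NULL,
                          t_mean = unname(mp[idx] / pmax(apply(means[, others, drop = FALSE],
                                                               1, max)[idx], eps)))
      }
    sel[[l]] <- list(post = sel_s)
  }
  structure(list(sel = sel, unit_t = NULL, design = design, stages = "post",
                 method = "ratio",
                 n_units = vapply(seq_len(store$n_layers),
                                  function(l) ncol(store$layers[[l]]$post), 1L)),
            class = "selectivity_map")
}

#' Overlap between two selectivity maps (intersection over union)
#'
#' @param m1,m2 `selectivity_map`s over the same model.
#' @param stage stage compared.
#' @return data.frame with per layer x domain IoU of selected unit indices.
#' @export
selectivity_overlap <- function(m1, m2, stage = "post") {
  rows <- list()
  for (l in seq_along(m1$sel)) {
    for (dn in names(m1$sel[[l]][[stage]])) {
      a <- m1$sel[[l]][[stage]][[dn]]$indices
      b <- m2$sel[[l]][[stage]][[dn]]$indices
      u <- length(union(a, b))
      rows[[length(rows) + 1L]] <-
        data.frame(layer = l, domain = dn,
                   iou = if (u == 0) NA_real_ else length(intersect(a, b)) / u,
                   n1 = length(a), n2 = length(b))
    }
  }
  do.call(rbind, rows)
}

#' Probe-set generalization of localized selectivity
#'
#' Recomputes contrast t statistics on an independent probe split,
#' restricted to the previously selected units, and reports per domain the
#' fraction of selected units with positive mean probe t and the
#' correlation between localizer and probe t across the selected units.
#'
#' @param map a `selectivity_map` from the localizer split.
#' @param probe_store an `activation_store` containing the probe split.
#' @param design the [localizer_design()].
#' @param stage stage examined.
#' @param split probe split tag.
#' @return data.frame (layer, domain, n_units, frac_positive, r, undefined);
#'   empty selective sets are flagged undefined rather than scored zero.
#' @export
generalization_check <- function(map, probe_store, design, stage = "post",
                                 split = "probe") {
  labels <- store_labels(probe_store, split)
  cats <- design_contrasts(design, labels)
  rows <- list()
  for (l in seq_along(map$sel)) {
    for (dn in names(design$domains)) {
      e <- map$sel[[l]][[stage]][[dn]]
      if (length(e$indices) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          layer = l, domain = dn, n_units = 0L, frac_positive = NA_real_,
          r = NA_real_, undefined = TRUE)
        next
      }
      A <- activations(probe_store, l, stage, split = split)[, e$indices, drop = FALSE]
      pref <- design$domains[[dn]]
      others <- setdiff(cats, pref)
      tmat <- vapply(others, function(oc) contrast_tmap(A, labels, pref, oc)$t,
                     numeric(ncol(A)))
      probe_t <- rowMeans(matrix(tmat, ncol = length(others)))
      rows[[length(rows) + 1L]] <- data.frame(
        layer = l, domain = dn, n_units = length(e$indices),
        frac_positive = mean(probe_t > 0),
        r = if (length(e$indices) >= 3 && stats::sd(e$t_mean) > 0 &&
                stats::sd(probe_t) > 0) stats::cor(e$t_mean, probe_t) else NA_real_,
        undefined = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Depth trends of selectivity
#'
#' Per-layer proportions of selective units per domain, plus Spearman rank
#' correlations between layer index and (a) the total proportion selective,
#' (b) the mean t of selective units.
#'
#' @param map a `selectivity_map` (t-test method) over >= 3 layers.
#' @param stage stage summarized.
#' @return list with `by_layer` (data.frame) and `spearman` (named vector
#'   `prop`, `t`).
#' @export
selectivity_summary <- function(map, stage = "post") {
  if (length(map$sel) < 3) stop("need >= 3 layers for depth trends")
  rows <- list()
  for (l in seq_along(map$sel)) {
    entries <- map$sel[[l]][[stage]]
    for (dn in names(entries)) {
      e <- entries[[dn]]
      rows[[length(rows) + 1L]] <- data.frame(
        layer = l, domain = dn, n_selective = length(e$indices),
        proportion = length(e$indices) / map$n_units[l],
        mean_t = if (length(e$indices)) mean(e$t_mean) else NA_real_)
    }
  }
  by_layer <- do.call(rbind, rows)
  tot <- stats::aggregate(proportion ~ layer, by_layer, sum)
  mt <- stats::aggregate(mean_t ~ layer, by_layer[!is.na(by_layer$mean_t), ], mean)
  sp_prop <- if (stats::sd(tot$proportion) > 0)
    stats::cor(tot$layer, tot$proportion, method = "spearman") else NA_real_
  sp_t <- if (nrow(mt) >= 3 && stats::sd(mt$mean_t) > 0)
    stats::cor(mt$layer, mt$mean_t, method = "spearman") else NA_real_
  list(by_layer = by_layer, spearman = c(prop = sp_prop, t = sp_t))
}

#' Precision/recall of recovered selectivity against planted ground truth
#'
#' @param map a `selectivity_map`.
#' @param model the generating `planted_model`.
#' @param stage stage compared.
#' @return data.frame (layer, domain, n_planted, n_recovered, precision,
#'   recall).
#' @export
recovery_scores <- function(map, model, stage = "post") {
  rows <- list()
  for (l in seq_along(map$sel)) {
    for (dn in names(model$planted[[l]])) {
      truth <- model$planted[[l]][[dn]]
      got <- map$sel[[l]][[stage]][[dn]]$indices
      tp <- length(intersect(truth, got))
      rows[[length(rows) + 1L]] <- data.frame(
        layer = l, domain = dn, n_planted = length(truth), n_recovered = length(got),
        precision = if (length(got)) tp / length(got) else NA_real_,
        recall = if (length(truth)) tp / length(truth) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
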