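#' Default stimulus configuration
#'
#' Describes a category-structured stimulus world. Each template category k
#' has a unit-norm template t_k drawn from a random orthonormal frame;
#' stimulus features are `category_signal * t_k + sigma_w * z` with
#' `z ~ N(0, I/d)`, so `sigma_w` is (approximately) the norm of the
#' within-category jitter. A "scrambled" category, when requested, is pure
#' isotropic jitter with no template and only appears in the localizer and
#' probe splits. The probe split re-draws jitter at its own `probe_sigma_w`,
#' emulating a distribution-shifted probe image set.
#'
#' `category_signal` sets the between- over within-category contrast seen by
#' a random linear readout of the features. The default 0.075 (with
#' sigma_w = 0.2 and 20 localizer stimuli per category) is calibrated from
#' two constraints: per-category mean features must still correlate > 0.8
#' with their template (correlation ~ c / sqrt(c^2 + sigma_w^2/n)), while
#' unplanted units must sit near the null under the localizer t contrast
#' (background t-SD ~ c * sqrt(n) / sigma_w ~ 1.5), so that planted
#' selectivity is recoverable against ground truth. `category_signal = 0`
#' yields an unstructured null world in which category labels carry no
#' signal (used for FDR calibration).
#'
#' @param categories character vector of template category names.
#' @param input_dim feature dimensionality (must be >= number of template
#'   categories).
#' @param sigma_w within-category jitter in `[0, 1)`.
#' @param probe_sigma_w jitter of the probe split.
#' @param category_signal template coefficient (>= 0).
#' @param scrambled add an isotropic "scrambled" category to the localizer
#'   and probe splits.
#' @param splits named integer vector: stimuli per category for each split.
#' @return a list of class `stimulus_config`.
#' @export
stimulus_config <- function(categories = c("face", "body", "scene", "word",
                                           "object", "tool", "animal", "vehicle"),
                            input_dim = 64L,
                            sigma_w = 0.2,
                            probe_sigma_w = 0.3,
                            category_signal = 0.075,
                            scrambled = TRUE,
                            splits = c(localizer = 20L, probe = 12L,
                                       readout_train = 24L, readout_eval = 16L,
                                       enc_train = 40L, enc_val = 20L, enc_test = 20L)) {
  cfg <- list(categories = categories, input_dim = as.integer(input_dim),
              sigma_w = sigma_w, probe_sigma_w = probe_sigma_w,
              category_signal = category_signal, scrambled = scrambled,
              splits = splits)
  class(cfg) <- "stimulus_config"
  cfg
}

#' Generate a category-structured stimulus set
#'
#' @param config a [stimulus_config()].
#' @param seed integer seed; identical config + seed reproduce the set
#'   bitwise.
#' @return object of class `stimulus_set` with fields `features`
#'   (n x input_dim), `category`, `split` (factors per row), `id` (integer
#'   stimulus ids), and the template frame used.
#' @export
generate_stimulus_set <- function(config, seed) {
  stopifnot(inherits(config, "stimulus_config"))
  K <- length(config$categories)
  d <- config$input_dim
  if (K < 2) stop("need >= 2 categories")
  if (d < K) stop("input_dim < n_categories: cannot build near-orthogonal templates")
  if (any(config$splits < 1)) stop("non-positive split size")
  if (config$sigma_w < 0 || config$sigma_w >= 1) stop("sigma_w must be in [0, 1)")
  if (config$category_signal < 0) stop("category_signal must be >= 0")

  with_seed(seed, {
    templates <- qr.Q(qr(matrix(stats::rnorm(d * K), d, K)))
    colnames(templates) <- config$categories

    scr_splits <- c("localizer", "probe")
    rows <- list(); cat_lab <- character(0); split_lab <- character(0)
    for (sp in names(config$splits)) {
      n <- config$splits[[sp]]
      sw <- if (sp == "probe") config$probe_sigma_w else config$sigma_w
      cats <- config$categories
      if (isTRUE(config$scrambled) && sp %in% scr_splits) cats <- c(cats, "scrambled")
      for (k in cats) {
        z <- matrix(stats::rnorm(n * d, sd = 1 / sqrt(d)), n, d)
        x <- if (k == "scrambled") sw * z
             else matrix(config$category_signal * templates[, k], n, d, byrow = TRUE) + sw * z
        rows[[length(rows) + 1L]] <- x
        cat_lab <- c(cat_lab, rep(k, n))
        split_lab <- c(split_lab, rep(sp, n))
      }
    }
    features <- do.call(rbind, rows)
    stopifnot_finite(features, "stimulus features")
    out <- list(features = features,
                category = factor(cat_lab),
                split = factor(split_lab, levels = names(config$splits)),
                id = seq_len(nrow(features)),
                templates = templates,
                config = config, seed = as.integer(seed))
    class(out) <- "stimulus_set"
    out
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli x %d dims, %d categories, splits: %s\n",
              nrow(x$features), ncol(x$features), nlevels(x$category),
              paste(levels(x$split), collapse = "/")))
  invisible(x)
}

#' Subset a stimulus set by split
#'
#' @param stimuli a `stimulus_set`.
#' @param split split tag(s) to keep.
#' @return a `stimulus_set` restricted to those rows (ids preserved).
#' @export
stimulus_subset <- function(stimuli, split) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  keep <- stimuli$split %in% split
  if (!any(keep)) stop(sprintf("no stimuli in split(s) %s", paste(split, collapse = ",")))
  out <- stimuli
  out$features <- stimuli$features[keep, , drop = FALSE]
  out$category <- droplevels(stimuli$category[keep])
  out$split <- stimuli$split[keep]
  out$id <- stimuli$id[keep]
  out
}
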