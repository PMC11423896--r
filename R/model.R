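#' Planted-selectivity model configuration
#'
#' A stack of fully connected layers with rectification, in which a known
#' fraction `rho` of each layer's units is "planted" to prefer one stimulus
#' domain with gain `g`. Planted construction: a planted unit's weight row is
#' a background-distributed random row plus `g` times the unit-norm *centered*
#' mean previous-layer response direction for its domain (the domain's mean
#' calibration response minus the grand mean, computed on the localizer
#' split — centering stops the gain being spent on the layer's shared
#' baseline, which would starve deep layers of contrast), with a bias
#' cancelling the projection of the mean non-preferred response so the unit
#' rests near zero for non-preferred input; row and bias are then rescaled by `1/sqrt(1+g^2)` so
#' planted output magnitudes match background units (rescaling does not
#' change the unit's selectivity statistics).
#'
#' The random connectivity fabric is modular with respect to the planted
#' circuit: every unit's *random* weight component is zero on the previous
#' layer's planted units (remaining entries rescaled to preserve total
#' variance), so planted selectivity propagates only through the calibrated
#' `g * dir` component of deeper planted units and never leaks into
#' background units. This keeps the planted masks a crisp ground truth —
#' without it, random downstream units genuinely inherit category
#' preference and recovery against the masks is ill-posed. With `g = 0`
#' the construction reduces exactly to the background distribution.
#'
#' @param n_layers number of layers (>= 2).
#' @param n_units units per layer (scalar or length `n_layers`).
#' @param rho planted fraction per domain per layer, in `[0, 0.5]` (scalar
#'   or per layer).
#' @param gain planted selectivity gain g >= 0.
#' @param tuning_jitter within-domain tuning diversity kappa >= 0: each
#'   planted unit's direction is `normalize(dir + kappa * xi_i)` with its
#'   own random unit vector `xi_i`, so units of a domain share the category
#'   preference but differ in sub-tuning (as real selective units do). This
#'   is what makes a voxel's source units identifiable to the encoding
#'   model; with `kappa = 0` a domain's planted units are clones and sparse
#'   source recovery is ill-posed.
#' @param domains named character vector mapping domain label to preferred
#'   stimulus category.
#' @return list of class `planted_model_config`.
#' @export
planted_model_config <- function(n_layers = 3L, n_units = 200L, rho = 0.05,
                                 gain = 4, tuning_jitter = 1,
                                 domains = c(face = "face", body = "body",
                                             scene = "scene", word = "word")) {
  if (tuning_jitter < 0) stop("tuning_jitter must be >= 0")
  cfg <- list(n_layers = as.integer(n_layers),
              n_units = rep_len(as.integer(n_units), n_layers),
              rho = rep_len(rho, n_layers), gain = gain,
              tuning_jitter = tuning_jitter, domains = domains)
  class(cfg) <- "planted_model_config"
  cfg
}

#' Build a planted-selectivity feature hierarchy
#'
#' Layers are built sequentially: each layer's planted directions are
#' calibrated on the previous layer's (possibly already planted) responses
#' to the localizer split, so selectivity propagates through depth the way
#' it would in a trained hierarchy. Ground-truth planted masks are recorded
#' per layer and domain and are pairwise disjoint within a layer.
#'
#' @param stimuli a `stimulus_set` providing the calibration (localizer)
#'   split.
#' @param config a [planted_model_config()].
#' @param seed integer seed.
#' @return object of class `planted_model`: `layers` (list of `W`, `b`),
#'   `planted` (per layer, named list domain -> unit indices), plus config.
#' @export
build_planted_model <- function(stimuli, config, seed) {
  stopifnot(inherits(stimuli, "stimulus_set"), inherits(config, "planted_model_config"))
  if (config$n_layers < 2) stop("need >= 2 layers")
  if (any(config$rho < 0 | config$rho > 0.5)) stop("rho must be in [0, 0.5]")
  if (config$gain < 0) stop("gain must be >= 0")
  domains <- config$domains
  if (!all(domains %in% levels(stimuli$category)))
    stop("every domain's preferred category must exist in the stimulus set")

  loc <- stimulus_subset(stimuli, "localizer")
  g <- config$gain
  scale_p <- 1 / sqrt(1 + g^2)

  with_seed(seed, {
    A <- loc$features
    layers <- list(); planted <- list(); prev_planted <- integer(0)
    for (l in seq_len(config$n_layers)) {
      n <- config$n_units[l]
      fan_in <- ncol(A)
      n_plant <- floor(config$rho[l] * n)
      if (config$rho[l] > 0 && n_plant < 1)
        stop(sprintf("layer %d: rho * n_units < 1, no units to plant", l))
      W <- matrix(stats::rnorm(n * fan_in, sd = 1 / sqrt(fan_in)), n, fan_in)
      b <- numeric(n)
      if (length(prev_planted)) {
        W[, prev_planted] <- 0
        W <- W * sqrt(fan_in / (fan_in - length(prev_planted)))
      }
      # disjoint planted masks across domains
      pool <- sample.int(n, n_plant * length(domains))
      masks <- split(pool, rep(seq_along(domains), each = n_plant))
      names(masks) <- names(domains)
      for (dn in names(domains)) {
        idx <- sort(masks[[dn]])
        masks[[dn]] <- idx
        m_d <- colMeans(A[loc$category == domains[[dn]], , drop = FALSE])
        m_o <- colMeans(A[loc$category != domains[[dn]], , drop = FALSE])
        v <- m_d - colMeans(A)
        nrm <- sqrt(sum(v^2))
        dir <- if (nrm > 1e-12) v / nrm else numeric(fan_in)
        kappa <- config$tuning_jitter
        for (u in idx) {
          xi <- stats::rnorm(fan_in)
          xi <- xi / sqrt(sum(xi^2))
          dir_u <- dir + kappa * xi
          dir_u <- dir_u / sqrt(sum(dir_u^2))
          W[u, ] <- scale_p * (W[u, ] + g * dir_u)
          b[u] <- scale_p * (-g * sum(dir_u * m_o))
        }
      }
      layers[[l]] <- list(W = W, b = b)
      planted[[l]] <- masks
      prev_planted <- sort(unlist(masks))
      A <- relu(A %*% t(W) + matrix(b, nrow(A), n, byrow = TRUE))
    }
    out <- list(layers = layers, planted = planted, gain = g,
                domains = domains, input_dim = ncol(stimuli$features),
                config = config, seed = as.integer(seed))
    class(out) <- "planted_model"
    out
  })
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("<planted_model> %d layers (%s units), gain g=%g, domains: %s\n",
              length(x$layers), paste(vapply(x$layers, function(l) nrow(l$W), 1L),
                                      collapse = "/"),
              x$gain, paste(names(x$domains), collapse = ",")))
  invisible(x)
}

#' Construct a lesion specification
#'
#' @param units named list: layer index (as character or integer name) ->
#'   integer unit indices whose post-rectification outputs are zeroed.
#' @param provenance free tag (`"domain"`, `"random"`, `"top_fraction"`, ...).
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(units = list(), provenance = "domain") {
  units <- units[lengths(units) > 0]
  if (length(units)) {
    names(units) <- as.character(as.integer(names(units)))
    for (nm in names(units)) {
      ix <- as.integer(units[[nm]])
      if (anyDuplicated(ix)) stop("duplicate unit indices in lesion spec")
      units[[nm]] <- ix
    }
  }
  structure(list(units = units, provenance = provenance), class = "lesion_spec")
}

validate_lesion <- function(spec, model) {
  if (is.null(spec)) return(invisible(NULL))
  stopifnot(inherits(spec, "lesion_spec"))
  for (nm in names(spec$units)) {
    l <- as.integer(nm)
    if (is.na(l) || l < 1 || l > length(model$layers))
      stop(sprintf("lesion references unknown layer %s", nm))
    n <- nrow(model$layers[[l]]$W)
    if (any(spec$units[[nm]] < 1 | spec$units[[nm]] > n))
      stop(sprintf("lesion unit index out of range for layer %d", l))
  }
  invisible(NULL)
}

#' Forward pass through a planted model
#'
#' Computes pre- and post-rectification activations at every layer, treating
#' the two as distinct computational stages. Under a lesion, the masked
#' units' post-rectification outputs are forced to zero before propagation,
#' so all downstream activations are recomputed under the lesion.
#'
#' @param model a `planted_model`.
#' @param stimuli a `stimulus_set` or a numeric feature matrix.
#' @param lesion optional [lesion_spec()].
#' @return object of class `activation_store`: `layers[[l]]$pre` / `$post`
#'   (stimulus x unit matrices), with the stimulus annotations carried over.
#' @export
forward_activations <- function(model, stimuli, lesion = NULL) {
  stopifnot(inherits(model, "planted_model"))
  validate_lesion(lesion, model)
  if (inherits(stimuli, "stimulus_set")) {
    X <- stimuli$features; category <- stimuli$category
    split <- stimuli$split; id <- stimuli$id
  } else {
    X <- as.matrix(stimuli); category <- NULL; split <- NULL; id <- seq_len(nrow(X))
  }
  if (ncol(X) != model$input_dim) stop("stimulus dimension does not match model input")
  layers <- vector("list", length(model$layers))
  A <- X
  for (l in seq_along(model$layers)) {
    W <- model$layers[[l]]$W; b <- model$layers[[l]]$b
    pre <- A %*% t(W) + matrix(b, nrow(A), length(b), byrow = TRUE)
    post <- relu(pre)
    if (!is.null(lesion)) {
      ix <- lesion$units[[as.character(l)]]
      if (length(ix)) post[, ix] <- 0
    }
    layers[[l]] <- list(pre = pre, post = post)
    A <- post
  }
  out <- list(layers = layers, category = category, split = split, id = id,
              n_layers = length(layers),
              lesion = lesion)
  class(out) <- "activation_store"
  out
}

#' @export
print.activation_store <- function(x, ...) {
  cat(sprintf("<activation_store> %d stimuli, %d layers%s\n",
              nrow(x$layers[[1]]$post), x$n_layers,
              if (!is.null(x$lesion)) " (lesioned)" else ""))
  invisible(x)
}

#' Extract one stage's activation matrix
#'
#' @param store an `activation_store`.
#' @param layer layer index.
#' @param stage `"pre"` or `"post"` rectification.
#' @param split optional split tag(s) to restrict rows to.
#' @return stimulus x unit matrix (with matching `category` attribute rows
#'   when restricted).
#' @export
activations <- function(store, layer, stage = "post", split = NULL) {
  stopifnot(inherits(store, "activation_store"))
  stage <- match.arg(stage, c("pre", "post"))
  M <- store$layers[[layer]][[stage]]
  if (!is.null(split)) {
    if (is.null(store$split)) stop("store carries no split annotations")
    M <- M[store$split %in% split, , drop = FALSE]
  }
  M
}

store_labels <- function(store, split = NULL) {
  lab <- store$category
  if (!is.null(split)) lab <- droplevels(lab[store$split %in% split])
  lab
}
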