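#' Voxel simulation configuration
#'
#' Simulated ROI voxels are noisy sparse non-negative mixtures of a domain's
#' true selective units: a voxel's noiseless response to a stimulus is
#' `w . a(stimulus)` with `w >= 0` supported on `s` units drawn from the
#' domain's planted units in one model layer. Trials (R repeats per
#' stimulus, shuffled so repeats can fall in different sessions) are split
#' into contiguous sessions; each session applies a multiplicative gain and
#' additive offset to the signal before trial noise `N(0, noise_sd^2)` is
#' added. Signals are standardized to unit variance across stimuli before
#' corruption so `noise_sd` is on the signal-SD scale and the reliability of
#' a voxel is directly controlled.
#'
#' @param layer source model layer.
#' @param stage activation stage, post-rectification by default.
#' @param n_voxels voxels per ROI domain.
#' @param s support size of the true mixing weights.
#' @param repeats R, presentations per stimulus (>= 2; default 3).
#' @param n_sessions number of contiguous session blocks.
#' @param noise_sd trial noise SD (>= 0), in units of signal SD.
#' @param gain_sd log-SD of the per-session multiplicative gain.
#' @param offset_sd SD of the per-session additive offset.
#' @param splits stimulus splits presented to the simulated subject.
#' @param shuffle_trials permute trial order (repeats cross sessions).
#' @return list of class `voxel_config`.
#' @export
voxel_config <- function(layer = 2L, stage = "post", n_voxels = 20L, s = 5L,
                         repeats = 3L, n_sessions = 4L, noise_sd = 1,
                         gain_sd = 0.2, offset_sd = 0.5,
                         splits = c("enc_train", "enc_val", "enc_test"),
                         shuffle_trials = TRUE) {
  cfg <- list(layer = as.integer(layer), stage = stage,
              n_voxels = as.integer(n_voxels), s = as.integer(s),
              repeats = as.integer(repeats), n_sessions = as.integer(n_sessions),
              noise_sd = noise_sd, gain_sd = gain_sd, offset_sd = offset_sd,
              splits = splits, shuffle_trials = shuffle_trials)
  class(cfg) <- "voxel_config"
  cfg
}

#' Simulate a trial-level voxel dataset with known ground truth
#'
#' @param store an `activation_store` holding responses to the encoding
#'   stimuli.
#' @param truth_masks per-domain unit masks for the source layer (named list
#'   domain -> unit indices), typically `model$planted[[layer]]`.
#' @param config a [voxel_config()].
#' @param seed integer seed.
#' @return object of class `voxel_dataset`: `responses` (trials x voxels),
#'   `session_id`, `stimulus_id`, `repeat_index` per trial, `roi_domain` per
#'   voxel, `truth_weights` (units x voxels, >= 0, support size <= s).
#' @export
simulate_voxel_dataset <- function(store, truth_masks, config, seed) {
  stopifnot(inherits(store, "activation_store"), inherits(config, "voxel_config"))
  if (config$noise_sd < 0) stop("noise_sd must be >= 0")
  if (config$s < 1) stop("support size s must be >= 1")
  if (config$repeats < 2) stop("need R >= 2 repeats")
  A <- activations(store, config$layer, config$stage, split = config$splits)
  keep <- store$split %in% config$splits
  stim_id <- store$id[keep]
  stim_cat <- store$category[keep]
  stim_split <- droplevels(store$split[keep])
  n_stim <- length(stim_id)
  domains <- names(truth_masks)
  for (dn in domains)
    if (length(truth_masks[[dn]]) < config$s)
      stop(sprintf("domain %s has fewer than s=%d source units", dn, config$s))

  with_seed(seed, {
    R <- config$repeats
    order_idx <- rep(seq_len(n_stim), R)
    if (isTRUE(config$shuffle_trials)) order_idx <- sample(order_idx)
    n_trials <- length(order_idx)
    sess_len <- ceiling(n_trials / config$n_sessions)
    session_id <- rep(seq_len(config$n_sessions), each = sess_len)[seq_len(n_trials)]
    gains <- exp(stats::rnorm(config$n_sessions, 0, config$gain_sd))
    offsets <- stats::rnorm(config$n_sessions, 0, config$offset_sd)

    n_vox <- config$n_voxels * length(domains)
    roi_domain <- rep(domains, each = config$n_voxels)
    W <- matrix(0, ncol(A), n_vox)
    signal <- matrix(0, n_stim, n_vox)
    for (v in seq_len(n_vox)) {
      support <- sample(truth_masks[[roi_domain[v]]], config$s)
      w <- stats::rexp(config$s)
      sig <- as.numeric(A[, support, drop = FALSE] %*% w)
      sd_sig <- stats::sd(sig)
      if (sd_sig > 1e-12) { w <- w / sd_sig; sig <- sig / sd_sig }
      W[support, v] <- w
      signal[, v] <- sig
    }
    resp <- gains[session_id] * signal[order_idx, , drop = FALSE] +
      offsets[session_id] +
      matrix(stats::rnorm(n_trials * n_vox, 0, config$noise_sd), n_trials, n_vox)

    rep_index <- stats::ave(order_idx, order_idx, FUN = seq_along)
    out <- list(responses = resp,
                session_id = session_id,
                stimulus_id = stim_id[order_idx],
                repeat_index = as.integer(rep_index),
                roi_domain = roi_domain,
                truth_weights = W,
                stim_meta = data.frame(id = stim_id, category = stim_cat,
                                       split = stim_split),
                layer = config$layer, stage = config$stage,
                noise_sd = config$noise_sd,
                session_gain = gains, session_offset = offsets,
                config = config, seed = as.integer(seed))
    class(out) <- "voxel_dataset"
    out
  })
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("<voxel_dataset> %d trials x %d voxels, %d sessions, noise_sd=%g\n",
              nrow(x$responses), ncol(x$responses),
              length(unique(x$session_id)), x$noise_sd))
  invisible(x)
}
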