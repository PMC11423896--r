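#' Z-score voxel responses within sessions
#'
#' Per voxel and session, responses are centered and scaled to unit sample
#' SD, removing per-session affine instabilities before repeat averaging.
#' Session-voxel cells with zero variance are left at 0 and counted in the
#' `flagged` attribute.
#'
#' @param data a `voxel_dataset` (every session needs >= 2 trials).
#' @return the dataset with z-scored `responses`.
#' @export
session_zscore <- function(data) {
  stopifnot(inherits(data, "voxel_dataset"))
  R <- data$responses
  flagged <- 0L
  for (s in unique(data$session_id)) {
    ix <- data$session_id == s
    if (sum(ix) < 2) stop("every session needs >= 2 trials")
    M <- R[ix, , drop = FALSE]
    mu <- colMeans(M)
    sd_ <- apply(M, 2, stats::sd)
    zero <- sd_ <= 0
    flagged <- flagged + sum(zero)
    sd_[zero] <- 1
    R[ix, ] <- sweep(sweep(M, 2, mu), 2, sd_, "/")
    if (any(zero)) R[ix, zero] <- 0
  }
  data$responses <- R
  attr(data, "zscored") <- TRUE
  attr(data, "flagged_zero_variance") <- flagged
  data
}

#' Average responses across stimulus repeats
#'
#' @param data a `voxel_dataset`, typically after [session_zscore()].
#' @param stimulus_ids optional stimulus ids to average (default: all
#'   present); an id absent from the data is an error.
#' @return stimulus x voxel matrix, rownames = stimulus ids (ascending).
#' @export
average_repeats <- function(data, stimulus_ids = NULL) {
  stopifnot(inherits(data, "voxel_dataset"))
  ids <- sort(unique(data$stimulus_id))
  if (!is.null(stimulus_ids)) {
    missing <- setdiff(stimulus_ids, ids)
    if (length(missing)) stop(sprintf("stimulus id(s) missing from dataset: %s",
                                      paste(missing, collapse = ",")))
    ids <- sort(stimulus_ids)
  }
  out <- matrix(NA_real_, length(ids), ncol(data$responses),
                dimnames = list(as.character(ids), NULL))
  g <- match(data$stimulus_id, ids)
  for (j in seq_len(ncol(data$responses)))
    out[, j] <- tapply(data$responses[, j], g, mean)[as.character(seq_along(ids))]
  out
}

#' Noise-ceiling signal-to-noise ratio per voxel
#'
#' Noise SD is the square root of the mean (over stimuli) unbiased
#' across-repeat variance; signal SD is `sqrt(max(0, var(all single-trial
#' responses) - noise variance))`; NCSNR is their ratio. A voxel with zero
#' noise SD gets +Inf. Downstream analyses keep only voxels with
#' NCSNR strictly above the threshold (reference 0.3).
#'
#' @param data a `voxel_dataset` (>= 2 repeats per stimulus), typically
#'   after [session_zscore()].
#' @return data.frame (voxel, roi_domain, signal_sd, noise_sd, ncsnr).
#' @export
ncsnr <- function(data) {
  stopifnot(inherits(data, "voxel_dataset"))
  reps <- table(data$stimulus_id)
  if (any(reps < 2)) stop("every stimulus needs >= 2 repeats for NCSNR")
  g <- factor(data$stimulus_id)
  out <- data.frame(voxel = seq_len(ncol(data$responses)),
                    roi_domain = data$roi_domain,
                    signal_sd = NA_real_, noise_sd = NA_real_, ncsnr = NA_real_)
  for (j in seq_len(ncol(data$responses))) {
    y <- data$responses[, j]
    noise_var <- mean(tapply(y, g, stats::var))
    total_var <- stats::var(y)
    signal_var <- max(0, total_var - noise_var)
    out$noise_sd[j] <- sqrt(noise_var)
    out$signal_sd[j] <- sqrt(signal_var)
    out$ncsnr[j] <- if (noise_var > 0) sqrt(signal_var) / sqrt(noise_var) else Inf
  }
  out
}

#' Fit a non-negative sparse (Lasso) encoding model for one voxel
#'
#' Minimizes `(1/(2n)) * ||y - X w - c||^2 + alpha * sum(w)` subject to
#' `w >= 0`, with an unpenalized, unconstrained intercept `c`, by cyclic
#' coordinate descent (soft-threshold clipped at zero). Convergence is
#' declared when the KKT conditions hold to `tol`.
#'
#' @param X stimulus x unit design matrix (the matched-selectivity subset).
#' @param y voxel response per stimulus.
#' @param alpha L1 strength (>= 0); reference value 0.1.
#' @param tol KKT tolerance (default 1e-6).
#' @param max_iter sweep cap.
#' @return object of class `encoding_fit`: `w` (>= 0), `intercept`,
#'   `alpha`, `converged`, `n_iter`.
#' @export
fit_nonneg_sparse_encoding <- function(X, y, alpha, tol = 1e-6, max_iter = 10000L) {
  if (alpha < 0) stop("alpha must be >= 0")
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("X needs >= 1 column")
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  stopifnot_finite(X, "X"); stopifnot_finite(y, "y")
  n <- nrow(X); p <- ncol(X)
  cn <- colSums(X^2) / n
  w <- numeric(p)
  cint <- mean(y)
  r <- y - cint            # residual y - Xw - c
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    delta <- 0
    for (j in seq_len(p)) {
      if (cn[j] <= 0) next
      gj <- sum(X[, j] * r) / n + cn[j] * w[j]
      wj_new <- max(0, (gj - alpha) / cn[j])
      if (wj_new != w[j]) {
        r <- r - X[, j] * (wj_new - w[j])
        delta <- max(delta, abs(wj_new - w[j]))
        w[j] <- wj_new
      }
    }
    dc <- mean(r)
    cint <- cint + dc
    r <- r - dc
    delta <- max(delta, abs(dc))
    # KKT: grad_j = -x_j.r/n + alpha; active coords need |grad| <= tol,
    # inactive need grad >= -tol
    grad <- -crossprod(X, r)[, 1] / n + alpha
    kkt_ok <- all(abs(grad[w > 0]) <= tol) && all(grad[w == 0] >= -tol) &&
      abs(mean(r)) <= tol
    if (kkt_ok) { converged <- TRUE; break }
    if (it >= max_iter || delta < tol * 1e-3) break
  }
  structure(list(w = w, intercept = cint, alpha = alpha,
                 converged = converged, n_iter = it),
            class = "encoding_fit")
}

#' Non-negative Lasso objective value
#' @param X,y problem data.
#' @param w,intercept candidate solution.
#' @param alpha L1 strength.
#' @return objective `(1/(2n))||y - Xw - c||^2 + alpha * sum(w)`.
#' @export
nnlasso_objective <- function(X, y, w, intercept, alpha) {
  n <- nrow(X)
  sum((y - as.numeric(X %*% w) - intercept)^2) / (2 * n) + alpha * sum(w)
}

#' Representational dissimilarity matrix (Pearson dissimilarity)
#'
#' Entry (i, j) is `1 - Pearson r` between pattern rows i and j. Rows with
#' zero variance produce NA entries and are flagged in the
#' `flagged_rows` attribute; the diagonal is 0 and defined entries lie in
#' `[0, 2]`.
#'
#' @param patterns stimulus x channel matrix (>= 2 channels).
#' @return n x n symmetric matrix of class `rdm`.
#' @export
compute_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2) stop("need >= 2 channels per pattern")
  sds <- apply(patterns, 1, stats::sd)
  flagged <- which(sds == 0)
  D <- 1 - suppressWarnings(stats::cor(t(patterns)))
  if (length(flagged)) { D[flagged, ] <- NA_real_; D[, flagged] <- NA_real_ }
  diag(D) <- 0
  attr(D, "flagged_rows") <- flagged
  class(D) <- c("rdm", class(D))
  D
}

#' Lower triangle of an RDM
#' @param D an `rdm` (or any square matrix).
#' @return numeric vector of the n(n-1)/2 below-diagonal entries.
#' @export
rdm_lower <- function(D) D[lower.tri(D)]

#' Evaluate encoding fits on a held-out split
#'
#' Predicts each voxel's response from its fit, then scores (a) the
#' univariate metric: Pearson r between predicted and measured ROI-mean
#' response profiles across stimuli, and (b) the veRSA metric: Pearson r
#' between the lower triangles of the predicted-pattern and
#' measured-pattern RDMs (same voxel set on both sides).
#'
#' @param fits list of `encoding_fit`s, one per voxel (fitted on the
#'   training split only).
#' @param X stimulus x unit matrix for the evaluation split (same unit
#'   subset used in training).
#' @param Y measured stimulus x voxel matrix for the evaluation split.
#' @param train_ids,eval_ids optional stimulus id vectors; any overlap is
#'   an error.
#' @return list with `univariate` and `versa` correlations and the
#'   predicted matrix.
#' @export
evaluate_encoding <- function(fits, X, Y, train_ids = NULL, eval_ids = NULL) {
  if (!is.null(train_ids) && !is.null(eval_ids) &&
      length(intersect(train_ids, eval_ids)))
    stop("evaluation split overlaps the training stimuli")
  if (length(fits) != ncol(Y)) stop("one fit per voxel required")
  W <- vapply(fits, function(f) f$w, numeric(ncol(X)))
  W <- matrix(W, ncol = length(fits))
  icpt <- vapply(fits, function(f) f$intercept, numeric(1))
  pred <- X %*% W + matrix(icpt, nrow(X), length(fits), byrow = TRUE)
  # a constant prediction (e.g. positivity forcing all weights to zero for a
  # mismatched subset) has no predictive power: score 0, flagged, not NA
  flat <- FALSE
  uni <- if (stats::sd(rowMeans(Y)) == 0) NA_real_
  else if (stats::sd(rowMeans(pred)) == 0) { flat <- TRUE; 0 }
  else stats::cor(rowMeans(pred), rowMeans(Y))
  versa <- if (ncol(Y) >= 2) {
    dp <- rdm_lower(compute_rdm(pred)); dm <- rdm_lower(compute_rdm(Y))
    ok <- is.finite(dp) & is.finite(dm)
    if (!any(is.finite(dp)) || (sum(ok) >= 3 && stats::sd(dp[ok]) == 0)) { flat <- TRUE; 0 }
    else if (sum(ok) >= 3 && stats::sd(dm[ok]) > 0) stats::cor(dp[ok], dm[ok])
    else NA_real_
  } else NA_real_
  list(univariate = uni, versa = versa, predicted = pred, flat_prediction = flat)
}

#' Select the best-predicting layer per metric on validation data
#'
#' @param metrics data.frame with columns `layer`, `univariate`, `versa`
#'   (validation-split correlations).
#' @return named integer vector (`univariate`, `versa`); ties go to the
#'   shallower layer.
#' @export
select_best_layer <- function(metrics) {
  if (nrow(metrics) < 1) stop("need >= 1 evaluated layer")
  pick <- function(v) {
    ok <- which(!is.na(v))
    if (!length(ok)) return(NA_integer_)
    metrics$layer[ok[which.max(v[ok])]]  # which.max takes the first = shallowest
  }
  m <- metrics[order(metrics$layer), ]
  c(univariate = pick(m$univariate), versa = pick(m$versa))
}

#' Full matched-subset encoding analysis for one ROI domain
#'
#' Fits per-voxel non-negative sparse encoding models from one domain's
#' selective units at every layer on the training stimuli, selects the best
#' layer per metric on the validation stimuli, and reports test-split
#' metrics from the selected layers only.
#'
#' @param store unlesioned `activation_store` over all stimuli.
#' @param map a `selectivity_map`.
#' @param prepared stimulus x voxel matrix (z-scored, repeat-averaged, and
#'   NCSNR-filtered), rownames = stimulus ids.
#' @param stimuli the `stimulus_set` (for split membership of ids).
#' @param unit_domain domain whose selective units form the design matrix
#'   (matched or mismatched to the ROI).
#' @param layers candidate layers (default all).
#' @param alpha L1 strength.
#' @param stage activation stage.
#' @return list: `val_metrics` (per layer), `best` (per metric),
#'   `test_univariate`, `test_versa`, `fits` (per layer).
#' @export
encoding_analysis <- function(store, map, prepared, stimuli, unit_domain,
                              layers = seq_along(map$sel), alpha = 0.1,
                              stage = "post") {
  ids <- as.integer(rownames(prepared))
  split_of <- stimuli$split[match(ids, stimuli$id)]
  row_of <- function(tag) which(split_of == tag)
  tr <- row_of("enc_train"); va <- row_of("enc_val"); te <- row_of("enc_test")
  if (!length(tr) || !length(va) || !length(te))
    stop("prepared matrix must contain enc_train, enc_val and enc_test stimuli")
  store_row <- match(ids, store$id)
  fits_by_layer <- list(); val_rows <- list()
  for (l in layers) {
    units <- selected_units(map, l, unit_domain, stage)
    if (length(units) == 0) {
      val_rows[[as.character(l)]] <- data.frame(layer = l, univariate = NA_real_,
                                                versa = NA_real_)
      next
    }
    A <- activations(store, l, stage)[store_row, units, drop = FALSE]
    fits <- lapply(seq_len(ncol(prepared)), function(v)
      fit_nonneg_sparse_encoding(A[tr, , drop = FALSE], prepared[tr, v], alpha))
    ev <- evaluate_encoding(fits, A[va, , drop = FALSE],
                            prepared[va, , drop = FALSE],
                            train_ids = ids[tr], eval_ids = ids[va])
    fits_by_layer[[as.character(l)]] <- fits
    val_rows[[as.character(l)]] <- data.frame(layer = l, univariate = ev$univariate,
                                              versa = ev$versa)
  }
  val_metrics <- do.call(rbind, val_rows)
  best <- select_best_layer(val_metrics)
  test_metric <- function(l, which) {
    if (is.na(l)) return(NA_real_)
    units <- selected_units(map, l, unit_domain, stage)
    A <- activations(store, l, stage)[store_row, units, drop = FALSE]
    ev <- evaluate_encoding(fits_by_layer[[as.character(l)]],
                            A[te, , drop = FALSE], prepared[te, , drop = FALSE],
                            train_ids = ids[tr], eval_ids = ids[te])
    ev[[which]]
  }
  list(val_metrics = val_metrics, best = best,
       test_univariate = test_metric(best[["univariate"]], "univariate"),
       test_versa = test_metric(best[["versa"]], "versa"),
       fits = fits_by_layer)
}

#' Monte-Carlo noise ceiling
#'
#' Per simulation, a noiseless response profile (or pattern set) is drawn
#' from the signal spec, a noisy counterpart is built by adding noise draws
#' averaged over `n_rep` repeats, and the metric between the two is
#' computed; the ceiling is the mean across simulations. In the synthetic
#' regime the signal/noise SDs are the generator's true parameters;
#' otherwise pass moment estimates from repeats (see [ncsnr()]).
#'
#' @param signal_sd signal SD per voxel (scalar or length `n_voxels`; all
#'   must be > 0).
#' @param noise_sd trial noise SD (>= 0).
#' @param n_stim stimuli per profile.
#' @param n_voxels voxels (>= 2 required for the rdm metric).
#' @param n_rep repeats averaged per measurement.
#' @param n_sim Monte-Carlo draws (>= 100).
#' @param seed integer seed.
#' @param metric `"univariate"` or `"rdm"`.
#' @return object of class `noise_ceiling`: `estimate` (mean r), `spread`
#'   (SD across simulations), `n_sim`, `metric`.
#' @export
noise_ceiling_mc <- function(signal_sd, noise_sd, n_stim, n_voxels = 1L,
                             n_rep = 3L, n_sim = 200L, seed = 1L,
                             metric = c("univariate", "rdm")) {
  metric <- match.arg(metric)
  if (n_sim < 100) stop("n_sim must be >= 100")
  if (any(signal_sd <= 0)) stop("signal variance must be positive")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (metric == "rdm" && n_voxels < 2) stop("rdm metric needs >= 2 voxels")
  sds <- rep_len(signal_sd, n_voxels)
  rs <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    Z <- sweep(matrix(stats::rnorm(n_stim * n_voxels), n_stim, n_voxels), 2, sds, "*")
    E <- matrix(stats::rnorm(n_stim * n_voxels, 0, noise_sd / sqrt(n_rep)),
                n_stim, n_voxels)
    noisy <- Z + E
    if (metric == "univariate") {
      if (noise_sd == 0) return(1)
      stats::cor(rowMeans(Z), rowMeans(noisy))
    } else {
      if (noise_sd == 0) return(1)
      stats::cor(rdm_lower(compute_rdm(Z)), rdm_lower(compute_rdm(noisy)))
    }
  }, numeric(1)))
  structure(list(estimate = mean(rs), spread = stats::sd(rs), n_sim = n_sim,
                 n_rep = n_rep, metric = metric, seed = as.integer(seed)),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("<noise_ceiling> %s: %.3f (MC sd %.3f, n_sim=%d)\n",
              x$metric, x$estimate, x$spread, x$n_sim))
  invisible(x)
}

#' Ground-truth recovery of voxel encoding weights on simulated data
#'
#' For each voxel of one ROI domain, fits non-negative sparse encoding
#' models from the domain's localized units over a small alpha grid,
#' selects alpha by validation-split MSE, and scores the chosen fit
#' against the simulator's true mixing weights: the fraction of true
#' source units contained in the recovered support, and the Pearson
#' correlation between recovered and true weight vectors.
#'
#' @param store unlesioned `activation_store`.
#' @param map a `selectivity_map`.
#' @param vox the simulated `voxel_dataset` (its truth weights are used).
#' @param stimuli the generating `stimulus_set`.
#' @param domain ROI domain scored.
#' @param layer source layer of the voxels.
#' @param alpha_grid candidate L1 strengths.
#' @param stage activation stage.
#' @return data.frame (voxel, support_containment, weight_cor, alpha).
#' @export
encoding_recovery <- function(store, map, vox, stimuli, domain,
                              layer = vox$layer,
                              alpha_grid = c(1e-4, 3e-4, 1e-3),
                              stage = "post") {
  prepared <- average_repeats(session_zscore(vox))
  ids <- as.integer(rownames(prepared))
  spl <- stimuli$split[match(ids, stimuli$id)]
  tr <- which(spl == "enc_train"); va <- which(spl == "enc_val")
  units <- selected_units(map, layer, domain, stage)
  if (!length(units)) stop("no selective units for the requested domain")
  A <- activations(store, layer, stage)[match(ids, store$id), units, drop = FALSE]
  rows <- lapply(which(vox$roi_domain == domain), function(v) {
    fits <- lapply(alpha_grid, function(al)
      fit_nonneg_sparse_encoding(A[tr, , drop = FALSE], prepared[tr, v], al))
    mse <- vapply(fits, function(f)
      mean((prepared[va, v] - A[va, , drop = FALSE] %*% f$w - f$intercept)^2),
      numeric(1))
    f <- fits[[which.min(mse)]]
    truth <- vox$truth_weights[units, v]
    tsup <- which(truth > 0)
    data.frame(voxel = v,
               support_containment = length(intersect(tsup, which(f$w > 1e-6))) /
                 max(1L, length(tsup)),
               weight_cor = suppressWarnings(stats::cor(f$w, truth)),
               alpha = alpha_grid[which.min(mse)])
  })
  do.call(rbind, rows)
}
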