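make_vox <- function(seed = 3, noise_sd = 0.5, n_voxels = 4L, ...) {
  w <- default_world()
  simulate_voxel_dataset(w$store, w$model$planted[[2]],
                         voxel_config(layer = 2L, n_voxels = n_voxels,
                                      noise_sd = noise_sd, ...), seed)
}

test_that("session z-scoring yields exact per-session moments and removes affine corruption", {
  vox <- make_vox()
  z <- session_zscore(vox)
  for (s in unique(z$session_id)) {
    M <- z$responses[z$session_id == s, ]
    expect_true(all(abs(colMeans(M)) < 1e-12))
    expect_true(all(abs(apply(M, 2, sd) - 1) < 1e-12))
  }
  # noiseless data with one full repeat per session: z-scoring removes the
  # per-session gain/offset exactly, so averaged responses match the signal
  vox0 <- make_vox(noise_sd = 0, n_sessions = 3L, repeats = 3L,
                   shuffle_trials = FALSE)
  z0 <- session_zscore(vox0)
  avg <- average_repeats(z0)
  w <- default_world()
  keep <- w$store$split %in% vox0$config$splits
  sig <- (w$store$layers[[2]]$post[keep, ] %*% vox0$truth_weights)
  sig <- sig[order(w$store$id[keep]), ]
  expect_true(all(abs(cor(avg, sig)[cbind(1:4, 1:4)] - 1) < 1e-8))
})

test_that("z-scoring flags zero-variance voxels and single-session equals global", {
  vox <- make_vox(n_sessions = 1L)
  z <- session_zscore(vox)
  expect_equal(unname(z$responses[, 1]), unname(scale(vox$responses[, 1])[, 1]))
  vox$responses[, 2] <- 5  # constant voxel
  z2 <- session_zscore(vox)
  expect_true(all(z2$responses[, 2] == 0))
  expect_gte(attr(z2, "flagged_zero_variance"), 1L)
})

test_that("repeat averaging is the exact mean and validates ids", {
  vox <- make_vox()
  avg <- average_repeats(vox)
  id1 <- sort(unique(vox$stimulus_id))[1]
  expect_equal(unname(avg[as.character(id1), 1]),
               mean(vox$responses[vox$stimulus_id == id1, 1]))
  expect_true(all(table(vox$stimulus_id) == vox$config$repeats))
  expect_error(average_repeats(vox, stimulus_ids = c(id1, 999999L)), "missing")
})

test_that("NCSNR separates signal-carrying from pure-noise voxels", {
  vox <- make_vox(noise_sd = 0.3)
  n_tr <- nrow(vox$responses)
  # append pure-noise voxels
  set.seed(9)
  vox$responses <- cbind(vox$responses, matrix(rnorm(n_tr * 3), n_tr, 3))
  vox$roi_domain <- c(vox$roi_domain, rep("noise", 3))
  rel <- ncsnr(session_zscore(vox))
  expect_true(all(rel$ncsnr[rel$roi_domain != "noise"] > 1))
  expect_true(all(rel$ncsnr[rel$roi_domain == "noise"] < 0.35))
  # threshold filter keeps exactly the voxels above threshold
  kept <- rel$voxel[rel$ncsnr > 0.3]
  expect_setequal(kept, rel$voxel[which(rel$ncsnr > 0.3)])
  # zero-noise voxel: infinite reliability flag
  vox0 <- make_vox(noise_sd = 0, gain_sd = 0, offset_sd = 0, n_sessions = 1L)
  expect_true(all(is.infinite(ncsnr(vox0)$ncsnr)))
})

test_that("NCSNR decreases with trial noise on average", {
  grid <- c(0.3, 1, 3)
  mean_ncsnr <- vapply(grid, function(ns) {
    mean(vapply(1:6, function(s)
      mean(ncsnr(session_zscore(make_vox(seed = s, noise_sd = ns)))$ncsnr),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ncsnr) < 0))
})

test_that("non-negative lasso solves exact and degenerate cases", {
  # alpha = 0 with orthonormal design recovers the true weights
  set.seed(10)
  q <- qr.Q(qr(matrix(rnorm(80), 20, 4)))
  w_star <- c(1.5, 0.2, 0, 3)
  y <- as.numeric(q %*% w_star) + 2
  fit <- fit_nonneg_sparse_encoding(q, y, alpha = 0, tol = 1e-9)
  expect_lt(max(abs(fit$w - w_star)), 1e-6)
  expect_lt(abs(fit$intercept - 2), 1e-6)
  # negated tuning: positivity binds, all weights zero, intercept = mean(y)
  y_neg <- as.numeric(-q %*% c(2, 1, 1, 1))
  fit_neg <- fit_nonneg_sparse_encoding(q, y_neg, alpha = 0.01)
  expect_true(all(fit_neg$w == 0))
  expect_equal(fit_neg$intercept, mean(y_neg), tolerance = 1e-10)
  expect_error(fit_nonneg_sparse_encoding(q, y, alpha = -1), "alpha")
  expect_error(fit_nonneg_sparse_encoding(q, y[-1], alpha = 0), "align")
})

test_that("active-set size is non-increasing in alpha on a fixed problem", {
  set.seed(11)
  X <- matrix(rnorm(300), 50, 6)
  y <- as.numeric(X %*% c(1, 0.5, 0.25, 0, 0, 0)) + rnorm(50, sd = 0.1)
  nnz <- vapply(c(0, 0.01, 0.05, 0.2, 1), function(a)
    sum(fit_nonneg_sparse_encoding(X, y, a)$w > 1e-8), numeric(1))
  expect_true(all(diff(nnz) <= 0))
  expect_equal(nnz[length(nnz)], 0)
})

test_that("coordinate descent agrees with glmnet's positive lasso", {
  set.seed(12)
  X <- matrix(rnorm(600), 100, 6)
  y <- as.numeric(X %*% c(2, 1, 0, 0, 0.5, 0)) + rnorm(100, sd = 0.2)
  for (alpha in c(0.05, 0.2)) {
    mine <- fit_nonneg_sparse_encoding(X, y, alpha)
    ref <- glmnet::glmnet(X, y, lambda = alpha, lower.limits = 0,
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-12)
    w_ref <- as.numeric(ref$beta)
    obj_mine <- nnlasso_objective(X, y, mine$w, mine$intercept, alpha)
    obj_ref <- nnlasso_objective(X, y, w_ref, as.numeric(ref$a0), alpha)
    expect_lt(abs(obj_mine - obj_ref), 1e-6)
    expect_lt(max(abs(mine$w - w_ref)), 1e-3)
  }
})

test_that("objective matches a brute-force grid oracle on small problems", {
  set.seed(13)
  for (i in 1:10) {
    p <- sample(2:3, 1)
    X <- matrix(rnorm(20 * p), 20, p)
    w_true <- runif(p, 0, 2) * rbinom(p, 1, 0.7)
    y <- as.numeric(X %*% w_true) + rnorm(20, sd = 0.2)
    alpha <- runif(1, 0.01, 0.3)
    fit <- fit_nonneg_sparse_encoding(X, y, alpha)
    expect_true(all(fit$w >= 0))
    oracle <- nnlasso_grid_oracle(X, y, alpha, w_max = max(2.5, max(fit$w) * 1.2))
    obj_fit <- nnlasso_objective(X, y, fit$w, fit$intercept, alpha)
    # grid solution can never beat the true optimum by more than resolution
    expect_lte(obj_fit, oracle$objective + 1e-8)
    expect_lte(oracle$objective - obj_fit, 0.5 * oracle$step^2 * ncol(X) + 0.05)
  }
})

test_that("RDMs satisfy their algebra", {
  set.seed(14)
  P <- matrix(rnorm(60), 10, 6)
  P[2, ] <- P[1, ]                      # identical rows
  P[3, ] <- -(P[1, ] - mean(P[1, ]))    # centered negation
  D <- compute_rdm(P)
  expect_equal(D[1, 2], 0, tolerance = 1e-12)
  expect_equal(D[1, 3], 2, tolerance = 1e-12)
  expect_equal(unname(diag(D)), rep(0, 10))
  expect_true(isSymmetric(unclass(D), tol = 1e-12))
  expect_true(all(D >= 0 & D <= 2))
  expect_length(rdm_lower(D), 10 * 9 / 2)
  # zero-variance rows flagged as undefined
  P[4, ] <- 7
  D2 <- compute_rdm(P)
  expect_equal(attr(D2, "flagged_rows"), 4L)
  expect_true(all(is.na(D2[4, -4])))
  expect_error(compute_rdm(P[, 1, drop = FALSE]), ">= 2 channels")
})

test_that("evaluation metrics are exact for perfect models and guard split leakage", {
  set.seed(15)
  X <- matrix(abs(rnorm(80)), 20, 4)
  W <- matrix(runif(8), 4, 2)
  fits <- lapply(1:2, function(v)
    structure(list(w = W[, v], intercept = v), class = "encoding_fit"))
  Y <- X %*% W + matrix(c(1, 2), 20, 2, byrow = TRUE)
  ev <- evaluate_encoding(fits, X, Y)
  expect_equal(ev$univariate, 1, tolerance = 1e-12)
  expect_equal(ev$versa, 1, tolerance = 1e-12)
  # shuffled measurements decorrelate the metrics
  ev_sh <- evaluate_encoding(fits, X, Y[sample(20), ])
  expect_lt(abs(ev_sh$univariate), 0.6)
  expect_error(evaluate_encoding(fits, X, Y, train_ids = 1:10, eval_ids = 5:8),
               "overlap")
  expect_error(evaluate_encoding(fits[1], X, Y), "one fit per voxel")
})

test_that("best-layer selection takes the argmax and breaks ties shallow", {
  m <- data.frame(layer = 1:3, univariate = c(0.1, 0.5, 0.9),
                  versa = c(0.4, 0.4, 0.2))
  best <- select_best_layer(m)
  expect_equal(unname(best["univariate"]), 3L)  # monotone -> deepest
  expect_equal(unname(best["versa"]), 1L)       # tie -> shallower
  expect_error(select_best_layer(m[0, ]), ">= 1 evaluated layer")
})

test_that("noise ceilings behave as limits demand", {
  nc0 <- noise_ceiling_mc(1, 0, 50, n_sim = 100, seed = 1)
  expect_equal(nc0$estimate, 1)
  nc_big <- noise_ceiling_mc(1, 50, 50, n_sim = 200, seed = 1)
  expect_lt(nc_big$estimate, 0.2)
  nc_rdm <- noise_ceiling_mc(1, 0, 30, n_voxels = 5, n_sim = 100, seed = 1,
                             metric = "rdm")
  expect_equal(nc_rdm$estimate, 1)
  expect_error(noise_ceiling_mc(0, 1, 50, n_sim = 100), "signal variance")
  expect_error(noise_ceiling_mc(1, -1, 50, n_sim = 100), "noise SD")
  expect_error(noise_ceiling_mc(1, 1, 50, n_sim = 50), "n_sim")
  expect_error(noise_ceiling_mc(1, 1, 50, n_voxels = 1, n_sim = 100,
                                metric = "rdm"), "rdm metric")
})

test_that("moment estimates feed the ceiling in the non-synthetic regime", {
  vox <- make_vox(noise_sd = 1)
  rel <- ncsnr(session_zscore(vox))
  nc <- noise_ceiling_mc(pmax(rel$signal_sd, 1e-3), mean(rel$noise_sd),
                         n_stim = 50, n_voxels = nrow(rel), n_rep = 3,
                         n_sim = 100, seed = 2, metric = "rdm")
  expect_true(nc$estimate > 0 && nc$estimate < 1)
})
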