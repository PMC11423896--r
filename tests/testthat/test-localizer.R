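test_that("contrast_tmap matches the pooled-variance t computed by hand", {
  # unit 1: preferred {2,2,2,2.4}, other {0,0,0,0}; textbook pooled t
  acts <- cbind(c(2, 2, 2, 2.4, 0, 0, 0, 0))
  labels <- rep(c("a", "b"), each = 4)
  tp <- contrast_tmap(acts, labels, "a", "b")
  m1 <- mean(c(2, 2, 2, 2.4)); m2 <- 0
  sp2 <- (sum((c(2, 2, 2, 2.4) - m1)^2) + 0) / 6
  t_hand <- (m1 - m2) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(tp$t[1], t_hand, tolerance = 1e-12)
  expect_equal(tp$p[1], 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  # antisymmetry
  expect_equal(contrast_tmap(acts, labels, "b", "a")$t[1], -t_hand)
  # cross-check against stats::t.test with equal variances
  ref <- t.test(acts[1:4, 1], acts[5:8, 1], var.equal = TRUE)
  expect_equal(tp$t[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tp$p[1], ref$p.value, tolerance = 1e-12)
})

test_that("contrast_tmap handles constant and degenerate inputs", {
  acts <- cbind(rep(3, 8), c(1, 1, 1, 1, 0, 0, 0, 0))
  labels <- rep(c("a", "b"), each = 4)
  tp <- contrast_tmap(acts, labels, "a", "b")
  expect_equal(tp$t[1], 0)   # no difference, no variance
  expect_equal(tp$p[1], 1)
  expect_equal(tp$t[2], Inf) # difference with zero variance
  expect_equal(tp$p[2], 0)
  expect_error(contrast_tmap(acts, labels, "zzz", "b"), "absent")
  expect_error(contrast_tmap(acts[c(1, 5:8), , drop = FALSE],
                             labels[c(1, 5:8)], "a", "b"), ">= 2 stimuli")
})

test_that("BH mask reproduces the hand-applied step-up rule", {
  # p = (.001, .2, .9), q = .05: ranks 1..3, thresholds .0167/.0333/.05
  expect_equal(bh_fdr_mask(c(0.001, 0.2, 0.9), 0.05), c(TRUE, FALSE, FALSE))
  # step-up includes everything below the largest passing rank
  # p sorted = (.01, .02, .02, .9); thresholds .0125/.025/.0375/.05 ->
  # rank 3 passes (0.02 <= 0.0375), so the first three all pass
  expect_equal(bh_fdr_mask(c(0.02, 0.01, 0.9, 0.02), 0.05),
               c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(bh_fdr_mask(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr_mask(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_equal(bh_fdr_mask(numeric(0), 0.05), logical(0))
  expect_error(bh_fdr_mask(c(0.5, 1.2), 0.05), "in \\[0, 1\\]")
})

test_that("localizer recovers planted units and keeps domains disjoint", {
  w <- default_world()
  rec <- recovery_scores(w$map, w$model)
  expect_true(all(rec$precision >= 0.9))
  expect_true(all(rec$recall >= 0.9))
  for (l in seq_along(w$map$sel)) {
    doms <- names(w$map$sel[[l]]$post)
    for (i in seq_along(doms)) for (j in seq_len(i - 1L)) {
      expect_length(intersect(w$map$sel[[l]]$post[[doms[i]]]$indices,
                              w$map$sel[[l]]$post[[doms[j]]]$indices), 0)
    }
    for (dn in doms) {
      e <- w$map$sel[[l]]$post[[dn]]
      expect_true(all(e$t_contrasts > 0))  # stored t all positive
    }
  }
})

test_that("a unit must win every contrast to be selective", {
  # unit 1 beats 4 of 5 categories but loses to "e"; unit 2 beats all
  set.seed(1)
  n <- 6
  mk <- function(mu) mu + rnorm(n, sd = 0.05)
  u1 <- c(mk(5), mk(0), mk(0), mk(0), mk(0), mk(6))  # loses a-vs-e
  u2 <- c(mk(5), mk(0), mk(0), mk(0), mk(0), mk(1))
  labels <- rep(c("a", "b", "c", "d", "scr", "e"), each = n)
  store <- fake_store(cbind(u1, u2), labels)
  design <- localizer_design(domains = c(a = "a"), q = 0.05)
  map <- localize_selective_units(store, design)
  expect_equal(map$sel[[1]]$post$a$indices, 2L)
})

test_that("ratio method uses an inclusive 2:1 boundary and post stages only", {
  means <- list(a = 4, b = 2, c = 1)  # unit 1: boundary inclusive
  acts <- cbind(rep(c(4, 2, 1), each = 4),      # selected at ratio 2
                rep(c(4, 2.5, 1), each = 4),    # not selected
                rep(c(0, 0, 0), each = 4))      # zero preferred mean: never
  labels <- rep(c("a", "b", "c"), each = 4)
  store <- fake_store(acts, labels)
  design <- localizer_design(domains = c(a = "a"), q = 0.05)
  map <- ratio_localize(store, design, ratio = 2)
  expect_equal(map$sel[[1]]$post$a$indices, 1L)
  expect_error(ratio_localize(store, design, stages = "pre"),
               "post-rectification")
})

test_that("ratio and t-test methods overlap on the planted model", {
  w <- default_world()
  map_ratio <- ratio_localize(w$store, localizer_design())
  ov <- selectivity_overlap(w$map, map_ratio)
  expect_true(all(ov$iou > 0, na.rm = TRUE))
  expect_true(any(ov$iou > 0.5, na.rm = TRUE))
})

test_that("probe generalization reproduces localizer t exactly on the same split", {
  # probe split constructed as a copy of the localizer rows; non-negative
  # activations so the post-rectification stage equals the raw matrix
  set.seed(4)
  acts <- matrix(abs(rnorm(240)), 40, 6)
  acts[1:10, 1:2] <- acts[1:10, 1:2] + 3  # units 1-2 prefer category a
  labels <- rep(rep(c("a", "b", "c", "d"), each = 10), 2)[1:40]
  store <- fake_store(rbind(acts, acts), c(labels, labels),
                      split = rep(c("localizer", "probe"), each = 40))
  design <- localizer_design(domains = c(a = "a"), q = 0.05)
  map <- localize_selective_units(store, design)
  gen <- generalization_check(map, store, design)
  sel <- map$sel[[1]]$post$a
  expect_gt(length(sel$indices), 0)
  probe_acts <- acts[, sel$indices, drop = FALSE]
  probe_t <- rowMeans(vapply(c("b", "c", "d"), function(oc)
    contrast_tmap(probe_acts, labels, "a", oc)$t, numeric(length(sel$indices))))
  expect_equal(unname(probe_t), unname(sel$t_mean), tolerance = 1e-10)
  expect_equal(gen$frac_positive[1], 1)
})

test_that("selectivity generalizes to the shifted probe set at g = 4", {
  w <- default_world()
  gen <- generalization_check(w$map, w$store, localizer_design())
  expect_true(all(!gen$undefined))
  expect_true(all(gen$frac_positive >= 0.9))
})

test_that("empty selective sets are flagged undefined, not scored zero", {
  set.seed(2)
  acts <- matrix(rnorm(80), 20, 4)
  labels <- rep(c("a", "b"), each = 10)
  store <- fake_store(rbind(acts, acts), rep(labels, 2),
                      split = rep(c("localizer", "probe"), each = 20))
  design <- localizer_design(domains = c(a = "a"), q = 0.05)
  map <- localize_selective_units(store, design)
  expect_length(map$sel[[1]]$post$a$indices, 0)   # empty, not missing
  gen <- generalization_check(map, store, design)
  expect_true(gen$undefined[1])
  expect_true(is.na(gen$frac_positive[1]))
})

test_that("depth trends: rho increasing by depth gives Spearman r = 1", {
  st <- generate_stimulus_set(stimulus_config(), 21)
  m <- build_planted_model(st, planted_model_config(rho = c(0.02, 0.05, 0.10)),
                           1021)
  map <- localize_selective_units(forward_activations(m, st), localizer_design())
  s <- selectivity_summary(map)
  expect_equal(unname(s$spearman["prop"]), 1)
  expect_error(selectivity_summary(
    localize_selective_units(fake_store(matrix(rnorm(40), 20, 2),
                                        rep(c("a", "b"), each = 10)),
                             localizer_design(domains = c(a = "a")))),
    ">= 3 layers")
})
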