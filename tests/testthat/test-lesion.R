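test_that("an empty lesion has zero recognition cost", {
  w <- trained_world()
  prof <- lesion_cost_profile(w$model, w$head, w$stimuli, lesion_spec(list()))
  expect_equal(unname(prof$cost), rep(0, length(prof$cost)))
})

test_that("the readout head is never modified by lesion evaluation", {
  w <- trained_world()
  before <- w$head$weights
  invisible(lesion_cost_profile(w$model, w$head, w$stimuli,
                                domain_lesion(w$map, "face")))
  expect_identical(w$head$weights, before)
})

test_that("lesioning everything reduces the readout to its bias", {
  w <- trained_world()
  all_units <- lapply(seq_along(w$model$layers), function(l)
    seq_len(nrow(w$model$layers[[l]]$W)))
  names(all_units) <- as.character(seq_along(all_units))
  prof <- lesion_cost_profile(w$model, w$head, w$stimuli, lesion_spec(all_units))
  # with zero features every stimulus gets the same bias-driven prediction
  winner <- w$head$levels[order(-w$head$bias, seq_along(w$head$bias))[1]]
  expected <- ifelse(names(prof$lesioned) == winner, 100, 0)
  expect_equal(unname(prof$lesioned), unname(expected))
  expect_equal(prof$cost, prof$baseline - prof$lesioned)
})

test_that("domain lesions produce dissociable own-category deficits", {
  w <- trained_world()
  doms <- names(w$model$domains)
  profs <- lapply(doms, function(dn)
    lesion_cost_profile(w$model, w$head, w$stimuli, domain_lesion(w$map, dn)))
  names(profs) <- doms
  for (dn in doms) {
    own <- profs[[dn]]$cost[[w$model$domains[[dn]]]]
    expect_equal(own, max(profs[[dn]]$cost))
    expect_gt(own, 25)
  }
  # cross-domain cost profiles are weakly or negatively related
  cmp <- compare_cost_profiles(profs$face, profs$scene)
  expect_false(cmp$undefined)
  expect_lt(cmp$r, 0.3)
})

test_that("cost profile comparison flags degenerate profiles", {
  p1 <- structure(list(cost = c(a = 10, b = 0, c = -5)), class = "cost_profile")
  expect_equal(compare_cost_profiles(p1, p1)$r, 1)
  p2 <- p1; p2$cost <- -(p1$cost - mean(p1$cost))
  expect_equal(compare_cost_profiles(p1, p2)$r, -1)
  flat <- structure(list(cost = c(a = 1, b = 1, c = 1)), class = "cost_profile")
  out <- compare_cost_profiles(p1, flat)
  expect_true(out$undefined)
  expect_true(is.na(out$r))
  p3 <- structure(list(cost = c(a = 1, z = 2)), class = "cost_profile")
  expect_error(compare_cost_profiles(p1, p3), "different category sets")
})

test_that("cross-validated top-affected categories identify the lesioned domain", {
  w <- trained_world()
  cv <- crossval_top_affected(w$model, w$head, w$stimuli,
                              domain_lesion(w$map, "face"), n_top = 2L,
                              seed = 1L)
  expect_true("face" %in% cv$categories)
  expect_gt(cv$holdout_mean_deficit, 10)
  # the destroyed category shows the max deficit on the held-out half too
  expect_equal(names(which.max(cv$profile_b$cost)), "face")
  # a second seed agrees on the planted domain
  cv2 <- crossval_top_affected(w$model, w$head, w$stimuli,
                               domain_lesion(w$map, "face"), n_top = 2L,
                               seed = 99L)
  expect_true("face" %in% cv2$categories)
  # selecting every category reproduces the overall mean on half B
  cv_all <- crossval_top_affected(w$model, w$head, w$stimuli,
                                  domain_lesion(w$map, "face"),
                                  n_top = length(cv$profile_b$cost), seed = 1L)
  expect_equal(cv_all$holdout_mean_deficit, mean(cv_all$profile_b$cost))
})

test_that("activation-cost correlation is negative for domain lesions and flagged when degenerate", {
  w <- trained_world()
  prof <- lesion_cost_profile(w$model, w$head, w$stimuli,
                              domain_lesion(w$map, "face"))
  ac <- activation_cost_correlation(w$store, selected_units(w$map, 3, "face"),
                                    prof, 3)
  expect_false(ac$undefined)
  expect_lt(ac$r, -0.5)
  expect_true(activation_cost_correlation(w$store, integer(0), prof, 3)$undefined)
  flat <- prof; flat$cost[] <- 2
  expect_true(activation_cost_correlation(w$store,
                                          selected_units(w$map, 3, "face"),
                                          flat, 3)$undefined)
})

test_that("random lesion nulls are reproducible and size-matched", {
  w <- trained_world()
  rn1 <- random_lesion_null(w$model, w$head, w$stimuli, w$map, "face",
                            n_draws = 2L, seed = 8L)
  rn2 <- random_lesion_null(w$model, w$head, w$stimuli, w$map, "face",
                            n_draws = 2L, seed = 8L)
  expect_identical(rn1$profiles[[1]]$cost, rn2$profiles[[1]]$cost)
  for (l in 1:3) {
    expect_length(rn1$specs[[1]]$units[[as.character(l)]],
                  length(selected_units(w$map, l, "face")))
  }
  # a draw matched to the full layer size equals the deterministic full lesion
  full_map <- w$map
  for (l in 1:3) full_map$sel[[l]]$post$face$indices <-
    seq_len(nrow(w$model$layers[[l]]$W))
  rn_full <- random_lesion_null(w$model, w$head, w$stimuli, full_map, "face",
                                n_draws = 1L, seed = 1L)
  all_units <- lapply(seq_along(w$model$layers), function(l)
    seq_len(nrow(w$model$layers[[l]]$W)))
  names(all_units) <- as.character(seq_along(all_units))
  full <- lesion_cost_profile(w$model, w$head, w$stimuli, lesion_spec(all_units))
  expect_equal(rn_full$profiles[[1]]$cost, full$cost)
  # random deficits spread less across categories than the domain lesion
  dom <- lesion_cost_profile(w$model, w$head, w$stimuli,
                             domain_lesion(w$map, "face"))
  expect_lt(mean(rn1$sd_cost), stats::sd(dom$cost) * 2)
})

test_that("early-layer lesions propagate to downstream selective units", {
  w <- trained_world()
  delta <- downstream_selectivity_change(w$model, w$map, "face", w$stimuli,
                                         early_layers = 1:2, target_layer = 3)
  expect_equal(names(which.min(delta)), "face")  # largest decrease
  expect_lt(delta[["face"]], 0)
  expect_error(downstream_selectivity_change(w$model, w$map, "face", w$stimuli,
                                             early_layers = 1:3,
                                             target_layer = 3),
               "must not be among")
  expect_error(downstream_selectivity_change(w$model, w$map, "face", w$stimuli,
                                             early_layers = 3, target_layer = 2),
               "strictly downstream")
  # a lesion spec with no units leaves the target untouched
  empty_map <- w$map
  for (l in 1:2) empty_map$sel[[l]]$post$face$indices <- integer(0)
  d0 <- downstream_selectivity_change(w$model, empty_map, "face", w$stimuli,
                                      early_layers = 1:2, target_layer = 3)
  expect_equal(unname(d0), rep(0, length(d0)))
})

test_that("top-fraction lesions rank by selectivity and correlate with full lesions", {
  w <- trained_world()
  spec_top <- domain_lesion(w$map, "face", top_fraction = 0.5)
  for (l in 1:3) {
    e <- w$map$sel[[l]]$post$face
    expect_true(all(spec_top$units[[as.character(l)]] %in% e$indices))
    kept <- spec_top$units[[as.character(l)]]
    # kept units carry the largest mean t
    t_kept <- e$t_mean[match(kept, e$indices)]
    expect_gte(min(t_kept), max(e$t_mean[!e$indices %in% kept]))
  }
  full <- lesion_cost_profile(w$model, w$head, w$stimuli,
                              domain_lesion(w$map, "face"))
  top <- lesion_cost_profile(w$model, w$head, w$stimuli, spec_top)
  expect_gt(compare_cost_profiles(full, top)$r, 0)
})
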