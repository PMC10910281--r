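test_that("lesion simulation handles the empty cohort and validates sizes", {
  ds <- simulate_lesions(0, small_territory(), seed = 1)
  expect_s3_class(ds, "lesion_dataset")
  expect_length(ds$subject_ids, 0)
  expect_error(overlap_map(ds), "empty")
  expect_error(territory_model(grid_shape = c(5, 5, 5),
                               size_range = c(1, 1000)),
               "exceeds the number of grid voxels")
  expect_error(territory_model(size_range = c(0, 10)), "at least 1")
  expect_error(territory_model(decay = 0), "positive")
})

test_that("lesion simulation is a pure function of its seed", {
  a <- simulate_lesions(5, small_territory(), seed = 42)
  b <- simulate_lesions(5, small_territory(), seed = 42)
  expect_identical(a$masks, b$masks)
  c <- simulate_lesions(5, small_territory(), seed = 43)
  expect_false(identical(a$masks, c$masks))
})

test_that("each simulated lesion is one 26-connected component", {
  ds <- simulate_lesions(25, small_territory(), seed = 7)
  for (m in ds$masks) {
    labels <- extmap:::label_components_26(m != 0)
    expect_identical(max(labels), 1L)
  }
  expect_identical(unname(ds$lesion_volumes),
                   vapply(ds$masks, function(m) sum(m != 0), 0))
})

test_that("lesion frequency decreases from the territory centre outwards", {
  terr <- territory_model(grid_shape = c(20L, 20L, 20L), decay = 0.2)
  ds <- simulate_lesions(200, terr, seed = 11)
  freq <- overlap_map(ds)$values
  centre_idx <- terr$centre
  expect_gt(freq[centre_idx[1], centre_idx[2], centre_idx[3]],
            freq[20, 20, 20])
  d <- extmap:::voxel_distance_map(terr$grid_shape, terr$centre)
  expect_lt(cor(as.vector(freq), as.vector(d), method = "spearman"), 0)
})

test_that("latent behaviour follows the stated load-to-deficit mapping", {
  terr <- territory_model(grid_shape = c(8L, 8L, 8L), size_range = c(1, 64))
  crit <- ball_region(c(8, 8, 8), c(4, 4, 4), 8)
  negl <- ball_region(c(8, 8, 8), c(6, 6, 4), 8)
  truth0 <- simulation_truth(terr, crit, negl, effect_size = 1,
                             neglect_effect = 1, noise_sd = 0, seed = 5)
  # three crafted subjects: no overlap, full destruction, partial (0.5)
  none <- array(0L, c(8, 8, 8)); none[1, 1, 1] <- 1L
  half <- crit; half[which(crit == 1)[1:4]] <- 0L
  ds <- lesion_dataset(list(none, crit, half))
  lat <- simulate_behaviour(ds, truth0)
  expect_equal(lat$miss_prob, c(0, 1, 0.5))
  expect_equal(lat$coc_expect[1], 0)
  expect_gt(lat$miss_prob[2], lat$miss_prob[3])  # monotone in load
  # mismatched grids error
  other <- lesion_dataset(list(array(0L, c(6, 6, 6))))
  expect_error(simulate_behaviour(other, truth0), "grid")
})

test_that("network truth uses the maximum load over critical masks", {
  terr <- territory_model(grid_shape = c(8L, 8L, 8L), size_range = c(1, 64))
  r1 <- ball_region(c(8, 8, 8), c(2, 2, 2), 6)
  r2 <- ball_region(c(8, 8, 8), c(7, 7, 7), 6)
  truth <- simulation_truth(terr, list(r1, r2), effect_size = 1,
                            noise_sd = 0, seed = 1)
  ds <- lesion_dataset(list(r1, r2))  # each subject destroys one node only
  lat <- simulate_behaviour(ds, truth)
  expect_equal(lat$miss_prob, c(1, 1))
})

test_that("confrontation simulation matches its binomial contract", {
  r0 <- simulate_confrontation(0, 10, seed = 1)
  expect_true(all(r0$bilateral_outcomes[, "contra"]))
  r1 <- simulate_confrontation(1, 10, seed = 1)
  expect_false(any(r1$bilateral_outcomes[, "contra"]))
  expect_identical(simulate_confrontation(0.3, 10, seed = 9),
                   simulate_confrontation(0.3, 10, seed = 9))
  # empty record allowed
  r_empty <- simulate_confrontation(0.5, 0, seed = 1)
  expect_identical(r_empty$n_bilateral, 0L)
  # large-sample frequency within 3 binomial SE of the latent probability
  big <- simulate_confrontation(0.5, 10000, seed = 2)
  miss_frac <- mean(!big$bilateral_outcomes[, "contra"])
  expect_lt(abs(miss_frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("extinction score converges to 100 x miss probability", {
  rec <- simulate_confrontation(0.3, 10000, seed = 3)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(compute_extinction_score(rec) - 30), 3 * 100 * se)
})

test_that("cancellation simulation honours its endpoint and calibration contracts", {
  lay <- cancellation_layout(35)
  s0 <- simulate_cancellation(0, lay, seed = 1)
  expect_true(all(s0$cancelled))
  expect_equal(compute_coc(s0), 0)
  s1 <- simulate_cancellation(1, lay, seed = 1)
  expect_identical(which(s1$cancelled), which.max(lay$target_x))
  sm1 <- simulate_cancellation(-1, lay, seed = 1)
  expect_identical(which(sm1$cancelled), which.min(lay$target_x))
  asym <- cancellation_sheet(c(0.2, 0.4, 1))
  expect_error(simulate_cancellation(0.3, asym), "symmetric")
  # Monte-Carlo calibration of the softmax link at an intermediate value
  cocs <- withr::with_seed(99, replicate(500, {
    sh <- simulate_cancellation(0.4, lay)
    if (any(sh$cancelled)) compute_coc(sh) else NA_real_
  }))
  expect_lt(abs(mean(cocs, na.rm = TRUE) - 0.4), 0.05)
})

test_that("the full cohort generator is seed-deterministic and well-formed", {
  a <- simulate_cohort(12, small_territory(), seed = 21)
  b <- simulate_cohort(12, small_territory(), seed = 21)
  expect_identical(a$behaviour, b$behaviour)
  expect_identical(a$lesions$masks, b$lesions$masks)
  expect_true(all(a$behaviour$ext_score >= 0 | is.na(a$behaviour$ext_score)))
  expect_true(all(a$behaviour$coc >= -1 & a$behaviour$coc <= 1))
  empty <- simulate_cohort(0, small_territory(), seed = 1)
  expect_identical(nrow(empty$behaviour), 0L)
})
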