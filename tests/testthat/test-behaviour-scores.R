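test_that("the assessability screen applies the 90% unilateral rule", {
  expect_false(screen_assessability(make_record(hits_uni_left = 8)))
  expect_true(screen_assessability(make_record(hits_uni_left = 9)))
  expect_true(screen_assessability(make_record(hits_uni_left = 10)))
})

test_that("extinction score counts contra misses among ipsi-detected trials", {
  expect_equal(compute_extinction_score(make_record(contra_miss = 4)), 40)
  expect_equal(compute_extinction_score(make_record(contra_miss = 0)), 0)
  # two ipsi-miss trials are excluded; 4 misses among the remaining 8
  expect_equal(compute_extinction_score(
    make_record(contra_miss = 4, ipsi_miss = 2)), 50)
  all_ipsi_missed <- make_record(ipsi_miss = 10)
  expect_error(compute_extinction_score(all_ipsi_missed), "unassessable")
})

test_that("extinction index evaluates the difference of differences", {
  expect_equal(compute_extinction_index(1, 0, 1, 1), 1)
  expect_equal(compute_extinction_index(1, 1, 1, 1), 0)
  expect_equal(compute_extinction_index(1, 1, 1, 0), -1)
  expect_error(compute_extinction_index(1.2, 0, 1, 1), "\\[0, 1\\]")
  # antisymmetry: swapping the two sides flips the sign
  withr::with_seed(4, for (i in 1:20) {
    p <- runif(4)
    expect_equal(compute_extinction_index(p[1], p[2], p[3], p[4]),
                 -compute_extinction_index(p[3], p[4], p[1], p[2]))
  })
})

test_that("CoC is the mean cancelled position and is order-invariant", {
  lay <- cancellation_layout(5)  # x = -1, -0.5, 0, 0.5, 1
  expect_equal(compute_coc(cancellation_sheet(lay$target_x, rep(TRUE, 5))), 0)
  right_only <- cancellation_sheet(lay$target_x, lay$target_x == 1)
  expect_equal(compute_coc(right_only), 1)
  expect_equal(compute_coc(cancellation_sheet(c(0.5, 1), c(TRUE, TRUE))), 0.75)
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- cancellation_sheet(lay$target_x[perm], (lay$target_x == 1)[perm])
  expect_equal(compute_coc(shuffled), compute_coc(right_only))
  expect_error(compute_coc(cancellation_sheet(lay$target_x)), "indeterminate")
})

test_that("two cancellation tasks average into one neglect score", {
  expect_equal(average_coc(0, 0), 0)
  expect_equal(average_coc(0.2, 0.4), 0.3)
  expect_equal(average_coc(-1, 1), 0)
  expect_error(average_coc(1.5, 0))
})

test_that("nuisance regression yields orthogonal residuals", {
  coc <- seq(0, 1, length.out = 20)
  perfect <- suppressWarnings(residualize_extinction(2 * coc, coc))
  expect_equal(perfect$residuals, rep(0, 20), tolerance = 1e-12)
  expect_equal(perfect$summary$r_squared, 1)
  expect_equal(perfect$summary$slope, 2)

  withr::with_seed(8, {
    ext <- rnorm(10000); cv <- rnorm(10000)
    fit <- residualize_extinction(ext, cv)
    se <- summary(lm(ext ~ cv))$coefficients[2, 2]
    expect_lt(abs(fit$summary$slope), 3 * se)
    expect_lt(abs(cor(fit$residuals, cv)), 1e-10)
  })
  expect_error(residualize_extinction(1:5, rep(0.2, 5)), "constant")
})

test_that("covariate-control validation computes Spearman rho", {
  expect_equal(validate_covariate_control(1:8, (1:8)^2)$rho, 1)
  expect_equal(validate_covariate_control(1:8, -(1:8))$rho, -1)
  # hand-derived: one adjacent transposition, rho = 1 - 6*2/(5*24)
  expect_equal(validate_covariate_control(1:5, c(1, 2, 3, 5, 4))$rho, 0.9)
  expect_error(validate_covariate_control(rep(1, 5), 1:5), "ties")
})

test_that("behaviour tables round-trip through CSV", {
  beh <- data.frame(subject_id = c("s1", "s2", "s3"),
                    ext_score = c(0, 40, 100), coc = c(0, 0.2, 0.8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_behaviour_csv(beh, path)
  back <- read_behaviour_csv(path)
  expect_equal(back$ext_score, beh$ext_score)
  expect_equal(back$coc, beh$coc)
  expect_true(all(is.na(back$ext_index)))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject_id = "s1", score = 1), bad,
                   row.names = FALSE)
  expect_error(read_behaviour_csv(bad), "must contain")
})
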