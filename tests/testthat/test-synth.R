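test_that("configuration invariants are enforced", {
  expect_error(synth_config(provided_rating_bounds = c(0.8, 0.2)),
               "bounds")
  expect_error(synth_config(slope_correlation = 1.2),
               "positive definite")
  expect_error(synth_config(factor_loading_matrix = matrix(0, 4, 5)),
               "one row per scale")
  expect_error(synth_config(cutpoints = list(compliance = c(1, 0, 2, 3),
                                             gatherings = c(-1, 0, 1, 2))),
               "strictly increasing")
  expect_error(synth_config(time4_retention_rate = 1.4), "\\[0, 1\\]")
})

test_that("a cohort at the emulated full scale produces 7200 Time-1 trial rows", {
  cfg <- synth_config(n_participants = 450, n_trials_per_timepoint = 16,
                      time2_retention_rate = 1, time4_retention_rate = 1,
                      seed = 77)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$influence_trials$timepoint == "t1"), 7200)
  expect_equal(nrow(co$truth), 450)
})

test_that("generation is deterministic under a fixed seed", {
  a <- small_cohort(seed = 5)
  b <- small_cohort(seed = 5)
  for (nm in c("participants", "influence_trials", "dictator", "mcq",
               "cyberball", "questionnaires", "outcomes", "truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c <- small_cohort(seed = 6)
  expect_false(identical(a$truth, c$truth))
})

test_that("cohort tables satisfy their range and shape invariants", {
  co <- small_cohort(n = 60, seed = 9)
  tr <- co$influence_trials
  expect_true(all(tr$initial >= 0 & tr$initial <= 1))
  expect_true(all(tr$second >= 0 & tr$second <= 1))
  expect_true(all(tr$provided >= 0.2 & tr$provided <= 0.8))
  expect_true(all(co$outcomes$compliance %in% 1:5))
  expect_true(all(co$outcomes$gatherings %in% 1:5))
  expect_lte(nrow(co$outcomes), nrow(co$participants))
  expect_equal(nrow(co$truth), nrow(co$participants))
  # trial count equals participants x trials at each present time point
  expect_equal(sum(tr$timepoint == "t1"),
               60 * co$config$n_trials_per_timepoint)
  expect_equal(sum(tr$timepoint == "t2"),
               sum(co$participants$present_t2) *
                 co$config$n_trials_per_timepoint)
})

test_that("null influence slopes with tiny noise leave second ratings at the initial ratings", {
  cfg <- synth_config(n_participants = 30, seed = 13,
                      true_delta_plus_mean = 0, true_delta_plus_sd = 0,
                      true_delta_minus_mean = 0, true_delta_minus_sd = 0,
                      true_residual_sd_location = log(1e-4),
                      true_residual_sd_spread = 0)
  # zero-SD slope traits make some z-scored truth columns constant
  co <- suppressWarnings(generate_cohort(cfg))
  expect_lt(max(abs(co$influence_trials$second -
                      co$influence_trials$initial)), 0.01)
})

test_that("floor/ceiling mass grows with the residual-SD location", {
  mass <- vapply(c(log(0.05), log(0.15), log(0.4)), function(loc) {
    co <- generate_cohort(synth_config(n_participants = 150, seed = 23,
                                       true_residual_sd_location = loc))
    mean(co$influence_trials$initial %in% c(0, 1))
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("occasion traits reproduce the configured test-retest correlation", {
  co <- generate_cohort(synth_config(n_participants = 450, seed = 31))
  r <- co$config$test_retest_r
  expect_equal(cor(co$truth$prosociality_t1, co$truth$prosociality_t2),
               r, tolerance = 0.08)
  expect_equal(cor(co$truth$delta_minus_t1, co$truth$delta_minus_t2),
               r, tolerance = 0.12)
})

test_that("outcome marginals match closed-form cumulative-probit probabilities under null effects", {
  cfg <- synth_config(
    n_participants = 4000, seed = 41, time4_retention_rate = 1,
    outcome_response_rate = 1,
    true_outcome_coefficients = list(
      compliance = c(prosociality = 0),
      gatherings = c(prosociality = 0)),
    covariate_coefficients = c(age = 0, day = 0, gender = 0, group = 0))
  co <- generate_cohort(cfg)
  probs <- drop(cumulative_probit_probs(0, cfg$cutpoints$compliance))
  freq <- tabulate(co$outcomes$compliance, 5) / nrow(co$outcomes)
  expect_lt(max(abs(freq - probs)), 0.025)
})

test_that("cyberball scores reproduce the calibrated phase means and change correlation", {
  cfg <- synth_config(n_participants = 400, seed = 51)
  cb <- generate_cyberball_scores(cfg)
  expect_equal(mean(cb$mood_baseline), 2.85, tolerance = 0.15)
  expect_equal(mean(cb$mood_exclusion), 3.85, tolerance = 0.15)
  expect_equal(mean(cb$mood_exclusion - cb$mood_baseline), 1.0,
               tolerance = 0.2)
  chm <- cb$mood_exclusion - (cb$mood_baseline + cb$mood_inclusion) / 2
  cha <- cb$anxiety_exclusion -
    (cb$anxiety_baseline + cb$anxiety_inclusion) / 2
  expect_equal(cor(chm, cha), 0.74, tolerance = 0.08)

  # null exclusion effect: all three phase means coincide
  cfg0 <- synth_config(n_participants = 400, seed = 52,
                       cyberball = utils::modifyList(
                         default_cyberball_calibration(),
                         list(mood_exclusion_shift = 0,
                              anxiety_exclusion_shift = 0,
                              mood_inclusion_mean = 2.85,
                              anxiety_inclusion_mean = 1.84)))
  cb0 <- generate_cyberball_scores(cfg0)
  expect_equal(mean(cb0$mood_exclusion), mean(cb0$mood_baseline),
               tolerance = 0.2)
})

test_that("questionnaire generation follows the loading structure", {
  # zero loadings: pure noise, pairwise correlations near zero
  cfg0 <- synth_config(n_participants = 300, seed = 61,
                       factor_loading_matrix = matrix(
                         0, 30, 5,
                         dimnames = dimnames(default_loading_matrix())),
                       item_missing_rate = 0)
  co0 <- generate_cohort(cfg0)
  q0 <- as.matrix(co0$questionnaires[co0$questionnaires$timepoint == "t1",
                                     -(1:2)])
  off <- cor(q0)[upper.tri(diag(30))]
  expect_lt(max(abs(off)), 0.25)
  expect_false(anyNA(q0))

  # strong 5-factor structure: leading five eigenvalues dominate, as in
  # the eigendecomposition of the implied population matrix
  L <- default_loading_matrix()
  Phi <- matrix(0.3, 5, 5); diag(Phi) <- 1
  h2 <- rowSums((L %*% Phi) * L)
  pop <- L %*% Phi %*% t(L) + diag(1 - h2)
  pop_eig <- eigen(pop, only.values = TRUE)$values
  co <- generate_cohort(synth_config(n_participants = 400, seed = 62,
                                     item_missing_rate = 0))
  q <- as.matrix(co$questionnaires[co$questionnaires$timepoint == "t1",
                                   -(1:2)])
  emp_eig <- eigen(cor(q), only.values = TRUE)$values
  expect_equal(emp_eig[1:5], pop_eig[1:5], tolerance = 0.2)
  expect_gt(emp_eig[5], max(pop_eig[6]) * 1.5)

  # factor-score table misaligned with the loading matrix is rejected
  expect_error(generate_questionnaires(co$config, matrix(0, 10, 3)),
               "misaligned")
})

test_that("a cohort round-trips losslessly through the text-table format", {
  co <- small_cohort(n = 25, seed = 71)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "schema.json")))
  back <- read_cohort(dir)
  for (nm in c("participants", "influence_trials", "dictator", "mcq",
               "cyberball", "questionnaires", "outcomes", "truth")) {
    expect_equal(co[[nm]], back[[nm]], tolerance = 0)
  }
  expect_identical(co$config, back$config)
  # the restored config regenerates the identical cohort
  expect_identical(generate_cohort(back$config)$truth, co$truth)
})
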