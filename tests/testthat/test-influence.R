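test_that("the delta decomposition follows its definitions exactly", {
  tr <- data.frame(participant_id = 1, scenario_id = 1:3,
                   initial = c(0.5, 0.5, 0.4),
                   provided = c(0.8, 0.2, 0.4),
                   second = c(0.6, 0.4, 0.4))
  tt <- build_trial_table(tr)
  expect_equal(tt$delta, c(0.3, -0.3, 0))
  expect_equal(tt$delta_plus, c(0.3, 0, 0))
  expect_equal(tt$delta_minus, c(0, -0.3, 0))

  co <- small_cohort(n = 30, seed = 3)
  tt2 <- trial_table_tp(co)
  expect_equal(tt2$delta_plus + tt2$delta_minus, tt2$delta)
  expect_true(all(tt2$delta_plus * tt2$delta_minus == 0))
  expect_true(all(tt2$delta_plus >= 0 & tt2$delta_minus <= 0))
})

test_that("rows with missing second ratings are dropped with a message", {
  tr <- data.frame(participant_id = 1:4, scenario_id = 1:4,
                   initial = 0.5, provided = 0.5,
                   second = c(0.4, NA, 0.6, NA))
  expect_message(tt <- build_trial_table(tr), "dropping 2")
  expect_equal(nrow(tt), 2)
  tr$second <- 0.5
  tr$provided <- c(0.1, 0.5, 0.5, 0.5)
  expect_warning(build_trial_table(tr), "outside the configured bounds")
})

test_that("the censored-normal likelihood matches a quadrature oracle and is proper", {
  expect_equal(censored_normal_loglik(0, 0, 1), log(0.5))
  grid <- expand.grid(mu = c(-0.5, 0.2, 0.5, 0.9, 1.5),
                      sigma = c(0.05, 0.2, 0.8))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; s <- grid$sigma[i]
    # total probability: interior integral plus both boundary masses
    interior <- integrate(function(y) exp(censored_normal_loglik(y, mu, s)),
                          1e-9, 1 - 1e-9, rel.tol = 1e-10)$value
    total <- interior + exp(censored_normal_loglik(0, mu, s)) +
      exp(censored_normal_loglik(1, mu, s))
    expect_equal(total, 1, tolerance = 1e-7)
    # boundary masses agree with quadrature over the latent tails
    lower <- integrate(function(z) dnorm(z, mu, s), -Inf, 0,
                       rel.tol = 1e-12)$value
    upper <- integrate(function(z) dnorm(z, mu, s), 1, Inf,
                       rel.tol = 1e-12)$value
    expect_lt(abs(exp(censored_normal_loglik(0, mu, s)) - lower), 1e-8)
    expect_lt(abs(exp(censored_normal_loglik(1, mu, s)) - upper), 1e-8)
  }
  expect_error(censored_normal_loglik(1.2, 0, 1), "outside")
  expect_error(censored_normal_loglik(0.5, 0, -1), "positive")
})

test_that("the ordered-beta likelihood reduces to the beta density in the interior", {
  set.seed(4)
  for (i in 1:20) {
    eta <- rnorm(1); c1 <- -3 + runif(1); c2 <- c1 + 1 + runif(1)
    phi <- runif(1, 2, 30); y <- runif(1, 0.05, 0.95)
    mu <- plogis(eta)
    oracle <- log(plogis(eta - c1) - plogis(eta - c2)) +
      dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
    expect_equal(ordered_beta_loglik(y, eta, c1, c2, phi), oracle,
                 tolerance = 1e-12)
  }
  # the three components form a proper distribution
  eta <- 0.4; c1 <- -2; c2 <- 1.5; phi <- 8
  interior <- integrate(function(y)
    exp(ordered_beta_loglik(y, eta, c1, c2, phi)), 1e-9, 1 - 1e-9,
    rel.tol = 1e-9)$value
  total <- interior + exp(ordered_beta_loglik(0, eta, c1, c2, phi)) +
    exp(ordered_beta_loglik(1, eta, c1, c2, phi))
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("the prosociality model recovers person-level intercepts and residual SDs", {
  co <- generate_cohort(synth_config(n_participants = 100, seed = 15))
  tt <- trial_table_tp(co)
  fit <- fit_prosociality(tt, fast_influence(seed = 2))
  expect_equal(nrow(fit$scores), 100)
  expect_gt(cor(fit$scores$prosociality, co$truth$prosociality_t1), 0.8)
  # person-specific residual SDs track the generating scale (rank order)
  expect_gt(cor(fit$scores$residual_sd, exp(co$truth$log_residual_sd),
                method = "spearman"), 0.5)
  expect_gt(min(fit$scores$residual_sd), 0)
  expect_equal(fit$global_mean, co$config$true_prosociality_mean,
               tolerance = 0.1)
})

test_that("homogeneous participants yield a near-zero participant intercept SD", {
  cfg <- synth_config(n_participants = 60, seed = 16,
                      true_prosociality_sd = 1e-6,
                      scenario_offset_sd = 0.05)
  co <- generate_cohort(cfg)
  fit <- fit_prosociality(trial_table_tp(co), fast_influence(seed = 3))
  expect_lt(fit$participant_sd, 0.05)
})

test_that("perfect conformers produce unit influence slopes", {
  # construct trials where the second rating equals the provided rating
  set.seed(17)
  n_p <- 30; n_t <- 16
  tr <- data.frame(
    participant_id = rep(1:n_p, each = n_t),
    scenario_id = rep(1:n_t, n_p),
    initial = runif(n_p * n_t, 0.2, 0.8),
    provided = runif(n_p * n_t, 0.2, 0.8))
  tr$second <- tr$provided
  tt <- build_trial_table(tr)
  fit <- fit_susceptibility(tt, fast_influence(seed = 4))
  # second = initial + 1 * delta+ + 1 * delta-
  expect_equal(unname(fit$fixed["b_init"]), 1, tolerance = 0.05)
  expect_equal(unname(fit$fixed["b_plus"]), 1, tolerance = 0.05)
  expect_equal(unname(fit$fixed["b_minus"]), 1, tolerance = 0.05)
  # posterior predictive: fitted means reproduce second = provided
  mu <- fit$fixed["b0"] + fit$fixed["b_init"] * tt$initial +
    fit$fixed["b_plus"] * tt$delta_plus +
    fit$fixed["b_minus"] * tt$delta_minus
  expect_lt(max(abs(mu - tt$provided)), 0.08)
})

test_that("null susceptibility yields fixed-effect intervals covering zero", {
  cfg <- synth_config(n_participants = 60, seed = 18,
                      true_delta_plus_mean = 0, true_delta_plus_sd = 0.02,
                      true_delta_minus_mean = 0,
                      true_delta_minus_sd = 0.02)
  co <- generate_cohort(cfg)
  fit <- fit_susceptibility(trial_table_tp(co), fast_influence(seed = 5))
  for (par in c("b_plus", "b_minus")) {
    h <- hdi(fit$draws[, par], 0.95)
    expect_lt(h[1], 0)
    expect_gt(h[2], 0)
  }
})

test_that("family comparison aligns participants and reports slope SDs", {
  co <- generate_cohort(synth_config(n_participants = 40, seed = 19))
  tt <- trial_table_tp(co)
  st <- fast_influence(seed = 6)
  f1 <- fit_susceptibility(tt, st)
  # identical model compared with itself correlates perfectly
  cmp_same <- compare_families(list(a = f1, b = f1))
  expect_equal(cmp_same$correlations["a", "b"], 1)
  # differing participant sets are aligned on the intersection
  f2 <- f1
  f2$scores <- f2$scores[1:30, ]
  expect_warning(cmp <- compare_families(list(full = f1, sub = f2)),
                 "aligned on 30")
  expect_equal(cmp$n_common, 30)
  expect_equal(cmp$summary$slope_sd_minus[1],
               unname(f1$slope_sd["delta_minus"]))
  # a family with collapsed random-slope variance reports a near-zero SD
  f3 <- f1
  f3$slope_sd[] <- c(1e-4, 1e-4)
  cmp3 <- compare_families(list(normal = f1, degenerate = f3))
  expect_lt(cmp3$summary$slope_sd_minus[2], 1e-3)
})

test_that("student-t susceptibility agrees with the primary family on clean data", {
  co <- generate_cohort(synth_config(n_participants = 50, seed = 20))
  tt <- trial_table_tp(co)
  st <- fast_influence(seed = 7)
  fn <- fit_susceptibility(tt, st, family = "normal")
  expect_message(ft <- fit_susceptibility(tt, st, family = "student_t"),
                 "boundary responses")
  cmp <- compare_families(list(normal = fn, student_t = ft))
  expect_gt(cmp$correlations["normal", "student_t"], 0.8)
})
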