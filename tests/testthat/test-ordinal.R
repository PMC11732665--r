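test_that("cumulative-probit cell probabilities match the closed form", {
  tau <- c(-1, 0, 1, 2)
  p <- drop(cumulative_probit_probs(0, tau))
  oracle <- c(pnorm(-1), pnorm(0) - pnorm(-1), pnorm(1) - pnorm(0),
              pnorm(2) - pnorm(1), 1 - pnorm(2))
  expect_lt(max(abs(p - oracle)), 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # symmetric cutpoints at zero latent mean give a symmetric distribution
  ps <- unname(drop(cumulative_probit_probs(0, c(-1.5, -0.5, 0.5, 1.5))))
  expect_equal(ps[1], ps[5], tolerance = 1e-12)
  expect_equal(ps[2], ps[4], tolerance = 1e-12)

  # extreme latent locations push all mass to the boundary category
  expect_gt(cumulative_probit_probs(50, tau)[, 5], 1 - 1e-10)
  expect_error(cumulative_probit_probs(0, c(1, 0, 2, 3)),
               "strictly increasing")
})

test_that("larger latent locations stochastically increase the response", {
  tau <- c(-2.05, -1.48, -0.81, 0.5)
  etas <- seq(-2, 2, by = 0.5)
  P <- cumulative_probit_probs(etas, tau)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  cum <- t(apply(P, 1, cumsum))
  for (k in 1:4) expect_true(all(diff(cum[, k]) < 0))
})

test_that("the multiplicity-adjusted credible level follows 1 - alpha/m", {
  expect_equal(adjusted_credible_level(11, 0.05), 0.995)
  expect_equal(adjusted_credible_level(1, 0.05), 0.95)
  expect_equal(adjusted_credible_level(2, 0.05), 0.975)
  expect_error(adjusted_credible_level(0, 0.05), ">= 1")
})

test_that("highest density intervals match normal quantiles and nest", {
  set.seed(9)
  draws <- rnorm(1e6)
  h95 <- hdi(draws, 0.95)
  expect_equal(h95, c(-1.96, 1.96), tolerance = 0.015)
  h995 <- hdi(draws, 0.995)
  expect_lt(h995[1], h95[1])
  expect_gt(h995[2], h95[2])
  # symmetric unimodal sample: HDI close to the equal-tailed interval
  expect_equal(h95, unname(quantile(draws, c(0.025, 0.975))),
               tolerance = 0.02)
  expect_warning(hdi(rnorm(100)), "1000 draws")
})

test_that("posterior effect-size bins sum to one and match the closed form", {
  expect_equal(unname(effect_size_classification(rep(0.05, 10))),
               c(1, 0, 0))
  expect_equal(unname(effect_size_classification(c(rep(-0.2, 5),
                                                   rep(0.2, 5)))),
               c(0, 1, 0))
  # boundary draws count towards the inner bin
  expect_equal(unname(effect_size_classification(c(0.1, 0.3))),
               c(0.5, 0.5, 0))
  set.seed(10)
  draws <- rnorm(5e5, 0.262, 0.082)
  bins <- effect_size_classification(draws)
  oracle_large <- 1 - pnorm((0.3 - 0.262) / 0.082) +
    pnorm((-0.3 - 0.262) / 0.082)
  expect_equal(unname(bins["p_medium_to_large"]), oracle_large,
               tolerance = 0.005)
  expect_equal(sum(bins), 1, tolerance = 1e-12)
})

test_that("the ordinal sampler recovers simulated coefficients and matches the MLE", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 500
  x <- rnorm(n); day <- rnorm(n)
  tau <- c(-1.5, -0.5, 0.5, 1.5)      # all five categories well populated
  y <- as.integer(cut(0.5 * x - 0.17 * day + rnorm(n),
                      c(-Inf, tau, Inf)))
  d <- data.frame(y = y, x = x, day = day)
  fit <- fit_ordinal_model(d, "y", "x", "day",
                           settings = ordinal_mcmc(warmup = 1000,
                                                   iter = 2000, seed = 4))
  expect_lt(abs(fit$summary["x", "mean"] - 0.5), 0.12)
  expect_true(fit$convergence_ok)
  # frequentist cross-check: posterior mean close to the probit MLE
  ml <- MASS::polr(factor(y) ~ x + day, data = d, method = "probit")
  expect_equal(unname(fit$summary["x", "mean"]), unname(coef(ml)["x"]),
               tolerance = 0.05)
  expect_equal(unname(fit$summary[paste0("cutpoint_", 1:4), "mean"]),
               unname(ml$zeta), tolerance = 0.12)
  # cutpoints are ordered in every retained draw
  cp <- fit$draws[, paste0("cutpoint_", 1:4)]
  expect_true(all(cp[, 2] > cp[, 1] & cp[, 3] > cp[, 2] &
                    cp[, 4] > cp[, 3]))
  # the adjusted interval contains the 95% interval
  expect_lt(fit$summary["x", "hdi_adj_lb"], fit$summary["x", "hdi95_lb"])
  expect_gt(fit$summary["x", "hdi_adj_ub"], fit$summary["x", "hdi95_ub"])
})

test_that("fitting is invariant to affine rescaling of the raw predictor", {
  set.seed(22)
  n <- 250
  x <- rnorm(n)
  y <- as.integer(cut(0.4 * x + rnorm(n),
                      c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)))
  d1 <- data.frame(y = y, x = x)
  d2 <- data.frame(y = y, x = 12 * x - 7)
  f1 <- fit_ordinal_model(d1, "y", "x", settings = fast_ordinal(seed = 5))
  f2 <- fit_ordinal_model(d2, "y", "x", settings = fast_ordinal(seed = 5))
  expect_equal(f1$summary[, "mean"], f2$summary[, "mean"],
               tolerance = 1e-10)
})

test_that("listwise deletion and missing-category handling are reported", {
  set.seed(23)
  n <- 150
  d <- data.frame(y = sample(c(1, 2, 4, 5), n, replace = TRUE),
                  x = rnorm(n), cov = rnorm(n))
  d$x[1:10] <- NA
  f <- fit_ordinal_model(d, "y", "x", "cov",
                         settings = fast_ordinal(seed = 6))
  expect_equal(f$n_used, n - 10)
  expect_equal(f$n_dropped, 10)
  cp <- f$draws[, grep("cutpoint", colnames(f$draws))]
  expect_true(all(apply(cp, 1, function(v) all(diff(v) > 0))))
})

test_that("the results table orders by effect magnitude and flags problems", {
  set.seed(24)
  mk <- function(mean_target, reliable = TRUE) {
    n <- 200
    x <- rnorm(n)
    y <- as.integer(cut(mean_target * x + rnorm(n),
                        c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)))
    f <- fit_ordinal_model(data.frame(y = y, x = x), "y", "x",
                           settings = fast_ordinal(seed = 7))
    f$convergence_ok <- reliable
    f
  }
  fits <- list(compliance = list(strong = mk(0.6),
                                 weak = mk(-0.1, reliable = FALSE),
                                 absent = NULL))
  tab <- build_results_table(fits)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$predictor[1], "strong")
  expect_true(is.na(tab$mean[tab$predictor == "absent"]))
  expect_false(tab$reliable[tab$predictor == "weak"])
  expect_true(abs(tab$mean[1]) >= abs(tab$mean[2]))
})
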