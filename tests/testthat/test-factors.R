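# Deterministic reference data used across retention tests.
make_factor_data <- function(n, L, Phi = NULL, seed = 1) {
  k <- ncol(L)
  if (is.null(Phi)) Phi <- diag(k)
  h2 <- rowSums((L %*% Phi) * L)
  stopifnot(all(h2 < 1))
  set.seed(seed)
  f <- matrix(rnorm(n * k), n) %*% chol(Phi)
  f %*% t(L) + matrix(rnorm(n * nrow(L)), n) %*% diag(sqrt(1 - h2))
}

test_that("parallel analysis separates structure from noise", {
  set.seed(2)
  noise <- matrix(rnorm(500 * 30), 500)
  expect_equal(parallel_analysis(noise, n_resamples = 150,
                                 seed = 3)$n_factors, 0L)

  L1 <- matrix(0.7, 12, 1)
  x1 <- make_factor_data(400, L1, seed = 4)
  expect_equal(parallel_analysis(x1, n_resamples = 150,
                                 seed = 5)$n_factors, 1L)

  # the generator's default five-factor battery
  co <- generate_cohort(synth_config(n_participants = 400, seed = 6))
  q <- as.matrix(co$questionnaires[co$questionnaires$timepoint == "t1",
                                   -(1:2)])
  expect_equal(parallel_analysis(q, n_resamples = 150,
                                 seed = 7)$n_factors, 5L)
  # resampling mode agrees on clear structure
  expect_equal(parallel_analysis(q, n_resamples = 150, seed = 7,
                                 mode = "resampling")$n_factors, 5L)
})

test_that("Velicer's MAP test finds the generating dimensionality", {
  # identity input: partialling any component degenerates (ridge warnings)
  expect_equal(suppressWarnings(velicer_map(diag(10))$n_factors), 0L)

  # closed-form 2-block correlation matrix
  R <- diag(12)
  R[1:6, 1:6] <- 0.6
  R[7:12, 7:12] <- 0.6
  diag(R) <- 1
  expect_equal(suppressWarnings(velicer_map(R)$n_factors), 2L)

  co <- generate_cohort(synth_config(n_participants = 400, seed = 8))
  q <- as.matrix(co$questionnaires[co$questionnaires$timepoint == "t1",
                                   -(1:2)])
  expect_equal(velicer_map(cor(q, use = "pairwise.complete.obs"))$n_factors,
               5L)
})

test_that("minres + oblimin recovers a known five-factor structure", {
  L <- default_loading_matrix()
  Phi <- matrix(0.3, 5, 5); diag(Phi) <- 1
  x <- make_factor_data(800, L, Phi, seed = 11)
  fit <- fit_factors(x, 5)
  al <- align_to_reference(fit$loadings, L)
  expect_true(all(al$congruence >= 0.95))
  expect_lt(fit$rmsr, 0.05)
  # reconstructed correlations match the observed matrix
  R <- cor(x)
  implied <- fit$loadings %*% fit$Phi %*% t(fit$loadings)
  resid <- (R - implied)[upper.tri(R)]
  expect_lt(sqrt(mean(resid^2)), 0.05)
  # factor correlations are a proper correlation matrix
  expect_equal(unname(diag(fit$Phi)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(eigen(fit$Phi, only.values = TRUE)$values > 0))
})

test_that("a single factor is recovered proportionally", {
  L1 <- matrix(seq(0.5, 0.85, length.out = 10), 10, 1)
  x <- make_factor_data(600, L1, seed = 12)
  fit <- fit_factors(x, 1)
  cr <- abs(sum(fit$loadings * L1) /
              sqrt(sum(fit$loadings^2) * sum(L1^2)))
  expect_gt(cr, 0.98)
})

test_that("rotation leaves an orthogonal simple structure essentially unchanged", {
  L <- matrix(0, 12, 2)
  L[1:6, 1] <- 0.75
  L[7:12, 2] <- 0.75
  x <- make_factor_data(2000, L, seed = 13)
  fit <- fit_factors(x, 2)
  al <- align_to_reference(fit$loadings, L)
  expect_lt(max(abs(al$loadings - L)), 0.08)
  expect_lt(abs(fit$Phi[1, 2]), 0.1)
})

test_that("factor scores are invariant to rescaling an input variable", {
  L <- default_loading_matrix()
  x <- make_factor_data(300, L, seed = 14)
  f1 <- fit_factors(x, 5)
  x2 <- x
  x2[, 3] <- x2[, 3] * 40 + 100     # affine rescaling of one column
  f2 <- fit_factors(x2, 5)
  cc <- abs(cor(f1$factor_scores, f2$factor_scores))
  expect_true(all(apply(cc, 1, max) > 0.999))
})

test_that("bartlett scores are available behind the switch", {
  L <- default_loading_matrix()
  x <- make_factor_data(300, L, seed = 15)
  fr <- fit_factors(x, 5, scores = "regression")
  fb <- fit_factors(x, 5, scores = "bartlett")
  # the two methods give highly correlated but not identical scores
  r <- abs(diag(cor(fr$factor_scores, fb$factor_scores)))
  expect_true(all(r > 0.98))
  expect_false(isTRUE(all.equal(fr$factor_scores, fb$factor_scores)))
})
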