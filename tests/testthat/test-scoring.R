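test_that("prorated sum tolerates limited missingness and equals the plain sum otherwise", {
  expect_equal(prorated_sum_score(rep(2, 10), 10), 20)
  # exactly 20% missing is still tolerated
  expect_equal(prorated_sum_score(c(2, 2, 2, 2, NA), 5), 10)
  # 1 of 10 missing, observed mean 2.0 -> 20 (mean(observed) x n_items)
  expect_equal(prorated_sum_score(c(rep(2, 9), NA), 10), 20)
  # more than 20% missing -> missing
  expect_true(is.na(prorated_sum_score(c(rep(2, 7), NA, NA, NA), 10)))
  expect_true(is.na(prorated_sum_score(rep(NA_real_, 5), 5)))
  # literal reading multiplies by the number of answered items
  expect_equal(prorated_sum_score(c(3, 3, 3, 3, NA), 5, literal = TRUE), 12)
  expect_error(prorated_sum_score(1:5, 6), "expected 6 responses")

  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- round(runif(n, 0, 3), 1)
    expect_equal(prorated_sum_score(x, n), sum(x))
  }
})

test_that("dictator scoring passes validated fractions through", {
  expect_equal(score_dictator(1.0), 1.0)
  expect_equal(score_dictator(0.0), 0.0)
  expect_equal(score_dictator(0.64), 0.64)
  expect_true(is.na(score_dictator(NA_real_)))
  expect_error(score_dictator(1.2), "\\[0, 1\\]")
})

test_that("prosocial recoding reflects anti-social items and is an involution", {
  expect_equal(recode_prosocial_direction(0.3, "antisocial"), 0.7)
  expect_equal(recode_prosocial_direction(0.3, "prosocial"), 0.3)
  expect_error(recode_prosocial_direction(0.3, "neutral"), "scenario_type")
  set.seed(11)
  x <- runif(50)
  type <- sample(c("prosocial", "antisocial"), 50, replace = TRUE)
  once <- recode_prosocial_direction(x, type)
  expect_true(all(once >= 0 & once <= 1))
  expect_equal(recode_prosocial_direction(once, type), x)
})

test_that("time-point averaging uses the available time point when one is missing", {
  expect_equal(average_timepoints(0.4, 0.8), 0.6)
  expect_equal(average_timepoints(NA, 0.8), 0.8)
  expect_equal(average_timepoints(0.4, NA), 0.4)
  expect_true(is.na(average_timepoints(NA_real_, NA_real_)))
  set.seed(3)
  z <- zscore(rnorm(200, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("monetary-choice scoring matches the exhaustive enumeration oracle", {
  items <- kirby_items()
  expect_equal(nrow(items), 27)
  expect_equal(as.vector(table(items$magnitude)), c(9, 9, 9))

  # extreme consistent responders land in the boundary bins
  all_delayed <- kirby_discount_rates(rep("delayed", 27), items)
  all_immediate <- kirby_discount_rates(rep("immediate", 27), items)
  for (mag in c("small", "medium", "large")) {
    ks <- items$k[items$magnitude == mag]
    expect_equal(all_delayed[[paste0("k_", mag)]], min(ks))
    expect_equal(all_immediate[[paste0("k_", mag)]], max(ks))
  }

  # random response patterns, including missing entries, agree exactly
  set.seed(19)
  for (i in 1:200) {
    ch <- sample(c("immediate", "delayed"), 27, replace = TRUE)
    if (i %% 4 == 0) ch[sample(27, sample(0:4, 1))] <- NA
    got <- kirby_discount_rates(ch, items)
    want <- kirby_bruteforce(ch, items)
    expect_equal(c(got$k_small, got$k_medium, got$k_large),
                 unname(want), tolerance = 1e-12)
  }

  # a band with more than 20% of choices missing is scored missing
  ch <- rep("delayed", 27)
  ch[items$magnitude == "small"][1:2] <- NA
  expect_true(is.na(kirby_discount_rates(ch, items)$k_small))
})

test_that("discounting composite averages cohort-wise z-scored log rates", {
  set.seed(5)
  ks <- exp(matrix(rnorm(60, log(0.01), 1), 20))
  comp <- discount_composite(ks[, 1], ks[, 2], ks[, 3])
  manual <- rowMeans(scale(log(ks)))
  expect_equal(comp, manual, tolerance = 1e-12)
})

test_that("rejection-sensitivity composite matches a hand-computed oracle", {
  mood <- data.frame(baseline = c(3, 2, 4, 3, 2),
                     inclusion = c(3, 3, 4, 2, 2),
                     exclusion = c(5, 3, 4, 4, 2))
  anx <- data.frame(baseline = c(1.5, 2, 1, 2.5, 2),
                    inclusion = c(1.5, 2, 1, 2, 2),
                    exclusion = c(2.5, 2, 1, 3, 2))
  got <- rejection_sensitivity_composite(mood, anx)

  # independent spreadsheet-style recomputation
  chm <- ((mood$exclusion - mood$baseline) +
            (mood$exclusion - mood$inclusion)) / 2
  cha <- ((anx$exclusion - anx$baseline) +
            (anx$exclusion - anx$inclusion)) / 2
  zm <- (chm - mean(chm)) / sd(chm)
  za <- (cha - mean(cha)) / sd(cha)
  expect_equal(got$composite, (zm + za) / 2, tolerance = 1e-12)
  expect_equal(got$mood_change, chm)

  # no change anywhere -> zero raw change
  flat <- data.frame(baseline = 1:5, inclusion = 1:5, exclusion = 1:5)
  # zero-variance change scores trigger the documented zscore warning
  null <- suppressWarnings(rejection_sensitivity_composite(flat, flat))
  expect_equal(null$mood_change, rep(0, 5))
  expect_error(
    rejection_sensitivity_composite(mood[, 1:2], anx),
    "baseline/inclusion/exclusion")
})
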