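# Synthetic cohort generation. Person-level latent traits drive every
# observed table; the traits are stored so downstream stages can be tested
# for recovery. Occasion-specific traits at the two pre-pandemic time
# points share correlation test_retest_r with a common stable trait.

# Mix a stable trait with occasion noise so that corr(T1, T2) = r while the
# marginal distribution is unchanged.
occasion_mix <- function(stable, occasion, r, mean = 0) {
  mean + sqrt(r) * (stable - mean) + sqrt(1 - r) * (occasion - mean)
}

#' Generate a complete synthetic cohort
#'
#' Draws person-level latent traits (prosociality, log residual SD,
#' correlated susceptibility slopes, altruism, log discount rate, rejection
#' sensitivity, five questionnaire factors), then generates every observed
#' table: participants and covariates, social-influence trials at Times 1
#' and 2 (initial ratings censored to the slider, peer ratings uniform on
#' the configured band, second ratings equal to initial plus the true
#' slope-weighted influence deltas plus person-scaled noise, censored),
#' dictator donations, monetary-choice responses, Cyberball scores at
#' Time 2, questionnaire sum scores, and the two ordinal outcomes drawn
#' from a cumulative-probit model at the configured true coefficients for
#' Time-4 respondents.
#'
#' @param config a [synth_config()].
#' @return object of class `synthetic_cohort`: a list of tables
#'   `participants`, `influence_trials`, `dictator`, `mcq`, `cyberball`,
#'   `questionnaires`, `outcomes`, the `truth` trait table and the
#'   originating `config`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_participants = 40, seed = 7))
#' nrow(cohort$truth)
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  r <- config$test_retest_r
  ids <- seq_len(n)

  ## --- participants and covariates -------------------------------------
  gender <- stats::rbinom(n, 1, 154 / 460)           # 1 = male
  group <- stats::rbinom(n, 1, 0.5)                  # 1 = intervention
  age_t1 <- clamp(stats::rnorm(n, 13.8, 1.35), 11.2, 16.8)
  age_t2 <- age_t1 + 75 / 365.25
  age_t4 <- age_t1 + 1061 / 365.25
  assessment_day <- floor(stats::runif(n, 0, 59))

  ## --- stable traits ----------------------------------------------------
  prosociality <- stats::rnorm(n, config$true_prosociality_mean,
                               config$true_prosociality_sd)
  log_residual_sd <- stats::rnorm(n, config$true_residual_sd_location,
                                  config$true_residual_sd_spread)
  rho <- config$slope_correlation
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  delta_plus_slope <- config$true_delta_plus_mean +
    config$true_delta_plus_sd * e1
  delta_minus_slope <- config$true_delta_minus_mean +
    config$true_delta_minus_sd * (rho * e1 + sqrt(1 - rho^2) * e2)
  altruism <- stats::rnorm(n, config$altruism_mean, config$altruism_sd)
  log_k <- stats::rnorm(n, config$log_k_mean, config$log_k_sd)
  rejection_sensitivity <- stats::rnorm(n)
  k_fac <- ncol(config$factor_loading_matrix)
  Phi <- matrix(config$factor_correlation, k_fac, k_fac); diag(Phi) <- 1
  factors <- draw_mvn(n, Phi)
  fac_names <- colnames(config$factor_loading_matrix) %||%
    paste0("factor_", seq_len(k_fac))
  colnames(factors) <- fac_names

  truth <- data.frame(participant_id = ids, prosociality = prosociality,
                      log_residual_sd = log_residual_sd,
                      delta_plus_slope = delta_plus_slope,
                      delta_minus_slope = delta_minus_slope,
                      altruism = altruism, log_k = log_k,
                      rejection_sensitivity = rejection_sensitivity)
  truth <- cbind(truth, as.data.frame(factors))

  ## --- presence / attrition --------------------------------------------
  present_t1 <- rep(TRUE, n)
  present_t2 <- stats::runif(n) < config$time2_retention_rate
  p4 <- config$time4_retention_rate
  if (config$attrition_mechanism == "trait" && p4 > 0 && p4 < 1) {
    lin <- stats::qlogis(p4) -
      config$attrition_trait_weight * zscore(factors[, "conduct"])
    present_t4 <- stats::runif(n) < stats::plogis(lin)
  } else {
    present_t4 <- stats::runif(n) < p4
  }
  responded <- present_t4 & stats::runif(n) < config$outcome_response_rate

  participants <- data.frame(participant_id = ids, gender = gender,
                             group = group, age_t1 = age_t1,
                             age_t2 = age_t2, age_t4 = age_t4,
                             assessment_day = assessment_day,
                             present_t1 = present_t1,
                             present_t2 = present_t2,
                             present_t4 = present_t4,
                             responded_outcomes = responded)

  ## --- occasion traits --------------------------------------------------
  occ <- list()
  for (tp in c("t1", "t2")) {
    o1 <- stats::rnorm(n); o2 <- stats::rnorm(n)
    occ[[tp]] <- list(
      prosociality = occasion_mix(prosociality,
        stats::rnorm(n, config$true_prosociality_mean,
                     config$true_prosociality_sd),
        r, config$true_prosociality_mean),
      delta_plus = occasion_mix(delta_plus_slope,
        config$true_delta_plus_mean + config$true_delta_plus_sd * o1,
        r, config$true_delta_plus_mean),
      delta_minus = occasion_mix(delta_minus_slope,
        config$true_delta_minus_mean + config$true_delta_minus_sd *
          (rho * o1 + sqrt(1 - rho^2) * o2),
        r, config$true_delta_minus_mean),
      altruism = occasion_mix(altruism,
        stats::rnorm(n, config$altruism_mean, config$altruism_sd),
        r, config$altruism_mean),
      log_k = occasion_mix(log_k,
        stats::rnorm(n, config$log_k_mean, config$log_k_sd),
        r, config$log_k_mean),
      factors = occasion_mix(factors, draw_mvn(n, Phi), r))
  }
  for (tp in c("t1", "t2")) {
    truth[[paste0("prosociality_", tp)]] <- occ[[tp]]$prosociality
    truth[[paste0("delta_plus_", tp)]] <- occ[[tp]]$delta_plus
    truth[[paste0("delta_minus_", tp)]] <- occ[[tp]]$delta_minus
  }

  ## --- scenario pool ----------------------------------------------------
  pool <- data.frame(
    scenario_id = seq_len(config$n_scenario_pool),
    scenario_type = rep(c("prosocial", "antisocial"),
                        length.out = config$n_scenario_pool),
    offset = stats::rnorm(config$n_scenario_pool, 0,
                          config$scenario_offset_sd))

  ## --- influence trials -------------------------------------------------
  sigma_i <- exp(log_residual_sd)
  trials <- list()
  fixed_set <- NULL
  if (config$scenario_mode == "fixed") {
    fixed_set <- stratified_scenarios(pool, config$n_trials_per_timepoint)
  }
  for (tp in c("t1", "t2")) {
    present <- if (tp == "t1") present_t1 else present_t2
    idx <- ids[present]
    trials[[tp]] <- generate_trials(config, pool, idx, tp,
                                    occ[[tp]], sigma_i, fixed_set)
  }
  influence_trials <- rbind(trials$t1, trials$t2)
  rownames(influence_trials) <- NULL

  ## --- dictator game ----------------------------------------------------
  dictator <- rbind(
    data.frame(participant_id = ids[present_t1], timepoint = "t1",
               donation = clamp(occ$t1$altruism[present_t1], 0, 1)),
    data.frame(participant_id = ids[present_t2], timepoint = "t2",
               donation = clamp(occ$t2$altruism[present_t2], 0, 1)))
  dictator$donation[stats::runif(nrow(dictator)) <
                      config$item_missing_rate] <- NA_real_

  ## --- monetary choice questionnaire ------------------------------------
  items <- kirby_items()
  mcq <- rbind(generate_mcq(config, items, ids[present_t1], "t1",
                            occ$t1$log_k[present_t1]),
               generate_mcq(config, items, ids[present_t2], "t2",
                            occ$t2$log_k[present_t2]))

  ## --- cyberball (Time 2 only) ------------------------------------------
  cyberball <- generate_cyberball_scores(
    config, truth = data.frame(
      participant_id = ids[present_t2],
      rejection_sensitivity = rejection_sensitivity[present_t2]))

  ## --- questionnaires ----------------------------------------------------
  qn <- rbind(
    cbind(participant_id = ids[present_t1], timepoint = "t1",
          generate_questionnaires(config, occ$t1$factors[present_t1, ,
                                                         drop = FALSE])),
    cbind(participant_id = ids[present_t2], timepoint = "t2",
          generate_questionnaires(config, occ$t2$factors[present_t2, ,
                                                         drop = FALSE])))
  rownames(qn) <- NULL

  ## --- ordinal outcomes ---------------------------------------------------
  outcomes <- generate_outcomes(config, truth, participants)

  structure(list(participants = participants,
                 influence_trials = influence_trials,
                 dictator = dictator, mcq = mcq, cyberball = cyberball,
                 questionnaires = qn, outcomes = outcomes, truth = truth,
                 scenario_pool = pool, config = config),
            class = "synthetic_cohort")
}

# Draw n rows from MVN(0, Phi) via Cholesky.
draw_mvn <- function(n, Phi) {
  z <- matrix(stats::rnorm(n * ncol(Phi)), n)
  z %*% chol(Phi)
}

# A stratified scenario set: half prosocial, half anti-social, drawn
# without replacement from the pool.
stratified_scenarios <- function(pool, n_trials) {
  pro <- pool$scenario_id[pool$scenario_type == "prosocial"]
  anti <- pool$scenario_id[pool$scenario_type == "antisocial"]
  c(sample(pro, n_trials %/% 2 + n_trials %% 2), sample(anti, n_trials %/% 2))
}

generate_trials <- function(config, pool, idx, tp, occ_tp, sigma_i,
                            fixed_set = NULL) {
  n_tr <- config$n_trials_per_timepoint
  rows <- lapply(idx, function(i) {
    scen <- fixed_set %||% stratified_scenarios(pool, n_tr)
    scen <- sample(scen)                      # presentation order
    type <- pool$scenario_type[scen]
    mu <- occ_tp$prosociality[i] + pool$offset[scen]
    initial_rec <- clamp(stats::rnorm(n_tr, mu, sigma_i[i]), 0, 1)
    prov_raw <- stats::runif(n_tr, config$provided_rating_bounds[1],
                             config$provided_rating_bounds[2])
    prov_rec <- ifelse(type == "antisocial", 1 - prov_raw, prov_raw)
    delta <- prov_rec - initial_rec
    dplus <- pmax(delta, 0); dminus <- pmin(delta, 0)
    noise_sd <- sigma_i[i] * config$second_rating_noise_scale
    second_rec <- clamp(initial_rec + occ_tp$delta_plus[i] * dplus +
                          occ_tp$delta_minus[i] * dminus +
                          stats::rnorm(n_tr, 0, noise_sd), 0, 1)
    data.frame(participant_id = i, timepoint = tp, trial = seq_len(n_tr),
               scenario_id = scen, scenario_type = type,
               initial = ifelse(type == "antisocial", 1 - initial_rec,
                                initial_rec),
               provided = prov_raw,
               second = ifelse(type == "antisocial", 1 - second_rec,
                               second_rec))
  })
  do.call(rbind, rows)
}

generate_mcq <- function(config, items, idx, tp, log_k_occ) {
  n_it <- nrow(items)
  rows <- lapply(seq_along(idx), function(j) {
    p_imm <- stats::plogis(config$mcq_consistency *
                             (log_k_occ[j] - log(items$k)))
    choice <- ifelse(stats::runif(n_it) < p_imm, "immediate", "delayed")
    choice[stats::runif(n_it) < config$item_missing_rate] <- NA_character_
    data.frame(participant_id = idx[j], timepoint = tp, item = items$item,
               choice = choice)
  })
  do.call(rbind, rows)
}

#' Generate Cyberball mood/anxiety scores
#'
#' Baseline and inclusion scores are drawn at the configured phase means;
#' the exclusion score equals the mid-point of the first two phases plus a
#' change score whose mean is the configured exclusion shift. Mood and
#' anxiety change scores share a person-level rejection-sensitivity trait,
#' reproducing the configured correlation between the two change scores.
#' With the exclusion shifts set to 0 the three phase means coincide.
#'
#' @param config a [synth_config()].
#' @param truth optional data.frame with `participant_id` and
#'   `rejection_sensitivity` (standard-normal trait); when omitted, traits
#'   are drawn for `n_participants` fresh participants.
#' @return data.frame with one row per participant: mood and anxiety at
#'   baseline/inclusion/exclusion (higher = lower mood / more anxious).
#' @export
generate_cyberball_scores <- function(config, truth = NULL) {
  validate_synth_config(config)
  if (is.null(truth)) {
    truth <- data.frame(participant_id = seq_len(config$n_participants),
                        rejection_sensitivity =
                          stats::rnorm(config$n_participants))
  }
  cb <- config$cyberball
  n <- nrow(truth)
  w <- sqrt(cb$change_correlation)
  u <- sqrt(1 - cb$change_correlation)
  mood_base <- stats::rnorm(n, cb$mood_baseline_mean, cb$mood_baseline_sd)
  mood_incl <- stats::rnorm(n, cb$mood_inclusion_mean, cb$mood_inclusion_sd)
  anx_base <- stats::rnorm(n, cb$anxiety_baseline_mean, cb$anxiety_baseline_sd)
  anx_incl <- stats::rnorm(n, cb$anxiety_inclusion_mean, cb$anxiety_inclusion_sd)
  tr <- truth$rejection_sensitivity
  ch_mood <- cb$mood_exclusion_shift +
    cb$mood_change_sd * (w * tr + u * stats::rnorm(n))
  ch_anx <- cb$anxiety_exclusion_shift +
    cb$anxiety_change_sd * (w * tr + u * stats::rnorm(n))
  mood_excl <- (mood_base + mood_incl) / 2 + ch_mood
  anx_excl <- (anx_base + anx_incl) / 2 + ch_anx
  data.frame(
    participant_id = truth$participant_id,
    mood_baseline = clamp(mood_base, cb$mood_range[1], cb$mood_range[2]),
    mood_inclusion = clamp(mood_incl, cb$mood_range[1], cb$mood_range[2]),
    mood_exclusion = clamp(mood_excl, cb$mood_range[1], cb$mood_range[2]),
    anxiety_baseline = clamp(anx_base, cb$anxiety_range[1], cb$anxiety_range[2]),
    anxiety_inclusion = clamp(anx_incl, cb$anxiety_range[1], cb$anxiety_range[2]),
    anxiety_exclusion = clamp(anx_excl, cb$anxiety_range[1], cb$anxiety_range[2]))
}

#' Generate questionnaire sum scores from factor scores
#'
#' Standardised latent scores are `loadings %*% factors` plus unique noise
#' (unit total variance per scale), then linearly mapped onto each scale's
#' declared sum-score range. Item-level missingness at the configured rate
#' is propagated through the prorated-sum rule: a scale whose simulated
#' missing-item fraction exceeds 20% is recorded as missing.
#'
#' @param config a [synth_config()].
#' @param truth matrix/data.frame of factor scores (participants x
#'   factors), aligned with the rows to generate.
#' @return data.frame of sum scores, one column per scale.
#' @export
generate_questionnaires <- function(config, truth) {
  validate_synth_config(config)
  f <- as.matrix(truth)
  L <- config$factor_loading_matrix
  stop_if_not(ncol(f) == ncol(L),
              "factor-score table misaligned with the loading matrix")
  stop_if_not(nrow(f) >= 1, "factor-score table is empty")
  k_fac <- ncol(L)
  Phi <- matrix(config$factor_correlation, k_fac, k_fac); diag(Phi) <- 1
  h2 <- rowSums((L %*% Phi) * L)
  stop_if_not(all(h2 < 1), "communalities must be < 1")
  sc <- config$questionnaire_scales
  z <- f %*% t(L) +
    matrix(stats::rnorm(nrow(f) * nrow(L)), nrow(f)) %*% diag(sqrt(1 - h2))
  lo <- sc$n_items * sc$item_min
  hi <- sc$n_items * sc$item_max
  mid <- (lo + hi) / 2
  scores <- sweep(sweep(z, 2, (hi - lo) / 6, `*`), 2, mid, `+`)
  scores <- pmin(pmax(scores, matrix(lo, nrow(f), nrow(sc), byrow = TRUE)),
                 matrix(hi, nrow(f), nrow(sc), byrow = TRUE))
  if (config$item_missing_rate > 0) {
    n_miss <- matrix(stats::rbinom(nrow(f) * nrow(sc),
                                   rep(sc$n_items, each = nrow(f)),
                                   config$item_missing_rate),
                     nrow(f))
    scores[n_miss / matrix(sc$n_items, nrow(f), nrow(sc), byrow = TRUE) >
             0.20] <- NA_real_
  }
  out <- as.data.frame(scores)
  names(out) <- sc$scale
  out
}

generate_outcomes <- function(config, truth, participants) {
  resp <- participants$responded_outcomes
  if (!any(resp)) {
    return(data.frame(participant_id = integer(0), compliance = integer(0),
                      gatherings = integer(0)))
  }
  # z-score true traits over the full cohort (the generating effects are on
  # the standardized trait scale)
  zt <- list(
    prosociality = zscore(truth$prosociality),
    prosocial_influence = zscore(truth$delta_plus_slope),
    antisocial_influence = zscore(truth$delta_minus_slope),
    altruism = zscore(truth$altruism),
    discounting = zscore(truth$log_k),
    rejection_sensitivity = zscore(truth$rejection_sensitivity),
    anxiety = zscore(truth$anxiety),
    depression = zscore(truth$depression),
    executive = zscore(truth$executive),
    conduct = zscore(truth$conduct),
    emotional = zscore(truth$emotional))
  cov_lin <- config$covariate_coefficients["age"] * zscore(participants$age_t4) +
    config$covariate_coefficients["day"] * zscore(participants$assessment_day) +
    config$covariate_coefficients["gender"] * participants$gender +
    config$covariate_coefficients["group"] * participants$group
  out <- data.frame(participant_id = participants$participant_id[resp])
  for (nm in names(config$true_outcome_coefficients)) {
    b <- config$true_outcome_coefficients[[nm]]
    stop_if_not(all(names(b) %in% names(zt)),
                sprintf("unknown predictor in coefficients for '%s'", nm))
    eta <- cov_lin
    for (p in names(b)) eta <- eta + b[[p]] * zt[[p]]
    latent <- eta[resp] + stats::rnorm(sum(resp))
    out[[nm]] <- as.integer(cut(latent,
                                c(-Inf, config$cutpoints[[nm]], Inf),
                                labels = FALSE))
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort\n")
  cat(sprintf("  participants: %d (T2: %d, T4: %d, outcomes: %d)\n",
              nrow(x$participants), sum(x$participants$present_t2),
              sum(x$participants$present_t4), nrow(x$outcomes)))
  cat(sprintf("  influence trials: %d rows; questionnaires: %d x %d\n",
              nrow(x$influence_trials), nrow(x$questionnaires),
              ncol(x$questionnaires) - 2))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}
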