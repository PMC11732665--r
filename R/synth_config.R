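# Configuration object holding every true parameter of the generative
# cohort: task calibrations, measurement-model truths, factor structure,
# outcome coefficients, retention/missingness and the seed.

#' Configuration of the synthetic cohort generator
#'
#' Collects all true parameters of the generative cohort. Defaults encode
#' the emulated study design: 460 participants, 16 social-influence trials
#' per time point drawn from an 82-scenario pool (half prosocial, half
#' anti-social), peer ratings uniform on 20--80% of the slider, two
#' pre-pandemic time points with test--retest correlation, a five-factor
#' structure over 30 questionnaire scores, and two 5-category ordinal
#' outcomes generated from a latent cumulative-probit model.
#'
#' @param n_participants cohort size at Time 1.
#' @param n_trials_per_timepoint social-influence trials per person per
#'   time point.
#' @param n_scenario_pool size of the scenario pool trials are drawn from.
#' @param scenario_mode `"resample"` draws a fresh stratified set of
#'   scenarios per participant and time point; `"fixed"` uses one common
#'   set (both administration modes are plausible; neither is asserted).
#' @param provided_rating_bounds lower/upper bounds of the uniform peer
#'   ("provided") rating, as fractions of the slider.
#' @param true_prosociality_mean,true_prosociality_sd mean and SD of the
#'   person-level prosociality trait on the recoded \[0, 1\] slider scale.
#' @param scenario_offset_sd SD of fixed per-scenario offsets (slider units).
#' @param true_residual_sd_location,true_residual_sd_spread location and
#'   spread (log scale) of the log-normal person-specific residual SDs of
#'   slider responses; larger location produces more floor/ceiling mass.
#' @param true_delta_plus_mean,true_delta_plus_sd population mean/SD of the
#'   per-person prosocial-influence slope.
#' @param true_delta_minus_mean,true_delta_minus_sd same for the
#'   anti-social-influence slope.
#' @param slope_correlation correlation of the two susceptibility slopes.
#' @param second_rating_noise_scale multiplier on the person residual SD for
#'   the second-rating noise.
#' @param altruism_mean,altruism_sd latent dictator-donation calibration
#'   (the latent normal is censored to \[0, 1\]; defaults give a donated
#'   fraction near 0.64 with roughly a quarter of donors at the ceiling).
#' @param log_k_mean,log_k_sd population distribution of log discount rate.
#' @param mcq_consistency logistic scale governing choice consistency on the
#'   monetary choice questionnaire (larger = more consistent).
#' @param cyberball list of Cyberball calibration constants (phase means and
#'   SDs, exclusion shifts, change-score SDs and their correlation, item
#'   ranges); defaults target the descriptives of the emulated task
#'   (mood means near 2.85 at baseline and 3.85 after exclusion, change
#'   correlation 0.74).
#' @param factor_loading_matrix questionnaire loading matrix (scales x
#'   factors).
#' @param factor_correlation common correlation among generating factors.
#' @param questionnaire_scales battery layout, see
#'   [default_questionnaire_scales()].
#' @param true_outcome_coefficients list of named coefficient vectors per
#'   outcome, see [default_true_coefficients()].
#' @param covariate_coefficients true effects of the four covariates (z-age,
#'   z-assessment-day, gender, group) on the latent outcomes.
#' @param cutpoints list of 4 strictly increasing latent cutpoints per
#'   outcome; defaults reproduce the skewed observed response marginals
#'   (most respondents in the top two compliance categories; a majority
#'   never attending gatherings).
#' @param test_retest_r correlation of person-level traits across the two
#'   pre-pandemic time points.
#' @param time2_retention_rate,time4_retention_rate fraction of the cohort
#'   present at Time 2 / Time 4.
#' @param outcome_response_rate fraction of Time-4 participants answering
#'   the outcome items.
#' @param attrition_mechanism `"mcar"` (default) or `"trait"`, where Time-4
#'   retention additionally depends on the conduct factor.
#' @param attrition_trait_weight logit-scale weight of the trait-dependent
#'   attrition mechanism.
#' @param item_missing_rate per-item missingness rate on questionnaires and
#'   task responses.
#' @param seed integer seed; identical configurations produce bit-identical
#'   cohorts.
#' @return validated object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 460L,
                         n_trials_per_timepoint = 16L,
                         n_scenario_pool = 82L,
                         scenario_mode = c("resample", "fixed"),
                         provided_rating_bounds = c(0.20, 0.80),
                         true_prosociality_mean = 0.65,
                         true_prosociality_sd = 0.15,
                         scenario_offset_sd = 0.12,
                         true_residual_sd_location = log(0.12),
                         true_residual_sd_spread = 0.35,
                         true_delta_plus_mean = 0.35,
                         true_delta_plus_sd = 0.30,
                         true_delta_minus_mean = 0.30,
                         true_delta_minus_sd = 0.30,
                         slope_correlation = 0.40,
                         second_rating_noise_scale = 1.0,
                         altruism_mean = 0.72,
                         altruism_sd = 0.38,
                         log_k_mean = log(0.01),
                         log_k_sd = 1.2,
                         mcq_consistency = 1.5,
                         cyberball = default_cyberball_calibration(),
                         factor_loading_matrix = default_loading_matrix(),
                         factor_correlation = 0.30,
                         questionnaire_scales = default_questionnaire_scales(),
                         true_outcome_coefficients = default_true_coefficients(),
                         covariate_coefficients = c(age = 0, day = -0.17,
                                                    gender = 0, group = 0),
                         cutpoints = list(
                           compliance = c(-2.05, -1.48, -0.81, 0.50),
                           gatherings = c(-1.64, -1.28, -0.84, -0.23)),
                         test_retest_r = 0.68,
                         time2_retention_rate = 0.88,
                         time4_retention_rate = 0.457,
                         outcome_response_rate = 0.976,
                         attrition_mechanism = c("mcar", "trait"),
                         attrition_trait_weight = 0.5,
                         item_missing_rate = 0.02,
                         seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_trials_per_timepoint = as.integer(n_trials_per_timepoint),
              n_scenario_pool = as.integer(n_scenario_pool),
              scenario_mode = match.arg(scenario_mode),
              provided_rating_bounds = provided_rating_bounds,
              true_prosociality_mean = true_prosociality_mean,
              true_prosociality_sd = true_prosociality_sd,
              scenario_offset_sd = scenario_offset_sd,
              true_residual_sd_location = true_residual_sd_location,
              true_residual_sd_spread = true_residual_sd_spread,
              true_delta_plus_mean = true_delta_plus_mean,
              true_delta_plus_sd = true_delta_plus_sd,
              true_delta_minus_mean = true_delta_minus_mean,
              true_delta_minus_sd = true_delta_minus_sd,
              slope_correlation = slope_correlation,
              second_rating_noise_scale = second_rating_noise_scale,
              altruism_mean = altruism_mean, altruism_sd = altruism_sd,
              log_k_mean = log_k_mean, log_k_sd = log_k_sd,
              mcq_consistency = mcq_consistency,
              cyberball = cyberball,
              factor_loading_matrix = factor_loading_matrix,
              factor_correlation = factor_correlation,
              questionnaire_scales = questionnaire_scales,
              true_outcome_coefficients = true_outcome_coefficients,
              covariate_coefficients = covariate_coefficients,
              cutpoints = cutpoints,
              test_retest_r = test_retest_r,
              time2_retention_rate = time2_retention_rate,
              time4_retention_rate = time4_retention_rate,
              outcome_response_rate = outcome_response_rate,
              attrition_mechanism = match.arg(attrition_mechanism),
              attrition_trait_weight = attrition_trait_weight,
              item_missing_rate = item_missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Default Cyberball calibration constants
#' @return named list of phase means/SDs, exclusion shifts, change-score
#'   structure and item ranges.
#' @export
default_cyberball_calibration <- function() {
  list(mood_baseline_mean = 2.85, mood_baseline_sd = 1.07,
       mood_inclusion_mean = 2.74, mood_inclusion_sd = 1.16,
       mood_exclusion_shift = 1.055,
       anxiety_baseline_mean = 1.84, anxiety_baseline_sd = 0.58,
       anxiety_inclusion_mean = 1.80, anxiety_inclusion_sd = 0.57,
       anxiety_exclusion_shift = 0.34,
       change_correlation = 0.74,
       mood_change_sd = 1.0, anxiety_change_sd = 0.45,
       mood_range = c(1, 7), anxiety_range = c(1, 4))
}

#' Validate a synthetic-cohort configuration
#'
#' Checks the structural invariants: strictly increasing cutpoints, ordered
#' provided-rating bounds inside \[0, 1\], a positive-definite slope
#' correlation, a loading matrix aligned with the battery layout, and rates
#' inside \[0, 1\].
#'
#' @param config object of class `synth_config`.
#' @return the config, invisibly; invalid configurations raise an error.
#' @export
validate_synth_config <- function(config) {
  stop_if_not(inherits(config, "synth_config"), "not a synth_config")
  b <- config$provided_rating_bounds
  stop_if_not(length(b) == 2 && b[1] >= 0 && b[1] < b[2] && b[2] <= 1,
              "provided rating bounds must satisfy 0 <= lo < hi <= 1")
  for (nm in names(config$cutpoints)) {
    cp <- config$cutpoints[[nm]]
    stop_if_not(length(cp) == 4 && all(diff(cp) > 0),
                sprintf("cutpoints for '%s' must be 4 strictly increasing values", nm))
  }
  r <- config$slope_correlation
  stop_if_not(is.finite(r) && abs(r) < 1,
              "slope correlation matrix is not positive definite")
  L <- config$factor_loading_matrix
  sc <- config$questionnaire_scales
  stop_if_not(is.matrix(L) && nrow(L) == nrow(sc),
              sprintf("loading matrix must have one row per scale (%d)", nrow(sc)))
  stop_if_not(all(is.finite(L)), "loading matrix must be finite")
  for (nm in c("test_retest_r", "time2_retention_rate",
               "time4_retention_rate", "outcome_response_rate",
               "item_missing_rate")) {
    v <- config[[nm]]
    stop_if_not(is.finite(v) && v >= 0 && v <= 1,
                sprintf("%s must lie in [0, 1]", nm))
  }
  stop_if_not(config$n_participants >= 1, "need at least one participant")
  stop_if_not(config$n_trials_per_timepoint >= 1, "need at least one trial")
  stop_if_not(config$n_scenario_pool >= config$n_trials_per_timepoint,
              "scenario pool smaller than trials per time point")
  cf <- config$true_outcome_coefficients
  stop_if_not(is.list(cf) && length(cf) >= 1 &&
                all(vapply(cf, is.numeric, logical(1))),
              "true_outcome_coefficients must be a list of named numeric vectors")
  invisible(config)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d  trials/timepoint: %d (pool %d, %s)\n",
              x$n_participants, x$n_trials_per_timepoint,
              x$n_scenario_pool, x$scenario_mode))
  cat(sprintf("  slopes: delta+ %.2f (sd %.2f), delta- %.2f (sd %.2f), r = %.2f\n",
              x$true_delta_plus_mean, x$true_delta_plus_sd,
              x$true_delta_minus_mean, x$true_delta_minus_sd,
              x$slope_correlation))
  cat(sprintf("  retention: T2 %.2f, T4 %.2f; test-retest r = %.2f; seed %d\n",
              x$time2_retention_rate, x$time4_retention_rate,
              x$test_retest_r, x$seed))
  invisible(x)
}
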