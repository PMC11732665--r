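# Default calibration of the synthetic cohort generator. The generator
# emulates a school-based adolescent cohort assessed at two pre-pandemic
# time points (behavioural tasks + a 30-scale questionnaire battery) and a
# during-pandemic online follow-up with two 5-category ordinal outcomes.

#' Default questionnaire battery layout
#'
#' Thirty synthetic well-being/behaviour/mental-health subscales emulating a
#' battery of standard instruments (anxiety/depression scales, executive
#' function ratings, strengths-and-difficulties subscales, emotion-regulation
#' subscales, well-being and mindfulness scales). Each row declares the item
#' count, the item response range, the generating factor (1 = anxiety,
#' 2 = depression, 3 = executive functioning, 4 = conduct problems,
#' 5 = emotional awareness) and the generating loading. The layout is a
#' synthetic emulation of such a battery, not the original instruments.
#'
#' @return data.frame with columns `scale`, `n_items`, `item_min`,
#'   `item_max`, `factor`, `loading`.
#' @export
default_questionnaire_scales <- function() {
  tab <- rbind(
    # anxiety block
    c("rcads_separation_anxiety",      7, 0, 3, 1,  0.72),
    c("rcads_generalized_anxiety",     6, 0, 3, 1,  0.75),
    c("rcads_panic",                   9, 0, 3, 1,  0.70),
    c("rcads_social_phobia",           9, 0, 3, 1,  0.68),
    c("rcads_obsessive_compulsive",    6, 0, 3, 1,  0.62),
    c("rcads_total_anxiety",          37, 0, 3, 1,  0.80),
    # depression block
    c("rcads_major_depression",       10, 0, 3, 2,  0.75),
    c("cesd_depression",              20, 0, 3, 2,  0.78),
    c("wemwbs_wellbeing",             14, 1, 5, 2, -0.65),
    c("camm_mindfulness",             10, 0, 4, 2, -0.55),
    c("sdq_emotional_symptoms",        5, 0, 2, 2,  0.60),
    c("ders_strategies",               8, 1, 5, 2,  0.62),
    # executive functioning block
    c("brief_working_memory",         12, 1, 3, 3,  0.75),
    c("brief_plan_organize",          13, 1, 3, 3,  0.74),
    c("brief_task_completion",        10, 1, 3, 3,  0.70),
    c("brief_organization_materials",  7, 1, 3, 3,  0.62),
    c("brief_monitor",                 5, 1, 3, 3,  0.66),
    c("brief_shift",                  10, 1, 3, 3,  0.58),
    # conduct problems block
    c("sdq_conduct_problems",          5, 0, 2, 4,  0.70),
    c("sdq_hyperactivity",             5, 0, 2, 4,  0.62),
    c("sdq_peer_problems",             5, 0, 2, 4,  0.48),
    c("sdq_prosocial",                 5, 0, 2, 4, -0.50),
    c("brief_inhibit",                13, 1, 3, 4,  0.60),
    c("ders_impulse",                  6, 1, 5, 4,  0.58),
    # emotional awareness block
    c("ders_awareness",                6, 1, 5, 5,  0.70),
    c("ders_clarity",                  5, 1, 5, 5,  0.72),
    c("ders_nonacceptance",            6, 1, 5, 5,  0.60),
    c("ders_goals",                    5, 1, 5, 5,  0.55),
    c("brief_emotional_control",      10, 1, 3, 5,  0.58),
    c("ders_total",                   36, 1, 5, 5,  0.65))
  out <- data.frame(scale = tab[, 1],
                    n_items = as.integer(tab[, 2]),
                    item_min = as.numeric(tab[, 3]),
                    item_max = as.numeric(tab[, 4]),
                    factor = as.integer(tab[, 5]),
                    loading = as.numeric(tab[, 6]),
                    stringsAsFactors = FALSE)
  out
}

#' Default 30 x 5 factor loading matrix
#'
#' Simple-structure loadings implied by [default_questionnaire_scales()]:
#' each scale loads on exactly one of the five generating factors.
#'
#' @param scales scale table (see [default_questionnaire_scales()]).
#' @return numeric matrix (scales x 5) with row/column names.
#' @export
default_loading_matrix <- function(scales = default_questionnaire_scales()) {
  L <- matrix(0, nrow(scales), 5,
              dimnames = list(scales$scale,
                              c("anxiety", "depression", "executive",
                                "conduct", "emotional")))
  L[cbind(seq_len(nrow(scales)), scales$factor)] <- scales$loading
  L
}

# Names of the 11 predictors the outcome models use.
predictor_names <- function() {
  c("prosociality", "prosocial_influence", "antisocial_influence",
    "altruism", "discounting", "rejection_sensitivity",
    "anxiety", "depression", "executive", "conduct", "emotional")
}

#' Default true standardized outcome coefficients
#'
#' The generating per-predictor effects on the latent outcome scale. They
#' are calibrated to the point estimates of the reference cohort analysis so
#' that a default synthetic run produces a recognisably shaped results
#' table; they are a calibration, not ground truth about any real cohort.
#'
#' @return list with components `compliance` and `gatherings`, each a named
#'   numeric vector over the 11 predictors.
#' @export
default_true_coefficients <- function() {
  list(
    compliance = c(
      prosociality = 0.262, prosocial_influence = -0.010,
      antisocial_influence = -0.271, altruism = 0.270,
      discounting = -0.039, rejection_sensitivity = -0.125,
      anxiety = 0.009, depression = 0.127, executive = -0.033,
      conduct = -0.184, emotional = -0.029),
    gatherings = c(
      prosociality = 0.002, prosocial_influence = 0.126,
      antisocial_influence = -0.065, altruism = 0.208,
      discounting = 0.151, rejection_sensitivity = -0.032,
      anxiety = -0.019, depression = 0.003, executive = -0.002,
      conduct = -0.103, emotional = 0.086))
}
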