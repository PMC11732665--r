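# Deterministic scoring of the pre-pandemic predictors: prorated
# questionnaire sums, dictator-game altruism, Cyberball rejection
# sensitivity, prosocial recoding of slider ratings, and averaging across
# the two pre-pandemic time points. All functions are pure.

#' Prorated sum score for a questionnaire scale
#'
#' Computes the scale sum while tolerating limited item-level missingness:
#' the mean of the answered items is multiplied by the total number of items
#' (equivalent to the plain sum when nothing is missing). If more than
#' `max_missing` of the responses are missing the score is missing.
#'
#' With `literal = TRUE` the mean of answered items is instead multiplied by
#' the number of *answered* items, which reduces to the observed-item sum —
#' an alternative reading of "multiplied by the number of non-missing
#' items"; the prorated default is the convention consistent with
#' sum-scoring equivalence under complete data.
#'
#' @param item_responses numeric vector of item responses with `NA` marking
#'   missing items.
#' @param n_items expected number of items on the scale.
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @param literal use the observed-item sum instead of prorating.
#' @return scalar score, or `NA` when missingness exceeds the threshold.
#' @examples
#' prorated_sum_score(c(2, 2, 2, NA), 4)  # 8: prorated
#' @export
prorated_sum_score <- function(item_responses, n_items, max_missing = 0.20,
                               literal = FALSE) {
  stop_if_not(n_items >= 1, "n_items must be >= 1")
  stop_if_not(length(item_responses) == n_items,
              sprintf("expected %d responses, got %d", n_items,
                      length(item_responses)))
  stop_if_not(is.numeric(item_responses) || all(is.na(item_responses)),
              "responses must be numeric or missing")
  miss <- is.na(item_responses)
  if (all(miss) || mean(miss) > max_missing) return(NA_real_)
  m <- mean(item_responses[!miss])
  if (literal) m * sum(!miss) else m * n_items
}

#' Dictator-game altruism score
#'
#' The donated fraction of the hypothetical endowment is itself the altruism
#' score; this validates the range and passes the value through.
#'
#' @param donation_fraction numeric vector in \[0, 1\] (or `NA`).
#' @return the validated fractions.
#' @export
score_dictator <- function(donation_fraction) {
  bad <- !is.na(donation_fraction) &
    (donation_fraction < 0 | donation_fraction > 1)
  stop_if_not(!any(bad), "donation fractions must lie in [0, 1]")
  donation_fraction
}

#' Recode slider ratings to a common prosocial direction
#'
#' Ratings of anti-social scenarios are reflected (`1 - rating`) so that a
#' higher value always indicates a more prosocial response; prosocial
#' scenarios pass through unchanged. The mapping is an involution.
#'
#' @param rating numeric vector in \[0, 1\].
#' @param scenario_type character vector, `"prosocial"` or `"antisocial"`,
#'   recycled against `rating`.
#' @return recoded ratings in \[0, 1\].
#' @export
recode_prosocial_direction <- function(rating, scenario_type) {
  stop_if_not(all(is.na(rating) | (rating >= 0 & rating <= 1)),
              "ratings must lie in [0, 1]")
  stop_if_not(all(scenario_type %in% c("prosocial", "antisocial")),
              "scenario_type must be 'prosocial' or 'antisocial'")
  ifelse(rep_len(scenario_type, length(rating)) == "antisocial",
         1 - rating, rating)
}

#' Cyberball rejection-sensitivity composite
#'
#' For each construct (mood, anxiety; both coded so that higher = worse),
#' the change score is the average of (exclusion - baseline) and
#' (exclusion - inclusion). The two change scores are z-scored across the
#' cohort — to put the differently scaled mood and anxiety instruments on a
#' common metric — and then averaged into a single composite. Participants
#' missing any phase receive a missing composite.
#'
#' @param mood data.frame or matrix with columns `baseline`, `inclusion`,
#'   `exclusion` (one row per participant); higher = lower mood.
#' @param anxiety same layout; higher = more anxious.
#' @return list with `composite` (z-composite per participant),
#'   `mood_change`, `anxiety_change` (raw change scores).
#' @export
rejection_sensitivity_composite <- function(mood, anxiety) {
  mood <- as.data.frame(mood)
  anxiety <- as.data.frame(anxiety)
  need <- c("baseline", "inclusion", "exclusion")
  stop_if_not(all(need %in% names(mood)) && all(need %in% names(anxiety)),
              "mood and anxiety need baseline/inclusion/exclusion columns")
  stop_if_not(nrow(mood) == nrow(anxiety),
              "mood and anxiety tables must align")
  chg <- function(tab) {
    ((tab$exclusion - tab$baseline) + (tab$exclusion - tab$inclusion)) / 2
  }
  mood_change <- chg(mood)
  anx_change <- chg(anxiety)
  composite <- (zscore(mood_change) + zscore(anx_change)) / 2
  list(composite = composite, mood_change = mood_change,
       anxiety_change = anx_change)
}

#' Average a predictor across the two pre-pandemic time points
#'
#' Element-wise mean of the Time-1 and Time-2 scores; when only one time
#' point is available that value is used as-is. Both missing yields missing.
#' Standardisation before and after averaging is applied by the pipeline,
#' not here.
#'
#' @param score_t1,score_t2 numeric vectors (recycled to common length).
#' @return numeric vector of averaged scores.
#' @export
average_timepoints <- function(score_t1, score_t2) {
  n <- max(length(score_t1), length(score_t2))
  out <- rowMeans(cbind(rep_len(score_t1, n), rep_len(score_t2, n)),
                  na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
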