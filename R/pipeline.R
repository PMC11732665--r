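# End-to-end pipeline: score the pre-pandemic predictors from the raw
# tables, reduce the questionnaire battery to factors, estimate the
# influence-task measures, average predictors across the two pre-pandemic
# time points (z-scored before and after averaging), and fit one
# cumulative-probit model per predictor and outcome with listwise deletion.

#' Score the deterministic pre-pandemic predictors
#'
#' Computes, per time point, dictator-game altruism, the delay-discounting
#' composite (cohort-wise z-scored log discount rates averaged over
#' magnitude bands) and the Cyberball rejection-sensitivity composite
#' (Time 2 only), then averages across time points (z-scoring before and
#' after averaging; a single available time point passes through).
#'
#' @param cohort a `synthetic_cohort` (or any list with the same tables).
#' @return data.frame keyed by `participant_id` with columns `altruism`,
#'   `discounting`, `rejection_sensitivity` (averaged, z-scored) and the
#'   per-timepoint intermediates.
#' @export
score_predictors <- function(cohort) {
  ids <- cohort$participants$participant_id
  out <- data.frame(participant_id = ids)

  # dictator-game altruism
  for (tp in c("t1", "t2")) {
    d <- cohort$dictator[cohort$dictator$timepoint == tp, ]
    v <- rep(NA_real_, length(ids))
    v[match(d$participant_id, ids)] <- score_dictator(d$donation)
    out[[paste0("altruism_", tp)]] <- v
  }

  # delay discounting: per-band rates, then the cohort-wise composite
  items <- kirby_items()
  for (tp in c("t1", "t2")) {
    m <- cohort$mcq[cohort$mcq$timepoint == tp, ]
    ks <- matrix(NA_real_, length(ids), 3,
                 dimnames = list(NULL, c("small", "medium", "large")))
    for (pid in unique(m$participant_id)) {
      ch <- m$choice[m$participant_id == pid][order(m$item[m$participant_id == pid])]
      sc <- kirby_discount_rates(ch, items)
      ks[match(pid, ids), ] <- c(sc$k_small, sc$k_medium, sc$k_large)
    }
    out[[paste0("discounting_", tp)]] <-
      discount_composite(ks[, "small"], ks[, "medium"], ks[, "large"])
  }

  # rejection sensitivity (Time 2 only)
  cb <- cohort$cyberball
  rs <- rejection_sensitivity_composite(
    mood = data.frame(baseline = cb$mood_baseline,
                      inclusion = cb$mood_inclusion,
                      exclusion = cb$mood_exclusion),
    anxiety = data.frame(baseline = cb$anxiety_baseline,
                         inclusion = cb$anxiety_inclusion,
                         exclusion = cb$anxiety_exclusion))
  v <- rep(NA_real_, length(ids))
  v[match(cb$participant_id, ids)] <- rs$composite
  out$rejection_sensitivity_t2 <- v

  out$altruism <- zscore(average_timepoints(zscore(out$altruism_t1),
                                            zscore(out$altruism_t2)))
  out$discounting <- zscore(average_timepoints(zscore(out$discounting_t1),
                                               zscore(out$discounting_t2)))
  out$rejection_sensitivity <- zscore(out$rejection_sensitivity_t2)
  out
}

#' Average the questionnaire battery across the pre-pandemic time points
#'
#' Aligns the per-time-point questionnaire score tables on the participant
#' roster, z-scores each scale within time point and averages the two
#' time points (participants with a single time point keep that value).
#' This is the input matrix the factor-reduction stage consumes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param input `"averaged"` (default) or `"t1"` for a single-time-point
#'   matrix.
#' @return numeric matrix (participants x scales).
#' @export
average_questionnaires <- function(cohort, input = c("averaged", "t1")) {
  input <- match.arg(input)
  ids <- cohort$participants$participant_id
  qn <- cohort$questionnaires
  scales <- setdiff(names(qn), c("participant_id", "timepoint"))
  get_tp <- function(tp) {
    sub <- qn[qn$timepoint == tp, ]
    m <- matrix(NA_real_, length(ids), length(scales),
                dimnames = list(NULL, scales))
    m[match(sub$participant_id, ids), ] <-
      as.matrix(sub[, scales, drop = FALSE])
    m
  }
  m1 <- get_tp("t1")
  if (input == "t1") return(apply(m1, 2, zscore))
  m2 <- get_tp("t2")
  z1 <- apply(m1, 2, zscore)
  z2 <- apply(m2, 2, zscore)
  w1 <- 1 - is.na(z1)
  w2 <- 1 - is.na(z2)
  avg <- (ifelse(is.na(z1), 0, z1) + ifelse(is.na(z2), 0, z2)) /
    pmax(w1 + w2, 1e-12)
  avg[w1 + w2 == 0] <- NA_real_
  avg
}

#' Estimate the influence-task measures for the pipeline
#'
#' Recodes ratings to the prosocial direction, builds the delta
#' decomposition and fits the prosociality and susceptibility models per
#' available time point, then averages the per-participant estimates
#' across time points (z-scored before and after).
#'
#' @param cohort a `synthetic_cohort`.
#' @param settings an [influence_mcmc()] list.
#' @param timepoints `"both"` or `"t1"` (single-time-point mode).
#' @param family susceptibility response family.
#' @return list with the per-participant predictor columns
#'   (`prosociality`, `prosocial_influence`, `antisocial_influence`), the
#'   underlying fits and the per-timepoint score tables.
#' @export
estimate_influence_measures <- function(cohort,
                                        settings = influence_mcmc(),
                                        timepoints = c("both", "t1"),
                                        family = "normal") {
  timepoints <- match.arg(timepoints)
  tps <- if (timepoints == "both") c("t1", "t2") else "t1"
  ids <- cohort$participants$participant_id
  fits <- list()
  cols <- list()
  for (tp in tps) {
    tr <- cohort$influence_trials[cohort$influence_trials$timepoint == tp, ]
    tr$initial <- recode_prosocial_direction(tr$initial, tr$scenario_type)
    tr$provided <- recode_prosocial_direction(tr$provided, tr$scenario_type)
    tr$second <- recode_prosocial_direction(tr$second, tr$scenario_type)
    tt <- build_trial_table(tr, cohort$config$provided_rating_bounds %||%
                              c(0.2, 0.8))
    tp_settings <- settings
    tp_settings$seed <- derive_seed(settings$seed, match(tp, c("t1", "t2")))
    pro <- fit_prosociality(tt, tp_settings)
    sus <- fit_susceptibility(tt, tp_settings, family = family)
    fits[[tp]] <- list(prosociality = pro, susceptibility = sus)
    m <- data.frame(participant_id = ids)
    m$prosociality <- pro$scores$prosociality[
      match(ids, pro$scores$participant_id)]
    m$prosocial_influence <- sus$scores$prosocial_susceptibility[
      match(ids, sus$scores$participant_id)]
    m$antisocial_influence <- sus$scores$antisocial_susceptibility[
      match(ids, sus$scores$participant_id)]
    cols[[tp]] <- m
  }
  avg <- data.frame(participant_id = ids)
  for (v in c("prosociality", "prosocial_influence",
              "antisocial_influence")) {
    if (length(tps) == 2) {
      avg[[v]] <- zscore(average_timepoints(zscore(cols$t1[[v]]),
                                            zscore(cols$t2[[v]])))
    } else {
      avg[[v]] <- zscore(cols$t1[[v]])
    }
  }
  list(predictors = avg, fits = fits, per_timepoint = cols)
}

#' Run the full analysis pipeline
#'
#' Orchestrates scoring, factor reduction, influence-model estimation and
#' the per-predictor cumulative-probit outcome models, and assembles the
#' results table and a run manifest. Each of the 11 predictors is tested
#' in its own model containing only that predictor plus the four
#' covariates (age at Time 4, assessment day, gender, intervention
#' group); participants with missing data are excluded per model.
#'
#' @param x a `synthetic_cohort` or a [synth_config()] (a config is
#'   generated first).
#' @param alpha overall error rate; the credible level is adjusted for the
#'   number of predictors tested.
#' @param n_factors number of questionnaire factors; `NULL` (default) uses
#'   the parallel-analysis suggestion.
#' @param factor_input fit factors on `"averaged"` (default) or `"t1"`
#'   questionnaire scores.
#' @param timepoints use `"both"` pre-pandemic time points (default) or
#'   `"t1"` only.
#' @param influence_settings,ordinal_settings MCMC settings per stage.
#' @param out_dir optional directory for result/manifest files.
#' @param verbose print stage progress.
#' @return object of class `adherence_run` with `predictors` (the analysis
#'   table), `factor_solution`, `influence`, `fits`, `results`
#'   (see [build_results_table()]) and `manifest`.
#' @export
run_pipeline <- function(x, alpha = 0.05, n_factors = NULL,
                         factor_input = "averaged",
                         timepoints = "both",
                         influence_settings = influence_mcmc(),
                         ordinal_settings = ordinal_mcmc(),
                         out_dir = NULL, verbose = TRUE) {
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  if (inherits(x, "synth_config")) {
    say("stage synth: generating cohort (n = %d, seed = %d)",
        x$n_participants, x$seed)
    cohort <- generate_cohort(x)
  } else {
    stop_if_not(inherits(x, "synthetic_cohort"),
                "x must be a synth_config or synthetic_cohort")
    cohort <- x
  }
  seed <- cohort$config$seed %||% 1L

  say("stage score: deterministic predictors")
  det <- score_predictors(cohort)

  say("stage factors: retention + minres/oblimin")
  qmat <- average_questionnaires(cohort, factor_input)
  pa <- parallel_analysis(qmat, seed = derive_seed(seed, 11L))
  vm <- velicer_map(cor_pairwise(qmat))
  k <- n_factors %||% pa$n_factors
  stop_if_not(k >= 1, "retention suggested 0 factors; supply n_factors")
  fac <- fit_factors(qmat, k)
  fac$retention <- list(parallel_analysis_k = pa$n_factors,
                        velicer_map_k = vm$n_factors)

  say("stage influence: hierarchical measurement models (%s)", timepoints)
  infl <- estimate_influence_measures(cohort, influence_settings,
                                      timepoints = timepoints)

  # assemble the analysis table
  pt <- cohort$participants
  pred_tab <- data.frame(participant_id = pt$participant_id,
                         altruism = det$altruism,
                         discounting = det$discounting,
                         rejection_sensitivity = det$rejection_sensitivity)
  for (v in c("prosociality", "prosocial_influence",
              "antisocial_influence")) {
    pred_tab[[v]] <- infl$predictors[[v]]
  }
  fac_cols <- colnames(fac$factor_scores)
  for (j in seq_along(fac_cols)) {
    pred_tab[[fac_cols[j]]] <- zscore(fac$factor_scores[, j])
  }
  pred_tab$age_t4 <- pt$age_t4
  pred_tab$assessment_day <- pt$assessment_day
  pred_tab$gender <- pt$gender
  pred_tab$group <- pt$group

  predictors <- c("prosociality", "prosocial_influence",
                  "antisocial_influence", "altruism", "discounting",
                  "rejection_sensitivity", fac_cols)
  covariates <- c("age_t4", "assessment_day", "gender", "group")
  outcomes <- setdiff(names(cohort$outcomes), "participant_id")
  analysis <- merge(cohort$outcomes, pred_tab, by = "participant_id")

  say("stage outcomes: %d predictors x %d outcomes",
      length(predictors), length(outcomes))
  fits <- list()
  model_log <- list()
  i <- 0L
  for (outc in outcomes) {
    fits[[outc]] <- list()
    for (pred in predictors) {
      i <- i + 1L
      os <- ordinal_settings
      os$seed <- derive_seed(seed, 100L + i)
      f <- fit_ordinal_model(analysis, outcome = outc, predictor = pred,
                             covariates = covariates, settings = os,
                             n_tests = length(predictors), alpha = alpha)
      fits[[outc]][[pred]] <- f
      model_log[[paste(outc, pred, sep = ".")]] <-
        list(n = f$n_used, dropped = f$n_dropped,
             rhat_max = max(f$rhat, na.rm = TRUE),
             ess_min = min(f$ess, na.rm = TRUE),
             converged = f$convergence_ok)
    }
  }
  results <- build_results_table(fits)

  manifest <- list(
    package_version = as.character(utils::packageVersion("adhereBayes")),
    seed = seed,
    config_hash = hash_object(serialize_config(cohort$config)),
    alpha = alpha,
    adjusted_level = adjusted_credible_level(length(predictors), alpha),
    n_factors = k,
    retention = fac$retention,
    factor_top_loadings = as.list(fac$top_loading),
    timepoints = timepoints,
    influence_settings = infl$fits$t1$prosociality$settings,
    ordinal_settings = ordinal_settings,
    models = model_log,
    files_produced = character(0),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start,
                                          units = "secs")))

  run <- structure(list(cohort = cohort, predictors = analysis,
                        factor_solution = fac, influence = infl,
                        fits = fits, results = results,
                        manifest = manifest),
                   class = "adherence_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(results = file.path(out_dir, "results_table.tsv"),
               predictors = file.path(out_dir, "predictors.tsv"),
               loadings = file.path(out_dir, "factor_loadings.tsv"),
               manifest = file.path(out_dir, "manifest.json"))
    write_table_precise(results, files["results"])
    write_table_precise(analysis, files["predictors"])
    write_table_precise(as.data.frame(fac$loadings), files["loadings"])
    run$manifest$files_produced <- unname(files)
    jsonlite::write_json(run$manifest, files["manifest"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  run
}

hash_object <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)
  unname(tools::md5sum(f))
}

#' @export
print.adherence_run <- function(x, ...) {
  cat("Adherence analysis run\n")
  cat(sprintf("  cohort n = %d; outcome respondents = %d\n",
              nrow(x$cohort$participants), nrow(x$cohort$outcomes)))
  cat(sprintf("  adjusted credible level: %.1f%%\n",
              100 * x$manifest$adjusted_level))
  cat("\nResults (ordered by |posterior mean| within outcome):\n")
  print(cbind(x$results[, c("outcome", "predictor")],
              round(x$results[, c("mean", "hdi95_lb", "hdi95_ub",
                                  "hdi_adj_lb", "hdi_adj_ub",
                                  "p_medium_to_large")], 3),
              n = x$results$n),
        row.names = FALSE)
  invisible(x)
}

#' Sensitivity analysis over susceptibility response families
#'
#' Refits the susceptibility model at Time 1 under each requested response
#' family, compares the per-participant anti-social-influence estimates
#' across families, and refits the primary-outcome ordinal model with each
#' family's estimates as the predictor. A family whose fit fails is
#' reported as absent and the analysis continues.
#'
#' @param cohort a `synthetic_cohort`.
#' @param families families to compare.
#' @param influence_settings,ordinal_settings MCMC settings.
#' @param alpha error rate for the ordinal refits (adjusted level uses
#'   `n_tests = 11` as in the main analysis).
#' @return object of class `sensitivity_report`: the family comparison and
#'   one ordinal-coefficient row per family (with that family's slope SD).
#' @export
sensitivity_analysis <- function(cohort,
                                 families = c("normal", "ordered_beta",
                                              "student_t"),
                                 influence_settings = influence_mcmc(),
                                 ordinal_settings = ordinal_mcmc(),
                                 alpha = 0.05) {
  tr <- cohort$influence_trials[cohort$influence_trials$timepoint == "t1", ]
  tr$initial <- recode_prosocial_direction(tr$initial, tr$scenario_type)
  tr$provided <- recode_prosocial_direction(tr$provided, tr$scenario_type)
  tr$second <- recode_prosocial_direction(tr$second, tr$scenario_type)
  tt <- build_trial_table(tr, cohort$config$provided_rating_bounds %||%
                            c(0.2, 0.8))
  fits <- list()
  for (fam in families) {
    fits[[fam]] <- tryCatch(
      fit_susceptibility(tt, influence_settings, family = fam),
      error = function(e) {
        warning(sprintf("family '%s' failed: %s", fam, conditionMessage(e)))
        NULL
      })
  }
  fitted <- fits[!vapply(fits, is.null, logical(1))]
  comparison <- if (length(fitted) >= 2) compare_families(fitted) else NULL

  det <- score_predictors(cohort)
  pt <- cohort$participants
  outc <- setdiff(names(cohort$outcomes), "participant_id")[1]
  rows <- list()
  i <- 0L
  for (fam in names(fits)) {
    i <- i + 1L
    if (is.null(fits[[fam]])) {
      rows[[fam]] <- data.frame(family = fam, mean = NA_real_,
                                hdi95_lb = NA_real_, hdi95_ub = NA_real_,
                                slope_sd_minus = NA_real_, n = NA_integer_)
      next
    }
    sc <- fits[[fam]]$scores
    d <- data.frame(participant_id = pt$participant_id,
                    age_t4 = pt$age_t4,
                    assessment_day = pt$assessment_day,
                    gender = pt$gender, group = pt$group)
    d$antisocial_influence <-
      zscore(sc$antisocial_susceptibility[match(d$participant_id,
                                                sc$participant_id)])
    d <- merge(cohort$outcomes[c("participant_id", outc)], d,
               by = "participant_id")
    os <- ordinal_settings
    os$seed <- derive_seed(ordinal_settings$seed, 500L + i)
    f <- fit_ordinal_model(d, outcome = outc,
                           predictor = "antisocial_influence",
                           covariates = c("age_t4", "assessment_day",
                                          "gender", "group"),
                           settings = os, n_tests = 11, alpha = alpha)
    s <- f$summary["antisocial_influence", ]
    rows[[fam]] <- data.frame(
      family = fam, mean = unname(s["mean"]),
      hdi95_lb = unname(s["hdi95_lb"]), hdi95_ub = unname(s["hdi95_ub"]),
      slope_sd_minus = unname(fits[[fam]]$slope_sd["delta_minus"]),
      n = f$n_used)
  }
  structure(list(comparison = comparison,
                 ordinal = do.call(rbind, c(rows, make.row.names = FALSE)),
                 outcome = outc, fits = fits),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: anti-social influence vs %s\n",
              x$outcome))
  if (!is.null(x$comparison)) print(x$comparison)
  cat("\nOrdinal coefficient per family:\n")
  print(cbind(x$ordinal[, "family", drop = FALSE],
              round(x$ordinal[, c("mean", "hdi95_lb", "hdi95_ub",
                                  "slope_sd_minus")], 3),
              n = x$ordinal$n),
        row.names = FALSE)
  invisible(x)
}
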