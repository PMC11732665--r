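# Shared fixtures, built in code.

# Small, fast cohort for structural checks.
small_cohort <- function(n = 40, seed = 101, ...) {
  generate_cohort(synth_config(n_participants = n, seed = seed, ...))
}

# Recode and decompose the influence trials of one time point.
trial_table_tp <- function(cohort, tp = "t1") {
  tr <- cohort$influence_trials[cohort$influence_trials$timepoint == tp, ]
  for (v in c("initial", "provided", "second")) {
    tr[[v]] <- recode_prosocial_direction(tr[[v]], tr$scenario_type)
  }
  build_trial_table(tr, cohort$config$provided_rating_bounds)
}

# Fast MCMC presets for tests.
fast_influence <- function(seed = 1L, ...) {
  influence_mcmc(n_adapt = 400, n_burn = 200, n_iter = 900, seed = seed, ...)
}

fast_ordinal <- function(seed = 1L, ...) {
  ordinal_mcmc(n_chains = 2, warmup = 300, iter = 500, seed = seed, ...)
}

# Independent brute-force scorer for the monetary choice questionnaire:
# enumerates every candidate rate with explicit loops.
kirby_bruteforce <- function(choices, items) {
  out <- numeric(3)
  names(out) <- c("small", "medium", "large")
  for (mag in names(out)) {
    ki <- items$k[items$magnitude == mag]
    ch <- choices[items$magnitude == mag]
    keep <- !is.na(ch)
    if (mean(!keep) > 0.2) {
      out[mag] <- NA_real_
      next
    }
    ks <- sort(ki)
    cand <- c(ks[1])
    for (i in 1:(length(ks) - 1)) cand <- c(cand, sqrt(ks[i] * ks[i + 1]))
    cand <- c(cand, ks[length(ks)])
    best_score <- -1
    best <- c()
    for (k in cand) {
      score <- 0
      for (j in seq_along(ki)) {
        if (!keep[j]) next
        if (ki[j] > k && ch[j] == "delayed") score <- score + 1
        if (ki[j] < k && ch[j] == "immediate") score <- score + 1
        if (ki[j] == k) score <- score + 1
      }
      if (score > best_score) {
        best_score <- score
        best <- k
      } else if (score == best_score) {
        best <- c(best, k)
      }
    }
    out[mag] <- exp(mean(log(best)))
  }
  out
}
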