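# Hierarchical Bayesian measurement models of the social-influence task,
# fit with JAGS. Two models: (i) prosociality — the person-level random
# intercept of the initial ratings under a censored-normal likelihood with
# scenario intercepts and person-specific (log-normally distributed)
# residual SDs; (ii) susceptibility — the second rating regressed on the
# initial rating and the delta+/delta- decomposition with correlated
# person-level random slopes, under a censored-normal (primary),
# Student-t (robust) or ordered-beta response family.

#' MCMC settings for the JAGS influence models
#'
#' Defaults are a desk-scale preset (two chains, moderate iterations) with
#' correspondingly relaxed convergence gates; production analyses should
#' raise `n_iter` and tighten the gates.
#'
#' @param n_chains chains.
#' @param n_adapt adaptation iterations.
#' @param n_burn burn-in iterations after adaptation.
#' @param n_iter retained iterations per chain.
#' @param thin thinning interval.
#' @param rhat_max,ess_min convergence gate on the scalar parameters.
#' @param lkj_eta shape of the LKJ-style prior density
#'   `(1 - rho^2)^(eta - 1)` on the slope correlation.
#' @param prior_sd_fixed prior SD of fixed effects.
#' @param seed integer seed.
#' @return list of settings.
#' @export
influence_mcmc <- function(n_chains = 2, n_adapt = 1000, n_burn = 500,
                           n_iter = 2500, thin = 1, rhat_max = 1.05,
                           ess_min = 100, lkj_eta = 2,
                           prior_sd_fixed = 2.5, seed = 1L) {
  list(n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
       n_iter = n_iter, thin = thin, rhat_max = rhat_max,
       ess_min = ess_min, lkj_eta = lkj_eta,
       prior_sd_fixed = prior_sd_fixed, seed = as.integer(seed))
}

jags_inits <- function(settings, extra = NULL) {
  lapply(seq_len(settings$n_chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = derive_seed(settings$seed, ch)), extra)
  })
}

# Censoring encoding for the JAGS dinterval idiom: interval = 0 below the
# floor, 1 interior, 2 above the ceiling; boundary observations have a
# latent (unobserved) response initialised just outside the bounds.
censor_encode <- function(y, bounds = c(0, 1)) {
  interval <- ifelse(y <= bounds[1], 0L, ifelse(y >= bounds[2], 2L, 1L))
  ystar <- ifelse(interval == 1L, y, NA_real_)
  init <- ifelse(is.na(ystar),
                 ifelse(interval == 0L, bounds[1] - 0.01, bounds[2] + 0.01),
                 NA_real_)
  list(interval = interval, ystar = ystar, init = init)
}

jags_diagnostics <- function(samples, scalar_pars, rhat_max, ess_min) {
  sub <- samples[, intersect(scalar_pars, coda::varnames(samples)),
                 drop = FALSE]
  rhat <- tryCatch(
    coda::gelman.diag(sub, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, ncol(sub[[1]])),
                                        coda::varnames(sub)))
  ess <- coda::effectiveSize(sub)
  list(rhat = rhat, ess = ess,
       ok = all(rhat < rhat_max, na.rm = TRUE) &&
         all(ess > ess_min, na.rm = TRUE))
}

posterior_matrix <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

prosociality_model_string <- "
model {
  for (t in 1:N) {
    interval[t] ~ dinterval(ystar[t], lims[1:2])
    ystar[t] ~ dnorm(mu[t], prec_res[part[t]])
    mu[t] <- b0 + a[part[t]] + s[scen[t]]
  }
  for (i in 1:P) {
    a[i] ~ dnorm(0, tau_a)
    zls[i] ~ dnorm(0, 1)
    # floored at the slider resolution to keep the likelihood finite
    log_sigma[i] <- max(-4.6, ls0 + sd_ls * zls[i])
    prec_res[i] <- exp(-2 * log_sigma[i])
  }
  for (j in 1:S) { s[j] ~ dnorm(0, tau_s) }
  b0_pop <- b0 + mean(s[1:S]) + mean(a[1:P])   # identified grand mean
  b0 ~ dnorm(0.5, prec_fixed)
  sd_a ~ dnorm(0, 1) T(0,)
  tau_a <- pow(sd_a, -2)
  sd_s ~ dnorm(0, 1) T(0,)
  tau_s <- pow(sd_s, -2)
  ls0 ~ dnorm(-2, 0.25)
  sd_ls ~ dnorm(0, 1) T(0,)
}"

#' Fit the prosociality measurement model
#'
#' Hierarchical censored-normal model of the initial ratings with a random
#' intercept per participant (the prosociality estimate), a random
#' intercept per scenario, and person-specific residual SDs modelled as a
#' log-scale normal random effect.
#'
#' @param trials trial table (see [build_trial_table()]); the `initial`
#'   column is the outcome.
#' @param settings an [influence_mcmc()] list.
#' @return object of class `prosociality_fit`: per-participant `scores`
#'   (posterior-mean intercept level `b0 + a_i` and residual SD
#'   `sigma_i`), global mean, scenario-intercept SD, scalar posterior
#'   draws and convergence diagnostics.
#' @export
fit_prosociality <- function(trials, settings = influence_mcmc()) {
  ids <- sort(unique(trials$participant_id))
  scens <- sort(unique(trials$scenario_id))
  stop_if_not(length(ids) >= 2, "need at least 2 participants")
  stop_if_not(length(scens) >= 2, "need at least 2 scenarios")
  part <- match(trials$participant_id, ids)
  scen <- match(trials$scenario_id, scens)
  cens <- censor_encode(trials$initial)

  data <- list(N = nrow(trials), P = length(ids), S = length(scens),
               interval = cens$interval, ystar = cens$ystar,
               lims = c(0, 1), part = part, scen = scen,
               prec_fixed = 1 / settings$prior_sd_fixed^2)
  jm <- rjags::jags.model(
    textConnection(prosociality_model_string), data = data,
    inits = jags_inits(settings, list(ystar = cens$init)),
    n.chains = settings$n_chains, n.adapt = settings$n_adapt,
    quiet = TRUE)
  stats::update(jm, settings$n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(
    jm, c("b0_pop", "a", "log_sigma", "sd_a", "sd_s", "sd_ls", "ls0"),
    n.iter = settings$n_iter, thin = settings$thin,
    progress.bar = "none")

  post <- posterior_matrix(samples)
  b0 <- post[, "b0_pop"]
  a_cols <- paste0("a[", seq_along(ids), "]")
  ls_cols <- paste0("log_sigma[", seq_along(ids), "]")
  scores <- data.frame(
    participant_id = ids,
    prosociality = mean(b0) + colMeans(post[, a_cols, drop = FALSE]),
    residual_sd = colMeans(exp(post[, ls_cols, drop = FALSE])))
  diag <- jags_diagnostics(samples,
                           c("b0_pop", "sd_a", "sd_s", "sd_ls", "ls0"),
                           settings$rhat_max, settings$ess_min)

  structure(list(scores = scores, global_mean = mean(b0),
                 participant_sd = mean(post[, "sd_a"]),
                 scenario_sd = mean(post[, "sd_s"]),
                 draws = post[, c("b0_pop", "sd_a", "sd_s", "sd_ls", "ls0")],
                 diagnostics = diag, settings = settings,
                 n_trials = nrow(trials)),
            class = "prosociality_fit")
}

#' @export
print.prosociality_fit <- function(x, ...) {
  cat(sprintf("Prosociality fit: %d participants, %d trials\n",
              nrow(x$scores), x$n_trials))
  cat(sprintf("  global mean %.3f, participant SD %.3f, scenario SD %.3f\n",
              x$global_mean, x$participant_sd, x$scenario_sd))
  cat(sprintf("  convergence: %s\n",
              ifelse(x$diagnostics$ok, "ok", "FLAGGED")))
  invisible(x)
}

susceptibility_model_core <- "
  for (i in 1:P) {
    e1[i] ~ dnorm(0, 1)
    e2[i] ~ dnorm(0, 1)
    up[i] <- sd_p * e1[i]
    um[i] <- sd_m * (rho * e1[i] + sqrt(1 - rho * rho) * e2[i])
  }
  b0 ~ dnorm(0, prec_fixed)
  b_init ~ dnorm(0, prec_fixed)
  b_plus ~ dnorm(0, prec_fixed)
  b_minus ~ dnorm(0, prec_fixed)
  sd_p ~ dnorm(0, 1) T(0,)
  sd_m ~ dnorm(0, 1) T(0,)
  rho ~ dunif(-1, 1)
  lkj_one ~ dbern(lkj_w)
  lkj_w <- pow(1 - rho * rho, lkj_eta - 1)
"

# The primary family carries person-specific residual SDs (log-scale
# normal random effect), matching the heteroscedastic, person-scaled noise
# of the slider responses.
susceptibility_normal_string <- paste0("
model {
  for (t in 1:N) {
    interval[t] ~ dinterval(ystar[t], lims[1:2])
    ystar[t] ~ dnorm(mu[t], prec_res[part[t]])
    mu[t] <- b0 + b_init * init[t] + (b_plus + up[part[t]]) * dp[t] +
             (b_minus + um[part[t]]) * dm[t]
  }
  for (i in 1:P) {
    zls[i] ~ dnorm(0, 1)
    prec_res[i] <- exp(-2 * max(-4.6, ls0 + sd_ls * zls[i]))
  }
  ls0 ~ dnorm(-2, 0.25)
  sd_ls ~ dnorm(0, 1) T(0,)
  sigma <- exp(ls0)
", susceptibility_model_core, "}")

susceptibility_student_string <- paste0("
model {
  for (t in 1:N) {
    y[t] ~ dt(mu[t], prec_res, nu)
    mu[t] <- b0 + b_init * init[t] + (b_plus + up[part[t]]) * dp[t] +
             (b_minus + um[part[t]]) * dm[t]
  }
  sigma ~ dnorm(0, 1) T(0,)
  prec_res <- pow(sigma, -2)
  nu <- 1 + nu_raw
  nu_raw ~ dexp(0.0345)
", susceptibility_model_core, "}")

# Ordered-beta family (logit link): discrete masses at the slider endpoints
# governed by two ordered cutpoints, a beta density in the interior.
# Implemented with the zeros trick.
susceptibility_ordbeta_string <- paste0("
model {
  for (t in 1:N) {
    eta[t] <- b0 + b_init * init[t] + (b_plus + up[part[t]]) * dp[t] +
              (b_minus + um[part[t]]) * dm[t]
  }
  for (q in 1:N0) {
    ll0[q] <- log(1 - ilogit(eta[i0[q]] - c1) + 1.0E-12)
    zeros0[q] ~ dpois(Cz - ll0[q])
  }
  for (q in 1:N1) {
    ll1[q] <- log(ilogit(eta[i1[q]] - c2) + 1.0E-12)
    zeros1[q] ~ dpois(Cz - ll1[q])
  }
  for (q in 1:Nc) {
    mu_c[q] <- ilogit(eta[ic[q]])
    a1[q] <- mu_c[q] * phi_b
    a2[q] <- (1 - mu_c[q]) * phi_b
    llc[q] <- log(ilogit(eta[ic[q]] - c1) - ilogit(eta[ic[q]] - c2) +
                  1.0E-12) +
              (a1[q] - 1) * log(yc[q]) + (a2[q] - 1) * log(1 - yc[q]) +
              loggam(phi_b) - loggam(a1[q]) - loggam(a2[q])
    zerosc[q] ~ dpois(Cz - llc[q])
  }
  c1 ~ dnorm(-3, 0.25)
  gap ~ dnorm(0, 0.25) T(0,)
  c2 <- c1 + gap
  phi_b ~ dgamma(2, 0.1)
", susceptibility_model_core, "}")

#' Fit the susceptibility-to-influence measurement model
#'
#' Regresses the second rating on the initial rating and the delta+/delta-
#' decomposition, with correlated per-participant random slopes on delta+
#' and delta- quantifying susceptibility to prosocial and anti-social
#' influence. Because delta- keeps its negative sign, a positive delta-
#' slope means conformity toward less prosocial ratings, i.e. higher
#' susceptibility to anti-social influence.
#'
#' Response families: `"normal"` (primary) treats the slider endpoints as
#' exact censoring masses; `"ordered_beta"` models the endpoint masses via
#' two ordered cutpoints with a beta density in the interior (logit link,
#' so coefficients live on the logit scale); `"student_t"` is a robust
#' heavy-tailed model with estimated degrees of freedom that deliberately
#' ignores the boundary masses (a message notes this).
#'
#' @param trials trial table from [build_trial_table()].
#' @param settings an [influence_mcmc()] list.
#' @param family response family.
#' @return object of class `susceptibility_fit`: per-participant `scores`
#'   (posterior-mean `prosocial_susceptibility = b_plus + up_i` and
#'   `antisocial_susceptibility = b_minus + um_i`), fixed-effect summary,
#'   slope SDs and correlation, scalar draws, diagnostics.
#' @export
fit_susceptibility <- function(trials, settings = influence_mcmc(),
                               family = c("normal", "student_t",
                                          "ordered_beta")) {
  family <- match.arg(family)
  stop_if_not(all(c("delta_plus", "delta_minus") %in% names(trials)),
              "trial table lacks the delta decomposition; run build_trial_table()")
  ids <- sort(unique(trials$participant_id))
  part <- match(trials$participant_id, ids)
  N <- nrow(trials)
  # centring the initial rating decorrelates the intercept from its slope;
  # the intercept is translated back to the original scale afterwards
  init_mean <- mean(trials$initial)
  base_data <- list(N = N, P = length(ids), part = part,
                    init = trials$initial - init_mean,
                    dp = trials$delta_plus,
                    dm = trials$delta_minus,
                    prec_fixed = 1 / settings$prior_sd_fixed^2,
                    lkj_eta = settings$lkj_eta, lkj_one = 1L)

  if (family == "normal") {
    cens <- censor_encode(trials$second)
    data <- c(base_data, list(interval = cens$interval, ystar = cens$ystar,
                              lims = c(0, 1)))
    model_string <- susceptibility_normal_string
    inits_extra <- list(ystar = cens$init)
  } else if (family == "student_t") {
    message("student_t family treats boundary responses as ordinary ",
            "observations (no censoring masses)")
    data <- c(base_data, list(y = trials$second))
    model_string <- susceptibility_student_string
    inits_extra <- NULL
  } else {
    y <- trials$second
    i0 <- which(y <= 0); i1 <- which(y >= 1)
    ic <- which(y > 0 & y < 1)
    data <- c(base_data,
              list(i0 = i0, i1 = i1, ic = ic, yc = y[ic],
                   N0 = length(i0), N1 = length(i1), Nc = length(ic),
                   zeros0 = rep(0L, length(i0)),
                   zeros1 = rep(0L, length(i1)),
                   zerosc = rep(0L, length(ic)), Cz = 50))
    # zeros-trick loops cannot be empty
    for (nm in c("i0", "i1", "ic")) {
      stop_if_not(length(data[[nm]]) > 0,
                  "ordered_beta family needs interior and boundary responses")
    }
    # the fixed effects live on the logit scale; widen their prior
    data$prec_fixed <- 1 / (2 * settings$prior_sd_fixed)^2
    model_string <- susceptibility_ordbeta_string
    inits_extra <- NULL
  }

  jm <- rjags::jags.model(
    textConnection(model_string), data = data,
    inits = jags_inits(settings, inits_extra),
    n.chains = settings$n_chains, n.adapt = settings$n_adapt,
    quiet = TRUE)
  stats::update(jm, settings$n_burn, progress.bar = "none")
  scalar_pars <- c("b0", "b_init", "b_plus", "b_minus", "sd_p", "sd_m",
                   "rho",
                   switch(family, normal = c("sigma", "ls0", "sd_ls"),
                          student_t = c("sigma", "nu"),
                          ordered_beta = c("c1", "c2", "phi_b")))
  samples <- rjags::coda.samples(
    jm, c(scalar_pars, "up", "um"), n.iter = settings$n_iter,
    thin = settings$thin, progress.bar = "none")

  post <- posterior_matrix(samples)
  post[, "b0"] <- post[, "b0"] - post[, "b_init"] * init_mean
  up_cols <- paste0("up[", seq_along(ids), "]")
  um_cols <- paste0("um[", seq_along(ids), "]")
  scores <- data.frame(
    participant_id = ids,
    prosocial_susceptibility = mean(post[, "b_plus"]) +
      colMeans(post[, up_cols, drop = FALSE]),
    antisocial_susceptibility = mean(post[, "b_minus"]) +
      colMeans(post[, um_cols, drop = FALSE]))
  diag <- jags_diagnostics(samples, scalar_pars,
                           settings$rhat_max, settings$ess_min)
  fixed <- colMeans(post[, c("b0", "b_init", "b_plus", "b_minus"),
                         drop = FALSE])

  structure(list(scores = scores, fixed = fixed,
                 slope_sd = c(delta_plus = mean(post[, "sd_p"]),
                              delta_minus = mean(post[, "sd_m"])),
                 slope_correlation = mean(post[, "rho"]),
                 draws = post[, scalar_pars, drop = FALSE],
                 family = family, diagnostics = diag,
                 settings = settings, n_trials = N),
            class = "susceptibility_fit")
}

#' @export
print.susceptibility_fit <- function(x, ...) {
  cat(sprintf("Susceptibility fit (%s family): %d participants, %d trials\n",
              x$family, nrow(x$scores), x$n_trials))
  cat(sprintf("  fixed: intercept %.3f, initial %.3f, delta+ %.3f, delta- %.3f\n",
              x$fixed["b0"], x$fixed["b_init"], x$fixed["b_plus"],
              x$fixed["b_minus"]))
  cat(sprintf("  slope SDs: delta+ %.3f, delta- %.3f; correlation %.2f\n",
              x$slope_sd["delta_plus"], x$slope_sd["delta_minus"],
              x$slope_correlation))
  cat(sprintf("  convergence: %s\n",
              ifelse(x$diagnostics$ok, "ok", "FLAGGED")))
  invisible(x)
}

#' Compare susceptibility estimates across response families
#'
#' Pairwise correlations of the per-participant anti-social-influence
#' estimates across families, plus each family's between-participant slope
#' SDs — the diagnostic used to judge whether a family collapses
#' between-subject variance. Fits with differing participant sets are
#' aligned on the intersection with a warning.
#'
#' @param fits named list of `susceptibility_fit` objects (>= 2).
#' @return object of class `family_comparison`: a correlation matrix and a
#'   per-family summary table.
#' @export
compare_families <- function(fits) {
  stop_if_not(length(fits) >= 2, "need at least 2 fitted families")
  stop_if_not(all(vapply(fits, inherits, logical(1), "susceptibility_fit")),
              "all elements must be susceptibility fits")
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$family, character(1))
  }
  common <- Reduce(intersect,
                   lapply(fits, function(f) f$scores$participant_id))
  sizes <- vapply(fits, function(f) nrow(f$scores), integer(1))
  if (any(sizes != length(common))) {
    warning(sprintf("participant sets differ; aligned on %d common ids",
                    length(common)))
  }
  anti <- sapply(fits, function(f) {
    f$scores$antisocial_susceptibility[match(common,
                                             f$scores$participant_id)]
  })
  correlations <- stats::cor(anti)
  summary_tab <- data.frame(
    family = names(fits),
    slope_sd_plus = vapply(fits, function(f)
      unname(f$slope_sd["delta_plus"]), numeric(1)),
    slope_sd_minus = vapply(fits, function(f)
      unname(f$slope_sd["delta_minus"]), numeric(1)),
    n_participants = sizes)
  structure(list(correlations = correlations, summary = summary_tab,
                 n_common = length(common)),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat("Anti-social influence estimates across response families\n")
  cat(sprintf("  common participants: %d\n", x$n_common))
  print(round(x$correlations, 3))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
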