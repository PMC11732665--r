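# Bayesian cumulative-probit ordinal regression. The observed 5-category
# response Y arises from a standard-normal latent variable crossing four
# ordered cutpoints; coefficients act on the latent scale, so with z-scored
# predictors they read as standardized effects. The sampler alternates
# (i) a collapsed random-walk Metropolis update of the cutpoints given the
# coefficients (latent responses integrated out), (ii) a draw of the latent
# responses from their truncated-normal full conditionals, and (iii) a
# conjugate multivariate-normal draw of the coefficients.

#' Cumulative-probit category probabilities
#'
#' `p(k) = Phi(tau_k - eta) - Phi(tau_{k-1} - eta)` with `tau_0 = -Inf` and
#' `tau_K = Inf`.
#'
#' @param eta latent location (scalar or vector).
#' @param cutpoints strictly increasing cutpoints (K - 1 values for K
#'   categories).
#' @return matrix of category probabilities (rows follow `eta`), each row
#'   summing to 1.
#' @examples
#' cumulative_probit_probs(0, c(-1, 0, 1, 2))
#' @export
cumulative_probit_probs <- function(eta, cutpoints) {
  stop_if_not(all(diff(cutpoints) > 0),
              "cutpoints must be strictly increasing")
  cdf <- cbind(0, stats::pnorm(outer(-eta, cutpoints, `+`)), 1)
  probs <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  colnames(probs) <- paste0("p", seq_len(ncol(probs)))
  probs
}

# Ordinal log-likelihood given coefficients and cutpoints.
ordinal_loglik <- function(y, eta, cutpoints) {
  tau <- c(-Inf, cutpoints, Inf)
  p <- stats::pnorm(tau[y + 1L] - eta) - stats::pnorm(tau[y] - eta)
  sum(log(pmax(p, 1e-300)))
}

#' Multiplicity-adjusted credible level
#'
#' The Bonferroni-style credible level `1 - alpha / n_tests`, reported to
#' three decimals: with 11 tests at alpha = 0.05 this gives 0.995.
#'
#' @param n_tests number of tests sharing the error budget.
#' @param alpha overall two-sided error rate.
#' @return adjusted credible level.
#' @export
adjusted_credible_level <- function(n_tests, alpha = 0.05) {
  stop_if_not(n_tests >= 1, "n_tests must be >= 1")
  stop_if_not(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  round(1 - alpha / n_tests, 3)
}

#' Highest density interval of a posterior sample
#'
#' The narrowest interval containing the requested posterior mass; for
#' discrete draws, ties between equal-width candidate windows resolve to
#' the leftmost.
#'
#' @param draws numeric vector of posterior draws.
#' @param level probability mass to contain (in (0, 1)).
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, level = 0.95) {
  stop_if_not(level > 0 && level < 1, "level must lie in (0, 1)")
  draws <- sort(draws[!is.na(draws)])
  n <- length(draws)
  if (n < 1000) warning("fewer than 1000 draws; interval may be unstable")
  m <- ceiling(level * n)
  if (m >= n) return(c(draws[1], draws[n]))
  widths <- draws[m:n] - draws[1:(n - m + 1)]
  i <- which.min(widths)                       # which.min takes the leftmost
  c(draws[i], draws[i + m - 1])
}

#' Posterior effect-size classification
#'
#' The probability that a standardized coefficient is small
#' (|b| <= `small`), small-to-medium (`small` < |b| <= `large`) or
#' medium-to-large (|b| > `large`); draws exactly on a boundary count
#' towards the inner bin.
#'
#' @param draws posterior draws of a standardized coefficient.
#' @param small,large bin boundaries (defaults 0.1 and 0.3).
#' @return named numeric vector of the three bin probabilities (sums to 1).
#' @export
effect_size_classification <- function(draws, small = 0.1, large = 0.3) {
  a <- abs(draws)
  c(p_small = mean(a <= small),
    p_small_to_medium = mean(a > small & a <= large),
    p_medium_to_large = mean(a > large))
}

#' MCMC settings for the ordinal sampler
#'
#' @param n_chains number of chains.
#' @param warmup,iter warmup and retained iterations per chain.
#' @param prior_sd_beta prior SD of the standardized coefficients.
#' @param prior_sd_cutpoint prior SD of the cutpoint location parameters.
#' @param mh_refresh collapsed Metropolis updates of the cutpoint block per
#'   iteration (several cheap refreshes improve cutpoint mixing).
#' @param rhat_max,ess_min convergence gate thresholds.
#' @param seed integer seed.
#' @return list of settings.
#' @export
ordinal_mcmc <- function(n_chains = 4, warmup = 750, iter = 1250,
                         prior_sd_beta = 2.5, prior_sd_cutpoint = 5,
                         mh_refresh = 5, rhat_max = 1.01, ess_min = 400,
                         seed = 1L) {
  list(n_chains = n_chains, warmup = warmup, iter = iter,
       prior_sd_beta = prior_sd_beta,
       prior_sd_cutpoint = prior_sd_cutpoint, mh_refresh = mh_refresh,
       rhat_max = rhat_max, ess_min = ess_min, seed = as.integer(seed))
}

# One chain of the partially collapsed sampler. Returns draws of beta and
# cutpoints.
run_ordinal_chain <- function(y, X, K, settings, chain_id) {
  n <- length(y); p <- ncol(X)
  sd_b <- settings$prior_sd_beta
  sd_c <- settings$prior_sd_cutpoint
  n_iter <- settings$warmup + settings$iter

  # initial cutpoints from the empirical cumulative distribution, jittered
  # across chains; empty categories fall back to equal spacing
  freq <- tabulate(y, K)
  cum <- cumsum(freq)[-K] / n
  cum <- pmin(pmax(cum, 0.01), 0.99)
  tau <- stats::qnorm(cum)
  if (any(diff(tau) <= 0)) tau <- seq(-1.5, 1.5, length.out = K - 1)
  theta <- c(tau[1], log(pmax(diff(tau), 0.05))) +
    stats::rnorm(K - 1, 0, 0.1)
  beta <- stats::rnorm(p, 0, 0.1)

  XtX <- crossprod(X)
  A <- XtX + diag(1 / sd_b^2, p)
  A_chol <- chol(A)

  log_post_theta <- function(theta, eta) {
    tau <- theta_to_tau(theta)
    ordinal_loglik(y, eta, tau) +
      sum(stats::dnorm(tau, 0, sd_c, log = TRUE)) +
      sum(theta[-1])                            # Jacobian of the log-diffs
  }

  draws <- matrix(NA_real_, settings$iter, p + K - 1)
  step <- 0.1
  accept <- 0
  eta <- drop(X %*% beta)
  lp <- log_post_theta(theta, eta)
  n_mh <- max(1L, settings$mh_refresh %||% 1L)
  for (it in seq_len(n_iter)) {
    # (i) collapsed MH updates of the cutpoint block
    for (r in seq_len(n_mh)) {
      prop <- theta + stats::rnorm(K - 1, 0, step)
      lp_prop <- log_post_theta(prop, eta)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; accept <- accept + 1
      }
    }
    if (it <= settings$warmup && it %% 50 == 0) {
      rate <- accept / (50 * n_mh); accept <- 0
      step <- step * exp(0.8 * (rate - 0.3))    # aim near 30% acceptance
    }
    tau <- theta_to_tau(theta)

    # (ii) latent responses from truncated normals
    tau_ext <- c(-Inf, tau, Inf)
    lo <- stats::pnorm(tau_ext[y] - eta)
    hi <- stats::pnorm(tau_ext[y + 1L] - eta)
    u <- lo + stats::runif(n) * (hi - lo)
    z <- eta + stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))

    # (iii) conjugate coefficient draw
    m <- backsolve(A_chol, backsolve(A_chol, crossprod(X, z),
                                     transpose = TRUE))
    beta <- drop(m + backsolve(A_chol, stats::rnorm(p)))
    eta <- drop(X %*% beta)
    lp <- log_post_theta(theta, eta)

    if (it > settings$warmup) {
      draws[it - settings$warmup, ] <- c(beta, tau)
    }
  }
  draws
}

theta_to_tau <- function(theta) cumsum(c(theta[1], exp(theta[-1])))

#' Fit a Bayesian cumulative-probit ordinal regression
#'
#' Regresses a K-category ordinal outcome on a z-scored predictor plus
#' covariates via a latent standard-normal variable with estimated ordered
#' cutpoints (no free intercept: the latent scale is identified by zero
#' mean and unit variance). Priors are normal(0, 2.5) on standardized
#' coefficients and wide normals on the ordered cutpoints.
#'
#' @param data data.frame containing the outcome and model terms.
#' @param outcome name of the ordinal outcome column (integer categories
#'   1..K).
#' @param predictor name of the focal predictor column.
#' @param covariates character vector of covariate columns.
#' @param settings an [ordinal_mcmc()] settings list.
#' @param standardize z-score the predictor and non-binary covariates on
#'   the analysis sample (default TRUE; binary 0/1 columns pass through).
#' @param n_tests number of planned tests, used for the
#'   multiplicity-adjusted credible level (default 11).
#' @param alpha overall error rate for the adjusted level.
#' @return object of class `ordinal_fit` with posterior draws, summaries
#'   (posterior mean, median, 95% and adjusted HDIs, effect-size bin
#'   probabilities for the focal predictor), convergence diagnostics and
#'   the analysis sample size `n_used` (listwise deletion; dropped count
#'   recorded as `n_dropped`).
#' @export
fit_ordinal_model <- function(data, outcome, predictor,
                              covariates = character(0),
                              settings = ordinal_mcmc(),
                              standardize = TRUE, n_tests = 11,
                              alpha = 0.05) {
  vars <- c(outcome, predictor, covariates)
  stop_if_not(all(vars %in% names(data)),
              paste("missing columns:",
                    paste(setdiff(vars, names(data)), collapse = ", ")))
  use <- stats::complete.cases(data[vars])
  n_dropped <- sum(!use)
  d <- data[use, vars, drop = FALSE]
  y <- as.integer(d[[outcome]])
  K <- max(y)
  stop_if_not(length(unique(y)) >= 2, "need at least 2 observed categories")
  stop_if_not(all(y >= 1), "outcome categories must be coded 1..K")

  X <- as.matrix(d[, c(predictor, covariates), drop = FALSE])
  if (standardize) {
    for (j in seq_len(ncol(X))) {
      col <- X[, j]
      if (length(unique(col)) > 2) X[, j] <- zscore(col)
    }
  }

  chains <- lapply(seq_len(settings$n_chains), function(ch) {
    with_seed(derive_seed(settings$seed, ch),
              run_ordinal_chain(y, X, K, settings, ch))
  })
  par_names <- c(colnames(X), paste0("cutpoint_", seq_len(K - 1)))
  chains <- lapply(chains, function(m) {
    colnames(m) <- par_names
    m
  })
  draws <- do.call(rbind, chains)

  mcl <- coda::mcmc.list(lapply(chains, coda::mcmc))
  rhat <- tryCatch(
    coda::gelman.diag(mcl, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(draws)))
  ess <- tryCatch(coda::effectiveSize(mcl),
                  error = function(e) rep(NA_real_, ncol(draws)))

  level_adj <- adjusted_credible_level(n_tests, alpha)
  summarise_par <- function(v) {
    c(mean = mean(v), median = stats::median(v), sd = stats::sd(v),
      stats::setNames(hdi(v, 0.95), c("hdi95_lb", "hdi95_ub")),
      stats::setNames(hdi(v, level_adj), c("hdi_adj_lb", "hdi_adj_ub")))
  }
  summary_tab <- t(apply(draws, 2, summarise_par))

  convergence_ok <- all(rhat < settings$rhat_max, na.rm = TRUE) &&
    all(ess > settings$ess_min, na.rm = TRUE)

  structure(list(draws = draws, chains = chains, summary = summary_tab,
                 predictor = predictor, outcome = outcome,
                 covariates = covariates,
                 effect_bins = effect_size_classification(draws[, predictor]),
                 adjusted_level = level_adj,
                 rhat = rhat, ess = ess, convergence_ok = convergence_ok,
                 n_used = length(y), n_dropped = n_dropped,
                 settings = settings),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Cumulative-probit ordinal fit: %s ~ %s (+ %d covariates)\n",
              x$outcome, x$predictor, length(x$covariates)))
  cat(sprintf("  n = %d (dropped %d); chains x iter = %d x %d\n",
              x$n_used, x$n_dropped, x$settings$n_chains,
              x$settings$iter))
  s <- x$summary[x$predictor, ]
  cat(sprintf("  %s: mean %.3f, 95%% HDI [%.3f, %.3f], %.1f%% HDI [%.3f, %.3f]\n",
              x$predictor, s["mean"], s["hdi95_lb"], s["hdi95_ub"],
              100 * x$adjusted_level, s["hdi_adj_lb"], s["hdi_adj_ub"]))
  cat(sprintf("  effect bins: small %.2f, small-medium %.2f, medium-large %.2f\n",
              x$effect_bins[1], x$effect_bins[2], x$effect_bins[3]))
  cat(sprintf("  convergence: %s (max Rhat %.3f, min ESS %.0f)\n",
              ifelse(x$convergence_ok, "ok", "FLAGGED"),
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE)))
  invisible(x)
}

#' Assemble the results table over predictors and outcomes
#'
#' One row per fitted predictor-outcome model: posterior mean and median of
#' the standardized coefficient, 95% and adjusted HDIs, effect-size bin
#' probabilities, analysis n and a reliability flag (convergence gate).
#' Rows are ordered by absolute posterior mean within outcome. Fits passed
#' as `NULL` produce a row of missing markers.
#'
#' @param fits named list (by outcome) of named lists (by predictor) of
#'   `ordinal_fit` objects or `NULL`.
#' @return data.frame report table.
#' @export
build_results_table <- function(fits) {
  rows <- list()
  for (outc in names(fits)) {
    for (pred in names(fits[[outc]])) {
      f <- fits[[outc]][[pred]]
      if (is.null(f)) {
        rows[[length(rows) + 1]] <- data.frame(
          outcome = outc, predictor = pred, mean = NA_real_,
          median = NA_real_, hdi95_lb = NA_real_, hdi95_ub = NA_real_,
          hdi_adj_lb = NA_real_, hdi_adj_ub = NA_real_,
          p_small = NA_real_, p_small_to_medium = NA_real_,
          p_medium_to_large = NA_real_, n = NA_integer_,
          reliable = NA)
        next
      }
      s <- f$summary[f$predictor, ]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outc, predictor = pred,
        mean = unname(s["mean"]), median = unname(s["median"]),
        hdi95_lb = unname(s["hdi95_lb"]), hdi95_ub = unname(s["hdi95_ub"]),
        hdi_adj_lb = unname(s["hdi_adj_lb"]),
        hdi_adj_ub = unname(s["hdi_adj_ub"]),
        p_small = unname(f$effect_bins["p_small"]),
        p_small_to_medium = unname(f$effect_bins["p_small_to_medium"]),
        p_medium_to_large = unname(f$effect_bins["p_medium_to_large"]),
        n = f$n_used, reliable = f$convergence_ok)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(match(tab$outcome, names(fits)), -abs(tab$mean),
               na.last = TRUE)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  tab
}
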