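# Social-influence task data preparation and the censored-normal
# observation model. A trial records an initial rating, a randomly
# generated peer ("provided") rating and a second rating, all recoded so
# higher = more prosocial. delta = provided - initial splits into its
# positive part (delta+, prosocial influence opportunity) and negative
# part (delta-, anti-social influence opportunity, kept negative).

#' Build the influence-trial model table
#'
#' Computes the delta decomposition for each trial: `delta = provided -
#' initial`, `delta_plus = max(delta, 0)`, `delta_minus = min(delta, 0)`.
#' Rows with a missing second rating are dropped (count reported via a
#' message). Ratings must already be recoded to the prosocial direction
#' (see [recode_prosocial_direction()]).
#'
#' @param trials data.frame with columns `participant_id`, `scenario_id`,
#'   `initial`, `provided`, `second` (all ratings in \[0, 1\], recoded).
#' @param provided_bounds expected bounds of the provided rating; values
#'   outside trigger a warning only, since observed data may differ.
#' @return data.frame with the delta decomposition appended.
#' @export
build_trial_table <- function(trials, provided_bounds = c(0.20, 0.80)) {
  need <- c("participant_id", "scenario_id", "initial", "provided", "second")
  stop_if_not(all(need %in% names(trials)),
              paste("missing columns:",
                    paste(setdiff(need, names(trials)), collapse = ", ")))
  for (col in c("initial", "provided", "second")) {
    v <- trials[[col]]
    stop_if_not(all(is.na(v) | (v >= 0 & v <= 1)),
                sprintf("%s ratings must lie in [0, 1]", col))
  }
  drop <- is.na(trials$second) | is.na(trials$initial) |
    is.na(trials$provided)
  if (any(drop)) {
    message(sprintf("dropping %d trial(s) with missing ratings", sum(drop)))
    trials <- trials[!drop, , drop = FALSE]
  }
  out_of_band <- trials$provided < min(provided_bounds, 1 - provided_bounds) |
    trials$provided > max(provided_bounds, 1 - provided_bounds)
  if (any(out_of_band)) {
    warning(sprintf("%d provided rating(s) outside the configured bounds",
                    sum(out_of_band)))
  }
  trials$delta <- trials$provided - trials$initial
  trials$delta_plus <- pmax(trials$delta, 0)
  trials$delta_minus <- pmin(trials$delta, 0)
  rownames(trials) <- NULL
  trials
}

#' Ordered-beta log density/mass for slider responses
#'
#' The ordered-beta likelihood for a response on the closed unit interval:
#' discrete masses at 0 and 1 governed by two ordered cutpoints on the
#' logit scale, and a continuous beta density (mean `plogis(eta)`,
#' precision `phi`) in the interior, weighted by the probability of
#' falling between the cutpoints. This is the same kernel the JAGS
#' ordered-beta susceptibility model evaluates.
#'
#' @param y response(s) in \[0, 1\].
#' @param eta latent location on the logit scale.
#' @param cut1,cut2 ordered cutpoints (`cut1 < cut2`) on the logit scale.
#' @param phi beta precision (> 0).
#' @return log density/mass, vectorized.
#' @export
ordered_beta_loglik <- function(y, eta, cut1, cut2, phi) {
  stop_if_not(all(cut1 < cut2), "cutpoints must be ordered (cut1 < cut2)")
  stop_if_not(all(phi > 0), "phi must be positive")
  stop_if_not(all(y >= 0 & y <= 1), "y must lie in [0, 1]")
  n <- max(length(y), length(eta))
  y <- rep_len(y, n); eta <- rep_len(eta, n)
  mu <- stats::plogis(eta)
  out <- numeric(n)
  at0 <- y == 0; at1 <- y == 1; mid <- !at0 & !at1
  out[at0] <- log(1 - stats::plogis(eta[at0] - cut1))
  out[at1] <- log(stats::plogis(eta[at1] - cut2))
  out[mid] <- log(stats::plogis(eta[mid] - cut1) -
                    stats::plogis(eta[mid] - cut2)) +
    stats::dbeta(y[mid], mu[mid] * phi, (1 - mu[mid]) * phi, log = TRUE)
  out
}

#' Censored-normal log density/mass for slider responses
#'
#' The slider response is a normal variable censored at the slider
#' endpoints: interior values carry the normal log density, a response at
#' the lower bound carries the mass `log Phi((lo - mu)/sigma)` and a
#' response at the upper bound `log(1 - Phi((hi - mu)/sigma))`. The
#' interior density plus both boundary masses integrates to 1 for any
#' `(mu, sigma)`.
#'
#' @param y observed response(s) in `[bounds[1], bounds[2]]`.
#' @param mu,sigma normal location and scale (sigma > 0).
#' @param bounds censoring bounds, default the unit slider.
#' @return log density/mass, vectorized over the longest argument.
#' @export
censored_normal_loglik <- function(y, mu, sigma, bounds = c(0, 1)) {
  stop_if_not(all(sigma > 0), "sigma must be positive")
  stop_if_not(length(bounds) == 2 && all(is.finite(bounds)) &&
                bounds[1] < bounds[2], "bounds must be finite with lo < hi")
  stop_if_not(all(y >= bounds[1] & y <= bounds[2]),
              "y outside the censoring bounds")
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  out <- stats::dnorm(y, mu, sigma, log = TRUE)
  at_lo <- y == bounds[1]
  at_hi <- y == bounds[2]
  out[at_lo] <- stats::pnorm(bounds[1], mu[at_lo], sigma[at_lo],
                             log.p = TRUE)
  out[at_hi] <- stats::pnorm(bounds[2], mu[at_hi], sigma[at_hi],
                             lower.tail = FALSE, log.p = TRUE)
  out
}
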