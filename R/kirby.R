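# Delay-discounting (27-item monetary choice questionnaire) scoring.
#
# Each item offers a smaller immediate reward (SIR) against a larger delayed
# reward (LDR) after a delay D. Under hyperbolic discounting V = A/(1 + kD),
# a respondent with discount rate k is indifferent on an item when
# k = (LDR/SIR - 1)/D; steeper discounters (larger k) take the immediate
# option on more items. Items split into three reward-magnitude bands
# (small/medium/large LDR) with nine items each.

.kirby_cache <- new.env(parent = emptyenv())

#' The 27-item monetary choice questionnaire item set
#'
#' Returns the standard published item table for the 27-item monetary choice
#' questionnaire: smaller immediate reward (`sir`), larger delayed reward
#' (`ldr`), delay in days and reward-magnitude band, with the implied
#' indifference discount rate `k = (ldr/sir - 1)/delay_days` appended.
#'
#' @return data.frame with columns `item`, `sir`, `ldr`, `delay_days`,
#'   `magnitude`, `k`.
#' @export
kirby_items <- function() {
  if (is.null(.kirby_cache$items)) {
    path <- system.file("extdata", "kirby_mcq_items.csv",
                        package = "adhereBayes", mustWork = TRUE)
    it <- utils::read.csv(path, stringsAsFactors = FALSE)
    it$k <- (it$ldr / it$sir - 1) / it$delay_days
    .kirby_cache$items <- it
  }
  .kirby_cache$items
}

# Candidate discount rates for one magnitude band: the geometric midpoints
# between consecutive item indifference rates, plus the two extreme item
# rates themselves as boundary candidates (assigned to fully patient /
# fully impatient responders).
kirby_candidates <- function(k_items) {
  ks <- sort(k_items)
  c(ks[1], sqrt(ks[-length(ks)] * ks[-1]), ks[length(ks)])
}

# Number of observed choices consistent with candidate rate k. A choice of
# the delayed reward is consistent when k < k_item (the delayed reward is
# subjectively worth more); an immediate choice is consistent when
# k > k_item; at exact indifference either choice is consistent.
kirby_consistency <- function(k, k_items, choices) {
  delayed <- choices == "delayed"
  immediate <- choices == "immediate"
  sum(delayed & k_items > k) + sum(immediate & k_items < k) +
    sum(k_items == k)
}

#' Score the 27-item monetary choice questionnaire
#'
#' Assigns each reward-magnitude band (small/medium/large) the candidate
#' discount rate maximising consistency with the observed choices. The
#' candidate grid consists of the geometric midpoints between the nine
#' items' implied indifference rates plus the two boundary rates; ties are
#' resolved by the geometric mean of the tied candidates. Bands with more
#' than `max_missing` missing choices are scored as missing.
#'
#' @param choices character vector of 27 responses, each `"immediate"`,
#'   `"delayed"` or `NA`, ordered by item number.
#' @param items item table as returned by [kirby_items()].
#' @param max_missing maximum tolerated fraction of missing choices within a
#'   band (default 0.20).
#' @return object of class `kirby_scores`: a list with per-band rates
#'   `k_small`, `k_medium`, `k_large`, per-band consistency proportions, and
#'   `log_k` (natural-log rates). The cohort-level composite (mean of
#'   z-scored log rates) is computed by [discount_composite()].
#' @examples
#' kirby_discount_rates(rep("delayed", 27))$k_small  # most patient bin
#' @export
kirby_discount_rates <- function(choices, items = kirby_items(),
                                 max_missing = 0.20) {
  stop_if_not(length(choices) == nrow(items),
              sprintf("expected %d choices, got %d", nrow(items),
                      length(choices)))
  choices <- as.character(choices)
  ok <- is.na(choices) | choices %in% c("immediate", "delayed")
  stop_if_not(all(ok), "choices must be 'immediate', 'delayed' or NA")

  out <- list()
  for (mag in c("small", "medium", "large")) {
    idx <- items$magnitude == mag
    ch <- choices[idx]
    ki <- items$k[idx]
    miss <- is.na(ch)
    if (mean(miss) > max_missing) {
      out[[paste0("k_", mag)]] <- NA_real_
      out[[paste0("consistency_", mag)]] <- NA_real_
      next
    }
    ch <- ch[!miss]
    ki_obs <- ki[!miss]
    cand <- kirby_candidates(ki)
    cons <- vapply(cand, kirby_consistency, numeric(1),
                   k_items = ki_obs, choices = ch)
    best <- cand[cons == max(cons)]
    out[[paste0("k_", mag)]] <- exp(mean(log(best)))
    out[[paste0("consistency_", mag)]] <- max(cons) / length(ch)
  }
  out$log_k <- log(c(small = out$k_small, medium = out$k_medium,
                     large = out$k_large))
  class(out) <- "kirby_scores"
  out
}

#' @export
print.kirby_scores <- function(x, ...) {
  cat("27-item monetary choice questionnaire scores\n")
  for (mag in c("small", "medium", "large")) {
    k <- x[[paste0("k_", mag)]]
    cons <- x[[paste0("consistency_", mag)]]
    cat(sprintf("  %-6s k = %-10.5g consistency = %s\n", mag,
                k, ifelse(is.na(cons), "NA", sprintf("%.2f", cons))))
  }
  invisible(x)
}

#' Cohort-wise delay-discounting composite
#'
#' The per-band discount rates are log-transformed, z-scored across the
#' cohort within band, and averaged over the bands available for each
#' person. All three bands missing yields a missing composite.
#'
#' @param k_small,k_medium,k_large numeric vectors of per-band discount
#'   rates, one entry per person.
#' @return numeric vector of composites.
#' @export
discount_composite <- function(k_small, k_medium, k_large) {
  zs <- cbind(zscore(log(k_small)), zscore(log(k_medium)),
              zscore(log(k_large)))
  out <- rowMeans(zs, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
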