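#' Score the changing-ion count
#'
#' 0 for no change, 1 for 1-4 changes (little), 2 for 5-19 changes
#' (intermediate), 3 for more than 19 changes (many). The condition with
#' the most changes supplies the count.
#'
#' @param count number of significantly changing ions (best condition).
#' @return integer score 0-3 (vectorised).
#' @export
scoreIons <- function(count) {
  stopifnot(all(count >= 0, na.rm = TRUE))
  ifelse(is.na(count), 0L,
         ifelse(count == 0, 0L,
                ifelse(count <= 4, 1L, ifelse(count <= 19, 2L, 3L))))
}

#' Score a p-value channel
#'
#' 0 for p > 1e-2, 1 for p < 1e-2, 2 for p < 1e-3 (strict comparisons: a
#' p exactly on a threshold falls to the weaker class). The most
#' significant p over all growth conditions is scored. A missing channel
#' (mutant absent from an analysis) scores 0.
#'
#' @param p best (smallest) p-value of the channel, or NA when missing.
#' @return integer score 0-2 (vectorised).
#' @export
scoreP <- function(p) {
  ifelse(is.na(p), 0L, ifelse(p < 1e-3, 2L, ifelse(p < 1e-2, 1L, 0L)))
}

#' Combine evidence channels into the functionality score
#'
#' Assembles, per mutant, the four evidence channels — maximal
#' changing-ion count over conditions (scored 0-3), best pathway
#' enrichment p, best mutant-pair correlation p and self-correlation p
#' (each scored 0-2) — sums them into the total 0-9 score and flags a
#' mutant functional at a total of 3 or higher.
#'
#' @param counts output of [callAndCount()].
#' @param enrichment output of [enrichmentAnalysis()] (may be NULL).
#' @param correlations output of [correlationAnalysis()] (may be NULL).
#' @return data.frame mutant, max_changing_ions, best_enrichment_p,
#'   best_pair_p, best_self_p, s_ions, s_enrich, s_pair, s_self, total,
#'   functional — sorted by decreasing total.
#' @export
scoreEvidence <- function(counts, enrichment = NULL,
                          correlations = NULL) {
  muts <- sort(unique(counts$mutant))
  maxCount <- vapply(muts, function(m)
    max(counts$n_changing[counts$mutant == m]), numeric(1))
  bestEnr <- rep(NA_real_, length(muts))
  if (!is.null(enrichment) && nrow(enrichment)) {
    for (i in seq_along(muts)) {
      pp <- enrichment$best_p[enrichment$mutant == muts[i]]
      if (length(pp)) bestEnr[i] <- min(pp, na.rm = TRUE)
    }
  }
  bestPair <- rep(NA_real_, length(muts))
  bestSelf <- rep(NA_real_, length(muts))
  if (!is.null(correlations)) {
    pr <- correlations$pairs
    for (i in seq_along(muts)) {
      pp <- pr$p[(pr$mutant_a == muts[i] | pr$mutant_b == muts[i]) &
                   !is.na(pr$p)]
      if (length(pp)) bestPair[i] <- min(pp)
      sp <- correlations$self$p[correlations$self$mutant == muts[i]]
      sp <- sp[!is.na(sp)]
      if (length(sp)) bestSelf[i] <- min(sp)
    }
  }
  out <- data.frame(
    mutant = muts,
    max_changing_ions = as.integer(maxCount),
    best_enrichment_p = bestEnr,
    best_pair_p = bestPair,
    best_self_p = bestSelf,
    s_ions = scoreIons(maxCount),
    s_enrich = scoreP(bestEnr),
    s_pair = scoreP(bestPair),
    s_self = scoreP(bestSelf))
  out$total <- out$s_ions + out$s_enrich + out$s_pair + out$s_self
  out$functional <- out$total >= 3L
  out <- out[order(-out$total, out$mutant), ]
  rownames(out) <- NULL
  out
}
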