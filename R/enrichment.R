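#' Rank relaxed-cutoff hits for enrichment
#'
#' Joins the lumped pathway entries with one mutant x condition slice of
#' the differential results and keeps entries passing the relaxed cutoff
#' (`p < relaxedP` and `|log2 FC| > relaxedL2fc`, a 10\% change), sorted by
#' descending absolute log2 fold change. Ties are broken by smaller
#' p-value, then lexically by entry id, so the ordering is deterministic.
#'
#' @param results one mutant x condition slice of [differentialAnalysis()]
#'   output (columns ion, median_log2fc, p).
#' @param entries lumped entries from [lumpPathwayEntries()].
#' @param relaxedP relaxed p-value cutoff (default 0.1).
#' @param relaxedL2fc relaxed absolute log2 fold-change cutoff
#'   (default 0.1375).
#' @return the hit entries, ordered, with columns of `entries` plus
#'   `median_log2fc` and `p`; zero rows when nothing passes.
#' @export
rankRelaxedHits <- function(results, entries, relaxedP = 0.1,
                            relaxedL2fc = 0.1375) {
  stats <- results[match(entries$ion, results$ion), ]
  ent <- cbind(entries, median_log2fc = stats$median_log2fc, p = stats$p)
  ent <- ent[is.finite(ent$median_log2fc) &
               ent$p < relaxedP & abs(ent$median_log2fc) > relaxedL2fc, ,
             drop = FALSE]
  ent[order(-abs(ent$median_log2fc), ent$p, ent$entry_id), , drop = FALSE]
}

#' One-sided hypergeometric over-representation tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` pathway members among `n` hits drawn without
#' replacement from a population of `N` entries containing `K` pathway
#' members.
#'
#' @param N population size.
#' @param K pathway members in the population.
#' @param n hit-subset size.
#' @param k pathway members among the hits.
#' @return the tail probability.
#' @examples
#' hypergeomTail(20, 5, 4, 3)  # 155/4845
#' @export
hypergeomTail <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || any(c(N, K, n, k) < 0))
    stop("require 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Iterative expanding-subset pathway enrichment
#'
#' Starting from the top-ranked hit alone, the hit subset is grown one
#' entry at a time down the sorted hit list; at every subset size a
#' hypergeometric over-representation test is run for each pathway, and
#' per pathway the most significant p-value over all subset sizes is
#' reported together with the size that achieved it.
#'
#' @param sortedHits ordered hit entries from [rankRelaxedHits()].
#' @param population all lumped entries detected in this mutant's
#'   condition (the sampling universe; must contain the hits).
#' @return data.frame pathway_id, best_p, best_subset_size,
#'   hits_in_pathway_at_best; pathways without members in the population
#'   are skipped, and with an empty hit list every pathway gets
#'   `best_p = 1`.
#' @export
iterativeEnrichment <- function(sortedHits, population) {
  N <- nrow(population)
  pws <- unique(population$pathway_id)
  pws <- pws[!is.na(pws)]
  if (!length(pws))
    return(data.frame(pathway_id = character(), best_p = numeric(),
                      best_subset_size = integer(),
                      hits_in_pathway_at_best = integer()))
  out <- data.frame(pathway_id = pws, best_p = 1,
                    best_subset_size = 0L, hits_in_pathway_at_best = 0L)
  nHits <- nrow(sortedHits)
  if (nHits == 0L || N == 0L) return(out)
  for (j in seq_along(pws)) {
    K <- sum(population$pathway_id == pws[j], na.rm = TRUE)
    if (K == 0L) next
    inPw <- cumsum(!is.na(sortedHits$pathway_id) &
                     sortedHits$pathway_id == pws[j])
    for (s in seq_len(nHits)) {
      p <- hypergeomTail(N, K, s, inPw[s])
      if (p < out$best_p[j]) {
        out$best_p[j] <- p
        out$best_subset_size[j] <- s
        out$hits_in_pathway_at_best[j] <- inPw[s]
      }
    }
  }
  out
}

#' Pathway enrichment across the screen
#'
#' Runs the relaxed-cutoff ranking and iterative hypergeometric enrichment
#' for every mutant x condition combination. The population for each test
#' is the set of lumped entries detected (annotated) in that condition —
#' enrichment is relative to what was measurable, not to the full pathway
#' database. No multiplicity correction is applied across pathways; the
#' reported `best_p` values are raw enrichment p-values.
#'
#' @param results full [differentialAnalysis()] output.
#' @param entries lumped entries from [lumpPathwayEntries()].
#' @param relaxedP,relaxedL2fc relaxed cutoffs (see [rankRelaxedHits()]).
#' @return data.frame mutant, condition, pathway_id, best_p,
#'   best_subset_size, hits_in_pathway_at_best.
#' @export
enrichmentAnalysis <- function(results, entries, relaxedP = 0.1,
                               relaxedL2fc = 0.1375) {
  combos <- unique(results[, c("mutant", "condition")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    slice <- results[results$mutant == combos$mutant[i] &
                       results$condition == combos$condition[i], ]
    pop <- entries[entries$ion %in% slice$ion, , drop = FALSE]
    hits <- rankRelaxedHits(slice, pop, relaxedP, relaxedL2fc)
    enr <- iterativeEnrichment(hits, pop)
    if (nrow(enr))
      out[[i]] <- cbind(mutant = combos$mutant[i],
                        condition = combos$condition[i], enr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
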