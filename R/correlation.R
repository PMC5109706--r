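#' Build per-condition fold-change profiles
#'
#' Reshapes differential results into one matrix per condition of median
#' log2 fold changes (ions x mutants), optionally restricted to the ions
#' annotated as deprotonated metabolites — the profiles the correlation
#' analyses operate on.
#'
#' @param results output of [differentialAnalysis()].
#' @param ions optional character vector of ion ids to keep (e.g. the
#'   annotated ions).
#' @return named list, one ions x mutants matrix per condition.
#' @export
foldChangeProfiles <- function(results, ions = NULL) {
  if (!is.null(ions)) results <- results[results$ion %in% ions, ]
  conds <- unique(results$condition)
  muts <- sort(unique(results$mutant))
  allIons <- sort(unique(results$ion))
  out <- lapply(conds, function(cond) {
    slice <- results[results$condition == cond, ]
    m <- matrix(NA_real_, length(allIons), length(muts),
                dimnames = list(allIons, muts))
    m[cbind(match(slice$ion, allIons), match(slice$mutant, muts))] <-
      slice$median_log2fc
    m
  })
  names(out) <- conds
  out
}

#' Pairwise Pearson correlations between mutant profiles
#'
#' Pearson correlation over the ions shared (finite in both) by each
#' mutant pair within one condition. Mutants with a zero-variance profile
#' get `NA` correlations with every partner and are flagged.
#'
#' @param profiles ions x mutants matrix of median log2 fold changes.
#' @param minShared minimum shared ions per pair (pairs below get `NA`).
#' @return list with `r` (symmetric mutants x mutants matrix, diagonal 1)
#'   and `degenerate` (logical per mutant, zero-variance profiles).
#' @export
profileCorrelations <- function(profiles, minShared = 3L) {
  degenerate <- apply(profiles, 2L, function(v) {
    v <- v[is.finite(v)]
    length(v) < 2L || var(v) == 0
  })
  r <- suppressWarnings(cor(profiles, use = "pairwise.complete.obs"))
  nShared <- crossprod(is.finite(profiles) * 1)
  r[nShared < minShared] <- NA_real_
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r) <- 1
  list(r = r, degenerate = degenerate)
}

#' Significance of one mutant pair's correlations
#'
#' Compares the pair's per-condition correlation coefficients against the
#' pooled coefficients of all remaining mutant pairs by a two-sided Welch
#' two-sample t-test; a pair is deemed significantly correlating at
#' `p < 0.01`.
#'
#' @param pairR the pair's coefficients (one per condition).
#' @param background coefficients of all other pairs, pooled across
#'   conditions.
#' @return the Welch p-value (1 when degenerate).
#' @export
pairSignificance <- function(pairR, background) {
  pairR <- pairR[is.finite(pairR)]
  background <- background[is.finite(background)]
  if (!length(background)) stop("background must be nonempty")
  if (length(pairR) < 2L || length(background) < 2L) return(1)
  welchTest(pairR, background)$p.value
}

#' Self-correlation of a mutant across conditions
#'
#' Pearson correlations of one mutant's profile between every unordered
#' pair of conditions (six coefficients for four conditions), over the
#' ions finite in both conditions.
#'
#' @param profile ions x conditions matrix of the mutant's median log2
#'   fold changes.
#' @param minShared minimum shared ions per condition pair.
#' @return data.frame condition_a, condition_b, r.
#' @export
selfCorrelations <- function(profile, minShared = 3L) {
  conds <- colnames(profile)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(profile)))
  if (ncol(profile) < 2L)
    return(data.frame(condition_a = character(),
                      condition_b = character(), r = numeric()))
  cp <- utils::combn(seq_len(ncol(profile)), 2L)
  r <- apply(cp, 2L, function(ix) {
    a <- profile[, ix[1]]; b <- profile[, ix[2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < minShared || var(a[ok]) == 0 || var(b[ok]) == 0)
      return(NA_real_)
    cor(a[ok], b[ok])
  })
  data.frame(condition_a = conds[cp[1, ]], condition_b = conds[cp[2, ]],
             r = r)
}

#' Significance of a mutant's self-correlation
#'
#' One-sample two-sided t-test of the condition-pair correlation
#' coefficients against a mean of zero. With fewer than two finite
#' coefficients no test is possible (`p = NA`, flagged). If the
#' coefficients are exactly tied the test degenerates and the exact
#' convention applies: p = 1 when the common value is 0 (no evidence),
#' p = 0 otherwise (deterministically nonzero).
#'
#' @param r numeric coefficients (six for four conditions).
#' @return list with `p.value`, `mean_r` and `flag` (character, "" when
#'   the test was regular).
#' @export
selfSignificance <- function(r) {
  r <- r[is.finite(r)]
  if (length(r) < 2L)
    return(list(p.value = NA_real_, mean_r = if (length(r)) mean(r)
                else NA_real_, flag = "insufficient"))
  if (var(r) == 0)
    return(list(p.value = if (mean(r) == 0) 1 else 0, mean_r = mean(r),
                flag = "degenerate"))
  tt <- t.test(r, mu = 0)
  list(p.value = tt$p.value, mean_r = mean(r), flag = "")
}

#' Mutant-pair and self correlation analysis
#'
#' Runs both correlation approaches over the screen: (i) for every
#' unordered mutant pair, the per-condition Pearson correlations of their
#' fold-change profiles, tested against the pooled coefficients of all
#' remaining pairs; (ii) for every mutant, the correlations of its own
#' profile between all condition pairs, tested against zero.
#'
#' @param results output of [differentialAnalysis()].
#' @param ions optional ion ids to restrict the profiles to (deprotonated
#'   annotated ions).
#' @param corrP significance threshold for both tests (default 0.01).
#' @return list with `pairs` (data.frame mutant_a, mutant_b, r_<cond>...,
#'   p, significant) and `self` (data.frame mutant, r_<pair>..., mean_r,
#'   p, significant).
#' @export
correlationAnalysis <- function(results, ions = NULL, corrP = 0.01) {
  empty <- list(
    pairs = data.frame(mutant_a = character(), mutant_b = character(),
                       p = numeric(), significant = logical()),
    self = data.frame(mutant = character(), mean_r = numeric(),
                      p = numeric(), flag = character(),
                      significant = logical()))
  if (!is.null(ions) && length(ions) == 0L) return(empty)
  profiles <- foldChangeProfiles(results, ions)
  if (!length(profiles) || !nrow(profiles[[1]])) return(empty)
  conds <- names(profiles)
  muts <- colnames(profiles[[1]])
  rByCond <- lapply(profiles, function(pr) profileCorrelations(pr)$r)

  pairsIx <- utils::combn(seq_along(muts), 2L)
  nPairs <- ncol(pairsIx)
  rMat <- matrix(NA_real_, nPairs, length(conds),
                 dimnames = list(NULL, conds))
  for (ci in seq_along(conds))
    rMat[, ci] <- rByCond[[ci]][t(pairsIx)]
  pairs <- data.frame(mutant_a = muts[pairsIx[1, ]],
                      mutant_b = muts[pairsIx[2, ]])
  colnames(rMat) <- paste0("r_", conds)
  pairs <- cbind(pairs, rMat)
  pairs$p <- NA_real_
  for (i in seq_len(nPairs)) {
    bg <- as.numeric(rMat[-i, ])
    ri <- as.numeric(rMat[i, ])
    if (sum(is.finite(ri)) >= 2L && sum(is.finite(bg)) >= 2L)
      pairs$p[i] <- pairSignificance(ri, bg)
  }
  pairs$significant <- !is.na(pairs$p) & pairs$p < corrP

  selfRows <- lapply(muts, function(m) {
    prof <- vapply(conds, function(cond) profiles[[cond]][, m],
                   numeric(nrow(profiles[[1]])))
    sc <- selfCorrelations(prof)
    sig <- selfSignificance(sc$r)
    row <- data.frame(mutant = m)
    if (nrow(sc)) {
      rr <- setNames(as.list(sc$r),
                     paste0("r_", sc$condition_a, ".", sc$condition_b))
      row <- cbind(row, rr)
    }
    row$mean_r <- sig$mean_r
    row$p <- sig$p.value
    row$flag <- sig$flag
    row
  })
  self <- do.call(rbind, selfRows)
  self$significant <- !is.na(self$p) & self$p < corrP
  list(pairs = pairs, self = self)
}
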