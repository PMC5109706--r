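#' Remove fold-change outliers
#'
#' One-pass removal of values deviating more than two sample standard
#' deviations (denominator n-1) from the mean. With fewer than three
#' values, or a zero SD, nothing is removed. An algebraic consequence of
#' the sample SD is that no value can be removed for n <= 5 (the maximal
#' standardised deviation is (n-1)/sqrt(n) < 2).
#'
#' @param x numeric, pooled fold changes of one mutant for one ion.
#' @param nSd deviation threshold in sample SDs (default 2).
#' @return the retained values.
#' @examples
#' pruneOutliers(c(1, 1, 1, 1, 1, 7))  # drops the 7
#' @export
pruneOutliers <- function(x, nSd = 2) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) {
    warning("fewer than 3 values: returned unpruned")
    return(x)
  }
  s <- sd(x)
  if (s == 0) return(x)
  x[abs(x - mean(x)) <= nSd * s]
}

#' Median log2 fold change
#'
#' @param fc numeric fold changes (linear scale, positive).
#' @return median of `log2(fc)`.
#' @export
medianLog2FC <- function(fc) {
  fc <- fc[is.finite(fc)]
  if (!length(fc)) stop("no fold changes to summarise")
  if (any(fc <= 0)) stop("fold changes must be positive")
  median(log2(fc))
}

#' Two-sided Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom. When the
#' pooled variance degenerates to zero the p-value is set to 1 and the
#' result flagged.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with `statistic`, `df`, `p.value` and `degenerate`.
#' @export
welchTest <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need at least 2 finite values")
  if (var(x) == 0 && var(y) == 0)
    return(list(statistic = 0, df = NA_real_, p.value = 1,
                degenerate = TRUE))
  tt <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, degenerate = FALSE)
}

# Vectorised Welch test over the rows of two matrices (NA-tolerant).
# Returns a data.frame with columns m1, n1, t, df, p.
.welchRows <- function(G, B) {
  n1 <- rowSums(is.finite(G))
  n2 <- rowSums(is.finite(B))
  m1 <- rowMeans(G, na.rm = TRUE)
  m2 <- rowMeans(B, na.rm = TRUE)
  v1 <- rowSums((G - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((B - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(t), df)
  bad <- !is.finite(t) | n1 < 2 | n2 < 2 | se2 == 0
  p[bad] <- 1
  t[bad] <- 0
  data.frame(m1 = m1, n1 = n1, t = t, df = df, p = p)
}

#' Storey q-values
#'
#' False-discovery-rate adjusted p-values with the null proportion
#' estimated by the smoother method: `pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda))` on the grid `lambda = 0.05, 0.10, ..., 0.95`, smoothed
#' with a df-3 cubic smoothing spline and evaluated at the largest lambda
#' (clipped into (0, 1]). With `pi0 = 1` the q-values coincide with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric p-values in [0, 1].
#' @param lambda grid for the pi0 smoother.
#' @param pi0 optionally fix the null proportion instead of estimating it.
#' @return numeric q-values, monotone in p.
#' @export
storeyQ <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch({
      fit <- smooth.spline(lambda, pi0l, df = 3)
      predict(fit, x = max(lambda))$y
    }, error = function(e) min(pi0l[length(pi0l)], 1))
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    pi0 <- min(pi0, 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(p[o] * m / (m:1)))[ro]
  pmin(q, 1)
}

#' Empirical wild-type fold-change cutoff
#'
#' Pools the absolute log2 fold changes of all wild-type ions and returns
#' their 97.5\% empirical quantile — the data-driven counterpart of the
#' fixed calling cutoff (0.3785, a 30\% change), which is reported
#' alongside it.
#'
#' @param wtLog2fc numeric, wild-type log2 fold changes (all ions pooled).
#' @param prob quantile level (default 0.975).
#' @param fixedCutoff the fixed calling cutoff reported alongside.
#' @return list with `wt_quantile`, `prob` and `fixed_cutoff`.
#' @export
deriveWTCutoff <- function(wtLog2fc, prob = 0.975, fixedCutoff = 0.3785) {
  wtLog2fc <- wtLog2fc[is.finite(wtLog2fc)]
  if (!length(wtLog2fc)) stop("no wild-type log2 fold changes supplied")
  list(wt_quantile = unname(quantile(abs(wtLog2fc), prob)),
       prob = prob, fixed_cutoff = fixedCutoff)
}

#' Differential ion analysis
#'
#' For every mutant, condition and ion: pools the mutant's replicate log2
#' fold changes, prunes outliers beyond two SDs, takes the median log2 fold
#' change, and assigns a p-value by a two-sided Welch t-test of the
#' mutant's (pruned) log2 fold changes against those of all other samples
#' of the same condition and batch (wild type included). P-values are
#' Storey-corrected within families given by `qFamily`: by default each
#' mutant x condition ion profile is its own correction family — the
#' family whose multiplicity the per-mutant ion calls actually face;
#' per-condition or global families are available for sensitivity
#' analyses. An ion changes significantly when `q < qCut` and
#' `|median log2 FC| > l2fcCut` (both strict).
#'
#' @param mset a \linkS4class{MetaboSet} with assay `"log2fc"` (see
#'   [computeFoldChanges()]).
#' @param qCut q-value cutoff (default 1e-3).
#' @param l2fcCut absolute median log2 fold-change cutoff (default 0.3785,
#'   a 30\% change).
#' @param mutants mutants to test (default: all non-WT mutants present).
#' @param qFamily Storey correction family: `"mutant_condition"` (default),
#'   `"condition_batch"` or `"global"`.
#' @return data.frame with columns mutant, condition, batch, ion, ion_mz,
#'   median_log2fc, n_used, p, q, significant.
#' @export
differentialAnalysis <- function(mset, qCut = 1e-3, l2fcCut = 0.3785,
                                 mutants = NULL,
                                 qFamily = c("mutant_condition",
                                             "condition_batch",
                                             "global")) {
  qFamily <- match.arg(qFamily)
  stopifnot(is(mset, "MetaboSet"))
  if (!"log2fc" %in% assayNames(mset))
    stop("run computeFoldChanges() first: assay 'log2fc' missing")
  l2 <- assay(mset, "log2fc")
  cd <- colData(mset)
  if (is.null(mutants)) mutants <- setdiff(unique(cd$mutant), "WT")
  mz <- rowData(mset)$mz
  res <- list()
  for (b in unique(cd$batch)) {
    for (cond in unique(cd$condition)) {
      inGrp <- cd$batch == b & cd$condition == cond
      if (!any(inGrp)) next
      grpMut <- intersect(mutants, unique(cd$mutant[inGrp]))
      blocks <- list()
      for (m in grpMut) {
        gIdx <- which(inGrp & cd$mutant == m)
        bIdx <- which(inGrp & cd$mutant != m)
        if (length(gIdx) < 2L || length(bIdx) < 2L) next
        G <- l2[, gIdx, drop = FALSE]
        # one-pass 2-SD pruning per ion, on the log2 scale
        mu <- rowMeans(G, na.rm = TRUE)
        s <- sqrt(rowSums((G - mu)^2, na.rm = TRUE) /
                    pmax(rowSums(is.finite(G)) - 1, 1))
        prune <- abs(G - mu) > 2 * s
        prune[is.na(prune)] <- FALSE
        prune[s == 0 | rowSums(is.finite(G)) < 3, ] <- FALSE
        Gp <- G
        Gp[prune] <- NA_real_
        med <- apply(Gp, 1L, median, na.rm = TRUE)
        wt <- .welchRows(Gp, l2[, bIdx, drop = FALSE])
        blocks[[m]] <- data.frame(
          mutant = m, condition = cond, batch = b,
          ion = rownames(l2), ion_mz = mz,
          median_log2fc = med, n_used = wt$n1, p = wt$p)
      }
      if (!length(blocks)) next
      res[[paste(b, cond)]] <- do.call(rbind, blocks)
    }
  }
  out <- do.call(rbind, res)
  fam <- switch(qFamily,
                mutant_condition = interaction(out$mutant, out$condition,
                                               out$batch, drop = TRUE),
                condition_batch = interaction(out$condition, out$batch,
                                              drop = TRUE),
                global = factor(rep(1L, nrow(out))))
  out$q <- NA_real_
  ok <- is.finite(out$median_log2fc)
  for (f in levels(fam)) {
    sel <- fam == f & ok
    if (any(sel)) out$q[sel] <- storeyQ(out$p[sel])
  }
  out$significant <- ok & out$q < qCut &
    abs(out$median_log2fc) > l2fcCut
  rownames(out) <- NULL
  out
}

#' Count significantly changing ions
#'
#' Tallies, per mutant and condition, the ions passing both the q-value
#' and fold-change thresholds, and assigns the descriptive class used for
#' scoring: none (0), little (1-4), intermediate (5-19) or many (>19).
#'
#' @param results output of [differentialAnalysis()].
#' @return data.frame mutant, condition, n_changing, class.
#' @export
callAndCount <- function(results) {
  agg <- aggregate(significant ~ mutant + condition, data = results,
                   FUN = function(z) sum(z, na.rm = TRUE))
  names(agg)[3] <- "n_changing"
  agg$class <- cut(agg$n_changing, c(-Inf, 0, 4, 19, Inf),
                   labels = c("none", "little", "intermediate", "many"))
  agg[order(agg$mutant, agg$condition), ]
}
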