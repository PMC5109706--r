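#' Fit the exponential growth rate of one well
#'
#' Linear fit to the log-transformed OD curve over the best exponential
#' window: points near the curve's maximum (the stationary plateau) and
#' below the detection floor are set aside, every remaining contiguous
#' window of at least `minPoints` points is scored by the R-squared of
#' the log-linear regression, and the longest window within `r2Slack` of
#' the best R-squared supplies the slope — averaging over the whole
#' exponential phase rather than a lucky short stretch. On noise-free
#' curves the selected window is perfectly log-linear and the fit is
#' exact. The fitted rate is invariant to rescaling the OD series by a
#' positive constant.
#'
#' @param time numeric, hours.
#' @param od numeric OD595 series.
#' @param minPoints minimal window length (default 5).
#' @param floor detection floor; points at or below it are ignored.
#' @param r2Floor the well is flagged non-growing when no window reaches
#'   this R-squared.
#' @param r2Slack windows within this R-squared slack of the best
#'   compete on length (default 1e-3).
#' @param capFrac points at or above this fraction of the maximal OD are
#'   treated as stationary and excluded from the window search.
#' @return list with `mu` (h^-1, NA when non-growing), `r2`, `window`
#'   (index range used) and `growing`.
#' @export
fitGrowthRate <- function(time, od, minPoints = 5L, floor = 0.01,
                          r2Floor = 0.9, r2Slack = 1e-3,
                          capFrac = 0.98) {
  keep <- which(is.finite(od) & od > floor & od < capFrac * max(od,
                                                                na.rm = TRUE))
  if (length(keep) < minPoints)
    return(list(mu = NA_real_, r2 = NA_real_, window = c(NA, NA),
                growing = FALSE))
  t <- time[keep]
  y <- log(od[keep])
  n <- length(t)
  # cumulative sums give O(1) slope/residual/R2 per window
  ct <- cumsum(t); ct2 <- cumsum(t^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(t * y)
  winSum <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  cand <- list()
  for (i in seq_len(n - minPoints + 1L)) {
    for (j in seq(i + minPoints - 1L, n)) {
      m <- j - i + 1L
      st <- winSum(ct, i, j); st2 <- winSum(ct2, i, j)
      sy <- winSum(cy, i, j); sy2 <- winSum(cy2, i, j)
      sty <- winSum(cty, i, j)
      sxx <- st2 - st^2 / m
      syy <- sy2 - sy^2 / m
      sxy <- sty - st * sy / m
      if (sxx <= 0) next
      slope <- sxy / sxx
      r2 <- if (syy <= 0) 0 else (sxy^2) / (sxx * syy)
      cand[[length(cand) + 1L]] <- c(r2 = r2, slope = slope, i = i,
                                     j = j, len = m)
    }
  }
  if (!length(cand))
    return(list(mu = NA_real_, r2 = NA_real_, window = c(NA, NA),
                growing = FALSE))
  cm <- do.call(rbind, cand)
  top <- max(cm[, "r2"])
  sel <- cm[cm[, "r2"] >= top - r2Slack & cm[, "slope"] > 0, ,
            drop = FALSE]
  if (top < r2Floor || nrow(sel) == 0L)
    return(list(mu = NA_real_, r2 = top, window = c(NA, NA),
                growing = FALSE))
  sel <- sel[order(-sel[, "len"], sel[, "i"]), , drop = FALSE]
  list(mu = unname(sel[1, "slope"]), r2 = unname(sel[1, "r2"]),
       window = keep[unname(sel[1, c("i", "j")])], growing = TRUE)
}

#' Maximum cell density at plateau entry
#'
#' Locates the entry into stationary phase as the first time, after the
#' point of fastest growth, at which the rolling OD slope falls below
#' `slopeFrac` of its peak; the maximal density is the mean OD from there
#' to the end of the curve. Without a detectable plateau the last observed
#' OD is returned and flagged.
#'
#' @param time numeric, hours.
#' @param od numeric OD595 series.
#' @param slopeFrac fraction of the peak rolling slope below which the
#'   curve counts as stationary.
#' @param halfWindow half-width (points) of the rolling slope window.
#' @return list with `max_density`, `t_entry` (h, NA without plateau) and
#'   `plateau` (logical).
#' @export
maxDensity <- function(time, od, slopeFrac = 0.05, halfWindow = 2L) {
  n <- length(od)
  stopifnot(length(time) == n, n >= 2 * halfWindow + 2L)
  slope <- rep(NA_real_, n)
  for (i in seq(halfWindow + 1L, n - halfWindow)) {
    ix <- (i - halfWindow):(i + halfWindow)
    slope[i] <- stats::coef(stats::lm.fit(cbind(1, time[ix]),
                                          od[ix]))[2]
  }
  pk <- which.max(slope)
  thr <- slopeFrac * slope[pk]
  post <- which(seq_len(n) > pk & slope < thr)
  if (!length(post))
    return(list(max_density = od[n], t_entry = NA_real_,
                plateau = FALSE))
  entry <- post[1]
  list(max_density = mean(od[entry:n]), t_entry = time[entry],
       plateau = TRUE)
}

#' Quantify growth traits for every well
#'
#' Fits the growth rate and maximal density per well and attaches the well
#' annotation. Heuristic quality flags replace manual curation: wells are
#' flagged `lag` when their time to doubling of the initial OD exceeds the
#' wild-type median (same condition) by more than 50\%, and `shape` when
#' the residual standard deviation of the log-linear fit inside the fitted
#' window exceeds `shapeTol`.
#'
#' @param growth list with `data` (well, time_h, od595) and `wells`
#'   (well, mutant, condition, replicate), as from [simulateGrowth()].
#' @param shapeTol residual SD (log OD) above which a well is flagged.
#' @param ... passed to [fitGrowthRate()].
#' @return data.frame well, mutant, condition, replicate, mu, r2,
#'   max_density, plateau, growing, t_double, lag_flag, shape_flag.
#' @export
growthTraits <- function(growth, shapeTol = 0.05, ...) {
  wells <- growth$wells
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    d <- growth$data[growth$data$well == wells$well[i], ]
    d <- d[order(d$time_h), ]
    fit <- fitGrowthRate(d$time_h, d$od595, ...)
    md <- maxDensity(d$time_h, d$od595)
    od0 <- d$od595[1]
    tDouble <- if (any(d$od595 >= 2 * od0))
      d$time_h[which(d$od595 >= 2 * od0)[1]] else NA_real_
    resid <- NA_real_
    if (fit$growing) {
      ix <- fit$window[1]:fit$window[2]
      ly <- log(d$od595[ix])
      co <- stats::coef(stats::lm.fit(cbind(1, d$time_h[ix]), ly))
      resid <- sd(ly - (co[1] + co[2] * d$time_h[ix]))
    }
    data.frame(well = wells$well[i], mutant = wells$mutant[i],
               condition = wells$condition[i],
               replicate = wells$replicate[i],
               mu = fit$mu, r2 = fit$r2, max_density = md$max_density,
               plateau = md$plateau, growing = fit$growing,
               t_double = tDouble, resid_sd = resid)
  })
  tr <- do.call(rbind, rows)
  tr$shape_flag <- !is.na(tr$resid_sd) & tr$resid_sd > shapeTol
  tr$lag_flag <- FALSE
  for (cond in unique(tr$condition)) {
    wtMed <- median(tr$t_double[tr$condition == cond &
                                  tr$mutant == "WT"], na.rm = TRUE)
    sel <- tr$condition == cond
    tr$lag_flag[sel] <- !is.na(tr$t_double[sel]) &
      tr$t_double[sel] > 1.5 * wtMed
  }
  tr
}

# Codified outlier-well rule: drop non-growing wells and wells whose mu
# deviates > 3 SD from their mutant x condition group.
.pruneWells <- function(traits) {
  tr <- traits[traits$growing & is.finite(traits$mu), ]
  keep <- rep(TRUE, nrow(tr))
  grp <- interaction(tr$mutant, tr$condition, drop = TRUE)
  for (g in levels(grp)) {
    ix <- which(grp == g)
    if (length(ix) < 3L) next
    s <- sd(tr$mu[ix])
    if (s == 0) next
    keep[ix] <- abs(tr$mu[ix] - mean(tr$mu[ix])) <= 3 * s
  }
  tr[keep, ]
}

#' Compare mutant growth traits to wild type
#'
#' Per mutant, condition and trait (growth rate, maximal density): Welch
#' two-sided t-test of the mutant's replicate values against the
#' wild-type's, Storey correction across all mutant x condition x trait
#' tests, and a call requiring both a relative difference of at least
#' `minDiff` (10\%) in group means and `q < qCut`. Outlier wells are
#' removed first by the codified rule (non-growing wells; wells whose
#' growth rate deviates more than 3 SD from their group).
#'
#' @param traits output of [growthTraits()].
#' @param minDiff minimal relative difference to wild type (default 0.10).
#' @param qCut q-value cutoff (default 1e-3).
#' @return data.frame mutant, condition, mu, mu_wt, rel_diff_mu, p_mu,
#'   q_mu, sig_mu, max_density, density_wt, rel_diff_density, p_density,
#'   q_density, sig_density.
#' @export
compareGrowthToWT <- function(traits, minDiff = 0.10, qCut = 1e-3) {
  tr <- .pruneWells(traits)
  combos <- unique(tr[tr$mutant != "WT", c("mutant", "condition")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    m <- combos$mutant[i]; cond <- combos$condition[i]
    mm <- tr[tr$mutant == m & tr$condition == cond, ]
    wt <- tr[tr$mutant == "WT" & tr$condition == cond, ]
    if (nrow(mm) < 2L || nrow(wt) < 2L) next
    pMu <- welchTest(mm$mu, wt$mu)$p.value
    pCd <- welchTest(mm$max_density, wt$max_density)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      mutant = m, condition = cond,
      mu = mean(mm$mu), mu_wt = mean(wt$mu),
      rel_diff_mu = abs(mean(mm$mu) - mean(wt$mu)) / mean(wt$mu),
      p_mu = pMu,
      max_density = mean(mm$max_density),
      density_wt = mean(wt$max_density),
      rel_diff_density = abs(mean(mm$max_density) -
                               mean(wt$max_density)) /
        mean(wt$max_density),
      p_density = pCd)
  }
  out <- do.call(rbind, rows)
  qall <- storeyQ(c(out$p_mu, out$p_density))
  out$q_mu <- qall[seq_len(nrow(out))]
  out$q_density <- qall[nrow(out) + seq_len(nrow(out))]
  out$sig_mu <- out$rel_diff_mu >= minDiff & out$q_mu < qCut
  out$sig_density <- out$rel_diff_density >= minDiff &
    out$q_density < qCut
  rownames(out) <- NULL
  out
}

#' Growth phenotype analysis
#'
#' Convenience wrapper: well-level trait fitting, outlier pruning and
#' mutant-vs-wild-type significance calls.
#'
#' @param growth list with `data` and `wells` (see [growthTraits()]).
#' @param minDiff,qCut see [compareGrowthToWT()].
#' @param ... passed to [growthTraits()].
#' @return list with `traits` (per well) and `tests` (per mutant x
#'   condition).
#' @export
growthAnalysis <- function(growth, minDiff = 0.10, qCut = 1e-3, ...) {
  traits <- growthTraits(growth, ...)
  list(traits = traits, tests = compareGrowthToWT(traits, minDiff, qCut))
}
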