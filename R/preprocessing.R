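# Robust LOWESS fit of y vs x returning fitted values in the original
# sample order. stats::lowess sorts x internally; run order / ODs are made
# unique by rank so ties cannot scramble the mapping back.
.lowessFit <- function(x, y, f, iter) {
  o <- order(x)
  fit <- lowess(x[o], y[o], f = f, iter = iter)
  out <- numeric(length(x))
  out[o] <- fit$y
  out
}

#' Correct run-order signal drift
#'
#' Fits, per ion and measurement batch, a LOWESS trend over run order and
#' divides it out, rescaling so the ion's batch mean is preserved (drift
#' in flow-injection MS is multiplicative). Because intensities also vary
#' strongly with extraction OD, and samples of different OD are scattered
#' along the run, the trend is by default estimated on OD-detrended
#' residuals (the intensity divided by a preliminary robust LOWESS fit of
#' intensity vs OD): otherwise the OD-driven scatter leaks into the drift
#' estimate as spurious wiggle. The raw intensities are then divided by
#' the run-order trend alone, so the OD dependence is preserved for the
#' downstream OD-wise reference. Drift-free input passes through
#' unchanged up to numerical tolerance.
#'
#' @param mset a \linkS4class{MetaboSet}.
#' @param span LOWESS span (fraction of points) for the drift trend.
#' @param iter robustness iterations.
#' @param odAdjust estimate the trend on OD-detrended residuals
#'   (default TRUE).
#' @param odSpan LOWESS span for the preliminary OD fit.
#' @param minSamples batches with fewer samples are left uncorrected with
#'   a warning.
#' @return the MetaboSet with an added assay `"corrected"`.
#' @export
correctDrift <- function(mset, span = 0.3, iter = 3L, odAdjust = TRUE,
                         odSpan = 0.5, minSamples = 5L) {
  stopifnot(is(mset, "MetaboSet"))
  ints <- intensities(mset)
  corrected <- ints
  batches <- colData(mset)$batch
  for (b in unique(batches)) {
    idx <- which(batches == b)
    if (length(idx) < minSamples) {
      warning(sprintf(
        "batch %s has %d (< %d) samples: drift correction skipped",
        b, length(idx), minSamples))
      next
    }
    ro <- colData(mset)$run_order[idx]
    od <- colData(mset)$od595[idx]
    for (i in seq_len(nrow(ints))) {
      y <- ints[i, idx]
      z <- y
      if (odAdjust) {
        odFit <- .lowessFit(od, y, f = odSpan, iter = iter)
        if (all(odFit > 0)) z <- y / odFit
      }
      trend <- .lowessFit(ro, z, f = span, iter = iter)
      if (any(trend <= 0)) next  # pathological trend: leave ion untouched
      trend <- trend / mean(trend)
      out <- y / trend
      corrected[i, idx] <- out * mean(y) / mean(out)
    }
  }
  assay(mset, "corrected") <- corrected
  mset
}

#' Restrict samples to an extraction-OD window
#'
#' Keeps samples whose extraction OD595 lies inside the closed window
#' `[lo, hi]`; both boundaries are inclusive.
#'
#' @param mset a \linkS4class{MetaboSet}.
#' @param window numeric length-2, `c(lo, hi)` with `lo < hi`.
#' @return the column-subset MetaboSet.
#' @export
filterODWindow <- function(mset, window = c(0.6, 1.7)) {
  stopifnot(is(mset, "MetaboSet"))
  if (length(window) != 2L || !(window[1] < window[2]))
    stop("window must be c(lo, hi) with lo < hi")
  od <- colData(mset)$od595
  keep <- od >= window[1] & od <= window[2]
  if (!any(keep))
    stop(sprintf("no samples inside the OD window [%g, %g]",
                 window[1], window[2]))
  mset[, keep]
}

# Pick the assay fold-change computations should run on.
.workingAssay <- function(mset) {
  if ("corrected" %in% assayNames(mset)) assay(mset, "corrected")
  else intensities(mset)
}

.referenceGrid <- function(ods) sort(unique(ods))

# Fit one set of per-ion robust LOWESS reference curves on a fixed OD
# grid; the local-linear fit reproduces an exactly linear OD response
# without bias.
.fitRefMatrix <- function(ints, ods, grid, span, iter) {
  vals <- matrix(NA_real_, nrow(ints), length(grid),
                 dimnames = list(rownames(ints), NULL))
  o <- order(ods)
  for (i in seq_len(nrow(ints))) {
    fit <- .lowessFit(ods, ints[i, ], f = span, iter = iter)
    vals[i, ] <- approx(ods[o], fit[o], xout = grid, rule = 2,
                        ties = "ordered")$y
  }
  vals
}

#' Fit per-ion OD-wise reference curves
#'
#' For each ion, fits a robust LOWESS curve of (drift-corrected) intensity
#' against extraction OD over \emph{all} samples — mutants and wild type
#' together — so the curve covers the whole OD window and individual strong
#' metabolic changes are downweighted by the robustness iterations. The
#' curve is tabulated on the sorted unique sample ODs; [evalReference()]
#' interpolates linearly in between and extrapolates as a constant.
#'
#' @param mset a \linkS4class{MetaboSet} (assay `"corrected"` is used when
#'   present, otherwise `"intensity"`).
#' @param span LOWESS span for the reference fit.
#' @param iter robustness iterations (robust mode).
#' @param minSamples below this number the fit falls back to a constant
#'   per-ion global median curve, with a warning.
#' @return a \linkS4class{ReferenceCurveSet}.
#' @export
fitReferenceCurve <- function(mset, span = 0.5, iter = 3L,
                              minSamples = 10L) {
  stopifnot(is(mset, "MetaboSet"))
  ints <- .workingAssay(mset)
  ods <- colData(mset)$od595
  grid <- .referenceGrid(ods)
  if (ncol(ints) < minSamples) {
    warning(sprintf(
      "only %d samples (< %d): reference falls back to global medians",
      ncol(ints), minSamples))
    med <- apply(ints, 1L, median)
    vals <- matrix(med, nrow(ints), length(grid),
                   dimnames = list(rownames(ints), NULL))
  } else {
    vals <- .fitRefMatrix(ints, ods, grid, span, iter)
  }
  new("ReferenceCurveSet", od = grid, values = vals, method = "plain",
      nSamples = ncol(ints), nPermutations = 0L)
}

#' Fit a replicate-balanced reference curve
#'
#' For measurement batches dominated by an over-replicated mutant, the
#' plain all-samples reference would be pulled towards that mutant's
#' metabolic state. This variant repeatedly subsamples `kKeep` samples of
#' each dominant mutant (keeping all other samples), fits a reference curve
#' per draw, and returns the pointwise median curve over `nPerm` draws.
#' With `kKeep` equal to the full replicate count every draw uses all
#' samples and the result reproduces the plain reference exactly.
#'
#' @param mset a \linkS4class{MetaboSet} (one measurement batch).
#' @param dominantMutants character, the over-replicated mutant labels.
#' @param kKeep samples to keep per dominant mutant per draw.
#' @param nPerm number of random draws (the study design used 1000).
#' @param span,iter LOWESS parameters, as in [fitReferenceCurve()].
#' @param seed integer master seed; each draw uses a derived child seed so
#'   the median curve is reproducible.
#' @return a \linkS4class{ReferenceCurveSet} with method `"balanced"`.
#' @export
fitReferenceCurveBalanced <- function(mset, dominantMutants, kKeep = 3L,
                                      nPerm = 1000L, span = 0.5,
                                      iter = 3L, seed = 1L) {
  stopifnot(is(mset, "MetaboSet"), nPerm >= 1L, kKeep >= 1L)
  mut <- colData(mset)$mutant
  domIdx <- lapply(dominantMutants, function(m) which(mut == m))
  names(domIdx) <- dominantMutants
  for (m in dominantMutants)
    if (length(domIdx[[m]]) < kKeep)
      stop(sprintf("mutant %s has %d samples, fewer than kKeep = %d",
                   m, length(domIdx[[m]]), kKeep))
  ints <- .workingAssay(mset)
  ods <- colData(mset)$od595
  grid <- .referenceGrid(ods)
  keepAlways <- setdiff(seq_len(ncol(ints)), unlist(domIdx))
  permSeeds <- deriveSeeds(seed, nPerm)
  curves <- array(NA_real_, c(nrow(ints), length(grid), nPerm))
  for (p in seq_len(nPerm)) {
    keep <- withSeed(permSeeds[p], {
      drawn <- unlist(lapply(domIdx, function(ix)
        if (length(ix) == kKeep) ix else sample(ix, kKeep)))
      sort(c(keepAlways, drawn))
    })
    curves[, , p] <- .fitRefMatrix(ints[, keep, drop = FALSE], ods[keep],
                                   grid, span, iter)
  }
  vals <- apply(curves, c(1, 2), median)
  dimnames(vals) <- list(rownames(ints), NULL)
  new("ReferenceCurveSet", od = grid, values = vals, method = "balanced",
      nSamples = ncol(ints), nPermutations = as.integer(nPerm))
}

#' Compute OD-wise fold changes
#'
#' For every sample and ion, the fold change is the (drift-corrected)
#' intensity divided by the ion's reference-curve value at that sample's
#' extraction OD; `log2fc = log2(fc)`. Ions whose reference curve is not
#' strictly positive at some sample OD are flagged in
#' `rowData(mset)$fc_ok` and their fold changes set to `NA`.
#'
#' @param mset a \linkS4class{MetaboSet}.
#' @param reference a \linkS4class{ReferenceCurveSet} for the same ions.
#' @return the MetaboSet with added assays `"fc"` and `"log2fc"`.
#' @export
computeFoldChanges <- function(mset, reference) {
  stopifnot(is(mset, "MetaboSet"), is(reference, "ReferenceCurveSet"),
            nrow(mset) == nrow(reference@values))
  ints <- .workingAssay(mset)
  refAt <- evalReference(reference, colData(mset)$od595)
  ok <- apply(refAt > 0, 1L, all)
  fc <- ints / refAt
  fc[!ok, ] <- NA_real_
  rowData(mset)$fc_ok <- ok
  assay(mset, "fc") <- fc
  assay(mset, "log2fc") <- log2(fc)
  mset
}
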