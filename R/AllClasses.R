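#' MetaboSet: container for an untargeted metabolomics screen
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are measured ions
#' (rowData carries `mz`, the measured m/z in Da), columns are extracted
#' samples. The sample manifest lives in `colData` with the columns
#' `mutant`, `condition`, `bio_replicate`, `day_replicate`, `batch`,
#' `run_order` and `od595`. The raw intensities are in assay `"intensity"`;
#' processing steps add assays `"corrected"`, `"fc"` and `"log2fc"`.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

MANIFEST_COLS <- c("mutant", "condition", "bio_replicate", "day_replicate",
                   "batch", "run_order", "od595")

setValidity("MetaboSet", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  miss <- setdiff(MANIFEST_COLS, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing manifest columns: ",
                         paste(miss, collapse = ", ")))
  if (!"mz" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'mz' is required")
  else if (any(!is.finite(rowData(object)$mz)) ||
           any(rowData(object)$mz <= 0))
    msg <- c(msg, "ion m/z values must be finite and positive")
  if ("od595" %in% colnames(colData(object)) &&
      any(!is.finite(colData(object)$od595)))
    msg <- c(msg, "od595 must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboSet
#'
#' @param intensity numeric matrix, ions x samples, strictly positive.
#' @param manifest data.frame with one row per sample and the columns
#'   `sample_id`, `mutant`, `condition`, `bio_replicate`, `day_replicate`,
#'   `batch`, `run_order`, `od595`.
#' @param mz numeric vector of ion m/z values, one per row of `intensity`.
#' @return a \linkS4class{MetaboSet}.
#' @examples
#' man <- data.frame(sample_id = c("s1", "s2"), mutant = c("WT", "m1"),
#'                   condition = "c1", bio_replicate = 1, day_replicate = 1,
#'                   batch = 1, run_order = 1:2, od595 = c(1, 1.1))
#' m <- matrix(c(100, 110, 200, 190), nrow = 2,
#'             dimnames = list(c("ion1", "ion2"), man$sample_id))
#' MetaboSet(m, man, mz = c(179.0561, 255.2330))
#' @export
MetaboSet <- function(intensity, manifest, mz) {
  stopifnot(is.matrix(intensity), nrow(manifest) == ncol(intensity),
            length(mz) == nrow(intensity))
  if (any(intensity <= 0))
    stop("intensities must be strictly positive")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("ion%04d", seq_len(nrow(intensity)))
  cd <- DataFrame(manifest)
  if ("sample_id" %in% colnames(cd)) {
    rownames(cd) <- cd$sample_id
    colnames(intensity) <- cd$sample_id
  }
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = cd,
    rowData = DataFrame(mz = as.numeric(mz)))
  new("MetaboSet", se)
}

#' @describeIn MetaboSet raw intensity matrix (ions x samples).
#' @param object a MetaboSet.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @export
setMethod("intensities", "MetaboSet", function(object)
  assay(object, "intensity"))

#' @describeIn MetaboSet ion m/z vector, named by ion id.
#' @export
setGeneric("ionMz", function(object) standardGeneric("ionMz"))

#' @export
setMethod("ionMz", "MetaboSet", function(object)
  setNames(rowData(object)$mz, rownames(object)))

#' @describeIn MetaboSet sample manifest as a data.frame.
#' @export
setGeneric("sampleManifest", function(object)
  standardGeneric("sampleManifest"))

#' @export
setMethod("sampleManifest", "MetaboSet", function(object) {
  df <- as.data.frame(colData(object))
  df$sample_id <- rownames(df)
  rownames(df) <- NULL
  df[, c("sample_id", MANIFEST_COLS)]
})

setMethod("show", "MetaboSet", function(object) {
  cat("MetaboSet:", nrow(object), "ions x", ncol(object), "samples\n")
  cat(" assays:", paste(assayNames(object), collapse = ", "), "\n")
  cd <- colData(object)
  cat(" mutants:", length(unique(cd$mutant)),
      "| conditions:", length(unique(cd$condition)),
      "| batches:", length(unique(cd$batch)), "\n")
  cat(" OD595 range: [", sprintf("%.2f", min(cd$od595)), ", ",
      sprintf("%.2f", max(cd$od595)), "]\n", sep = "")
})

#' StudyDesign: layout of a phosphomutant metabolomics screen
#'
#' Holds the mutant panel, growth conditions, batch partition and the full
#' sample manifest (wells, replicates, run order and extraction ODs).
#'
#' @slot mutants character, mutant labels (wild type "WT" excluded).
#' @slot conditions character, growth-condition labels.
#' @slot batches named list partitioning `mutants` into measurement batches.
#' @slot dominantMutants character, mutants over-replicated in batch 2.
#' @slot manifest data.frame sample manifest (see [MetaboSet()]).
#' @slot seed integer seed the design was drawn with.
#' @export
setClass("StudyDesign", representation(
  mutants = "character",
  conditions = "character",
  batches = "list",
  dominantMutants = "character",
  manifest = "data.frame",
  seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if ("WT" %in% object@mutants)
    msg <- c(msg, "mutants must not contain WT (wild type is implicit)")
  inb <- unlist(object@batches)
  if (!setequal(inb, object@mutants) || anyDuplicated(inb))
    msg <- c(msg, "batches must partition the mutant set")
  for (b in unique(object@manifest$batch)) {
    mb <- object@manifest[object@manifest$batch == b, ]
    if (!"WT" %in% mb$mutant)
      msg <- c(msg, sprintf("WT missing from batch %s", b))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@mutants), "mutants (+WT),",
      length(object@conditions), "conditions,",
      length(object@batches), "batches,",
      nrow(object@manifest), "samples\n")
  if (length(object@dominantMutants))
    cat(" dominant in batch 2:",
        paste(object@dominantMutants, collapse = ", "), "\n")
})

#' GroundTruth: spike ledger of a simulated screen
#'
#' Records everything the generator injected, so that recovery of effects
#' by the analysis pipeline can be checked: the per-mutant spike table, the
#' per-ion baseline intensities and OD-response exponents, the per-batch
#' drift coefficients, the replicate noise level and the true growth rates.
#'
#' @slot spikes data.frame with columns mutant, condition, ion, log2_effect.
#' @slot baselines named numeric, per-ion baseline intensity.
#' @slot odExponents named numeric, per-ion OD-response power-law exponent.
#' @slot drift list per batch of quadratic drift coefficients c(a, b).
#' @slot driftAmplitude numeric, max fractional drift deviation.
#' @slot noiseSigma numeric, replicate noise SD on the log2 scale.
#' @slot growth data.frame mutant, condition, mu (h^-1), lag (h), capacity.
#' @slot seed integer.
#' @export
setClass("GroundTruth", representation(
  spikes = "data.frame",
  baselines = "numeric",
  odExponents = "numeric",
  drift = "list",
  driftAmplitude = "numeric",
  noiseSigma = "numeric",
  growth = "data.frame",
  seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@spikes) && "WT" %in% object@spikes$mutant)
    msg <- c(msg, "spikes are only allowed on non-WT mutants")
  if (any(object@baselines <= 0))
    msg <- c(msg, "baseline intensities must be positive")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@baselines), "ions,",
      nrow(object@spikes), "spiked mutant x condition x ion effects\n")
  cat(" noise sigma (log2):", object@noiseSigma,
      "| drift amplitude:", object@driftAmplitude, "\n")
})

#' @describeIn GroundTruth the spike ledger as a data.frame.
#' @param object a GroundTruth.
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))

#' @export
setMethod("spikes", "GroundTruth", function(object) object@spikes)

#' ReferenceCurveSet: per-ion OD-wise reference intensity curves
#'
#' A fitted intensity-vs-OD curve per ion, stored as values on a common OD
#' grid. Evaluation at arbitrary OD uses linear interpolation between grid
#' points with constant extrapolation at the window edges (see
#' [evalReference()]).
#'
#' @slot od numeric, increasing OD grid the curves are tabulated on.
#' @slot values numeric matrix, ions x grid points, fitted intensities.
#' @slot method character, "plain" or "balanced".
#' @slot nSamples integer, number of samples used in the fit.
#' @slot nPermutations integer, permutations used (balanced variant only).
#' @export
setClass("ReferenceCurveSet", representation(
  od = "numeric",
  values = "matrix",
  method = "character",
  nSamples = "integer",
  nPermutations = "integer"))

setValidity("ReferenceCurveSet", function(object) {
  msg <- character()
  if (is.unsorted(object@od, strictly = TRUE))
    msg <- c(msg, "OD grid must be strictly increasing")
  if (ncol(object@values) != length(object@od))
    msg <- c(msg, "values must have one column per OD grid point")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "fitted reference values must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceCurveSet", function(object) {
  cat("ReferenceCurveSet (", object@method, "): ",
      nrow(object@values), " ions on ", length(object@od),
      " OD grid points in [", sprintf("%.2f", min(object@od)), ", ",
      sprintf("%.2f", max(object@od)), "]\n", sep = "")
  if (object@method == "balanced")
    cat(" pointwise median over", object@nPermutations, "permutations\n")
})

#' Evaluate reference curves at given ODs
#'
#' @param ref a \linkS4class{ReferenceCurveSet}.
#' @param od numeric vector of ODs.
#' @return numeric matrix, ions x length(od), linearly interpolated between
#'   the fitted grid points and held constant outside the grid.
#' @export
evalReference <- function(ref, od) {
  stopifnot(is(ref, "ReferenceCurveSet"), all(is.finite(od)))
  if (length(ref@od) == 1L) {
    out <- matrix(ref@values[, 1L], nrow = nrow(ref@values),
                  ncol = length(od))
  } else {
    out <- t(apply(ref@values, 1L, function(v)
      approx(ref@od, v, xout = od, rule = 2)$y))
    if (length(od) == 1L) out <- matrix(out, ncol = 1L)
  }
  dimnames(out) <- list(rownames(ref@values), names(od))
  out
}
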