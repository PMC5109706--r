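#' Screen configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' study's printed thresholds: significance `q < 1e-3` with
#' `|log2 FC| > 0.3785` (a 30\% change), relaxed enrichment cutoff
#' `p < 0.1` with `|log2 FC| > 0.1375` (a 10\% change), correlation
#' significance `p < 0.01`, growth-effect gate 10\%, OD window
#' `[0.6, 1.7]`, 1000 balanced-reference permutations.
#'
#' @param qCut q-value cutoff for significant ions.
#' @param l2fcCut absolute median log2 fold-change cutoff.
#' @param relaxedP,relaxedL2fc relaxed cutoffs feeding enrichment.
#' @param corrP correlation significance threshold.
#' @param growthDiff minimal relative growth difference vs wild type.
#' @param odWindow admissible extraction-OD window.
#' @param lowessFracDrift,lowessFracRef LOWESS spans for drift and
#'   reference fits.
#' @param lowessIter robustness iterations.
#' @param nPerm permutations for the balanced reference.
#' @param kKeep dominant-mutant samples kept per permutation.
#' @param tolerance annotation mass tolerance (Da).
#' @param qFamily Storey correction family for the differential stage
#'   (see [differentialAnalysis()]).
#' @param seed master RNG seed.
#' @return a named list of class `ScreenConfig`.
#' @export
screenConfig <- function(qCut = 1e-3, l2fcCut = 0.3785, relaxedP = 0.1,
                         relaxedL2fc = 0.1375, corrP = 0.01,
                         growthDiff = 0.10, odWindow = c(0.6, 1.7),
                         lowessFracDrift = 0.3, lowessFracRef = 0.5,
                         lowessIter = 3L, nPerm = 1000L, kKeep = 3L,
                         tolerance = 0.005,
                         qFamily = "mutant_condition", seed = 1L) {
  cfg <- list(qCut = qCut, l2fcCut = l2fcCut, relaxedP = relaxedP,
              relaxedL2fc = relaxedL2fc, corrP = corrP,
              growthDiff = growthDiff, odWindow = odWindow,
              lowessFracDrift = lowessFracDrift,
              lowessFracRef = lowessFracRef, lowessIter = lowessIter,
              nPerm = as.integer(nPerm), kKeep = as.integer(kKeep),
              tolerance = tolerance, qFamily = qFamily,
              seed = as.integer(seed))
  thr <- c(cfg$qCut, cfg$l2fcCut, cfg$relaxedP, cfg$relaxedL2fc,
           cfg$corrP, cfg$growthDiff, cfg$tolerance)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all thresholds must be positive")
  if (cfg$odWindow[1] >= cfg$odWindow[2])
    stop("odWindow must be c(lo, hi) with lo < hi")
  class(cfg) <- "ScreenConfig"
  cfg
}

#' @export
print.ScreenConfig <- function(x, ...) {
  cat("ScreenConfig\n")
  cat(sprintf("  significant ion: q < %g & |log2FC| > %g\n",
              x$qCut, x$l2fcCut))
  cat(sprintf("  relaxed hits:    p < %g & |log2FC| > %g\n",
              x$relaxedP, x$relaxedL2fc))
  cat(sprintf("  correlations:    p < %g\n", x$corrP))
  cat(sprintf("  OD window [%g, %g]; LOWESS spans %g (drift) / %g (ref)\n",
              x$odWindow[1], x$odWindow[2], x$lowessFracDrift,
              x$lowessFracRef))
  cat(sprintf("  balanced reference: %d permutations, keep %d; seed %d\n",
              x$nPerm, x$kKeep, x$seed))
  invisible(x)
}

#' Run the full metabolic screen
#'
#' End-to-end pipeline: drift correction per batch, OD-window filtering,
#' per batch x condition OD-wise reference curves (the permutation-balanced
#' variant for batches with dominant over-replicated mutants), fold
#' changes, differential calling with Storey correction, deprotonated-ion
#' annotation and pathway lumping, iterative hypergeometric enrichment,
#' mutant-pair and self correlations, the composite functionality score,
#' and (optionally) the growth phenotype analysis. Deterministic stages
#' are bit-identical under a fixed config.
#'
#' @param mset a \linkS4class{MetaboSet} with raw intensities.
#' @param universe annotation universe: list with `metabolites` and
#'   `pathways` (see [generateAnnotationUniverse()]), or NULL to skip
#'   annotation-dependent stages.
#' @param config a [screenConfig()].
#' @param dominantMutants mutants over-replicated in their batch; their
#'   batches use the balanced reference.
#' @param growth optional growth bundle (see [growthAnalysis()]).
#' @param driftCorrect run the drift-correction stage (default TRUE).
#' @return list of class `ScreenReport`: `foldChanges` (MetaboSet),
#'   `differential`, `counts`, `wtCutoff`, `annotation`, `entries`,
#'   `enrichment`, `correlations`, `scores`, `growth`, `log`, `config`.
#' @export
runScreen <- function(mset, universe = NULL, config = screenConfig(),
                      dominantMutants = character(), growth = NULL,
                      driftCorrect = TRUE) {
  stopifnot(is(mset, "MetaboSet"))
  log <- list()
  note <- function(stage, detail)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, detail = detail)

  note("input", sprintf("%d ions x %d samples", nrow(mset), ncol(mset)))
  if (driftCorrect) {
    mset <- correctDrift(mset, span = config$lowessFracDrift,
                         iter = config$lowessIter)
    note("drift", "per-batch LOWESS drift correction applied")
  }
  n0 <- ncol(mset)
  mset <- filterODWindow(mset, config$odWindow)
  note("od_filter", sprintf("%d -> %d samples in OD window [%g, %g]",
                            n0, ncol(mset), config$odWindow[1],
                            config$odWindow[2]))

  cd <- colData(mset)
  groups <- unique(data.frame(batch = cd$batch, condition = cd$condition))
  fc <- matrix(NA_real_, nrow(mset), ncol(mset),
               dimnames = dimnames(intensities(mset)))
  l2 <- fc
  fcOk <- rep(TRUE, nrow(mset))
  for (i in seq_len(nrow(groups))) {
    sel <- which(cd$batch == groups$batch[i] &
                   cd$condition == groups$condition[i])
    sub <- mset[, sel]
    domHere <- intersect(dominantMutants, unique(colData(sub)$mutant))
    ref <- if (length(domHere)) {
      note("reference", sprintf(
        "batch %s / %s: balanced reference (%d permutations, keep %d)",
        groups$batch[i], groups$condition[i], config$nPerm, config$kKeep))
      fitReferenceCurveBalanced(sub, domHere, kKeep = config$kKeep,
                                nPerm = config$nPerm,
                                span = config$lowessFracRef,
                                iter = config$lowessIter,
                                seed = config$seed + i)
    } else {
      fitReferenceCurve(sub, span = config$lowessFracRef,
                        iter = config$lowessIter)
    }
    sub <- computeFoldChanges(sub, ref)
    fc[, sel] <- assay(sub, "fc")
    l2[, sel] <- assay(sub, "log2fc")
    fcOk <- fcOk & rowData(sub)$fc_ok
  }
  assay(mset, "fc") <- fc
  assay(mset, "log2fc") <- l2
  rowData(mset)$fc_ok <- fcOk
  note("fold_changes", sprintf("%d/%d ions with valid reference",
                               sum(fcOk), length(fcOk)))

  differential <- differentialAnalysis(mset, qCut = config$qCut,
                                       l2fcCut = config$l2fcCut,
                                       qFamily = config$qFamily)
  counts <- callAndCount(differential)
  note("differential", sprintf("%d tests, %d significant",
                               nrow(differential),
                               sum(differential$significant, na.rm = TRUE)))
  wtL2 <- l2[, cd$mutant == "WT", drop = FALSE]
  wtCutoff <- deriveWTCutoff(as.numeric(wtL2),
                             fixedCutoff = config$l2fcCut)
  note("wt_cutoff", sprintf(
    "WT |log2FC| 97.5%% quantile %.4f (fixed calling cutoff %.4f)",
    wtCutoff$wt_quantile, wtCutoff$fixed_cutoff))

  annotation <- entries <- enrichment <- NULL
  annIons <- NULL
  if (!is.null(universe)) {
    annotation <- annotateIons(ionMz(mset), universe$metabolites,
                               tolerance = config$tolerance)
    entries <- lumpPathwayEntries(annotation, universe$pathways)
    annIons <- annotation$ion[annotation$annotated]
    note("annotation", sprintf("%d/%d ions annotated, %d lumped entries",
                               sum(annotation$annotated),
                               nrow(annotation), nrow(entries)))
    enrichment <- enrichmentAnalysis(differential, entries,
                                     relaxedP = config$relaxedP,
                                     relaxedL2fc = config$relaxedL2fc)
    note("enrichment", sprintf("%d pathway tests",
                               if (is.null(enrichment)) 0L
                               else nrow(enrichment)))
  }
  correlations <- correlationAnalysis(differential, ions = annIons,
                                      corrP = config$corrP)
  note("correlation", sprintf("%d mutant pairs, %d self profiles",
                              nrow(correlations$pairs),
                              nrow(correlations$self)))
  scores <- scoreEvidence(counts, enrichment, correlations)
  note("scoring", sprintf("%d mutants scored, %d functional (total >= 3)",
                          nrow(scores), sum(scores$functional)))
  growthRes <- NULL
  if (!is.null(growth)) {
    growthRes <- growthAnalysis(growth, minDiff = config$growthDiff,
                                qCut = config$qCut)
    note("growth", sprintf("%d wells, %d mutant x condition tests",
                           nrow(growthRes$traits),
                           nrow(growthRes$tests)))
  }
  out <- list(foldChanges = mset, differential = differential,
              counts = counts, wtCutoff = wtCutoff,
              annotation = annotation, entries = entries,
              enrichment = enrichment, correlations = correlations,
              scores = scores, growth = growthRes,
              log = do.call(rbind, log), config = config)
  class(out) <- "ScreenReport"
  out
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat("ScreenReport\n")
  for (i in seq_len(nrow(x$log)))
    cat(sprintf("  [%s] %s\n", x$log$stage[i], x$log$detail[i]))
  cat("Top of the functionality ranking:\n")
  print(head(x$scores[, c("mutant", "s_ions", "s_enrich", "s_pair",
                          "s_self", "total", "functional")], 8))
  invisible(x)
}

#' Simulate a screen and measure recovery of the injected truth
#'
#' One-command calibration demo: generates a design, annotation universe
#' and ground truth (spiking a chosen log2 effect on ions of one pathway
#' for the designated mutants), simulates intensities, runs the full
#' screen and tabulates how well the injected effects were recovered —
#' per-ion sensitivity and false calls, whether the spiked pathway attains
#' the minimum enrichment p, and the functional calls of spiked vs null
#' mutants.
#'
#' @param config a [screenConfig()]; `config$seed` drives all randomness.
#' @param nPhosphosites,nMimic panel size (see [generateDesign()]).
#' @param conditions condition labels.
#' @param nMetabolites,nPathways annotation universe size.
#' @param spikedMutants mutants receiving the perturbation.
#' @param spikePathway pathway id the spiked ions belong to.
#' @param nSpikedIons ions of the pathway to spike.
#' @param log2Effect spiked effect size.
#' @param noiseSigma replicate noise SD (log2 scale).
#' @param driftAmplitude run-order drift amplitude.
#' @param odExponentRange per-ion OD-response exponent range.
#' @param twoBatches use the two-batch design with a dominant mutant?
#' @param nBioReplicates,nWTReplicates,nDayReplicates replication.
#' @return list with `report` (ScreenReport), `truth`, `design` and
#'   `recovery` (list: `ion_sensitivity`, `n_false_ions`,
#'   `n_null_tests`, `spiked_pathway_is_top`, `functional` data.frame).
#' @export
simulateAndScore <- function(config = screenConfig(),
                             nPhosphosites = 10L, nMimic = 0L,
                             conditions = c("glucose_NH4",
                                            "glucose_proline"),
                             nMetabolites = 200L, nPathways = 8L,
                             spikedMutants = "Site01_OUT",
                             spikePathway = "PW01", nSpikedIons = 8L,
                             log2Effect = 1, noiseSigma = 0.1,
                             driftAmplitude = 0.1,
                             odExponentRange = c(0.8, 1.2),
                             twoBatches = FALSE, nBioReplicates = 3L,
                             nWTReplicates = 4L, nDayReplicates = 2L) {
  seeds <- deriveSeeds(config$seed, 4L)
  design <- generateDesign(nPhosphosites, nMimic, conditions,
                           nBioReplicates = nBioReplicates,
                           nWTReplicates = nWTReplicates,
                           nDayReplicates = nDayReplicates,
                           twoBatches = twoBatches, seed = seeds[1])
  universe <- generateAnnotationUniverse(nMetabolites, nPathways,
                                         seed = seeds[2])
  nIons <- length(universe$ionMz)
  # spike ions annotated to the chosen pathway
  ann <- annotateIons(universe$ionMz, universe$metabolites,
                      tolerance = config$tolerance)
  members <- universe$pathways$metabolite_id[
    universe$pathways$pathway_id == spikePathway]
  pwIons <- ann$ion[vapply(ann$candidates,
                           function(cc) any(cc %in% members), logical(1))]
  if (length(pwIons) < nSpikedIons)
    stop("spike pathway has too few annotated ions")
  spikeIons <- withSeed(seeds[3], sample(pwIons, nSpikedIons))
  spikes <- if (length(spikedMutants)) expand.grid(
    mutant = spikedMutants, condition = conditions, ion = spikeIons,
    stringsAsFactors = FALSE) else NULL
  if (!is.null(spikes)) spikes$log2_effect <- log2Effect
  truth <- makeGroundTruth(design, nIons = nIons, spikes = spikes,
                           noiseSigma = noiseSigma,
                           driftAmplitude = driftAmplitude,
                           odExponentRange = odExponentRange,
                           seed = seeds[4])
  mset <- simulateIntensities(design, truth, mz = universe$ionMz)
  report <- runScreen(mset, universe, config,
                      dominantMutants = design@dominantMutants)

  diffr <- report$differential
  key <- function(d) paste(d$mutant, d$condition, d$ion)
  sp <- spikes(truth)
  spKey <- if (nrow(sp)) key(sp) else character()
  isSpiked <- key(diffr) %in% spKey
  ionSens <- if (any(isSpiked))
    mean(diffr$significant[isSpiked], na.rm = TRUE) else NA_real_
  nFalse <- sum(diffr$significant[!isSpiked], na.rm = TRUE)
  topPw <- NA
  if (!is.null(report$enrichment) && nrow(sp)) {
    enr <- report$enrichment[report$enrichment$mutant %in% sp$mutant, ]
    if (nrow(enr))
      topPw <- enr$pathway_id[which.min(enr$best_p)] == spikePathway
  }
  fun <- report$scores[, c("mutant", "total", "functional")]
  fun$spiked <- fun$mutant %in% sp$mutant
  list(report = report, truth = truth, design = design,
       recovery = list(ion_sensitivity = ionSens,
                       n_false_ions = nFalse,
                       n_null_tests = sum(!isSpiked),
                       spiked_pathway_is_top = topPw,
                       functional = fun))
}
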