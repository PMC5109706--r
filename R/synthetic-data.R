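#' Generate the layout of a phosphomutant screen
#'
#' Builds a mutant panel of phosphodeletion ("OUT") mutants, one per
#' phosphosite, plus phosphomimic ("IN") mutants for the first `nMimic`
#' sites, partitions the panel into measurement batches, and lays out the
#' full sample manifest: per condition and day replicate, every mutant in
#' `nBioReplicates` wells and the wild type in `nWTReplicates` wells, with a
#' random run order within each batch and extraction ODs drawn uniformly
#' from `odRange`.
#'
#' With `twoBatches = TRUE` the second batch reproduces the situation where
#' a single phosphosite's mutants dominate the batch: the dominant mutants
#' keep `nBioReplicates` wells while the remaining batch-2 mutants get a
#' single well per plate.
#'
#' @param nPhosphosites number of phosphosites (one OUT mutant each).
#' @param nMimic number of sites with an additional IN mutant
#'   (`nMimic <= nPhosphosites`).
#' @param conditions character vector of growth-condition labels.
#' @param nBioReplicates wells per mutant per plate (default 3).
#' @param nWTReplicates wild-type wells per plate (default 4).
#' @param nDayReplicates number of day replicates, i.e. repeated
#'   grow-and-extract rounds per plate (default 2).
#' @param twoBatches partition the panel into two measurement batches?
#' @param dominantSite index of the phosphosite whose mutants dominate
#'   batch 2 (used only when `twoBatches = TRUE`; defaults to the last
#'   mimicked site so that both an OUT and an IN mutant dominate).
#' @param odRange extraction OD595 range samples are drawn from.
#' @param seed integer RNG seed.
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' d <- generateDesign(26, 6, seed = 1)
#' length(d@mutants)  # 32
#' @export
generateDesign <- function(nPhosphosites, nMimic = 0L,
                           conditions = c("glucose_NH4", "pyruvate_NH4",
                                          "glucose_glutamine",
                                          "glucose_proline"),
                           nBioReplicates = 3L, nWTReplicates = 4L,
                           nDayReplicates = 2L, twoBatches = TRUE,
                           dominantSite = NULL,
                           odRange = c(0.6, 1.7), seed = 1L) {
  if (nPhosphosites < 1L || nMimic < 0L)
    stop("nPhosphosites must be >= 1 and nMimic >= 0")
  if (nMimic > nPhosphosites)
    stop("nMimic must not exceed nPhosphosites")
  sites <- sprintf("Site%02d", seq_len(nPhosphosites))
  mutants <- c(paste0(sites, "_OUT"),
               if (nMimic > 0L) paste0(sites[seq_len(nMimic)], "_IN"))

  if (twoBatches && nPhosphosites >= 2L) {
    if (is.null(dominantSite))
      dominantSite <- if (nMimic > 0L) nMimic else nPhosphosites
    dom <- mutants[grepl(sprintf("^Site%02d_", dominantSite), mutants)]
    others <- setdiff(mutants, dom)
    # roughly a quarter of the non-dominant panel travels with batch 2
    n2 <- max(1L, floor(length(others) / 4))
    batch2 <- c(dom, others[seq_len(n2)])
    batches <- list(batch1 = setdiff(mutants, batch2), batch2 = batch2)
  } else {
    dom <- character()
    batches <- list(batch1 = mutants)
  }

  manifest <- withSeed(seed, {
    rows <- list()
    for (bi in seq_along(batches)) {
      bmut <- batches[[bi]]
      for (cond in conditions) {
        for (day in seq_len(nDayReplicates)) {
          for (m in c(bmut, "WT")) {
            nrep <- if (m == "WT") nWTReplicates
                    else if (bi == 2L && length(dom) && !m %in% dom) 1L
                    else nBioReplicates
            rows[[length(rows) + 1L]] <- data.frame(
              mutant = m, condition = cond,
              bio_replicate = seq_len(nrep), day_replicate = day,
              batch = bi)
          }
        }
      }
    }
    man <- do.call(rbind, rows)
    # run order: random measurement sequence within each batch,
    # extraction ODs uniform over the admissible window
    man$run_order <- NA_integer_
    for (bi in unique(man$batch)) {
      idx <- which(man$batch == bi)
      man$run_order[idx] <- sample(length(idx))
    }
    man$od595 <- runif(nrow(man), odRange[1], odRange[2])
    man$sample_id <- sprintf("b%d_%s_%s_d%d_r%d", man$batch, man$condition,
                             man$mutant, man$day_replicate,
                             man$bio_replicate)
    man[, c("sample_id", MANIFEST_COLS)]
  })

  new("StudyDesign", mutants = mutants, conditions = conditions,
      batches = batches, dominantMutants = dom, manifest = manifest,
      seed = as.integer(seed))
}

#' Assemble the ground truth of a simulated screen
#'
#' Draws the per-ion generative parameters (baseline intensity, OD-response
#' exponent), the per-batch smooth run-order drift profile, and records the
#' spike table, noise level and true growth parameters.
#'
#' The drift profile is a quadratic in normalised run position scaled so
#' that its maximal fractional deviation equals `driftAmplitude`; the OD
#' response is an ion-specific power law `OD^gamma` with `gamma` drawn from
#' `odExponentRange` (set the range to `c(0, 0)` for OD-independent ions or
#' `c(1, 1)` for exactly proportional response).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param nIons number of measured ions.
#' @param spikes data.frame with columns mutant, condition, ion (ion id
#'   `"ion%04d"` or integer index), log2_effect; NULL for no spikes.
#' @param noiseSigma replicate noise SD on the log2-intensity scale.
#' @param driftAmplitude maximal fractional run-order drift (0 = flat).
#' @param odExponentRange range of per-ion OD power-law exponents.
#' @param baselineLogRange range of log10 baseline intensities.
#' @param growthDeficits data.frame mutant, condition, fraction: relative
#'   growth-rate reduction vs wild type (e.g. 0.2 for a 20\% deficit).
#' @param muWT wild-type growth rate (h^-1) applied in every condition.
#' @param lag lag time (h) before exponential growth.
#' @param capacity carrying capacity (plateau OD595).
#' @param seed integer RNG seed.
#' @return a \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(design, nIons, spikes = NULL,
                            noiseSigma = 0.1, driftAmplitude = 0.1,
                            odExponentRange = c(0.5, 1.5),
                            baselineLogRange = c(4, 6),
                            growthDeficits = NULL,
                            muWT = 0.35, lag = 1, capacity = 1.5,
                            seed = 1L) {
  stopifnot(is(design, "StudyDesign"), nIons >= 1L)
  ionIds <- sprintf("ion%04d", seq_len(nIons))
  if (is.null(spikes)) {
    spikes <- data.frame(mutant = character(), condition = character(),
                         ion = character(), log2_effect = numeric())
  } else {
    spikes <- as.data.frame(spikes)
    if (is.numeric(spikes$ion)) spikes$ion <- ionIds[spikes$ion]
    stopifnot(all(spikes$ion %in% ionIds),
              all(spikes$mutant %in% design@mutants),
              all(spikes$condition %in% design@conditions))
  }
  gt <- withSeed(seed, {
    baselines <- setNames(10^runif(nIons, baselineLogRange[1],
                                   baselineLogRange[2]), ionIds)
    odExp <- setNames(runif(nIons, odExponentRange[1], odExponentRange[2]),
                      ionIds)
    drift <- lapply(unique(design@manifest$batch), function(b) {
      if (driftAmplitude <= 0) return(c(a = 0, b = 0))
      co <- c(a = runif(1, -1, 1), b = runif(1, -1, 1))
      # rescale so max |d(u) - 1| over u in [0,1] equals the amplitude
      u <- seq(0, 1, length.out = 201)
      dev <- max(abs(co["a"] * (u - 0.5) + co["b"] * ((u - 0.5)^2 - 1 / 12)))
      if (dev > 0) co <- co * driftAmplitude / dev
      co
    })
    names(drift) <- paste0("batch", unique(design@manifest$batch))
    list(baselines = baselines, odExp = odExp, drift = drift)
  })
  growth <- expand.grid(mutant = c(design@mutants, "WT"),
                        condition = design@conditions,
                        stringsAsFactors = FALSE)
  growth$mu <- muWT
  growth$lag <- lag
  growth$capacity <- capacity
  if (!is.null(growthDeficits)) {
    for (i in seq_len(nrow(growthDeficits))) {
      sel <- growth$mutant == growthDeficits$mutant[i] &
        growth$condition == growthDeficits$condition[i]
      growth$mu[sel] <- growth$mu[sel] * (1 - growthDeficits$fraction[i])
    }
  }
  new("GroundTruth", spikes = spikes, baselines = gt$baselines,
      odExponents = gt$odExp, drift = gt$drift,
      driftAmplitude = driftAmplitude, noiseSigma = noiseSigma,
      growth = growth, seed = as.integer(seed))
}

# Multiplicative drift factor for batch b at normalised run position u.
driftFactor <- function(truth, batch, u) {
  co <- truth@drift[[paste0("batch", batch)]]
  1 + co["a"] * (u - 0.5) + co["b"] * ((u - 0.5)^2 - 1 / 12)
}

#' Simulate an ion-intensity table
#'
#' Generates intensities as
#' `baseline(ion) * OD^gamma(ion) * drift(batch, run order) *
#' 2^(spiked log2 effect) * 2^(N(0, sigma))`, i.e. an OD-dependent,
#' drift-modulated, log-normally noisy measurement with multiplicative
#' spiked effects on selected mutant x condition x ion combinations.
#' Deterministic for a fixed `truth@seed`.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param truth a \linkS4class{GroundTruth} from [makeGroundTruth()].
#' @param mz optional ion m/z values (defaults to an evenly spaced ladder
#'   across the 50-1000 acquisition range).
#' @return a \linkS4class{MetaboSet} with assay `"intensity"`.
#' @export
simulateIntensities <- function(design, truth, mz = NULL) {
  stopifnot(is(design, "StudyDesign"), is(truth, "GroundTruth"))
  man <- design@manifest
  ionIds <- names(truth@baselines)
  nIons <- length(ionIds)
  if (is.null(mz)) mz <- seq(60, 990, length.out = nIons)
  stopifnot(length(mz) == nIons)

  # normalised run position within batch
  u <- numeric(nrow(man))
  for (b in unique(man$batch)) {
    idx <- man$batch == b
    u[idx] <- (man$run_order[idx] - 1) / max(1L, sum(idx) - 1L)
  }
  odPart <- t(vapply(truth@odExponents, function(g) man$od595^g,
                     numeric(nrow(man))))
  driftPart <- matrix(vapply(seq_len(nrow(man)), function(j)
    driftFactor(truth, man$batch[j], u[j]), numeric(1)),
    nrow = nIons, ncol = nrow(man), byrow = TRUE)
  spikePart <- matrix(0, nIons, nrow(man),
                      dimnames = list(ionIds, man$sample_id))
  sp <- truth@spikes
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      cols <- man$mutant == sp$mutant[i] & man$condition == sp$condition[i]
      spikePart[sp$ion[i], cols] <- spikePart[sp$ion[i], cols] +
        sp$log2_effect[i]
    }
  }
  noise <- withSeed(truth@seed, {
    if (truth@noiseSigma > 0)
      matrix(rnorm(nIons * nrow(man), 0, truth@noiseSigma),
             nIons, nrow(man))
    else matrix(0, nIons, nrow(man))
  })
  intensity <- truth@baselines * odPart * driftPart *
    2^(spikePart + noise)
  dimnames(intensity) <- list(ionIds, man$sample_id)
  MetaboSet(intensity, man, mz = mz)
}

#' Simulate microplate growth curves
#'
#' Wells follow a lag / exponential / stationary trajectory:
#' `OD(t) = OD0` for `t < lag`, `OD0 * exp(mu * (t - lag))` until the
#' carrying capacity is reached, then a plateau at the capacity. Optional
#' additive Gaussian measurement noise.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param truth a \linkS4class{GroundTruth} (supplies mu, lag, capacity).
#' @param times numeric, sampling times in hours.
#' @param od0 inoculation OD595.
#' @param noiseSd additive measurement noise SD (OD units); relative noise
#'   can be had via `relativeNoise`.
#' @param relativeNoise if TRUE, `noiseSd` is interpreted as a fraction of
#'   the current OD (multiplicative noise).
#' @param nReplicates wells per mutant x condition.
#' @param seed integer RNG seed.
#' @return list with `data` (long data.frame: well, time_h, od595) and
#'   `wells` (data.frame: well, mutant, condition, replicate).
#' @export
simulateGrowth <- function(design, truth, times = seq(0, 24, by = 0.25),
                           od0 = 0.03, noiseSd = 0, relativeNoise = TRUE,
                           nReplicates = 6L, seed = 1L) {
  stopifnot(is(design, "StudyDesign"), is(truth, "GroundTruth"), od0 > 0)
  gr <- truth@growth
  if (any(gr$mu <= 0)) stop("true growth rates must be positive")
  wells <- expand.grid(replicate = seq_len(nReplicates),
                       mutant = c(design@mutants, "WT"),
                       condition = design@conditions,
                       stringsAsFactors = FALSE)
  wells$well <- sprintf("w%04d", seq_len(nrow(wells)))
  data <- withSeed(seed, {
    out <- vector("list", nrow(wells))
    for (i in seq_len(nrow(wells))) {
      p <- gr[gr$mutant == wells$mutant[i] &
                gr$condition == wells$condition[i], ]
      od <- ifelse(times < p$lag, od0,
                   pmin(p$capacity, od0 * exp(p$mu * (times - p$lag))))
      if (noiseSd > 0) {
        eps <- rnorm(length(times), 0, noiseSd)
        od <- if (relativeNoise) od * (1 + eps) else od + eps
        od <- pmax(od, 1e-4)
      }
      out[[i]] <- data.frame(well = wells$well[i], time_h = times,
                             od595 = od)
    }
    do.call(rbind, out)
  })
  list(data = data, wells = wells[, c("well", "mutant", "condition",
                                      "replicate")])
}

#' Generate a synthetic annotation universe
#'
#' Draws metabolite monoisotopic masses whose deprotonated ions fall in the
#' 50-1000 m/z acquisition window, groups metabolites into pathways, and
#' derives the measured ion m/z list. A stated fraction of ions is isobaric,
#' i.e. maps to more than one metabolite ([M-H]- ions of equal mass).
#'
#' @param nMetabolites number of metabolites.
#' @param nPathways number of pathways.
#' @param multiAnnotationFraction target fraction of ions annotated to more
#'   than one metabolite (isobars are created by assigning a partner
#'   metabolite the same mass).
#' @param metabolitesPerPathway pathway size (sampled without replacement).
#' @param massRange neutral monoisotopic mass range (Da).
#' @param seed integer RNG seed.
#' @return list with `metabolites` (data.frame metabolite_id, mass),
#'   `pathways` (data.frame pathway_id, metabolite_id) and `ionMz`
#'   (numeric, sorted unique [M-H]- m/z values).
#' @export
generateAnnotationUniverse <- function(nMetabolites, nPathways,
                                       multiAnnotationFraction = 0,
                                       metabolitesPerPathway = 15L,
                                       massRange = c(80, 900),
                                       seed = 1L) {
  stopifnot(nMetabolites >= 1L, nPathways >= 0L,
            multiAnnotationFraction >= 0, multiAnnotationFraction <= 1)
  withSeed(seed, {
    ids <- sprintf("M%04d", seq_len(nMetabolites))
    mass <- runif(nMetabolites, massRange[1], massRange[2])
    f <- multiAnnotationFraction
    # k isobaric ions out of (nMetabolites - k) total ions => k = f*n/(1+f)
    k <- floor(f * nMetabolites / (1 + f))
    if (k > 0) {
      donors <- seq_len(k)
      partners <- k + seq_len(k)
      mass[partners] <- mass[donors]
    }
    pw <- if (nPathways > 0) {
      sz <- min(metabolitesPerPathway, nMetabolites)
      do.call(rbind, lapply(seq_len(nPathways), function(p) data.frame(
        pathway_id = sprintf("PW%02d", p),
        metabolite_id = sample(ids, sz))))
    } else {
      data.frame(pathway_id = character(), metabolite_id = character())
    }
    list(metabolites = data.frame(metabolite_id = ids, mass = mass),
         pathways = pw,
         ionMz = sort(unique(mass)) - PROTON_MASS)
  })
}

#' Build a spike table concentrated in one pathway
#'
#' Selects ions annotated to members of one pathway and assigns them a
#' common log2 effect for the given mutant x condition combinations —
#' the pathway-clustered perturbation the enrichment analysis is meant to
#' detect.
#'
#' @param universe an annotation universe from [generateAnnotationUniverse()].
#' @param mset a \linkS4class{MetaboSet} whose ions the spikes refer to.
#' @param pathway pathway id to concentrate spikes in.
#' @param mutants,conditions mutants and conditions to perturb (crossed).
#' @param nIons number of pathway ions to spike.
#' @param log2Effect spiked log2 effect size.
#' @param tolerance annotation mass tolerance (Da).
#' @return data.frame suitable as the `spikes` argument of
#'   [makeGroundTruth()].
#' @export
spikesForPathway <- function(universe, mset, pathway, mutants, conditions,
                             nIons = 8L, log2Effect = 1,
                             tolerance = 0.005) {
  ann <- annotateIons(ionMz(mset), universe$metabolites,
                      tolerance = tolerance)
  members <- universe$pathways$metabolite_id[
    universe$pathways$pathway_id == pathway]
  inPw <- vapply(ann$candidates, function(cc) any(cc %in% members),
                 logical(1))
  ions <- ann$ion[inPw]
  if (length(ions) < nIons)
    stop(sprintf("pathway %s has only %d annotated ions (< %d requested)",
                 pathway, length(ions), nIons))
  ions <- ions[seq_len(nIons)]
  out <- expand.grid(mutant = mutants, condition = conditions,
                     ion = ions, stringsAsFactors = FALSE)
  out$log2_effect <- log2Effect
  out
}
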