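test_that("drift correction leaves drift-free input unchanged", {
  od <- runif(30, 0.7, 1.6)
  ints <- matrix(rep(c(1000, 5e5), each = 30), nrow = 2, byrow = TRUE)
  ms <- manualMetaboSet(ints, od)
  out <- correctDrift(ms)
  expect_equal(assay(out, "corrected"), intensities(ms),
               tolerance = 1e-6)
})

test_that("a linear 20% drift is removed", {
  set.seed(3)
  n <- 60
  od <- runif(n, 0.7, 1.6)
  drift <- seq(0.9, 1.1, length.out = n)    # +/-10% linear in run order
  base <- 2e4 * od                           # OD-responsive ion
  ints <- matrix(base * drift, nrow = 1)
  ms <- manualMetaboSet(ints, od, runOrder = seq_len(n))
  out <- assay(correctDrift(ms), "corrected")[1, ]
  # residual run-order trend after correction: slope ~ 0
  rel <- out / (2e4 * od)
  slope <- coef(lm(rel ~ seq_len(n)))[2]
  expect_lt(abs(slope), 1e-3 * mean(rel))
  # uncorrected slope is clearly nonzero, for contrast
  slope0 <- coef(lm(I(ints[1, ] / (2e4 * od)) ~ seq_len(n)))[2]
  expect_gt(abs(slope0), 1e-3)
})

test_that("batches are corrected independently", {
  od <- rep(1, 40)
  ints <- matrix(1000, 1, 40)
  man <- data.frame(sample_id = sprintf("s%02d", 1:40), mutant = "WT",
                    condition = "c1", bio_replicate = 1:40,
                    day_replicate = 1, batch = rep(1:2, each = 20),
                    run_order = rep(1:20, 2), od595 = od)
  ms <- MetaboSet(ints, man, mz = 100)
  base <- assay(correctDrift(ms), "corrected")
  # perturbing batch 2 must not change batch 1's correction
  ints2 <- ints
  ints2[1, 21:40] <- 1000 * seq(0.8, 1.2, length.out = 20)
  ms2 <- MetaboSet(ints2, man, mz = 100)
  pert <- assay(correctDrift(ms2), "corrected")
  expect_equal(pert[1, 1:20], base[1, 1:20])
  # too few samples per batch: skipped with warning
  expect_warning(correctDrift(ms[, 1:3]), "skipped")
})

test_that("the OD window filter is inclusive and validated", {
  od <- c(0.5, 0.6, 1.0, 1.7, 1.8)
  ms <- manualMetaboSet(matrix(100, 1, 5), od)
  kept <- filterODWindow(ms, c(0.6, 1.7))
  expect_equal(colData(kept)$od595, c(0.6, 1.0, 1.7))
  inside <- manualMetaboSet(matrix(100, 1, 3), c(0.8, 1.0, 1.2))
  expect_equal(ncol(filterODWindow(inside)), 3)
  expect_error(filterODWindow(ms, c(0.9, 0.8)), "lo < hi")
  expect_error(filterODWindow(ms, c(5, 6)), "no samples")
})

test_that("reference curves recover constant and linear responses", {
  set.seed(8)
  od <- runif(100, 0.6, 1.7)
  const <- matrix(4e4, 1, 100)
  refC <- fitReferenceCurve(manualMetaboSet(const, od))
  expect_equal(as.numeric(refC@values), rep(4e4, length(refC@od)),
               tolerance = 1e-9)
  lin <- matrix(3e4 * od, 1)
  refL <- fitReferenceCurve(manualMetaboSet(lin, od))
  grid <- refL@od
  expect_equal(as.numeric(refL@values), 3e4 * grid, tolerance = 0.01)
  # evaluation interpolates linearly and clamps at the window edges
  v <- evalReference(refL, c(0.2, 1.0, 5))
  expect_equal(unname(v[1, 1]), unname(refL@values[1, 1]))
  expect_equal(unname(v[1, 3]), unname(refL@values[1, length(grid)]))
  expect_equal(unname(v[1, 2]), 3e4 * 1.0, tolerance = 0.01)
  expect_warning(fitReferenceCurve(manualMetaboSet(matrix(100, 1, 4),
                                                   c(0.7, 1, 1.2, 1.5))),
                 "medians")
})

test_that("robust mode resists a strong outlying sample", {
  set.seed(12)
  od <- runif(80, 0.6, 1.7)
  y <- 1e4 * od * exp(rnorm(80, 0, 0.05))
  y[40] <- y[40] * 8   # one strong metabolic outlier
  ms <- manualMetaboSet(matrix(y, 1), od)
  robust <- fitReferenceCurve(ms, iter = 3)
  plain <- fitReferenceCurve(ms, iter = 0)
  truth <- 1e4 * robust@od
  expect_lt(mean(abs(robust@values - truth)),
            mean(abs(plain@values - truth)))
})

test_that("balanced reference: exact with all replicates, stable under null dominance", {
  design <- generateDesign(10, 0, "c1", twoBatches = TRUE, seed = 5)
  truth <- makeGroundTruth(design, nIons = 25, noiseSigma = 0.1,
                           driftAmplitude = 0, seed = 6)
  mset <- simulateIntensities(design, truth)
  b2 <- mset[, colData(mset)$batch == 2]
  dom <- design@dominantMutants
  plain <- fitReferenceCurve(b2)
  kAll <- min(table(colData(b2)$mutant[colData(b2)$mutant %in% dom]))
  balAll <- fitReferenceCurveBalanced(b2, dom, kKeep = kAll, nPerm = 3,
                                      seed = 4)
  expect_identical(balAll@values, plain@values)
  # dominant mutant statistically identical to WT: the 50-permutation
  # median curve stays close to the plain curve
  bal <- fitReferenceCurveBalanced(b2, dom, kKeep = 3, nPerm = 50,
                                   seed = 4)
  expect_lt(mean(abs(bal@values / plain@values - 1)), 0.05)
  # deterministic under the master seed
  bal2 <- fitReferenceCurveBalanced(b2, dom, kKeep = 3, nPerm = 50,
                                    seed = 4)
  expect_identical(bal@values, bal2@values)
  expect_error(fitReferenceCurveBalanced(b2, dom, kKeep = 100),
               "fewer than kKeep")
})

test_that("a single permutation equals one subsampled fit", {
  design <- generateDesign(6, 0, "c1", twoBatches = TRUE, seed = 15)
  truth <- makeGroundTruth(design, nIons = 8, noiseSigma = 0.05,
                           driftAmplitude = 0, seed = 16)
  mset <- simulateIntensities(design, truth)
  b2 <- mset[, colData(mset)$batch == 2]
  dom <- design@dominantMutants
  bal <- fitReferenceCurveBalanced(b2, dom, kKeep = 2, nPerm = 1,
                                   seed = 99)
  # reproduce the single draw with the same derived child seed
  permSeed <- phosmet:::deriveSeeds(99, 1)
  mut <- colData(b2)$mutant
  domIdx <- lapply(dom, function(m) which(mut == m))
  keep <- phosmet:::withSeed(permSeed, {
    drawn <- unlist(lapply(domIdx, function(ix) sample(ix, 2)))
    sort(c(setdiff(seq_len(ncol(b2)), unlist(domIdx)), drawn))
  })
  manual <- fitReferenceCurve(b2[, keep])
  manualOnGrid <- t(apply(manual@values, 1, function(v)
    approx(manual@od, v, xout = bal@od, rule = 2)$y))
  expect_equal(unname(bal@values), unname(manualOnGrid),
               tolerance = 1e-10)
})

test_that("fold changes are ratios to the reference at the sample OD", {
  od <- c(0.8, 1.0, 1.2, 1.4)
  ints <- matrix(1000, 2, 4)
  ms <- manualMetaboSet(ints, od)
  ref <- fitReferenceCurve(ms, minSamples = 1L)
  ms <- computeFoldChanges(ms, ref)
  expect_equal(as.numeric(assay(ms, "fc")), rep(1, 8))
  expect_equal(as.numeric(assay(ms, "log2fc")), rep(0, 8))
  # doubling the intensity of one sample gives log2fc = 1 there
  ints2 <- ints
  ints2[1, 2] <- 2000
  ms2 <- computeFoldChanges(manualMetaboSet(ints2, od), ref)
  expect_equal(assay(ms2, "log2fc")[1, 2], 1)
})

test_that("end-to-end identity: flat generative factors give zero fold changes", {
  design <- tinyDesign(4, c("c1", "c2"), seed = 31)
  truth <- makeGroundTruth(design, nIons = 20, noiseSigma = 0,
                           driftAmplitude = 0, odExponentRange = c(0, 0),
                           seed = 32)
  mset <- simulateIntensities(design, truth)
  rep0 <- runScreen(mset, NULL, screenConfig(seed = 1))
  l2 <- assay(rep0$foldChanges, "log2fc")
  expect_lt(max(abs(l2)), 1e-6)
  expect_equal(sum(rep0$differential$significant), 0)
})
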