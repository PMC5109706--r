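test_that("design combinatorics follow the panel construction", {
  d <- generateDesign(26, 6, seed = 1)
  expect_length(d@mutants, 32)
  expect_equal(sum(grepl("_OUT$", d@mutants)), 26)
  expect_equal(sum(grepl("_IN$", d@mutants)), 6)
  expect_length(generateDesign(1, 0, twoBatches = FALSE, seed = 1)@mutants,
                1)
  expect_length(generateDesign(5, 5, seed = 1)@mutants, 10)
  expect_error(generateDesign(0, 0), "nPhosphosites")
  expect_error(generateDesign(3, 4), "nMimic")
})

test_that("the manifest satisfies the design invariants", {
  d <- generateDesign(8, 2, seed = 3)
  man <- d@manifest
  # WT on every plate of every batch, each mutant in exactly one batch
  for (b in unique(man$batch))
    expect_true("WT" %in% man$mutant[man$batch == b])
  batchOf <- tapply(man$batch[man$mutant != "WT"],
                    man$mutant[man$mutant != "WT"],
                    function(x) length(unique(x)))
  expect_true(all(batchOf == 1))
  expect_setequal(unlist(d@batches), d@mutants)
  # run order is a permutation within each batch; ODs in the stated range
  for (b in unique(man$batch)) {
    ro <- man$run_order[man$batch == b]
    expect_setequal(ro, seq_along(ro))
  }
  expect_true(all(man$od595 >= 0.6 & man$od595 <= 1.7))
  # dominant mutants are the only batch-2 mutants in full replication
  m2 <- man[man$batch == 2 & man$mutant != "WT", ]
  reps <- tapply(m2$bio_replicate, m2$mutant, max)
  expect_true(all(reps[d@dominantMutants] == 3))
  expect_true(all(reps[setdiff(names(reps), d@dominantMutants)] == 1))
})

test_that("intensities follow the generative model exactly when noise-free", {
  d <- tinyDesign(2, "c1", seed = 5)
  spikes <- data.frame(mutant = "Site01_OUT", condition = "c1",
                       ion = "ion0003", log2_effect = 1)
  truth <- makeGroundTruth(d, nIons = 4, spikes = spikes, noiseSigma = 0,
                           driftAmplitude = 0, seed = 6)
  mset <- simulateIntensities(d, truth)
  man <- sampleManifest(mset)
  ints <- intensities(mset)
  for (j in seq_len(nrow(man))) {
    expected <- truth@baselines * man$od595[j]^truth@odExponents
    if (man$mutant[j] == "Site01_OUT") expected["ion0003"] <-
        2 * expected["ion0003"]
    expect_equal(unname(ints[, j]), unname(expected), tolerance = 1e-12)
  }
  # the injected effect is exactly log2(mutant/WT) at matched OD
  wt <- which(man$mutant == "WT")[1]
  mu <- which(man$mutant == "Site01_OUT")[1]
  odRatio <- (man$od595[mu] / man$od595[wt])^truth@odExponents["ion0003"]
  expect_equal(unname(log2(ints["ion0003", mu] /
                             (ints["ion0003", wt] * odRatio))),
               1, tolerance = 1e-10)
})

test_that("simulation is deterministic under a fixed seed", {
  d1 <- generateDesign(4, 1, seed = 9)
  d2 <- generateDesign(4, 1, seed = 9)
  expect_identical(d1@manifest, d2@manifest)
  t1 <- makeGroundTruth(d1, nIons = 10, noiseSigma = 0.2, seed = 7)
  t2 <- makeGroundTruth(d2, nIons = 10, noiseSigma = 0.2, seed = 7)
  expect_identical(intensities(simulateIntensities(d1, t1)),
                   intensities(simulateIntensities(d2, t2)))
  g1 <- simulateGrowth(d1, t1, noiseSd = 0.02, seed = 3)
  g2 <- simulateGrowth(d2, t2, noiseSd = 0.02, seed = 3)
  expect_identical(g1$data, g2$data)
})

test_that("growth curves obey their closed form", {
  d <- tinyDesign(1, "c1", seed = 2)
  truth <- makeGroundTruth(d, nIons = 2, muWT = log(2), lag = 2,
                           capacity = 1.5, seed = 2)
  g <- simulateGrowth(d, truth, times = seq(0, 20, 0.5), od0 = 0.03,
                      noiseSd = 0, nReplicates = 1, seed = 1)
  w <- g$data[g$data$well == g$wells$well[g$wells$mutant == "WT"][1], ]
  # flat during lag
  expect_true(all(w$od595[w$time_h < 2] == 0.03))
  # doubles each hour after the lag, before the plateau
  pre <- w[w$time_h >= 2 & w$od595 < 1.5, ]
  expect_equal(pre$od595, 0.03 * 2^(pre$time_h - 2), tolerance = 1e-12)
  # plateau exactly at the carrying capacity
  expect_equal(max(w$od595), 1.5)
  badTruth <- truth
  badTruth@growth$mu <- -0.1
  expect_error(simulateGrowth(d, badTruth), "positive")
})

test_that("annotation universe maps masses into [M-H]- m/z space", {
  u <- generateAnnotationUniverse(50, 4, multiAnnotationFraction = 0,
                                  seed = 13)
  expect_length(u$ionMz, 50)  # no isobars: one ion per metabolite
  expect_equal(sort(u$metabolites$mass) - 1.00728, u$ionMz)
  expect_true(all(u$ionMz >= 50 & u$ionMz <= 1000))
  expect_true(all(u$pathways$metabolite_id %in%
                    u$metabolites$metabolite_id))
  # a stated fraction of ions becomes isobaric
  u2 <- generateAnnotationUniverse(60, 2, multiAnnotationFraction = 0.2,
                                   seed = 13)
  expect_lt(length(u2$ionMz), 60)
  ann <- annotateIons(u2$ionMz, u2$metabolites, tolerance = 0)
  expect_true(any(ann$n_candidates > 1))
  # single pathway containing everything: hits enrich it or nothing
  u3 <- generateAnnotationUniverse(20, 1, metabolitesPerPathway = 20,
                                   seed = 1)
  expect_setequal(u3$pathways$metabolite_id, u3$metabolites$metabolite_id)
})

test_that("replicate noise matches its stated log-normal law", {
  # |log2 FC| of unspiked ions against the true generative reference is
  # exactly the injected normal noise; its 97.5% quantile must sit within
  # 3 Monte-Carlo SEs of the analytic value
  d <- generateDesign(6, 0, c("c1", "c2"), twoBatches = FALSE, seed = 21)
  sigma <- 0.15
  truth <- makeGroundTruth(d, nIons = 40, noiseSigma = sigma,
                           driftAmplitude = 0, seed = 22)
  mset <- simulateIntensities(d, truth)
  man <- sampleManifest(mset)
  refTrue <- truth@baselines %o% rep(1, nrow(man)) *
    t(vapply(truth@odExponents, function(g) man$od595^g,
             numeric(nrow(man))))
  l2 <- log2(intensities(mset) / refTrue)
  q <- quantile(abs(l2), 0.975)
  qAnalytic <- sigma * qnorm(0.9875)
  n <- length(l2)
  se <- sqrt(0.975 * 0.025 / n) / (2 * dnorm(qnorm(0.9875)) / sigma)
  expect_lt(abs(q - qAnalytic), 3 * se)
})
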