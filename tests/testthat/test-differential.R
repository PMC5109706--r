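test_that("outlier pruning removes only >2-SD deviations, one pass", {
  # mean 2, sample SD sqrt(6) ~ 2.449: |7-2| = 5 > 4.899 -> removed
  expect_equal(pruneOutliers(c(1, 1, 1, 1, 1, 7)), rep(1, 5))
  # all equal: SD = 0 convention, nothing removed
  expect_equal(pruneOutliers(rep(3, 6)), rep(3, 6))
  expect_warning(out <- pruneOutliers(c(1, 9)), "unpruned")
  expect_equal(out, c(1, 9))
})

test_that("no value is removable at n <= 5 under the sample SD", {
  # max |x - mean|/SD is (n-1)/sqrt(n) < 2 for n <= 5
  set.seed(4)
  for (n in 3:5) {
    for (r in 1:20) {
      x <- rnorm(n, sd = runif(1, 0.1, 10))
      expect_length(pruneOutliers(x), n)
    }
    expect_lt((n - 1) / sqrt(n), 2)
  }
  # while at n = 6 removal is possible
  expect_lt(length(pruneOutliers(c(1, 1, 1, 1, 1, 7))), 6)
})

test_that("median log2 fold change summarises on the log scale", {
  expect_equal(medianLog2FC(c(1, 2, 4)), 1)
  expect_equal(medianLog2FC(1.3), log2(1.3))
  expect_equal(round(medianLog2FC(1.3), 4), 0.3785)
  expect_equal(medianLog2FC(c(0.5, 2)), 0)
  expect_error(medianLog2FC(numeric()), "no fold changes")
  expect_error(medianLog2FC(c(1, -2)), "positive")
})

test_that("Welch test matches the textbook statistic", {
  x <- c(0.1, 0.2, 0.3)
  y <- c(0.0, 0.0, 0.1, 0.1)
  w <- welchTest(x, y)
  # hand computation: t = (mx - my) / sqrt(vx/nx + vy/ny),
  # df by Satterthwaite
  vx <- var(x) / 3; vy <- var(y) / 4
  tHand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  dfHand <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 3)
  pHand <- 2 * pt(-abs(tHand), dfHand)
  expect_equal(w$statistic, tHand, tolerance = 1e-12)
  expect_equal(w$df, dfHand, tolerance = 1e-12)
  expect_equal(w$p.value, pHand, tolerance = 1e-12)
  # identical degenerate groups: t = 0, p = 1
  d <- welchTest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(d$p.value, 1)
  expect_true(d$degenerate)
  # near-separation drives p toward 0
  set.seed(1)
  sep <- welchTest(1 + rnorm(5, 0, 1e-4), rnorm(5, 0, 1e-4))
  expect_lt(sep$p.value, 1e-6)
})

test_that("Welch p is invariant to shifts and group order", {
  set.seed(2)
  x <- rnorm(6, 1); y <- rnorm(10)
  p0 <- welchTest(x, y)$p.value
  expect_equal(welchTest(x + 5, y + 5)$p.value, p0, tolerance = 1e-12)
  expect_equal(welchTest(y, x)$p.value, p0, tolerance = 1e-12)
})

test_that("Storey q-values behave and reduce to BH at pi0 = 1", {
  expect_equal(storeyQ(rep(1, 10)), rep(1, 10))
  expect_equal(storeyQ(numeric()), numeric())
  set.seed(5)
  p <- c(runif(200), runif(25, 0, 1e-4))
  expect_equal(storeyQ(p, pi0 = 1), p.adjust(p, method = "BH"),
               tolerance = 1e-12)
  # monotone: sorting by p sorts q
  q <- storeyQ(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  expect_error(storeyQ(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("the pi0 smoother is calibrated on uniform nulls", {
  set.seed(6)
  p <- runif(1e4)
  q <- storeyQ(p)
  # recover pi0 via the ratio q/BH on the largest p-value
  pi0hat <- max(q) / max(p.adjust(p, method = "BH"))
  expect_gte(pi0hat, 0.9)
  expect_lte(pi0hat, 1.1)
})

test_that("the wild-type cutoff is the 97.5% quantile of |log2FC|", {
  expect_equal(deriveWTCutoff(rep(0, 100))$wt_quantile, 0)
  set.seed(7)
  sigma <- 0.18
  x <- rnorm(2e4, 0, sigma)
  got <- deriveWTCutoff(x)
  expect_equal(got$fixed_cutoff, 0.3785)
  qa <- sigma * qnorm(0.9875)
  se <- sqrt(0.975 * 0.025 / 2e4) / (2 * dnorm(qnorm(0.9875)) / sigma)
  expect_lt(abs(got$wt_quantile - qa), 3 * se)
  expect_error(deriveWTCutoff(numeric()), "no wild-type")
})

test_that("changing-ion counts map onto the scoring classes", {
  res <- data.frame(
    mutant = rep(c("a", "b", "c", "d"), c(30, 10, 10, 10)),
    condition = "c1",
    significant = c(rep(TRUE, 20), rep(FALSE, 10),  # a: 20 -> many
                    rep(TRUE, 4), rep(FALSE, 6),    # b: 4 -> little
                    rep(TRUE, 5), rep(FALSE, 5),    # c: 5 -> intermediate
                    rep(FALSE, 10)))                # d: 0 -> none
  cc <- callAndCount(res)
  expect_equal(cc$n_changing, c(20, 4, 5, 0))
  expect_equal(as.character(cc$class),
               c("many", "little", "intermediate", "none"))
})

test_that("spiked effects are recovered and boundaries are strict", {
  design <- tinyDesign(8, "c1", seed = 41)
  spikes <- data.frame(mutant = "Site01_OUT", condition = "c1",
                       ion = sprintf("ion%04d", 1:8), log2_effect = 1)
  truth <- makeGroundTruth(design, nIons = 60, spikes = spikes,
                           noiseSigma = 0.05, driftAmplitude = 0.05,
                           seed = 42)
  mset <- simulateIntensities(design, truth)
  rep0 <- runScreen(mset, NULL, screenConfig(seed = 1))
  d <- rep0$differential
  spiked <- d$mutant == "Site01_OUT" & d$ion %in% spikes$ion
  expect_equal(sum(d$significant[spiked]), 8)
  expect_equal(sum(d$significant[!spiked]), 0)
  cc <- callAndCount(d)
  expect_equal(cc$n_changing[cc$mutant == "Site01_OUT"], 8)
  # strictness: q or fold change exactly on the cutoff must not pass
  dd <- data.frame(mutant = "m", condition = "c",
                   median_log2fc = c(0.3785, 0.5, 0.5),
                   q = c(1e-6, 1e-3, 0.5e-3))
  sig <- dd$q < 1e-3 & abs(dd$median_log2fc) > 0.3785
  expect_equal(sig, c(FALSE, FALSE, TRUE))
})
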