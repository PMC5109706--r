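test_that("relaxed hits are thresholded and sorted by absolute change", {
  entries <- data.frame(entry_id = paste0("e", 1:4),
                        ion = paste0("i", 1:4), ion_mz = 1:4,
                        pathway_id = "P", n_lumped = 1L)
  res <- data.frame(ion = paste0("i", 1:4),
                    median_log2fc = c(0.9, -1.2, 0.5, 0.10),
                    p = c(0.01, 0.02, 0.03, 0.001))
  hits <- rankRelaxedHits(res, entries)
  # 0.10 < 0.1375 excluded; order by |log2FC| descending
  expect_equal(hits$ion, c("i2", "i1", "i3"))
  # the relaxed fold-change cutoff corresponds to a 10% change
  expect_equal(round(log2(1.1), 4), 0.1375)
  # p boundary is strict
  res$p <- rep(0.1, 4)
  expect_equal(nrow(rankRelaxedHits(res, entries)), 0)
})

test_that("hypergeometric tail matches combinatorial arithmetic", {
  expect_equal(hypergeomTail(20, 5, 4, 3), 155 / 4845)
  expect_equal(hypergeomTail(50, 10, 4, 0), 1)     # P(X >= 0)
  expect_equal(hypergeomTail(10, 4, 10, 4), 1)     # exhaustive draw
  expect_error(hypergeomTail(10, 11, 2, 1), "<=")
  expect_error(hypergeomTail(10, 4, 2, 3), "<=")
})

test_that("hypergeometric tail equals exhaustive enumeration (small N)", {
  for (N in c(4, 9, 14)) {
    for (K in 0:N) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeomTail(N, K, n, k),
                       enumHyperTail(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("iterative enrichment scans expanding subsets", {
  # population of 50 entries, top hit alone in pathway P with K = 1:
  # best p at subset size 1 is 1/50
  pop <- data.frame(entry_id = paste0("e", 1:50),
                    ion = paste0("i", 1:50), ion_mz = 1:50,
                    pathway_id = c("P", rep("Q", 49)), n_lumped = 1L)
  hits <- pop[1, ]
  hits$median_log2fc <- 2
  hits$p <- 1e-4
  out <- iterativeEnrichment(hits, pop)
  expect_equal(out$best_p[out$pathway_id == "P"], 1 / 50)
  expect_equal(out$best_subset_size[out$pathway_id == "P"], 1L)
  # hits outside every pathway: all best_p = 1
  pop2 <- pop
  pop2$pathway_id <- c(NA, rep("Q", 49))
  hits2 <- pop2[1, ]
  out2 <- iterativeEnrichment(hits2, pop2)
  expect_equal(out2$best_p, 1)
  # empty hit list: p = 1 everywhere
  out3 <- iterativeEnrichment(hits[0, ], pop)
  expect_true(all(out3$best_p == 1))
})

test_that("reported best p never exceeds any fixed-subset-size p", {
  set.seed(9)
  pop <- data.frame(entry_id = paste0("e", 1:40),
                    ion = paste0("i", 1:40), ion_mz = 1:40,
                    pathway_id = sample(c("A", "B", "C"), 40, TRUE),
                    n_lumped = 1L)
  hits <- pop[sample(40, 12), ]
  hits$median_log2fc <- sort(runif(12, 0.2, 2), decreasing = TRUE)
  hits$p <- 1e-3
  out <- iterativeEnrichment(hits, pop)
  for (j in seq_len(nrow(out))) {
    K <- sum(pop$pathway_id == out$pathway_id[j])
    for (s in 1:12) {
      k <- sum(hits$pathway_id[1:s] == out$pathway_id[j])
      expect_lte(out$best_p[j], hypergeomTail(40, K, s, k) + 1e-12)
    }
  }
})

test_that("a pathway-concentrated spike attains the minimum enrichment p", {
  res <- simulateAndScore(screenConfig(seed = 3), nPhosphosites = 6,
                          nMetabolites = 120, nPathways = 6)
  expect_true(res$recovery$spiked_pathway_is_top)
  # and the enrichment grows less significant as signal shrinks to zero
  resNull <- simulateAndScore(screenConfig(seed = 3), nPhosphosites = 6,
                              nMetabolites = 120, nPathways = 6,
                              log2Effect = 0)
  enr <- res$report$enrichment
  enrNull <- resNull$report$enrichment
  best <- min(enr$best_p[enr$mutant == "Site01_OUT" &
                           enr$pathway_id == "PW01"])
  bestNull <- min(enrNull$best_p[enrNull$mutant == "Site01_OUT" &
                                   enrNull$pathway_id == "PW01"])
  expect_lt(best, bestNull)
})
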