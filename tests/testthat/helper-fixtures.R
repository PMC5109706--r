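# Small fixtures built in code, shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A minimal one-batch design: nSites OUT mutants, WT, given conditions.
tinyDesign <- function(nSites = 3, conditions = c("c1", "c2"), seed = 11,
                       ...) {
  generateDesign(nSites, 0, conditions, twoBatches = FALSE, seed = seed,
                 ...)
}

# MetaboSet with hand-set intensities: one batch, explicit ODs.
manualMetaboSet <- function(intensity, od, mutant = NULL,
                            runOrder = NULL) {
  n <- length(od)
  if (is.null(mutant)) mutant <- rep("WT", n)
  if (is.null(runOrder)) runOrder <- seq_len(n)
  man <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                    mutant = mutant, condition = "c1",
                    bio_replicate = seq_len(n), day_replicate = 1L,
                    batch = 1L, run_order = runOrder, od595 = od)
  MetaboSet(intensity, man, mz = seq(100, by = 10,
                                     length.out = nrow(intensity)))
}

# Exhaustive hypergeometric upper tail by direct combinatorial sums:
# the independent oracle for hypergeomTail().
enumHyperTail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
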