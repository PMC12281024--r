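suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Two-sample, six-replicate table of three MOTUs used across curation tests.
# Sample s1 sequences mostly MOTU A, sample s2 mostly MOTU B; replicate
# s1_r3 is orthogonal to everything (all reads on MOTU C).
tinyOutlierTable <- function() {
  counts <- cbind(
    s1_r1 = c(90L, 10L, 0L),
    s1_r2 = c(85L, 15L, 0L),
    s1_r3 = c(0L, 0L, 100L),
    s2_r1 = c(10L, 90L, 0L),
    s2_r2 = c(12L, 88L, 0L),
    s2_r3 = c(8L, 92L, 0L)
  )
  rownames(counts) <- c("A", "B", "C")
  smap <- setNames(rep(c("s1", "s2"), each = 3), colnames(counts))
  ReplicateCounts(counts, smap)
}

tinyMotuMeta <- function(ids, seq_length = 60, total_reads = 1000,
                         best_identity = 0.99, family = "Salicaceae",
                         functional_group = "deciduous_shrub") {
  data.frame(motu_id = ids, seq_length = seq_length,
             total_reads = total_reads, best_identity = best_identity,
             family = family, functional_group = functional_group)
}

# random normalised composition table
randomComposition <- function(nTaxa, nSamples, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(nTaxa * nSamples, 1), nTaxa, nSamples)
  m <- sweep(m, 2, colSums(m), `/`)
  dimnames(m) <- list(sprintf("t%02d", seq_len(nTaxa)),
                      sprintf("s%02d", seq_len(nSamples)))
  m
}

smallStudyConfig <- function(nSamples = 16, ...) {
  studyConfig(nSamples = nSamples, nAsvs = 60, readDepthMean = 2000,
              microbiomeDepthMean = 2000, ...)
}
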