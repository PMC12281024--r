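test_that("identical configurations give byte-identical studies", {
  cfg <- smallStudyConfig(seed = 5)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(assay(dietReplicates(a), "counts"),
                   assay(dietReplicates(b), "counts"))
  expect_identical(assay(microbiomeCounts(a), "counts"),
                   assay(microbiomeCounts(b), "counts"))
  expect_identical(hostData(a), hostData(b))
  expect_identical(truthRegistry(a)@outlierReplicates,
                   truthRegistry(b)@outlierReplicates)
  # a different seed changes the draws
  c <- simulateStudy(smallStudyConfig(seed = 6))
  expect_false(identical(assay(dietReplicates(a), "counts"),
                         assay(dietReplicates(c), "counts")))
})

test_that("rate-zero and count-zero configurations plant nothing", {
  st <- simulateStudy(smallStudyConfig(outlierReplicateRate = 0,
                                       artefactMotuCount = 0, seed = 9))
  reg <- truthRegistry(st)
  expect_length(reg@outlierReplicates, 0)
  expect_equal(nrow(reg@artefactMotus), 0L)
  expect_equal(nrow(dietReplicates(st)), 39L) # no artefact rows
})

test_that("generated tables satisfy their structural invariants", {
  st <- simulateStudy(smallStudyConfig(seed = 13))
  counts <- assay(dietReplicates(st), "counts")
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  # replicate depths within sampling range of the configured mean
  # (Poisson depth 2000 plus a few percent of spiked artefact reads)
  depths <- colSums(counts)
  expect_true(all(depths > 2000 - 6 * sqrt(2000)))
  expect_true(all(depths < 2000 * 1.12 + 6 * sqrt(2000)))
  # true compositions sum to one
  reg <- truthRegistry(st)
  expect_equal(unname(rowSums(reg@trueCompositions)),
               rep(1, nrow(reg@trueCompositions)), tolerance = 1e-9)
  # host invariants
  h <- hostData(st)
  expect_true(all(h$age >= 2))
  expect_true(all(h$body_mass > 0))
  expect_equal(nrow(h), 16L)
  validObject(st)
})

test_that("planted outlier replicates sit farther from their sample mean", {
  gaps <- vapply(1:5, function(s) {
    st <- simulateStudy(studyConfig(nSamples = 30, nAsvs = 20,
                                    readDepthMean = 3000,
                                    microbiomeDepthMean = 500,
                                    outlierReplicateRate = 0.15,
                                    seed = 300 + s))
    x <- dietReplicates(st)
    counts <- assay(x, "counts")
    props <- sweep(counts, 2, colSums(counts), `/`)
    smap <- replicateSamples(x)
    dw <- vapply(colnames(x), function(r) {
      sdx <- names(smap)[smap == smap[r]]
      sqrt(sum((props[, r] - rowMeans(props[, sdx, drop = FALSE]))^2))
    }, numeric(1))
    isOut <- colnames(x) %in% truthRegistry(st)@outlierReplicates
    if (!any(isOut)) return(NA_real_)
    mean(dw[isOut]) - mean(dw[!isOut])
  }, numeric(1))
  expect_true(all(gaps > 0, na.rm = TRUE))
})

test_that("generated latent diversity regresses back to the true Salix slope", {
  aHat <- vapply(1:40, function(s) {
    st <- simulateStudy(studyConfig(nSamples = 48, nAsvs = 20,
                                    readDepthMean = 1500,
                                    microbiomeDepthMean = 500,
                                    seed = 600 + s))
    h <- hostData(st)
    unname(coef(lm(h$diversity_true ~ scale(h$salix_true)))[2])
  }, numeric(1))
  expect_lt(abs(mean(aHat) - 0.3), 0.05)
})

test_that("spiked artefacts each violate their advertised rule", {
  st <- simulateStudy(smallStudyConfig(artefactMotuCount = 0, seed = 31))
  rc <- dietReplicates(st)
  sp <- spikeArtefacts(rc, 4, seed = 77)
  reg <- sp$registry
  expect_equal(reg$reason, c("short", "low_reads", "low_identity", "sub1pct"))
  meta <- motuMeta(sp$table)
  counts <- assay(sp$table, "counts")
  byId <- function(id, col) meta[meta$motu_id == id, col]
  expect_lt(byId(reg$motu_id[1], "seq_length"), 10)
  expect_lte(sum(counts[reg$motu_id[2], ]), 10)
  expect_lt(byId(reg$motu_id[3], "best_identity"), 0.94)
  # sub1pct: below 1% of every replicate depth but above 10 reads total
  depths <- colSums(counts)
  expect_true(all(counts[reg$motu_id[4], ] / depths < 0.01))
  expect_gt(sum(counts[reg$motu_id[4], ]), 10)
  # the full curation pipeline removes exactly the artefacts
  cur <- curateDiet(sp$table)
  removedIds <- c(cur$basicRemoved$motu_id, cur$rraRemoved$motu_id)
  expect_true(all(reg$motu_id %in% removedIds))
  # spiking zero artefacts is the identity
  sp0 <- spikeArtefacts(rc, 0)
  expect_identical(assay(sp0$table, "counts"), assay(rc, "counts"))
})

test_that("configuration validation names the offending field", {
  expect_error(studyConfig(ndviByYear = c(0.2, 0.3)), "ndviByYear")
  expect_error(studyConfig(julyTempByYear = 1:3), "julyTempByYear")
  expect_error(studyConfig(outlierReplicateRate = 1.4),
               "outlierReplicateRate")
  expect_error(studyConfig(nReplicates = 0), "nReplicates")
  expect_error(pathTruth(noiseSdMass = 0), "noiseSdMass")
})
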