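test_that("basic MOTU filter applies the length and read-total boundaries", {
  counts <- cbind(r1 = c(6L, 5L, 4L), r2 = c(5L, 5L, 7L))
  rownames(counts) <- c("keep", "rare", "short")
  meta <- tinyMotuMeta(rownames(counts))
  meta$seq_length <- c(10, 60, 9)
  meta$total_reads <- c(11, 10, 11)
  x <- ReplicateCounts(counts, c(r1 = "s1", r2 = "s2"), meta)
  out <- basicMotuFilter(x)
  # length exactly 10 and total exactly 11 survive; total 10 and length 9 do not
  expect_equal(rownames(out$kept), "keep")
  expect_setequal(out$removed$motu_id, c("rare", "short"))
  expect_equal(out$removed$reason[out$removed$motu_id == "rare"], "low_reads")
  expect_equal(out$removed$reason[out$removed$motu_id == "short"], "short")
  # surviving counts untouched
  expect_equal(assay(out$kept, "counts")["keep", ], counts["keep", ])
})

test_that("basic MOTU filter handles the empty table and missing metadata", {
  counts <- matrix(integer(0), 0, 2,
                   dimnames = list(character(0), c("r1", "r2")))
  x <- ReplicateCounts(counts, c(r1 = "s1", r2 = "s2"))
  out <- basicMotuFilter(x)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(nrow(out$removed), 0L)
  counts2 <- cbind(r1 = c(5L, 5L), r2 = c(5L, 5L))
  rownames(counts2) <- c("A", "B")
  x2 <- ReplicateCounts(counts2, c(r1 = "s1", r2 = "s2"))
  expect_error(basicMotuFilter(x2), "seq_length")
  expect_error(
    ReplicateCounts(counts2, c(r1 = "s1", r2 = "s2"), tinyMotuMeta("A")),
    "B")
})

test_that("replicate averaging weights replicates equally", {
  counts <- cbind(r1 = c(30L, 70L), r2 = c(50L, 50L))
  rownames(counts) <- c("A", "B")
  x <- ReplicateCounts(counts, c(r1 = "s1", r2 = "s1"))
  comp <- collapseReplicates(x)
  expect_equal(unname(assay(comp, "rra")[, "s1"]), c(0.4, 0.6))
  # single replicate
  x1 <- ReplicateCounts(counts[, 1, drop = FALSE], c(r1 = "s1"))
  expect_equal(unname(assay(collapseReplicates(x1), "rra")[, "s1"]),
               c(0.3, 0.7))
  # scaling one replicate's depth by 10 changes nothing (proportions first)
  counts10 <- counts
  counts10[, "r2"] <- counts10[, "r2"] * 10L
  x10 <- ReplicateCounts(counts10, c(r1 = "s1", r2 = "s1"))
  expect_equal(assay(collapseReplicates(x10), "rra"),
               assay(comp, "rra"))
  # zero-read replicate is an error
  counts0 <- cbind(counts, r3 = c(0L, 0L))
  x0 <- ReplicateCounts(counts0, c(r1 = "s1", r2 = "s1", r3 = "s1"))
  expect_error(collapseReplicates(x0), "r3")
})

test_that("identical replicates yield dw = 0 and a single quiet iteration", {
  counts <- cbind(s1_r1 = c(50L, 50L), s1_r2 = c(50L, 50L),
                  s2_r1 = c(80L, 20L), s2_r2 = c(80L, 20L))
  rownames(counts) <- c("A", "B")
  smap <- setNames(c("s1", "s1", "s2", "s2"), colnames(counts))
  res <- replicateOutlierFilter(ReplicateCounts(counts, smap))
  expect_equal(res@iterations, 1L)
  expect_equal(nrow(removedReplicates(res)), 0L)
  expect_equal(length(removedSamples(res)), 0L)
  expect_equal(ncol(keptReplicates(res)), 4L)
})

test_that("an orthogonal replicate is the one removed (hand-checked case)", {
  x <- tinyOutlierTable()
  res <- replicateOutlierFilter(x)
  expect_equal(removedReplicates(res)$replicate_id, "s1_r3")
  expect_equal(length(removedSamples(res)), 0L)
  expect_setequal(colnames(keptReplicates(res)),
                  setdiff(colnames(x), "s1_r3"))
  # hand computation of the first-iteration dw for the orthogonal replicate:
  # proportions of s1: r1 = (.9,.1,0), r2 = (.85,.15,0), r3 = (0,0,1)
  # average = (.58333, .08333, .33333); dw(r3) = sqrt(sum((r3 - avg)^2))
  avg <- colMeans(rbind(c(.9, .1, 0), c(.85, .15, 0), c(0, 0, 1)))
  dwHand <- sqrt(sum((c(0, 0, 1) - avg)^2))
  got <- removedReplicates(res)$dw[1]
  expect_equal(got, dwHand, tolerance = 1e-12)
  # and dw of the orthogonal replicate exceeds every other first-round dw
  props <- sweep(assay(x, "counts"), 2, colSums(assay(x, "counts")), `/`)
  smap <- replicateSamples(x)
  dwAll <- vapply(colnames(x), function(r) {
    s <- smap[r]
    sqrt(sum((props[, r] -
                rowMeans(props[, names(smap)[smap == s], drop = FALSE]))^2))
  }, numeric(1))
  expect_equal(names(which.max(dwAll)), "s1_r3")
})

test_that("the outlier filter terminates, is idempotent, and audits removals", {
  st <- simulateStudy(studyConfig(nSamples = 24, nAsvs = 30,
                                  readDepthMean = 3000,
                                  microbiomeDepthMean = 1000, seed = 21))
  x <- basicMotuFilter(dietReplicates(st))$kept
  res <- replicateOutlierFilter(x)
  expect_lte(res@iterations, ncol(x))
  expect_equal(length(filterThresholds(res)), res@iterations)
  # removed replicates never reappear
  expect_false(any(removedReplicates(res)$replicate_id %in%
                     colnames(keptReplicates(res))))
  # idempotence after convergence
  again <- replicateOutlierFilter(keptReplicates(res))
  expect_equal(nrow(removedReplicates(again)), 0L)
  expect_equal(length(removedSamples(again)), 0L)
})

test_that("the outlier filter refuses degenerate inputs", {
  counts <- cbind(s1_r1 = c(10L, 5L), s1_r2 = c(9L, 6L))
  rownames(counts) <- c("A", "B")
  x <- ReplicateCounts(counts, setNames(c("s1", "s1"), colnames(counts)))
  expect_error(replicateOutlierFilter(x), "two samples")
})

test_that("RRA and identity filters apply the 1% and 94% rules", {
  rra <- cbind(s1 = c(0.694, 0.3, 0.004, 0.002),
               s2 = c(0.194, 0.5, 0.3, 0.006))
  rownames(rra) <- c("ok1", "badId", "ok2", "rare")
  meta <- tinyMotuMeta(rownames(rra))
  meta$best_identity <- c(0.99, 0.939, 0.95, 0.99)
  comp <- SampleComposition(rra, level = "motu", motuMeta = meta)
  out <- rraIdentityFilter(comp)
  # rare: max RRA 0.006 < 1%; badId: identity 0.939 < 94% despite RRA 0.5
  expect_setequal(out$removed$motu_id, c("badId", "rare"))
  expect_equal(out$removed$reason[out$removed$motu_id == "badId"],
               "low_identity")
  expect_equal(out$removed$reason[out$removed$motu_id == "rare"], "sub1pct")
  # survivors renormalised; discarded mass logged
  expect_equal(unname(colSums(assay(out$kept, "rra"))), c(1, 1))
  expect_equal(unname(metadata(out$kept)$discarded_mass),
               c(1 - 0.698, 1 - 0.494), tolerance = 1e-12)
  # a table whose MOTUs all pass comes back unchanged
  meta2 <- tinyMotuMeta(c("a", "b"))
  rra2 <- cbind(s1 = c(0.6, 0.4), s2 = c(0.2, 0.8))
  rownames(rra2) <- c("a", "b")
  comp2 <- SampleComposition(rra2, level = "motu", motuMeta = meta2)
  out2 <- rraIdentityFilter(comp2)
  expect_equal(nrow(out2$removed), 0L)
  expect_equal(assay(out2$kept, "rra"), rra2)
})

test_that("taxonomic aggregation sums groups and conserves column sums", {
  rra <- cbind(s1 = c(0.2, 0.3, 0.5), s2 = c(0.1, 0.1, 0.8))
  rownames(rra) <- c("m1", "m2", "m3")
  meta <- tinyMotuMeta(rownames(rra))
  meta$family <- c("Poaceae", "Poaceae", "Salicaceae")
  comp <- SampleComposition(rra, level = "motu", motuMeta = meta)
  fam <- aggregateTaxonomy(comp, "family")
  expect_equal(rownames(fam), c("Poaceae", "Salicaceae")) # lexicographic
  expect_equal(unname(assay(fam, "rra")["Poaceae", ]), c(0.5, 0.2))
  # every MOTU its own family: output equals input (up to row order)
  meta$family <- c("F1", "F2", "F3")
  comp1 <- SampleComposition(rra, level = "motu", motuMeta = meta)
  fam1 <- aggregateTaxonomy(comp1, "family")
  expect_equal(unname(assay(fam1, "rra")), unname(rra))
  # conservation property over random tables
  for (seed in 1:5) {
    m <- randomComposition(12, 6, seed = seed)
    metaR <- tinyMotuMeta(rownames(m))
    metaR$family <- sample(c("Fa", "Fb", "Fc"), 12, replace = TRUE)
    cR <- SampleComposition(m, level = "motu", motuMeta = metaR)
    fR <- aggregateTaxonomy(cR, "family")
    expect_equal(colSums(assay(fR, "rra")), colSums(m), tolerance = 1e-12)
  }
  # missing label errors naming the MOTU
  metaNA <- tinyMotuMeta(rownames(rra))
  metaNA$family[2] <- NA
  compNA <- SampleComposition(rra, level = "motu", motuMeta = metaNA)
  expect_error(aggregateTaxonomy(compNA, "family"), "m2")
})

test_that("the full pipeline removes nothing from a defect-free study", {
  st <- simulateStudy(studyConfig(outlierReplicateRate = 0,
                                  artefactMotuCount = 0, seed = 2))
  expect_length(truthRegistry(st)@outlierReplicates, 0)
  cur <- curateDiet(dietReplicates(st))
  expect_equal(nrow(cur$basicRemoved), 0L)
  expect_equal(nrow(removedReplicates(cur$outlier)), 0L)
  expect_equal(length(removedSamples(cur$outlier)), 0L)
  expect_equal(nrow(cur$rraRemoved), 0L)
  expect_equal(ncol(cur$composition), 97L)
})

test_that("planted outliers are purged with few innocent casualties", {
  sens <- fpr <- numeric(3)
  for (i in 1:3) {
    st <- simulateStudy(studyConfig(seed = 400 + i))
    rc <- dietReplicates(st)
    cur <- curateDiet(rc)
    reg <- truthRegistry(st)
    keptreps <- colnames(keptReplicates(cur$outlier))
    nonout <- setdiff(colnames(rc), reg@outlierReplicates)
    sens[i] <- mean(!reg@outlierReplicates %in% keptreps)
    fpr[i] <- mean(!nonout %in% keptreps)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.05)
})
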