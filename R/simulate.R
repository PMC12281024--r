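#' Ground-truth path coefficients
#'
#' Constructor for [PathTruth-class].  The coefficients are standardised:
#' body mass is generated on a scale where its total standard deviation is
#' one unit (of \code{massScaleKg} kilograms), with every systematic
#' component — the direct and mediated paths, the valley offsets and the
#' quadratic age effect — inside that unit variance.  The default residual
#' standard deviation 0.758 completes the default configuration's total
#' variance to one, so ordinary least squares on z-scored variables
#' (adjusting for valley and age) recovers the generating coefficients as
#' its estimands.
#'
#' @param aTrue standardised Salix -> diversity coefficient (|a| < 1)
#' @param bTrue standardised diversity -> mass coefficient
#' @param cDirectTrue standardised direct Salix -> mass coefficient
#' @param lactationInteraction extra Salix slope for lactating females
#'   (default 0: the mediation triangle alone)
#' @param valleyMassOffsets additive kg offsets, one per valley
#' @param noiseSdMass residual sd of the standardised mass equation
#' @return a [PathTruth-class] object
#' @export
pathTruth <- function(aTrue = 0.3, bTrue = -0.25, cDirectTrue = 0.4,
                      lactationInteraction = 0,
                      valleyMassOffsets = c(-1.5, -0.5, 0.5, 1.5),
                      noiseSdMass = 0.758) {
  new("PathTruth", aTrue = aTrue, bTrue = bTrue, cDirectTrue = cDirectTrue,
      lactationInteraction = lactationInteraction,
      valleyMassOffsets = valleyMassOffsets, noiseSdMass = noiseSdMass)
}

#' Configuration of a synthetic metabarcoding study
#'
#' Builds a [StudyConfig-class] whose defaults emulate a seven-year,
#' four-valley Svalbard reindeer rumen study: 97 sampled females, three PCR
#' replicates each, a diet of 39 plant MOTUs in 14 families and 8
#' functional groups dominated by the dwarf shrub \emph{Salix}, annual
#' maximum NDVI rising over the years around a mean of 0.226 and July
#' temperatures fluctuating around 6.9 degrees C without trend.  The
#' per-sample Salix share of the diet increases with the year's NDVI
#' (logistic-linear on the Dirichlet mean) and the grass share with July
#' temperature.  A configurable fraction of PCR replicates (default 10\%)
#' is planted as outliers drawn from an unrelated composition, and
#' \code{artefactMotuCount} artefact MOTUs are spiked in, each built to
#' violate one curation rule.
#'
#' @param nValleys,nYears sampling design dimensions
#' @param nSamples total number of sampled individuals, allocated
#'   round-robin over the valley x year grid
#' @param nReplicates PCR replicates per sample
#' @param nMotus,nFamilies,nFunctionalGroups diet table dimensions
#' @param readDepthMean mean sequencing depth per PCR replicate (Poisson)
#' @param overdispersion Dirichlet concentration scale of the true diet
#'   compositions; larger is less between-animal spread
#' @param outlierReplicateRate probability a replicate is a planted outlier
#' @param artefactMotuCount number of artefact MOTUs to spike in
#' @param ndviByYear annual maximum NDVI, one value per year in [-1, 1]
#' @param julyTempByYear mean July temperature per year (degrees C)
#' @param salixNdviSlope logit-scale slope of the Salix Dirichlet mean on
#'   (NDVI - mean NDVI)
#' @param grassTempSlope logit-scale slope of the grass Dirichlet mean on
#'   (July temperature - mean)
#' @param nAsvs number of microbiome ASVs
#' @param microbiomeDepthMean mean microbiome library size (Poisson)
#' @param massBaselineKg baseline October body mass
#' @param massScaleKg kg per unit of the standardised mass combination
#' @param pathTruth a [PathTruth-class] (see [pathTruth()])
#' @param seed integer seed; identical configurations give byte-identical
#'   studies
#' @return a [StudyConfig-class] object
#' @export
studyConfig <- function(nValleys = 4, nYears = 7, nSamples = 97,
                        nReplicates = 3, nMotus = 39, nFamilies = 14,
                        nFunctionalGroups = 8, readDepthMean = 10000,
                        overdispersion = 60, outlierReplicateRate = 0.1,
                        artefactMotuCount = 4,
                        ndviByYear = c(0.17, 0.19, 0.20, 0.22, 0.24, 0.26, 0.28),
                        julyTempByYear = c(8.1, 6.3, 6.9, 6.1, 7.4, 6.5, 7.2),
                        salixNdviSlope = 6, grassTempSlope = 0.4,
                        nAsvs = 400, microbiomeDepthMean = 30000,
                        massBaselineKg = 49, massScaleKg = 5,
                        pathTruth = metabarDiet::pathTruth(), seed = 1) {
  new("StudyConfig",
      nValleys = as.integer(nValleys), nYears = as.integer(nYears),
      nSamples = as.integer(nSamples), nReplicates = as.integer(nReplicates),
      nMotus = as.integer(nMotus), nFamilies = as.integer(nFamilies),
      nFunctionalGroups = as.integer(nFunctionalGroups),
      readDepthMean = as.integer(readDepthMean),
      overdispersion = as.numeric(overdispersion),
      outlierReplicateRate = as.numeric(outlierReplicateRate),
      artefactMotuCount = as.integer(artefactMotuCount),
      ndviByYear = as.numeric(ndviByYear),
      julyTempByYear = as.numeric(julyTempByYear),
      salixNdviSlope = as.numeric(salixNdviSlope),
      grassTempSlope = as.numeric(grassTempSlope),
      nAsvs = as.integer(nAsvs),
      microbiomeDepthMean = as.integer(microbiomeDepthMean),
      massBaselineKg = as.numeric(massBaselineKg),
      massScaleKg = as.numeric(massScaleKg),
      pathTruth = pathTruth, seed = as.integer(seed))
}

# Deterministic per-stage sub-seed so adding a stage never perturbs the
# draws of earlier stages.  Kept below 2^31 - 1.
.subSeed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 2147483647) * 7919 + stage * 104729) %%
               2147483647)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

.valleyNames <- c("Eskerdalen", "Sassendalen", "Colesdalen", "Semmeldalen")
# logits of valley-mean Salix diet shares of roughly 0.25, 0.47, 0.74, 0.92
.valleySalixLogit <- c(-1.1, -0.13, 1.07, 2.39)

.familyPool <- c("Salicaceae", "Poaceae", "Cyperaceae", "Juncaceae",
                 "Ericaceae", "Equisetaceae", "Fabaceae", "Rosaceae",
                 "Saxifragaceae", "Brassicaceae", "Polygonaceae",
                 "Ranunculaceae", "Caryophyllaceae", "Asteraceae")
.groupOfFamily <- c(Salicaceae = "deciduous_shrub", Poaceae = "grass",
                    Cyperaceae = "sedge", Juncaceae = "rush",
                    Ericaceae = "evergreen_shrub", Equisetaceae = "horsetail",
                    Fabaceae = "legume", Rosaceae = "forb",
                    Saxifragaceae = "forb", Brassicaceae = "forb",
                    Polygonaceae = "forb", Ranunculaceae = "forb",
                    Caryophyllaceae = "forb", Asteraceae = "forb")

.makeMotuMeta <- function(config) {
  nm <- config@nMotus
  ids <- sprintf("MOTU_%03d", seq_len(nm))
  fams <- rep(.familyPool, length.out = max(config@nFamilies, 1))[
    seq_len(config@nFamilies)]
  # MOTU 1 is Salix; MOTUs 2-3 grasses; the rest cycle over the remaining
  # families so every family is represented
  famOf <- character(nm)
  famOf[1] <- fams[1]
  if (nm >= 2) famOf[2] <- fams[min(2, length(fams))]
  if (nm >= 3) famOf[3] <- fams[min(2, length(fams))]
  if (nm >= 4) {
    rest <- fams[-1]
    famOf[4:nm] <- rep(rest, length.out = nm - 3)
  }
  groups <- unname(.groupOfFamily[famOf])
  # collapse to the configured number of functional groups
  uniq <- unique(unname(.groupOfFamily[fams]))
  if (length(uniq) > config@nFunctionalGroups) {
    keepG <- uniq[seq_len(config@nFunctionalGroups)]
    groups[!groups %in% keepG] <- keepG[length(keepG)]
  }
  data.frame(
    motu_id = ids,
    seq_length = sample(15:120, nm, replace = TRUE),
    total_reads = NA_real_, # filled in once counts are drawn
    best_identity = round(stats::runif(nm, 0.95, 1), 4),
    family = famOf,
    functional_group = groups
  )
}

#' Simulate a complete synthetic study
#'
#' Generates one full study from a [StudyConfig-class]: true per-sample
#' diet compositions drawn from valley/year Dirichlet distributions whose
#' Salix mean increases with that year's NDVI and whose grass mean
#' increases with July temperature; PCR replicates as multinomial draws of
#' the true composition at Poisson depths, with a configurable fraction of
#' planted outlier replicates drawn from an unrelated symmetric
#' Dirichlet(1) composition; artefact MOTUs each violating one curation
#' rule; a microbiome mixing two community archetypes with weight driven by
#' the sample's Salix share (so expected microbiome diversity increases
#' with Salix); and host body mass generated from the true path
#' coefficients (valley offset + quadratic age effect + direct Salix path
#' + diversity-mediated path + noise), with latent diversity itself
#' a * z(Salix) + noise.  Everything planted is recorded in the
#' [TruthRegistry-class].  Identical configurations (including the seed)
#' give byte-identical output.
#'
#' @param config a [StudyConfig-class], see [studyConfig()]
#' @return a [SyntheticStudy-class]
#' @examples
#' study <- simulateStudy(studyConfig(nSamples = 12, nAsvs = 50,
#'   readDepthMean = 2000, microbiomeDepthMean = 2000, seed = 7))
#' study
#' @export
simulateStudy <- function(config = studyConfig()) {
  stopifnot(is(config, "StudyConfig"))
  validObject(config)
  truth <- config@pathTruth
  if (abs(truth@aTrue) >= 1)
    stop("|aTrue| must be < 1 (diversity is generated on a standardised scale)")

  ## stage 1: sampling design ----------------------------------------------
  set.seed(.subSeed(config@seed, 1L))
  valleys <- rep(.valleyNames, length.out = config@nValleys)
  years <- 1998L + seq_len(config@nYears) - 1L
  cells <- expand.grid(valley = seq_len(config@nValleys),
                       year = seq_len(config@nYears))
  cellOf <- rep(seq_len(nrow(cells)), length.out = config@nSamples)
  sampleIds <- sprintf("S%03d", seq_len(config@nSamples))
  valleyIdx <- cells$valley[cellOf]
  yearIdx <- cells$year[cellOf]
  age <- sample(2:12, config@nSamples, replace = TRUE)
  lactating <- stats::rbinom(config@nSamples, 1, 0.5) == 1

  ## stage 2: MOTU metadata -------------------------------------------------
  set.seed(.subSeed(config@seed, 2L))
  meta <- .makeMotuMeta(config)

  ## stage 3: true diet compositions ---------------------------------------
  set.seed(.subSeed(config@seed, 3L))
  ndvi <- config@ndviByYear[yearIdx]
  temp <- config@julyTempByYear[yearIdx]
  vl <- rep(.valleySalixLogit, length.out = config@nValleys)[valleyIdx]
  salixMean <- stats::plogis(vl + config@salixNdviSlope *
                               (ndvi - mean(config@ndviByYear)))
  grassMean <- stats::plogis(stats::qlogis(0.045) + config@grassTempSlope *
                               (temp - mean(config@julyTempByYear)))
  nm <- config@nMotus
  otherW <- if (nm > 2) 0.97^seq_len(nm - 2) else numeric(0)
  trueComp <- matrix(0, config@nSamples, nm,
                     dimnames = list(sampleIds, meta$motu_id))
  for (i in seq_len(config@nSamples)) {
    sg <- salixMean[i] + grassMean[i]
    scaleBack <- if (sg > 0.95) 0.95 / sg else 1
    mv <- numeric(nm)
    mv[1] <- salixMean[i] * scaleBack
    if (nm >= 2) mv[2] <- grassMean[i] * scaleBack
    if (nm > 2) mv[3:nm] <- (1 - mv[1] - mv[2]) * otherW / sum(otherW)
    trueComp[i, ] <- .rdirichlet(config@overdispersion * mv)
  }
  salixTrue <- trueComp[, 1]

  ## stage 4: PCR replicate counts with planted outliers --------------------
  set.seed(.subSeed(config@seed, 4L))
  repIds <- as.vector(t(outer(sampleIds, seq_len(config@nReplicates),
                              function(s, r) sprintf("%s_r%d", s, r))))
  repSample <- rep(sampleIds, each = config@nReplicates)
  counts <- matrix(0L, nm, length(repIds),
                   dimnames = list(meta$motu_id, repIds))
  isOutlier <- stats::runif(length(repIds)) < config@outlierReplicateRate
  for (j in seq_along(repIds)) {
    depth <- stats::rpois(1, config@readDepthMean)
    comp <- if (isOutlier[j]) .rdirichlet(rep(1, nm))
            else trueComp[repSample[j], ]
    counts[, j] <- stats::rmultinom(1, size = max(depth, 1L), prob = comp)
  }
  meta$total_reads <- rowSums(counts)
  rc <- ReplicateCounts(counts, stats::setNames(repSample, repIds), meta)

  ## stage 5: artefact MOTUs -------------------------------------------------
  spiked <- spikeArtefacts(rc, config@artefactMotuCount,
                           seed = .subSeed(config@seed, 5L))
  rc <- spiked$table

  ## stage 6: latent diversity and body mass --------------------------------
  set.seed(.subSeed(config@seed, 6L))
  zS <- as.numeric(scale(salixTrue))
  divZ <- truth@aTrue * zS +
    sqrt(1 - truth@aTrue^2) * stats::rnorm(config@nSamples)
  # valley and age effects enter the standardised mass combination (in
  # units of massScaleKg) so the total variance stays near one and the
  # generating coefficients remain the standardised estimands
  vW <- rep(truth@valleyMassOffsets, length.out = config@nValleys)[valleyIdx] /
    config@massScaleKg
  aW <- (-0.15 * (age - 7)^2) / config@massScaleKg
  massZ <- truth@cDirectTrue * zS + truth@bTrue * divZ +
    truth@lactationInteraction * zS * lactating +
    (vW - mean(vW)) + (aW - mean(aW)) +
    truth@noiseSdMass * stats::rnorm(config@nSamples)
  bodyMass <- config@massBaselineKg + config@massScaleKg * massZ

  ## stage 7: microbiome -----------------------------------------------------
  set.seed(.subSeed(config@seed, 7L))
  na <- config@nAsvs
  archDiverse <- {
    w <- seq_len(na)^-0.7; w / sum(w)
  }
  archDominated <- {
    w <- seq_len(na)^-1.6
    w <- w[sample.int(na)] # decouple the rank orders of the two archetypes
    w / sum(w)
  }
  asvIds <- sprintf("ASV_%04d", seq_len(na))
  micro <- matrix(0L, na, config@nSamples,
                  dimnames = list(asvIds, sampleIds))
  wMix <- pmin(pmax(salixTrue + stats::rnorm(config@nSamples, 0, 0.1), 0), 1)
  for (i in seq_len(config@nSamples)) {
    mv <- wMix[i] * archDiverse + (1 - wMix[i]) * archDominated
    comp <- .rdirichlet(40 * mv)
    depth <- stats::rpois(1, config@microbiomeDepthMean)
    micro[, i] <- stats::rmultinom(1, size = max(depth, 1L), prob = comp)
  }
  phyla <- sample(c("Bacteroidota", "Firmicutes", "Proteobacteria",
                    "Actinobacteriota", "Spirochaetota", "Verrucomicrobiota"),
                  na, replace = TRUE,
                  prob = c(0.385, 0.428, 0.06, 0.06, 0.035, 0.032))
  famPool <- c("Prevotellaceae", "Lachnospiraceae", "Ruminococcaceae",
               "Rikenellaceae", "Oscillospiraceae", "Fibrobacteraceae",
               "Christensenellaceae", "Akkermansiaceae")
  asvFam <- ifelse(stats::runif(na) < 0.6,
                   sample(famPool, na, replace = TRUE), NA_character_)
  mb <- MicrobiomeCounts(micro, data.frame(asv_id = asvIds, phylum = phyla,
                                           family = asvFam))

  hosts <- data.frame(
    sample_id = sampleIds,
    valley = valleys[valleyIdx],
    year = years[yearIdx],
    age = age,
    lactating = lactating,
    body_mass = bodyMass,
    ndvi_max = ndvi,
    july_temp = temp,
    salix_true = salixTrue,
    diversity_true = divZ
  )

  registry <- new("TruthRegistry",
                  trueCompositions = trueComp,
                  outlierReplicates = repIds[isOutlier],
                  artefactMotus = spiked$registry)

  new("SyntheticStudy", replicates = rc, microbiome = mb,
      hosts = hosts, truth = registry, config = config)
}

#' Spike artefact MOTUs into a replicate count table
#'
#' Adds \code{n} artefact MOTUs, cycling over the four defect classes the
#' curation filters target: \code{"short"} (amplicon below 10 nt),
#' \code{"low_reads"} (dataset total of at most 10 reads),
#' \code{"low_identity"} (best-identity below 94\% but abundant), and
#' \code{"sub1pct"} (never reaching 1\% relative abundance in any sample
#' but with an unremarkable read total).  Each artefact is built to trip
#' its own rule while passing the others where the rules are not logically
#' coupled (a 10-read MOTU is necessarily also below 1\% RRA; it is removed
#' by the basic read-total filter before the abundance rule is consulted).
#'
#' @param x a [ReplicateCounts-class]
#' @param n number of artefact MOTUs to add (0 returns the input unchanged)
#' @param seed integer seed
#' @return list with \code{table} (the augmented [ReplicateCounts-class])
#'   and \code{registry} (data.frame with columns motu_id, reason)
#' @export
spikeArtefacts <- function(x, n, seed = 1) {
  stopifnot(is(x, "ReplicateCounts"), n >= 0)
  emptyReg <- data.frame(motu_id = character(0), reason = character(0))
  if (n == 0)
    return(list(table = x, registry = emptyReg))
  set.seed(seed)
  counts <- assay(x, "counts")
  nRep <- ncol(counts)
  depths <- pmax(colSums(counts), 1)
  reasons <- rep(c("short", "low_reads", "low_identity", "sub1pct"),
                 length.out = n)
  newRows <- matrix(0L, n, nRep)
  metaAdd <- data.frame(
    motu_id = sprintf("ART_%02d", seq_len(n)),
    seq_length = NA_real_, total_reads = NA_real_,
    best_identity = NA_real_,
    family = "Salicaceae", functional_group = "deciduous_shrub",
    reason = reasons
  )
  for (k in seq_len(n)) {
    r <- reasons[k]
    len <- 60; ident <- 0.99
    if (r == "short") {
      len <- 8
      newRows[k, ] <- stats::rpois(nRep, 0.02 * depths)
    } else if (r == "low_reads") {
      j <- sample.int(nRep, 1)
      newRows[k, j] <- 10L
    } else if (r == "low_identity") {
      ident <- 0.90
      newRows[k, ] <- stats::rpois(nRep, 0.03 * depths)
    } else { # sub1pct: ~0.3% of depth everywhere, totals well above 10
      newRows[k, ] <- stats::rpois(nRep, 0.003 * depths)
    }
    metaAdd$seq_length[k] <- len
    metaAdd$best_identity[k] <- ident
  }
  # guard the constructions that depend on random draws
  short <- reasons == "sub1pct"
  if (any(short)) {
    mx <- apply(sweep(newRows[short, , drop = FALSE], 2, depths, `/`), 1, max)
    # cap any draw that strays to >= 1% of its replicate depth
    for (k in which(short)[mx >= 0.01]) {
      newRows[k, ] <- pmin(newRows[k, ],
                           as.integer(floor(0.009 * depths)))
    }
    tot <- rowSums(newRows[short, , drop = FALSE])
    for (k in which(short)[tot <= 10]) newRows[k, 1] <- 11L
  }
  metaAdd$total_reads <- rowSums(newRows)
  rownames(newRows) <- metaAdd$motu_id
  oldMeta <- motuMeta(x)
  oldMeta$total_reads <- rowSums(counts)
  combMeta <- rbind(oldMeta[c("motu_id", .motuMetaColumns)],
                    metaAdd[c("motu_id", .motuMetaColumns)])
  comb <- rbind(counts, newRows)
  out <- ReplicateCounts(comb, replicateSamples(x), combMeta)
  list(table = out,
       registry = metaAdd[, c("motu_id", "reason")])
}
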