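#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData `colData<-` `rowData<-` `assay<-`
NULL

.checkCountAssay <- function(object, assayName = "counts") {
  msg <- character()
  if (!assayName %in% names(assays(object)))
    return(sprintf("assay '%s' is required", assayName))
  m <- assay(object, assayName)
  if (anyNA(m) || any(!is.finite(m)))
    msg <- c(msg, sprintf("assay '%s' contains NA or non-finite values", assayName))
  else if (any(m < 0))
    msg <- c(msg, sprintf("assay '%s' contains negative values", assayName))
  if ((nrow(object) > 0 && is.null(rownames(object))) ||
      (ncol(object) > 0 && is.null(colnames(object))))
    msg <- c(msg, "row and column names are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicated row (taxon) ids")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicated column ids")
  }
  msg
}

#' Replicate-level MOTU read counts
#'
#' A \linkS4class{SummarizedExperiment} holding integer read counts per MOTU
#' (rows) and PCR replicate (columns).  The replicate-to-sample map lives in
#' \code{colData(x)$sample_id}; per-MOTU metadata (amplicon length, total
#' reads, best-identity fraction, plant family, functional group) lives in
#' \code{rowData(x)}.  This is the input of the curation pipeline.
#'
#' @seealso [ReplicateCounts()], [basicMotuFilter()], [replicateOutlierFilter()]
#' @aliases ReplicateCounts-class
#' @exportClass ReplicateCounts
setClass("ReplicateCounts", contains = "SummarizedExperiment")

setValidity("ReplicateCounts", function(object) {
  msg <- .checkCountAssay(object, "counts")
  if (length(msg))
    return(msg)
  m <- assay(object, "counts")
  if (any(abs(m - round(m)) > 1e-8))
    msg <- c(msg, "read counts must be integral")
  if (!"sample_id" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'sample_id' column (replicate -> sample map)")
  else if (anyNA(colData(object)$sample_id))
    msg <- c(msg, "sample_id contains NA")
  if (length(msg)) msg else TRUE
})

#' Per-sample relative read abundances
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"rra"}: taxa (MOTUs,
#' families or functional groups) as rows, samples as columns, each column
#' summing to one when normalised.  \code{metadata(x)$level} records the
#' taxonomic level and \code{metadata(x)$normalised} whether columns are
#' proportions.
#'
#' @aliases SampleComposition-class
#' @exportClass SampleComposition
setClass("SampleComposition", contains = "SummarizedExperiment")

setValidity("SampleComposition", function(object) {
  msg <- character()
  if (!"rra" %in% names(assays(object)))
    return("assay 'rra' is required")
  m <- assay(object, "rra")
  if (anyNA(m) || any(m < -1e-12) || any(m > 1 + 1e-9))
    msg <- c(msg, "rra values must lie in [0, 1]")
  lev <- metadata(object)$level
  if (is.null(lev) || !lev %in% c("motu", "family", "functional_group"))
    msg <- c(msg, "metadata level must be one of 'motu', 'family', 'functional_group'")
  norm <- metadata(object)$normalised
  if (isTRUE(norm) && ncol(m) > 0L) {
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "normalised composition columns must sum to 1 (tolerance 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Microbiome ASV counts
#'
#' A \linkS4class{SummarizedExperiment} of 16S amplicon sequence variant (ASV)
#' read counts, ASVs as rows and samples as columns.  \code{rowData(x)} may
#' carry \code{phylum} and \code{family} labels; partial taxonomy (NA) is
#' allowed, as family-level assignment rates below 100\% are the norm.
#'
#' @aliases MicrobiomeCounts-class
#' @exportClass MicrobiomeCounts
setClass("MicrobiomeCounts", contains = "SummarizedExperiment")

setValidity("MicrobiomeCounts", function(object) {
  msg <- .checkCountAssay(object, "counts")
  if (length(msg)) msg else TRUE
})

#' Result of the iterative PCR-replicate outlier filter
#'
#' Holds the filtered replicate table plus a full audit trail: which
#' replicates were removed at which iteration (with their within-sample
#' distance dw), which samples were dropped for retaining fewer than two
#' replicates, and the dissimilarity threshold used at each iteration.
#'
#' @slot kept filtered [ReplicateCounts] object
#' @slot removedReplicates data.frame with columns \code{replicate_id},
#'   \code{sample_id}, \code{iteration}, \code{dw}
#' @slot removedSamples character vector of dropped sample ids
#' @slot thresholds numeric, one dissimilarity threshold per iteration
#' @slot iterations integer, number of iterations run (>= 1)
#' @aliases CurationResult-class
#' @exportClass CurationResult
setClass("CurationResult",
  representation(
    kept = "ReplicateCounts",
    removedReplicates = "data.frame",
    removedSamples = "character",
    thresholds = "numeric",
    iterations = "integer"
  )
)

setValidity("CurationResult", function(object) {
  msg <- character()
  if (object@iterations < 1L)
    msg <- c(msg, "iterations must be >= 1")
  if (length(object@thresholds) != object@iterations)
    msg <- c(msg, "one threshold per iteration is required")
  need <- c("replicate_id", "sample_id", "iteration", "dw")
  if (!all(need %in% colnames(object@removedReplicates)))
    msg <- c(msg, "removedReplicates must have columns replicate_id, sample_id, iteration, dw")
  else if (any(object@removedReplicates$replicate_id %in% colnames(object@kept)))
    msg <- c(msg, "a removed replicate reappears in the kept table")
  if (length(msg)) msg else TRUE
})

#' Permutation test result
#'
#' @slot statistic observed statistic
#' @slot method label of the statistic (e.g. "pearson", "spearman")
#' @slot nPerm number of random permutations
#' @slot pValue one-sided permutation p-value, computed as
#'   (number of null statistics >= observed + 1) / (nPerm + 1)
#' @slot seed integer seed used for the permutation stream
#' @slot nullStatistics the null statistics (possibly empty if not stored)
#' @aliases PermutationTestResult-class
#' @exportClass PermutationTestResult
setClass("PermutationTestResult",
  representation(
    statistic = "numeric",
    method = "character",
    nPerm = "integer",
    pValue = "numeric",
    seed = "integer",
    nullStatistics = "numeric"
  )
)

setValidity("PermutationTestResult", function(object) {
  msg <- character()
  if (length(object@pValue) != 1L || object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must be a single value in (0, 1]")
  if (object@nPerm < 1L)
    msg <- c(msg, "nPerm must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Sequential (by-terms) PERMANOVA table
#'
#' Rows are the model terms in fitting order, followed by \code{Residual} and
#' \code{Total}.  Columns: degrees of freedom, sequential sums of squares,
#' pseudo-F, R-squared and permutation p-value.
#'
#' @slot table data.frame with columns Df, SumOfSqs, F, R2, Pr
#' @slot nPerm number of permutations used for the p-values
#' @slot seed integer seed of the permutation stream
#' @aliases PermanovaResult-class
#' @exportClass PermanovaResult
setClass("PermanovaResult",
  representation(table = "data.frame", nPerm = "integer", seed = "integer")
)

setValidity("PermanovaResult", function(object) {
  tab <- object@table
  msg <- character()
  need <- c("Df", "SumOfSqs", "F", "R2", "Pr")
  if (!all(need %in% colnames(tab)))
    return("table must have columns Df, SumOfSqs, F, R2, Pr")
  if (!all(c("Residual", "Total") %in% rownames(tab)))
    return("table must contain Residual and Total rows")
  terms <- setdiff(rownames(tab), c("Residual", "Total"))
  r2sum <- sum(tab[c(terms, "Residual"), "R2"])
  if (abs(r2sum - 1) > 1e-9)
    msg <- c(msg, "term R2 plus residual R2 must sum to 1")
  dfsum <- sum(tab[c(terms, "Residual"), "Df"])
  if (dfsum != tab["Total", "Df"])
    msg <- c(msg, "term plus residual df must equal total df (n - 1)")
  if (length(msg)) msg else TRUE
})

#' Direct/indirect path decomposition result
#'
#' Standardised path coefficients of the mediation triangle diet (Salix RRA)
#' -> microbiome diversity -> body mass: \code{a} (Salix to diversity),
#' \code{b} (diversity to mass, given Salix), \code{cDirect} (Salix to mass,
#' given diversity).  The indirect effect is the product \code{a * b} and the
#' total effect \code{cDirect + a * b}, both held exactly by construction.
#'
#' @slot a standardised coefficient, Salix -> diversity
#' @slot b standardised coefficient, diversity -> mass given Salix
#' @slot cDirect standardised coefficient, Salix -> mass given diversity
#' @slot indirect a * b
#' @slot total cDirect + a * b
#' @slot metric diversity metric label ("shannon" or "chao1")
#' @slot partials named numeric: partial correlations of salix and diversity
#'   from the mass equation (empty when coefficients were supplied directly)
#' @slot directExceedsIndirect logical, |cDirect| > |indirect|
#' @aliases PathModelResult-class
#' @exportClass PathModelResult
setClass("PathModelResult",
  representation(
    a = "numeric", b = "numeric", cDirect = "numeric",
    indirect = "numeric", total = "numeric",
    metric = "character", partials = "numeric",
    directExceedsIndirect = "logical"
  )
)

setValidity("PathModelResult", function(object) {
  msg <- character()
  if (!identical(object@indirect, object@a * object@b))
    msg <- c(msg, "indirect must equal a * b exactly")
  if (!identical(object@total, object@cDirect + object@indirect))
    msg <- c(msg, "total must equal cDirect + indirect exactly")
  if (!object@metric %in% c("shannon", "chao1", "none"))
    msg <- c(msg, "metric must be 'shannon', 'chao1' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Ground-truth path coefficients for the synthetic-study generator
#'
#' @slot aTrue standardised Salix -> diversity coefficient
#' @slot bTrue standardised diversity -> mass coefficient
#' @slot cDirectTrue standardised direct Salix -> mass coefficient
#' @slot lactationInteraction extra Salix slope (standardised) for lactating
#'   females; 0 by default so the default study matches the plain mediation
#'   triangle
#' @slot valleyMassOffsets additive kg offsets per valley
#' @slot noiseSdMass residual standard deviation of the standardised mass
#'   equation (> 0).  Body mass is generated on a standardised scale with
#'   every systematic component (paths, valley offsets, age effect) inside
#'   it; the default 0.758 completes the default configuration's total
#'   mass variance to one, so the generating coefficients coincide with
#'   the standardised estimands.
#' @aliases PathTruth-class
#' @exportClass PathTruth
setClass("PathTruth",
  representation(
    aTrue = "numeric", bTrue = "numeric", cDirectTrue = "numeric",
    lactationInteraction = "numeric", valleyMassOffsets = "numeric",
    noiseSdMass = "numeric"
  ),
  prototype(
    aTrue = 0.3, bTrue = -0.25, cDirectTrue = 0.4,
    lactationInteraction = 0,
    valleyMassOffsets = c(-1.5, -0.5, 0.5, 1.5),
    noiseSdMass = 0.758
  )
)

setValidity("PathTruth", function(object) {
  if (length(object@noiseSdMass) != 1L || object@noiseSdMass <= 0)
    return("noiseSdMass must be a single positive value")
  TRUE
})

#' Configuration of a synthetic metabarcoding study
#'
#' Dimensions and generative parameters of one simulated study: the sampling
#' design (valleys x years, replicate count), diet table dimensions, read
#' depths, planted-defect rates, the environmental drivers (annual maximum
#' NDVI, mean July temperature) and the true path coefficients.
#' See [studyConfig()] for defaults and field meanings.
#'
#' @aliases StudyConfig-class
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(
    nValleys = "integer", nYears = "integer", nSamples = "integer",
    nReplicates = "integer", nMotus = "integer", nFamilies = "integer",
    nFunctionalGroups = "integer", readDepthMean = "integer",
    overdispersion = "numeric", outlierReplicateRate = "numeric",
    artefactMotuCount = "integer", ndviByYear = "numeric",
    julyTempByYear = "numeric", salixNdviSlope = "numeric",
    grassTempSlope = "numeric", nAsvs = "integer",
    microbiomeDepthMean = "integer", massBaselineKg = "numeric",
    massScaleKg = "numeric", pathTruth = "PathTruth", seed = "integer"
  )
)

setValidity("StudyConfig", function(object) {
  msg <- character()
  counts <- c(
    nValleys = object@nValleys, nYears = object@nYears,
    nSamples = object@nSamples, nReplicates = object@nReplicates,
    nMotus = object@nMotus, nFamilies = object@nFamilies,
    nFunctionalGroups = object@nFunctionalGroups,
    readDepthMean = object@readDepthMean, nAsvs = object@nAsvs,
    microbiomeDepthMean = object@microbiomeDepthMean
  )
  bad <- names(counts)[counts < 1L]
  if (length(bad))
    msg <- c(msg, sprintf("count field(s) below 1: %s", paste(bad, collapse = ", ")))
  if (object@outlierReplicateRate < 0 || object@outlierReplicateRate > 1)
    msg <- c(msg, "outlierReplicateRate must be a probability in [0, 1]")
  if (object@artefactMotuCount < 0L)
    msg <- c(msg, "artefactMotuCount must be >= 0")
  if (object@overdispersion <= 0)
    msg <- c(msg, "overdispersion must be positive")
  if (length(object@ndviByYear) != object@nYears)
    msg <- c(msg, sprintf("ndviByYear must have length nYears = %d", object@nYears))
  if (any(object@ndviByYear < -1 | object@ndviByYear > 1))
    msg <- c(msg, "ndviByYear values must lie in [-1, 1]")
  if (length(object@julyTempByYear) != object@nYears)
    msg <- c(msg, sprintf("julyTempByYear must have length nYears = %d", object@nYears))
  if (length(object@pathTruth@valleyMassOffsets) != object@nValleys)
    msg <- c(msg, sprintf("valleyMassOffsets must have length nValleys = %d", object@nValleys))
  if (object@nFamilies > object@nMotus)
    msg <- c(msg, "nFamilies cannot exceed nMotus")
  if (object@nFunctionalGroups > object@nFamilies)
    msg <- c(msg, "nFunctionalGroups cannot exceed nFamilies")
  if (length(msg)) msg else TRUE
})

#' Ground-truth registry of a synthetic study
#'
#' Records everything the generator planted so downstream filters can be
#' scored against known labels: the true per-sample diet compositions, the
#' ids of replicates drawn from an unrelated composition ("failed PCRs"),
#' and artefact MOTUs with the filter rule each was built to violate.
#'
#' @slot trueCompositions matrix (samples x MOTUs) of true diet proportions,
#'   rows summing to 1
#' @slot outlierReplicates character ids of planted outlier replicates
#' @slot artefactMotus data.frame with columns \code{motu_id} and
#'   \code{reason} ("short", "low_reads", "low_identity", "sub1pct")
#' @aliases TruthRegistry-class
#' @exportClass TruthRegistry
setClass("TruthRegistry",
  representation(
    trueCompositions = "matrix",
    outlierReplicates = "character",
    artefactMotus = "data.frame"
  ),
  prototype(
    trueCompositions = matrix(numeric(0), 0, 0),
    outlierReplicates = character(0),
    artefactMotus = data.frame(motu_id = character(0), reason = character(0))
  )
)

setValidity("TruthRegistry", function(object) {
  msg <- character()
  if (nrow(object@trueCompositions) > 0L) {
    rs <- rowSums(object@trueCompositions)
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, "true composition rows must sum to 1 (tolerance 1e-9)")
  }
  if (!all(c("motu_id", "reason") %in% colnames(object@artefactMotus)))
    msg <- c(msg, "artefactMotus needs columns motu_id and reason")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic study
#'
#' Container produced by [simulateStudy()]: the replicate-level diet counts,
#' the matched microbiome table, host metadata (valley, year, age, lactation,
#' body mass, NDVI, July temperature, plus the latent truth variables), the
#' ground-truth registry and the generating configuration.
#'
#' @slot replicates [ReplicateCounts]
#' @slot microbiome [MicrobiomeCounts]
#' @slot hosts data.frame of host metadata, one row per sample
#' @slot truth [TruthRegistry]
#' @slot config [StudyConfig]
#' @aliases SyntheticStudy-class
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  representation(
    replicates = "ReplicateCounts",
    microbiome = "MicrobiomeCounts",
    hosts = "data.frame",
    truth = "TruthRegistry",
    config = "StudyConfig"
  )
)

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  reg <- object@truth
  reps <- colnames(object@replicates)
  if (!all(reg@outlierReplicates %in% reps))
    msg <- c(msg, "registered outlier replicate missing from replicate table")
  if (!all(reg@artefactMotus$motu_id %in% rownames(object@replicates)))
    msg <- c(msg, "registered artefact MOTU missing from replicate table")
  if (!all(object@hosts$sample_id %in% colData(object@replicates)$sample_id))
    msg <- c(msg, "host sample ids and replicate sample map disagree")
  if (length(msg)) msg else TRUE
})
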