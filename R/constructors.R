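#' Build a replicate-level MOTU count table
#'
#' @param counts non-negative integer matrix, MOTUs as rows (named), PCR
#'   replicates as columns (named).
#' @param sampleMap replicate-to-sample map: either a named character vector
#'   (names = replicate ids, values = sample ids) or a data.frame with
#'   columns \code{replicate_id} and \code{sample_id}.  Every replicate
#'   column must map to exactly one sample.
#' @param motuMeta optional data.frame of per-MOTU metadata with columns
#'   \code{motu_id}, \code{seq_length}, \code{total_reads},
#'   \code{best_identity}, \code{family}, \code{functional_group}.  Every
#'   MOTU in \code{counts} must be covered; the check errors naming the
#'   first missing MOTU.
#' @return a [ReplicateCounts-class] object
#' @examples
#' m <- matrix(c(10L, 90L, 20L, 80L), 2,
#'   dimnames = list(c("M1", "M2"), c("r1", "r2"))
#' )
#' rc <- ReplicateCounts(m, c(r1 = "s1", r2 = "s1"))
#' replicateSamples(rc)
#' @export
ReplicateCounts <- function(counts, sampleMap, motuMeta = NULL) {
  counts <- as.matrix(counts)
  if (is.data.frame(sampleMap)) {
    stopifnot(all(c("replicate_id", "sample_id") %in% colnames(sampleMap)))
    sm <- stats::setNames(as.character(sampleMap$sample_id),
                          as.character(sampleMap$replicate_id))
  } else {
    sm <- sampleMap
  }
  if (is.null(colnames(counts)) || (nrow(counts) > 0 && is.null(rownames(counts))))
    stop("counts must have MOTU row names and replicate column names")
  if (nrow(counts) == 0L && is.null(rownames(counts)))
    rownames(counts) <- character(0)
  missing <- setdiff(colnames(counts), names(sm))
  if (length(missing))
    stop("no sample mapping for replicate(s): ", paste(missing, collapse = ", "))
  cd <- DataFrame(sample_id = unname(sm[colnames(counts)]),
                  row.names = colnames(counts))
  rd <- .motuMetaRowData(rownames(counts), motuMeta)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("ReplicateCounts", se)
}

.motuMetaColumns <- c("seq_length", "total_reads", "best_identity",
                      "family", "functional_group")

.motuMetaRowData <- function(motuIds, motuMeta) {
  if (is.null(motuMeta))
    return(DataFrame(row.names = motuIds))
  if (!"motu_id" %in% colnames(motuMeta))
    stop("motuMeta must have a 'motu_id' column")
  missing <- setdiff(motuIds, motuMeta$motu_id)
  if (length(missing))
    stop("MOTU(s) present in the count table but absent from metadata: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(motuMeta$motu_id))
    stop("duplicated motu_id in metadata")
  idx <- match(motuIds, motuMeta$motu_id)
  keep <- intersect(c(.motuMetaColumns,
                      setdiff(colnames(motuMeta), c("motu_id", .motuMetaColumns))),
                    colnames(motuMeta))
  DataFrame(motuMeta[idx, keep, drop = FALSE], row.names = motuIds)
}

#' Build a per-sample composition (RRA) table
#'
#' @param rra numeric matrix in [0, 1], taxa as rows, samples as columns;
#'   when \code{normalised = TRUE} every column must sum to 1 (tolerance
#'   1e-9).
#' @param level taxonomic level of the rows: \code{"motu"}, \code{"family"}
#'   or \code{"functional_group"}.
#' @param normalised logical flag; un-normalised tables (e.g. after
#'   discarding rare taxa without renormalising) are allowed but flagged.
#' @param motuMeta optional per-taxon metadata (see [ReplicateCounts()]).
#' @return a [SampleComposition-class] object
#' @export
SampleComposition <- function(rra, level = c("motu", "family", "functional_group"),
                              normalised = TRUE, motuMeta = NULL) {
  level <- match.arg(level)
  rra <- as.matrix(rra)
  rd <- if (level == "motu") .motuMetaRowData(rownames(rra), motuMeta)
        else DataFrame(row.names = rownames(rra))
  se <- SummarizedExperiment(assays = list(rra = rra), rowData = rd)
  metadata(se)$level <- level
  metadata(se)$normalised <- normalised
  new("SampleComposition", se)
}

#' Build a microbiome ASV count table
#'
#' @param counts non-negative integer matrix, ASVs as rows, samples as
#'   columns, both named.
#' @param taxonomy optional data.frame with columns \code{asv_id},
#'   \code{phylum}, \code{family}; NA labels are allowed (unassigned taxa).
#' @return a [MicrobiomeCounts-class] object
#' @export
MicrobiomeCounts <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV row names and sample column names")
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    stopifnot("asv_id" %in% colnames(taxonomy))
    idx <- match(rownames(counts), taxonomy$asv_id)
    rd <- DataFrame(taxonomy[idx, setdiff(colnames(taxonomy), "asv_id"),
                             drop = FALSE],
                    row.names = rownames(counts))
  }
  se <- SummarizedExperiment(assays = list(counts = counts), rowData = rd)
  new("MicrobiomeCounts", se)
}

#' @describeIn ReplicateCounts per-MOTU metadata as a data.frame
#'   (motu_id plus the metadata columns)
#' @param x a ReplicateCounts or SampleComposition object
#' @export
setMethod("motuMeta", "SummarizedExperiment", function(x) {
  data.frame(motu_id = rownames(x),
             as.data.frame(rowData(x)),
             row.names = NULL, check.names = FALSE)
})

#' @describeIn ReplicateCounts named character vector mapping replicate id
#'   to sample id
#' @export
setMethod("replicateSamples", "ReplicateCounts", function(x) {
  stats::setNames(colData(x)$sample_id, colnames(x))
})

#' @describeIn CurationResult-class the filtered replicate table
#' @param x a CurationResult
#' @export
setMethod("keptReplicates", "CurationResult", function(x) x@kept)

#' @describeIn CurationResult-class audit table of removed replicates
#' @export
setMethod("removedReplicates", "CurationResult", function(x) x@removedReplicates)

#' @describeIn CurationResult-class ids of samples dropped after convergence
#' @export
setMethod("removedSamples", "CurationResult", function(x) x@removedSamples)

#' @describeIn CurationResult-class per-iteration dissimilarity thresholds
#' @export
setMethod("filterThresholds", "CurationResult", function(x) x@thresholds)

#' @describeIn PathModelResult-class named vector of the five path
#'   quantities (a, b, c_direct, indirect, total)
#' @param x a PathModelResult
#' @export
setMethod("pathCoefficients", "PathModelResult", function(x) {
  c(a = x@a, b = x@b, c_direct = x@cDirect,
    indirect = x@indirect, total = x@total)
})

#' @describeIn SyntheticStudy-class the replicate-level diet count table
#' @param x a SyntheticStudy
#' @export
setMethod("dietReplicates", "SyntheticStudy", function(x) x@replicates)

#' @describeIn SyntheticStudy-class the matched microbiome count table
#' @export
setMethod("microbiomeCounts", "SyntheticStudy", function(x) x@microbiome)

#' @describeIn SyntheticStudy-class host metadata, one row per sample
#' @export
setMethod("hostData", "SyntheticStudy", function(x) x@hosts)

#' @describeIn SyntheticStudy-class the ground-truth registry
#' @export
setMethod("truthRegistry", "SyntheticStudy", function(x) x@truth)

#' @describeIn PermanovaResult-class the sequential ANOVA-like table
#' @param x a PermanovaResult
#' @export
setMethod("permanovaTable", "PermanovaResult", function(x) x@table)

setMethod("show", "CurationResult", function(object) {
  cat("Iterative PCR-replicate outlier filter\n")
  cat(sprintf("  iterations: %d (thresholds %s)\n", object@iterations,
              paste(signif(object@thresholds, 4), collapse = ", ")))
  cat(sprintf("  removed replicates: %d\n", nrow(object@removedReplicates)))
  cat(sprintf("  removed samples: %d\n", length(object@removedSamples)))
  cat(sprintf("  kept: %d MOTUs x %d replicates (%d samples)\n",
              nrow(object@kept), ncol(object@kept),
              length(unique(colData(object@kept)$sample_id))))
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("Permutation test (%s)\n", object@method))
  cat(sprintf("  statistic: %.4f\n", object@statistic))
  cat(sprintf("  p-value: %.4g (%d permutations, seed %d)\n",
              object@pValue, object@nPerm, object@seed))
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("Sequential PERMANOVA (%d permutations)\n", object@nPerm))
  print(format(object@table, digits = 4))
})

setMethod("show", "PathModelResult", function(object) {
  cat(sprintf("Path decomposition (diversity metric: %s)\n", object@metric))
  cat(sprintf("  a (salix -> diversity):        % .4f\n", object@a))
  cat(sprintf("  b (diversity -> mass | salix): % .4f\n", object@b))
  cat(sprintf("  c' (salix -> mass | diversity):% .4f\n", object@cDirect))
  cat(sprintf("  indirect (a*b):                % .4f\n", object@indirect))
  cat(sprintf("  total (c' + a*b):              % .4f\n", object@total))
  cat(sprintf("  |direct| > |indirect|: %s\n", object@directExceedsIndirect))
})

setMethod("show", "SyntheticStudy", function(object) {
  cfg <- object@config
  cat("Synthetic metabarcoding study\n")
  cat(sprintf("  %d samples, %d valleys x %d years, %d PCR replicates/sample\n",
              cfg@nSamples, cfg@nValleys, cfg@nYears, cfg@nReplicates))
  cat(sprintf("  diet: %d MOTUs (%d families, %d functional groups)\n",
              nrow(object@replicates), cfg@nFamilies, cfg@nFunctionalGroups))
  cat(sprintf("  microbiome: %d ASVs\n", nrow(object@microbiome)))
  cat(sprintf("  planted outlier replicates: %d; artefact MOTUs: %d\n",
              length(object@truth@outlierReplicates),
              nrow(object@truth@artefactMotus)))
})
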