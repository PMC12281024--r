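#' Read a tab-separated count table
#'
#' Parses a tab-separated file with a header row, the first column holding
#' taxon ids and the remaining columns numeric counts, preserving the file
#' order of ids.  Ragged rows, non-numeric cells and duplicate ids are
#' rejected with the offending line number.
#'
#' @param path file path
#' @return numeric matrix with taxon ids as rownames and the header's
#'   column names
#' @export
readCountTable <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1)
    stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  nc <- length(header)
  if (nc < 2)
    stop(path, ": header must have an id column plus at least one count column")
  body <- fields[-1]
  ids <- character(length(body))
  m <- matrix(NA_real_, length(body), nc - 1)
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != nc)
      stop(path, ": line ", i + 1, " has ", length(f),
           " fields, expected ", nc)
    ids[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals))
      stop(path, ": non-numeric value on line ", i + 1)
    m[i, ] <- vals
  }
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(path, ": duplicate id '", ids[dup[1]], "' on line ", dup[1] + 1)
  dimnames(m) <- list(ids, header[-1])
  m
}

#' Write a count or composition table as tab-separated text
#'
#' Inverse of [readCountTable()]: first column the row ids (header taken
#' from \code{idColumn}), remaining columns the matrix columns.  Writes are
#' byte-for-byte reproducible for identical input.
#'
#' @param x matrix or [ReplicateCounts-class] / [SampleComposition-class] /
#'   [MicrobiomeCounts-class]
#' @param path output file path
#' @param idColumn header name of the id column
#' @return the path, invisibly
#' @export
writeCountTable <- function(x, path, idColumn = "id") {
  m <- if (is(x, "SampleComposition")) assay(x, "rra")
       else if (is(x, "SummarizedExperiment")) assay(x, "counts")
       else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicate-level count table with its sample map and MOTU metadata
#'
#' @param countsPath tab-separated MOTU x replicate counts (see
#'   [readCountTable()])
#' @param sampleMapPath tab-separated file with columns \code{replicate_id}
#'   and \code{sample_id}
#' @param motuMetaPath optional tab-separated MOTU metadata with columns
#'   \code{motu_id}, \code{seq_length}, \code{total_reads},
#'   \code{best_identity}, \code{family}, \code{functional_group}
#' @return a [ReplicateCounts-class]
#' @export
readReplicateCounts <- function(countsPath, sampleMapPath, motuMetaPath = NULL) {
  counts <- readCountTable(countsPath)
  smap <- utils::read.delim(sampleMapPath, stringsAsFactors = FALSE)
  meta <- if (!is.null(motuMetaPath))
    utils::read.delim(motuMetaPath, stringsAsFactors = FALSE) else NULL
  ReplicateCounts(counts, smap, meta)
}

#' Read host metadata
#'
#' Tab-separated host table with at least \code{sample_id}, \code{valley},
#' \code{year}, \code{age}, \code{lactating}, \code{body_mass}; validates
#' that ages are at least 2 years (only adult females enter the analysis)
#' and masses positive.
#'
#' @param path file path
#' @return data.frame
#' @export
readHostMetadata <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "valley", "year", "age", "lactating", "body_mass")
  missing <- setdiff(need, colnames(h))
  if (length(missing))
    stop("host metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (any(h$age < 2))
    stop("host metadata contains age < 2 (only adults are analysed)")
  if (any(h$body_mass <= 0))
    stop("host metadata contains non-positive body mass")
  h$lactating <- as.logical(h$lactating)
  h
}

#' Write a synthetic study to a directory of tab-separated files
#'
#' Writes the replicate counts, the replicate-to-sample map, the MOTU
#' metadata, the microbiome counts with taxonomy, the host table, a flat
#' key-value rendering of the configuration and the truth registry in long
#' format (id, category, reason).
#'
#' @param study a [SyntheticStudy-class]
#' @param dir output directory (created if needed)
#' @return named character vector of the files written, invisibly
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  rc <- dietReplicates(study)
  writeCountTable(rc, p("diet_replicate_counts.tsv"), idColumn = "motu_id")
  utils::write.table(
    data.frame(replicate_id = colnames(rc),
               sample_id = colData(rc)$sample_id),
    p("replicate_sample_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(motuMeta(rc), p("motu_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mb <- microbiomeCounts(study)
  writeCountTable(mb, p("microbiome_counts.tsv"), idColumn = "asv_id")
  utils::write.table(
    data.frame(asv_id = rownames(mb), as.data.frame(rowData(mb))),
    p("asv_taxonomy.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hostData(study), p("host_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- study@config
  slotNames <- methods::slotNames(class(cfg))
  kv <- unlist(lapply(slotNames, function(s) {
    v <- methods::slot(cfg, s)
    if (is(v, "PathTruth")) {
      ts <- methods::slotNames(class(v))
      stats::setNames(vapply(ts, function(t)
        paste(methods::slot(v, t), collapse = ","), character(1)),
        paste0("pathTruth.", ts))
    } else stats::setNames(paste(v, collapse = ","), s)
  }))
  writeLines(paste(names(kv), kv, sep = "\t"), p("study_config.tsv"))
  reg <- truthRegistry(study)
  nOut <- length(reg@outlierReplicates)
  long <- rbind(
    data.frame(id = reg@outlierReplicates,
               category = rep("outlier_replicate", nOut),
               reason = rep("unrelated_composition", nOut)),
    data.frame(id = reg@artefactMotus$motu_id,
               category = rep("artefact_motu", nrow(reg@artefactMotus)),
               reason = reg@artefactMotus$reason))
  utils::write.table(long, p("truth_registry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(replicate_counts = p("diet_replicate_counts.tsv"),
             sample_map = p("replicate_sample_map.tsv"),
             motu_meta = p("motu_metadata.tsv"),
             microbiome = p("microbiome_counts.tsv"),
             taxonomy = p("asv_taxonomy.tsv"),
             hosts = p("host_metadata.tsv"),
             config = p("study_config.tsv"),
             truth = p("truth_registry.tsv"))
  invisible(files)
}

#' Pipeline run configuration
#'
#' Collects the stage parameters of [runPipeline()] with the standard
#' curation thresholds as defaults: minimum amplicon length 10 nt, read
#' total above 10, minimum RRA 1\%, best identity 94\%, 10,000
#' permutations.
#'
#' @param outDir output directory
#' @param seed integer master seed for every stochastic stage
#' @param study a [StudyConfig-class] for the simulate stage (its seed is
#'   overridden by \code{seed})
#' @param minLength,minReads,minRra,minIdentity curation thresholds
#' @param nPerm permutations for Mantel and PERMANOVA
#' @param aggregateLevel taxonomic level of the curated diet table used in
#'   the association stage
#' @return a list of class \code{runConfig}
#' @export
runConfig <- function(outDir, seed = 1, study = studyConfig(seed = seed),
                      minLength = 10, minReads = 10, minRra = 0.01,
                      minIdentity = 0.94, nPerm = 10000,
                      aggregateLevel = "family") {
  stopifnot(minRra >= 0, minRra <= 1, minIdentity >= 0, minIdentity <= 1,
            nzchar(outDir))
  study@seed <- as.integer(seed)
  structure(list(outDir = outDir, seed = as.integer(seed), study = study,
                 minLength = minLength, minReads = minReads,
                 minRra = minRra, minIdentity = minIdentity,
                 nPerm = as.integer(nPerm),
                 aggregateLevel = aggregateLevel),
            class = "runConfig")
}

#' Run the full pipeline: simulate, curate, diversity, associate, path
#'
#' Executes the stages in fixed order on a synthetic study, writes every
#' result table as tab-separated text plus an audit log recording the seed,
#' the thresholds and each removal with its triggering rule, and returns
#' the in-memory results.  Identical configurations (including the seed)
#' give byte-identical result tables; the log additionally carries wall
#' clock timestamps.
#'
#' @param config a [runConfig()] list
#' @return (invisibly) list with elements \code{study}, \code{curation},
#'   \code{familyComposition}, \code{diversity}, \code{mantel} (pearson and
#'   spearman [PermutationTestResult-class]s), \code{permanova}
#'   ([PermanovaResult-class]), \code{paths} (one [PathModelResult-class]
#'   per diversity metric), \code{files}
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir <- config$outDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  logPath <- file.path(dir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logln <- function(...) {
    writeLines(paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ",
                      sprintf(...)), logCon)
  }
  logln("run start; seed=%d; thresholds: minLength=%g minReads=%g minRra=%g minIdentity=%g nPerm=%d",
        config$seed, config$minLength, config$minReads, config$minRra,
        config$minIdentity, config$nPerm)

  ## simulate ---------------------------------------------------------------
  study <- simulateStudy(config$study)
  writeStudy(study, file.path(dir, "study"))
  logln("simulate: %d samples, %d MOTUs (%d artefacts), %d replicates (%d planted outliers)",
        config$study@nSamples, nrow(dietReplicates(study)),
        nrow(truthRegistry(study)@artefactMotus),
        ncol(dietReplicates(study)),
        length(truthRegistry(study)@outlierReplicates))

  ## curate -----------------------------------------------------------------
  cur <- curateDiet(dietReplicates(study), minLength = config$minLength,
                    minReads = config$minReads, minRra = config$minRra,
                    minIdentity = config$minIdentity)
  for (i in seq_len(nrow(cur$basicRemoved)))
    logln("curate/basic: removed MOTU %s (rule: %s)",
          cur$basicRemoved$motu_id[i], cur$basicRemoved$reason[i])
  rr <- removedReplicates(cur$outlier)
  for (i in seq_len(nrow(rr)))
    logln("curate/outlier: removed replicate %s at iteration %d (rule: dw=%.4f > threshold)",
          rr$replicate_id[i], rr$iteration[i], rr$dw[i])
  for (s in removedSamples(cur$outlier))
    logln("curate/outlier: removed sample %s (rule: fewer than 2 replicates left)", s)
  for (i in seq_len(nrow(cur$rraRemoved)))
    logln("curate/rra: removed MOTU %s (rule: %s)",
          cur$rraRemoved$motu_id[i], cur$rraRemoved$reason[i])
  famComp <- aggregateTaxonomy(cur$motuComposition, config$aggregateLevel)
  writeCountTable(cur$motuComposition,
                  file.path(dir, "curated_motu_rra.tsv"), idColumn = "motu_id")
  writeCountTable(famComp, file.path(dir, "curated_family_rra.tsv"),
                  idColumn = config$aggregateLevel)
  auditRow <- function(stage, id, rule) {
    data.frame(stage = rep(stage, length(id)), id = id,
               rule = rep_len(rule, length(id)))
  }
  audit <- rbind(
    auditRow("basic", cur$basicRemoved$motu_id, cur$basicRemoved$reason),
    auditRow("replicate_outlier", rr$replicate_id,
             sprintf("dw=%.6g", rr$dw)),
    auditRow("sample_drop", removedSamples(cur$outlier), "single_replicate"),
    auditRow("rra_identity", cur$rraRemoved$motu_id, cur$rraRemoved$reason))
  utils::write.table(audit, file.path(dir, "curation_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## align samples ----------------------------------------------------------
  keptSamples <- colnames(famComp)
  hosts <- hostData(study)
  hosts <- hosts[match(keptSamples, hosts$sample_id), ]
  mb <- microbiomeCounts(study)[, keptSamples]

  ## diversity --------------------------------------------------------------
  mbScaled <- commonScale(mb)
  dietDiv <- sampleDiversity(famComp, metrics = c("shannon", "hill1"))
  dietDiv$table <- "diet_family"
  mbDiv <- sampleDiversity(mbScaled, metrics = c("shannon", "chao1"))
  mbDiv$table <- "microbiome"
  divTab <- rbind(dietDiv, mbDiv)
  utils::write.table(divTab, file.path(dir, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logln("diversity: %d values written", nrow(divTab))

  ## associate --------------------------------------------------------------
  dDiet <- brayCurtis(famComp)
  dMicro <- brayCurtis(mbScaled)
  mantelP <- mantelTest(dDiet, dMicro, "pearson", nPerm = config$nPerm,
                        seed = config$seed)
  mantelS <- mantelTest(dDiet, dMicro, "spearman", nPerm = config$nPerm,
                        seed = config$seed)
  salixRow <- grep("^Salicaceae$|^MOTU_001$", rownames(famComp), value = TRUE)
  salix <- if (length(salixRow)) assay(famComp, "rra")[salixRow[1], ]
           else assay(famComp, "rra")[1, ]
  design <- data.frame(valley = factor(hosts$valley),
                       year = factor(hosts$year),
                       salix = as.numeric(salix),
                       row.names = hosts$sample_id)
  perm <- permanovaSequential(dMicro, design,
                              terms = c("valley", "year", "salix"),
                              nPerm = config$nPerm, seed = config$seed)
  mantelTab <- data.frame(
    method = c("pearson", "spearman"),
    statistic = c(mantelP@statistic, mantelS@statistic),
    p_value = c(mantelP@pValue, mantelS@pValue),
    n_perm = config$nPerm, seed = config$seed)
  utils::write.table(mantelTab, file.path(dir, "mantel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ptab <- permanovaTable(perm)
  utils::write.table(data.frame(term = rownames(ptab), ptab),
                     file.path(dir, "permanova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logln("associate: mantel r=%.3f (pearson), %.3f (spearman); permanova salix R2=%.4f",
        mantelP@statistic, mantelS@statistic, ptab["salix", "R2"])

  ## path -------------------------------------------------------------------
  adjusters <- data.frame(valley = factor(hosts$valley), age = hosts$age)
  paths <- lapply(c(shannon = "shannon", chao1 = "chao1"), function(met) {
    div <- mbDiv$value[mbDiv$metric == met][
      match(keptSamples, mbDiv$sample_id[mbDiv$metric == met])]
    pathDecomposition(salix, div, hosts$body_mass, adjusters, metric = met)
  })
  pathTab <- do.call(rbind, lapply(paths, function(p) {
    data.frame(metric = p@metric, t(pathCoefficients(p)),
               direct_exceeds_indirect = p@directExceedsIndirect)
  }))
  utils::write.table(pathTab, file.path(dir, "path_decomposition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logln("path: indirect (shannon) = %.4f; indirect (chao1) = %.4f",
        paths$shannon@indirect, paths$chao1@indirect)
  logln("run complete")

  invisible(list(study = study, curation = cur, familyComposition = famComp,
                 diversity = divTab,
                 mantel = list(pearson = mantelP, spearman = mantelS),
                 permanova = perm, paths = paths,
                 files = list.files(dir, recursive = TRUE,
                                    full.names = TRUE)))
}
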