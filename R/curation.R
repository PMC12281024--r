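#' Basic MOTU filters: amplicon length and dataset-wide read total
#'
#' Removes MOTUs whose amplicon is shorter than \code{minLength}
#' nucleotides and/or whose total read count over the whole dataset is at
#' most \code{minReads}.  Note the asymmetric boundaries: length
#' \emph{strictly below} 10 is removed, totals \emph{at or below} 10 are
#' removed.  Counts of surviving MOTUs are untouched.
#'
#' @param x a [ReplicateCounts-class] object whose \code{rowData} carries
#'   \code{seq_length} (and optionally \code{total_reads}; when absent the
#'   dataset-wide total is computed from the table itself)
#' @param minLength minimum amplicon length in nucleotides (kept if
#'   \code{seq_length >= minLength}); default 10
#' @param minReads read-total cut-off (kept if \code{total_reads >
#'   minReads}); default 10
#' @return list with elements \code{kept} (the filtered
#'   [ReplicateCounts-class]) and \code{removed} (data.frame with columns
#'   \code{motu_id}, \code{seq_length}, \code{total_reads}, \code{reason})
#' @export
basicMotuFilter <- function(x, minLength = 10, minReads = 10) {
  stopifnot(is(x, "ReplicateCounts"))
  if (nrow(x) == 0L)
    return(list(kept = x,
                removed = data.frame(motu_id = character(0),
                                     seq_length = numeric(0),
                                     total_reads = numeric(0),
                                     reason = character(0))))
  rd <- rowData(x)
  if (!"seq_length" %in% colnames(rd) || anyNA(rd$seq_length)) {
    bad <- if (!"seq_length" %in% colnames(rd)) rownames(x)
           else rownames(x)[is.na(rd$seq_length)]
    stop("missing seq_length metadata for MOTU(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  totals <- if ("total_reads" %in% colnames(rd) && !anyNA(rd$total_reads))
    rd$total_reads else rowSums(assay(x, "counts"))
  tooShort <- rd$seq_length < minLength
  tooRare <- totals <= minReads
  drop <- tooShort | tooRare
  reason <- ifelse(tooShort & tooRare, "short;low_reads",
                   ifelse(tooShort, "short", "low_reads"))
  removed <- data.frame(motu_id = rownames(x)[drop],
                        seq_length = as.numeric(rd$seq_length)[drop],
                        total_reads = as.numeric(totals)[drop],
                        reason = reason[drop], row.names = NULL)
  list(kept = x[!drop, ], removed = removed)
}

#' Iterative PCR-replicate outlier filter
#'
#' Detects and removes non-functional PCR replicates by comparing, on each
#' iteration, the distribution of within-sample distances \emph{dw} (the
#' Euclidean distance of each replicate's proportion vector to the average
#' profile of its sample) against the distribution of between-sample
#' distances \emph{db} (all pairwise Euclidean distances between the
#' per-sample average profiles).  Replicates from the same sample are
#' expected to be closer to each other than any two samples are (dw < db);
#' replicates with dw above the dissimilarity threshold — the crossing
#' point of the two distance densities — are discarded, the averages
#' recomputed, and the process repeated until no replicate is removed.
#' Samples retaining fewer than two replicates at the end are dropped.
#'
#' Distances are computed on within-replicate proportion vectors so that
#' replicates of different sequencing depth are comparable.  The threshold
#' is the crossing point of Gaussian kernel density estimates (Silverman's
#' rule-of-thumb bandwidth) of dw and db located between the two
#' distribution means; when no crossing exists there (e.g. the
#' distributions are well separated or degenerate) the midpoint of the two
#' means is used.  Removal uses a strict inequality (dw > threshold), and
#' at most one replicate — the one with the largest dw — is removed per
#' sample per iteration before the averages are recomputed.  An outlying
#' replicate drags its own sample average towards itself, inflating the dw
#' of the sample's good replicates (to about one third of the outlier's
#' distance, versus two thirds for the outlier itself, in a triplicate);
#' removing only the worst replicate per sample and re-averaging lets the
#' good replicates fall back below the threshold on the next iteration
#' instead of being discarded alongside the true outlier.
#'
#' @param x a [ReplicateCounts-class] object with at least two samples
#'   having two or more replicates each
#' @param maxIter iteration cap; defaults to the number of replicates,
#'   which the loop cannot exceed since each iteration before convergence
#'   removes at least one replicate
#' @return a [CurationResult-class] carrying the filtered table and the
#'   full audit trail
#' @export
replicateOutlierFilter <- function(x, maxIter = ncol(x)) {
  stopifnot(is(x, "ReplicateCounts"))
  counts <- assay(x, "counts")
  depths <- colSums(counts)
  if (any(depths == 0))
    stop("replicate(s) with zero reads cannot be normalised: ",
         paste(colnames(x)[depths == 0], collapse = ", "))
  props <- sweep(counts, 2, depths, `/`)
  smap <- replicateSamples(x)
  nPerSample <- table(smap)
  if (sum(nPerSample >= 2) < 2)
    stop("need at least two samples with two or more PCR replicates")

  active <- colnames(x)
  removed <- data.frame(replicate_id = character(0), sample_id = character(0),
                        iteration = integer(0), dw = numeric(0))
  thresholds <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter)
      stop("replicate outlier filter failed to converge after ", maxIter,
           " iterations; removed so far: ",
           paste(removed$replicate_id, collapse = ", "))
    sampleOf <- smap[active]
    samples <- unique(sampleOf)
    if (length(samples) < 2)
      stop("fewer than two sample averages left; db is undefined")
    avg <- vapply(samples, function(s) {
      rowMeans(props[, active[sampleOf == s], drop = FALSE])
    }, numeric(nrow(props)))
    dw <- vapply(seq_along(active), function(i) {
      sqrt(sum((props[, active[i]] - avg[, sampleOf[i]])^2))
    }, numeric(1))
    db <- as.numeric(stats::dist(t(avg)))
    thr <- .densityIntersection(dw, db)
    thresholds <- c(thresholds, thr)
    flagged <- which(dw > thr)
    if (!length(flagged))
      break
    # at most one removal per sample per iteration: the worst replicate
    byS <- split(flagged, sampleOf[flagged])
    out <- vapply(byS, function(ix) ix[which.max(dw[ix])], integer(1))
    removed <- rbind(removed, data.frame(
      replicate_id = active[out], sample_id = unname(sampleOf[out]),
      iteration = iter, dw = dw[out]))
    active <- active[-out]
  }

  keptCount <- table(smap[active])
  dropSamples <- names(keptCount)[keptCount < 2]
  keepReps <- active[!smap[active] %in% dropSamples]
  new("CurationResult",
      kept = x[, keepReps],
      removedReplicates = removed,
      removedSamples = as.character(dropSamples),
      thresholds = thresholds,
      iterations = iter)
}

# Crossing point of the kernel density estimates of two samples, searched
# between the two sample means; falls back to the midpoint of the means for
# degenerate inputs (too few points, zero spread) or when no crossing lies
# between the means.
.densityIntersection <- function(dw, db, n = 512) {
  m1 <- mean(dw); m2 <- mean(db)
  mid <- (m1 + m2) / 2
  if (length(dw) < 2 || length(db) < 2)
    return(mid)
  if (stats::sd(dw) < 1e-12 || stats::sd(db) < 1e-12 || abs(m1 - m2) < 1e-12)
    return(mid)
  lo <- min(dw, db); hi <- max(dw, db)
  fw <- stats::density(dw, bw = "nrd0", from = lo, to = hi, n = n)
  fb <- stats::density(db, bw = "nrd0", from = lo, to = hi, n = n)
  g <- fw$x
  d <- fw$y - fb$y
  inside <- g >= min(m1, m2) & g <= max(m1, m2)
  idx <- which(inside)
  if (length(idx) < 2)
    return(mid)
  s <- d[idx]
  flip <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != 0 | s[-length(s)] != 0))
  if (!length(flip)) {
    zero <- which(s == 0)
    if (length(zero)) return(g[idx[zero[1]]])
    return(mid)
  }
  i1 <- idx[flip[1]]; i2 <- i1 + 1L
  # linear interpolation of the zero of (fw - fb)
  g[i1] + (g[i2] - g[i1]) * d[i1] / (d[i1] - d[i2])
}

#' Average PCR replicates into per-sample relative read abundances
#'
#' Each replicate is first normalised to proportions, then the unweighted
#' arithmetic mean over a sample's replicates is taken, so every replicate
#' carries equal weight regardless of its sequencing depth.  Output columns
#' sum to one.
#'
#' @param x a [ReplicateCounts-class] object (typically
#'   \code{keptReplicates()} of a [replicateOutlierFilter()] result) or a
#'   [CurationResult-class]
#' @return a MOTU-level [SampleComposition-class]
#' @export
collapseReplicates <- function(x) {
  if (is(x, "CurationResult"))
    x <- keptReplicates(x)
  stopifnot(is(x, "ReplicateCounts"))
  counts <- assay(x, "counts")
  depths <- colSums(counts)
  if (any(depths == 0))
    stop("replicate(s) with zero reads cannot be normalised: ",
         paste(colnames(x)[depths == 0], collapse = ", "))
  props <- sweep(counts, 2, depths, `/`)
  smap <- replicateSamples(x)
  samples <- unique(unname(smap))
  rra <- vapply(samples, function(s) {
    rowMeans(props[, names(smap)[smap == s], drop = FALSE])
  }, numeric(nrow(props)))
  dimnames(rra) <- list(rownames(x), samples)
  se <- SummarizedExperiment(assays = list(rra = rra), rowData = rowData(x))
  metadata(se)$level <- "motu"
  metadata(se)$normalised <- TRUE
  new("SampleComposition", se)
}

#' Abundance and best-identity MOTU filters
#'
#' Discards MOTUs that never reach the minimum relative read abundance in
#' any sample (default 1\%) and MOTUs whose best-identity match against the
#' reference database falls below the identity cut-off (default 94\%).  The
#' surviving composition is renormalised so columns sum to one; the
#' discarded abundance mass per sample is recorded in
#' \code{metadata()$discarded_mass} so the un-renormalised table is
#' recoverable.
#'
#' @param x a MOTU-level [SampleComposition-class]; \code{rowData} must
#'   carry \code{best_identity}
#' @param minRra minimum RRA a MOTU must reach in at least one sample
#'   (kept if \code{max RRA >= minRra}); default 0.01
#' @param minIdentity best-identity cut-off (kept if
#'   \code{best_identity >= minIdentity}); default 0.94
#' @return list with \code{kept} (renormalised [SampleComposition-class])
#'   and \code{removed} (data.frame with motu_id, max_rra, best_identity,
#'   reason)
#' @export
rraIdentityFilter <- function(x, minRra = 0.01, minIdentity = 0.94) {
  stopifnot(is(x, "SampleComposition"))
  if (!identical(metadata(x)$level, "motu"))
    stop("rraIdentityFilter expects a MOTU-level composition table")
  rra <- assay(x, "rra")
  rd <- rowData(x)
  if (!"best_identity" %in% colnames(rd) || anyNA(rd$best_identity)) {
    bad <- if (!"best_identity" %in% colnames(rd)) rownames(x)
           else rownames(x)[is.na(rd$best_identity)]
    stop("missing best_identity metadata for MOTU(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  maxRra <- apply(rra, 1, max)
  lowRra <- maxRra < minRra
  lowId <- rd$best_identity < minIdentity
  drop <- lowRra | lowId
  reason <- ifelse(lowRra & lowId, "sub1pct;low_identity",
                   ifelse(lowRra, "sub1pct", "low_identity"))
  removed <- data.frame(motu_id = rownames(x)[drop],
                        max_rra = maxRra[drop],
                        best_identity = as.numeric(rd$best_identity)[drop],
                        reason = reason[drop], row.names = NULL)
  keptRra <- rra[!drop, , drop = FALSE]
  discarded <- 1 - colSums(keptRra)
  emptied <- colSums(keptRra) <= 0
  if (any(emptied)) {
    warning("sample(s) lost all abundance mass and were dropped: ",
            paste(colnames(keptRra)[emptied], collapse = ", "))
    keptRra <- keptRra[, !emptied, drop = FALSE]
    discarded <- discarded[!emptied]
  }
  keptRra <- sweep(keptRra, 2, colSums(keptRra), `/`)
  se <- SummarizedExperiment(assays = list(rra = keptRra),
                             rowData = rd[!drop, , drop = FALSE])
  metadata(se)$level <- "motu"
  metadata(se)$normalised <- TRUE
  metadata(se)$discarded_mass <- discarded
  list(kept = new("SampleComposition", se), removed = removed)
}

#' Aggregate a composition table to family or functional-group level
#'
#' Sums relative read abundances within taxonomic groups.  Column sums are
#' conserved exactly up to floating tolerance, and groups are ordered
#' lexicographically for deterministic output.
#'
#' @param x a MOTU-level [SampleComposition-class] whose \code{rowData}
#'   carries \code{family} and \code{functional_group}
#' @param level \code{"family"} or \code{"functional_group"}
#' @return a [SampleComposition-class] at the requested level
#' @export
aggregateTaxonomy <- function(x, level = c("family", "functional_group")) {
  level <- match.arg(level)
  stopifnot(is(x, "SampleComposition"))
  rd <- rowData(x)
  if (!level %in% colnames(rd))
    stop("rowData lacks a '", level, "' column")
  labels <- as.character(rd[[level]])
  bad <- is.na(labels) | labels == ""
  if (any(bad))
    stop("missing ", level, " label for MOTU(s): ",
         paste(rownames(x)[bad], collapse = ", "))
  agg <- rowsum(assay(x, "rra"), group = labels)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  se <- SummarizedExperiment(assays = list(rra = agg))
  metadata(se)$level <- level
  metadata(se)$normalised <- metadata(x)$normalised
  new("SampleComposition", se)
}

#' Run the full diet-curation pipeline
#'
#' Convenience wrapper chaining [basicMotuFilter()],
#' [replicateOutlierFilter()], [collapseReplicates()],
#' [rraIdentityFilter()] and (optionally) [aggregateTaxonomy()], collecting
#' the audit information of every stage.
#'
#' @param x a [ReplicateCounts-class]
#' @param minLength,minReads see [basicMotuFilter()]
#' @param minRra,minIdentity see [rraIdentityFilter()]
#' @param level optional aggregation level ("family" or
#'   "functional_group"); NULL keeps the MOTU level
#' @return list with elements \code{composition} (the curated
#'   [SampleComposition-class]), \code{motuComposition} (before
#'   aggregation), \code{basicRemoved}, \code{outlier} (the
#'   [CurationResult-class]), \code{rraRemoved}
#' @export
curateDiet <- function(x, minLength = 10, minReads = 10,
                       minRra = 0.01, minIdentity = 0.94, level = NULL) {
  basic <- basicMotuFilter(x, minLength = minLength, minReads = minReads)
  outl <- replicateOutlierFilter(basic$kept)
  comp <- collapseReplicates(keptReplicates(outl))
  rraf <- rraIdentityFilter(comp, minRra = minRra, minIdentity = minIdentity)
  final <- rraf$kept
  if (!is.null(level))
    final <- aggregateTaxonomy(rraf$kept, level = level)
  list(composition = final, motuComposition = rraf$kept,
       basicRemoved = basic$removed, outlier = outl,
       rraRemoved = rraf$removed)
}
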