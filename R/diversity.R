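#' Hill number of order q
#'
#' Effective number of taxa \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}} of an
#' abundance vector.  At \eqn{q = 0} this is observed richness, at
#' \eqn{q = 1} (taken as the continuity limit) the exponential of Shannon
#' entropy, and at \eqn{q = 2} the inverse Simpson concentration.
#' Zero-abundance categories are ignored; counts are normalised to
#' proportions internally, so the result is scale-invariant.
#'
#' @param p non-negative abundance vector (counts or proportions), at least
#'   one positive entry
#' @param q non-negative diversity order
#' @return the Hill number, a single numeric value
#' @examples
#' hillNumber(rep(1, 4), q = 1) # uniform over 4 -> 4
#' hillNumber(c(0.5, 0.3, 0.2), q = 0) # richness -> 3
#' @export
hillNumber <- function(p, q) {
  p <- .asProportions(p)
  if (length(q) != 1L || is.na(q) || q < 0)
    stop("q must be a single non-negative number")
  if (q == 1)
    return(exp(shannonIndex(p)))
  sum(p^q)^(1 / (1 - q))
}

#' Shannon entropy
#'
#' \eqn{H = -\sum_i p_i \log p_i} (natural log) over the non-zero entries of
#' an abundance vector; 0 for a single-category vector.
#'
#' @inheritParams hillNumber
#' @return Shannon entropy in nats
#' @export
shannonIndex <- function(p) {
  p <- .asProportions(p)
  -sum(p * log(p))
}

.asProportions <- function(p) {
  if (length(p) == 0L)
    stop("empty abundance vector")
  if (anyNA(p) || any(p < 0))
    stop("abundances must be non-negative and non-missing")
  p <- p[p > 0]
  if (length(p) == 0L)
    stop("abundance vector has no positive entry")
  p / sum(p)
}

#' Chao1 richness estimator
#'
#' \eqn{S_{chao1} = S_{obs} + F_1^2 / (2 F_2)} where \eqn{F_1} and
#' \eqn{F_2} are the numbers of singleton and doubleton taxa.  When no
#' doubletons are present the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} is used, which avoids the
#' division by zero.  Requires integer counts: singletons are only defined
#' on an unscaled (or integer-rounded) count vector.
#'
#' @param counts non-negative integer count vector
#' @return estimated richness (>= observed richness)
#' @examples
#' chao1(c(1, 1, 2, 2, 5)) # 5 + 4/4 = 6
#' @export
chao1 <- function(counts) {
  if (length(counts) == 0L)
    stop("empty count vector")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("Chao1 requires integer counts; round scaled counts first ",
         "(see commonScale) or use the raw counts")
  counts <- round(counts)
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0)
    sObs + f1^2 / (2 * f2)
  else
    sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Common scaling of library sizes
#'
#' Scales every sample's counts by (smallest library size / its library
#' size), a deterministic alternative to rarefying by subsampling.  Scaled
#' counts are rounded half-to-even to integers by default so that
#' singleton-based estimators (Chao1) remain defined; set
#' \code{round = FALSE} to keep fractional counts for sensitivity checks.
#' The minimum-depth sample is returned unchanged.
#'
#' @param x a [MicrobiomeCounts-class] object (or plain count matrix,
#'   samples as columns)
#' @param round logical; round scaled counts half-to-even (default TRUE)
#' @return an object of the same class with adjusted counts
#' @export
commonScale <- function(x, round = TRUE) {
  m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  depths <- colSums(m)
  if (any(depths == 0)) {
    bad <- colnames(m)[depths == 0]
    stop("sample(s) with zero read depth: ", paste(bad, collapse = ", "))
  }
  minDepth <- min(depths)
  scaled <- sweep(m, 2, minDepth / depths, `*`)
  if (round)
    scaled <- round(scaled) # round() is half-to-even in R
  if (is(x, "SummarizedExperiment")) {
    assay(x, "counts") <- scaled
    x
  } else {
    scaled
  }
}

#' Arcsine square-root transform
#'
#' The variance-stabilising transform \eqn{\arcsin(\sqrt p)} (radians) for
#' proportions, used before fitting linear models to relative read
#' abundances.
#'
#' @param p proportion(s) in [0, 1]
#' @return transformed value(s) in [0, pi/2]
#' @export
arcsineTransform <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Per-sample diversity of a count or composition table
#'
#' Applies a diversity metric column-wise (per sample) and returns a tidy
#' data.frame.
#'
#' @param x a [MicrobiomeCounts-class], [SampleComposition-class] or matrix
#'   (taxa rows, sample columns)
#' @param metrics character subset of \code{c("shannon", "chao1", "hill1",
#'   "richness")}
#' @return data.frame with columns sample_id, metric, value
#' @export
sampleDiversity <- function(x, metrics = c("shannon", "chao1")) {
  metrics <- match.arg(metrics,
                       c("shannon", "chao1", "hill1", "richness"),
                       several.ok = TRUE)
  m <- if (is(x, "SampleComposition")) assay(x, "rra")
       else if (is(x, "SummarizedExperiment")) assay(x, "counts")
       else as.matrix(x)
  fns <- list(
    shannon = shannonIndex,
    chao1 = chao1,
    hill1 = function(v) hillNumber(v, 1),
    richness = function(v) sum(v > 0)
  )
  out <- lapply(metrics, function(met) {
    data.frame(sample_id = colnames(m), metric = met,
               value = apply(m, 2, fns[[met]]), row.names = NULL)
  })
  do.call(rbind, out)
}
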