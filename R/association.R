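#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between the
#' abundance profiles of every pair of samples (columns).  Works on raw
#' counts or relative abundances; 0 for identical profiles, 1 for disjoint
#' supports.
#'
#' @param x a [SampleComposition-class], [MicrobiomeCounts-class] or plain
#'   non-negative matrix with taxa as rows and samples as columns
#' @return a \code{\link[stats]{dist}} object labelled with the sample ids
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "SampleComposition")) assay(x, "rra")
       else if (is(x, "SummarizedExperiment")) assay(x, "counts")
       else as.matrix(x)
  if (ncol(m) < 2)
    stop("need at least two samples")
  if (anyNA(m) || any(m < 0))
    stop("abundances must be non-negative and non-missing")
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample(s) with all-zero abundances: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    xi <- m[, i]
    for (j in (i + 1):n) {
      d[j, i] <- sum(abs(xi - m[, j])) / (tot[i] + tot[j])
    }
  }
  out <- stats::as.dist(d)
  attr(out, "Labels") <- colnames(m)
  attr(out, "method") <- "bray-curtis"
  out
}

.asDistMatrix <- function(D, arg = "D") {
  m <- as.matrix(D)
  if (nrow(m) != ncol(m))
    stop(arg, " is not square")
  if (max(abs(m - t(m))) > 1e-12)
    stop(arg, " is not symmetric")
  if (any(diag(m) != 0))
    stop(arg, " must have a zero diagonal")
  m
}

.checkMatchedIds <- function(m1, m2) {
  id1 <- rownames(m1); id2 <- rownames(m2)
  if (!is.null(id1) && !is.null(id2) && !identical(id1, id2)) {
    only1 <- setdiff(id1, id2); only2 <- setdiff(id2, id1)
    stop("distance matrices have mismatched sample ids",
         if (length(only1)) paste0("; only in first: ",
                                   paste(only1, collapse = ", ")) else "",
         if (length(only2)) paste0("; only in second: ",
                                   paste(only2, collapse = ", ")) else "",
         if (!length(only1) && !length(only2)) "; same ids, different order"
         else "")
  }
  if (nrow(m1) != nrow(m2))
    stop("distance matrices differ in size")
}

#' Mantel test of association between two distance matrices
#'
#' The statistic is the Pearson (or Spearman, via average ranks of the
#' lower-triangle entries) correlation between the lower triangles of the
#' two matrices.  The null distribution is built by simultaneously
#' permuting rows and columns of the second matrix; the p-value is
#' one-sided (upper tail), computed as (exceedances + 1) / (nPerm + 1) so
#' it can never be exactly zero.
#'
#' @param D1,D2 distance matrices (\code{dist} objects or symmetric
#'   matrices) over the same samples in the same order
#' @param method \code{"pearson"} or \code{"spearman"}
#' @param nPerm number of permutations (default 10000)
#' @param seed integer seed for the permutation stream
#' @param storeNull keep the vector of null statistics in the result
#' @return a [PermutationTestResult-class]
#' @export
mantelTest <- function(D1, D2, method = c("pearson", "spearman"),
                       nPerm = 10000, seed = 1, storeNull = FALSE) {
  method <- match.arg(method)
  m1 <- .asDistMatrix(D1, "D1")
  m2 <- .asDistMatrix(D2, "D2")
  .checkMatchedIds(m1, m2)
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (method == "spearman") {
    v1 <- rank(v1)
    r2 <- m2
    r2[lt] <- rank(m2[lt])
    r2 <- t(r2)        # mirror the ranks into the upper triangle
    r2[lt] <- rank(m2[lt])
    m2 <- r2
  }
  v2 <- m2[lt]
  stat <- stats::cor(v1, v2)
  nPerm <- as.integer(nPerm)
  nullStats <- numeric(nPerm)
  set.seed(seed)
  for (i in seq_len(nPerm)) {
    p <- sample.int(n)
    nullStats[i] <- stats::cor(v1, m2[p, p][lt])
  }
  pVal <- (sum(nullStats >= stat) + 1) / (nPerm + 1)
  new("PermutationTestResult",
      statistic = stat, method = paste0("mantel-", method),
      nPerm = nPerm, pValue = pVal, seed = as.integer(seed),
      nullStatistics = if (storeNull) nullStats else numeric(0))
}

#' Sequential (by-terms) PERMANOVA of a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix over an ordered
#' list of model terms, each adjusted for all earlier terms (Type-I,
#' "by terms").  The Gower-centred inner-product matrix
#' \eqn{G = -\tfrac12 J (D \circ D) J} (with \eqn{J = I - n^{-1} 1 1'})
#' supplies the sums of squares as traces of projected G; the sequential SS
#' of term k is the gain in explained trace when the term's columns join
#' the cumulative design.  Pseudo-F for each term is
#' (SS_term / df_term) / (SS_residual / df_residual) and R-squared is
#' SS_term / SS_total.  Significance is assessed by freely permuting the
#' sample labels of the distance matrix and recomputing the full sequential
#' table for each permutation; p-values use (exceedances + 1) / (nPerm + 1).
#'
#' Factor terms enter as full dummy codings with first-level reference
#' (term df = number of non-reference levels); numeric terms contribute one
#' df.
#'
#' @param D distance matrix (\code{dist} or symmetric matrix)
#' @param design data.frame of covariates, rows matching the samples of
#'   \code{D} (matched by rownames when both are named, else by position)
#' @param terms character vector naming the design columns in fitting
#'   order; defaults to all columns in order
#' @param nPerm number of permutations (default 999)
#' @param seed integer seed for the permutation stream
#' @return a [PermanovaResult-class]
#' @export
permanovaSequential <- function(D, design, terms = colnames(design),
                                nPerm = 999, seed = 1) {
  m <- .asDistMatrix(D)
  n <- nrow(m)
  if (nrow(design) != n)
    stop("design has ", nrow(design), " rows but D has ", n, " samples")
  if (!is.null(rownames(m)) && !is.null(rownames(design)) &&
      !all(rownames(design) == as.character(seq_len(n)))) {
    if (!setequal(rownames(m), rownames(design)))
      stop("design rownames do not match the distance matrix labels")
    design <- design[rownames(m), , drop = FALSE]
  }
  missingTerms <- setdiff(terms, colnames(design))
  if (length(missingTerms))
    stop("term(s) not in design: ", paste(missingTerms, collapse = ", "))

  G <- .gowerCentre(m)
  ssTotal <- sum(diag(G))

  # cumulative orthonormal bases and projectors, one per term
  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  X <- matrix(1, n, 1)
  for (k in seq_along(terms)) {
    v <- design[[terms[k]]]
    cols <- if (is.numeric(v)) matrix(as.numeric(v), ncol = 1)
            else stats::model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    X <- cbind(X, cols)
    qrX <- qr(X)
    expected <- (if (k == 1) 1L else ranks[k - 1]) +
      if (is.numeric(v)) 1L else nlevels(factor(v)) - 1L
    if (qrX$rank < expected)
      stop("cumulative design becomes rank deficient at term '", terms[k], "'")
    ranks[k] <- qrX$rank
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
  }
  dfTerms <- diff(c(1L, ranks))
  dfResid <- n - ranks[length(ranks)]
  if (dfResid < 1)
    stop("no residual degrees of freedom")

  seqSS <- function(Gmat) {
    ssModel <- vapply(hats, function(H) sum(H * Gmat), numeric(1))
    diff(c(0, ssModel))
  }
  ssTerm <- seqSS(G)
  ssResid <- ssTotal - sum(ssTerm)
  fObs <- (ssTerm / dfTerms) / (ssResid / dfResid)

  nPerm <- as.integer(nPerm)
  exceed <- numeric(length(terms))
  set.seed(seed)
  for (i in seq_len(nPerm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    ssT <- seqSS(Gp)
    ssR <- ssTotal - sum(ssT)
    fPerm <- (ssT / dfTerms) / (ssR / dfResid)
    exceed <- exceed + (fPerm >= fObs)
  }
  pVals <- (exceed + 1) / (nPerm + 1)

  tab <- data.frame(
    Df = c(dfTerms, dfResid, n - 1L),
    SumOfSqs = c(ssTerm, ssResid, ssTotal),
    F = c(fObs, NA, NA),
    R2 = c(ssTerm / ssTotal, ssResid / ssTotal, 1),
    Pr = c(pVals, NA, NA),
    row.names = c(terms, "Residual", "Total")
  )
  new("PermanovaResult", table = tab, nPerm = nPerm, seed = as.integer(seed))
}

.gowerCentre <- function(m) {
  A <- -0.5 * m^2
  n <- nrow(A)
  rm <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1, rm), 2, rm) + gm
}

#' Ordinary least squares on z-scored variables
#'
#' Standardises the response and every continuous predictor to mean 0 and
#' standard deviation 1 (denominator n - 1), fits ordinary least squares,
#' and derives the partial correlation of each continuous predictor from
#' its t-statistic, \eqn{r = t / \sqrt{t^2 + df}} (sign matching the
#' coefficient).  Optional adjusters enter the design unstandardised:
#' factors as full dummy codings with first-level reference, numeric
#' adjusters z-scored.
#'
#' @param response numeric vector
#' @param predictors data.frame (or named list) of continuous predictors
#' @param adjusters optional data.frame of adjustment covariates
#' @return list with components \code{coefficients} (standardised, named by
#'   predictor), \code{se}, \code{t}, \code{df}, \code{partial}
#'   (partial correlations), \code{sigma}, \code{r_squared}
#' @export
standardizedOLS <- function(response, predictors, adjusters = NULL) {
  predictors <- as.data.frame(predictors)
  n <- length(response)
  if (nrow(predictors) != n)
    stop("response and predictors differ in length")
  zscore <- function(v, what) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12)
      stop("constant variable cannot be z-scored: ", what)
    (v - mean(v)) / s
  }
  y <- zscore(response, "response")
  Xp <- vapply(names(predictors),
               function(nm) zscore(predictors[[nm]], nm), numeric(n))
  Xp <- matrix(Xp, nrow = n, dimnames = list(NULL, names(predictors)))
  Xa <- NULL
  if (!is.null(adjusters)) {
    adjusters <- as.data.frame(adjusters)
    if (nrow(adjusters) != n)
      stop("adjusters differ in length from response")
    parts <- lapply(names(adjusters), function(nm) {
      v <- adjusters[[nm]]
      if (is.numeric(v)) {
        out <- matrix(zscore(v, nm), ncol = 1)
        colnames(out) <- nm
        out
      } else {
        mm <- stats::model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, sub("^f", ".", colnames(mm)))
        mm
      }
    })
    Xa <- do.call(cbind, parts)
  }
  X <- cbind(`(Intercept)` = 1, Xp, Xa)
  if (n <= ncol(X))
    stop("need n > number of model columns (", ncol(X), ")")
  if (kappa(X, exact = TRUE) > 1e8)
    stop("collinear predictors: design condition number above 1e8")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design (collinear predictors)")
  coef <- qr.coef(qrX, y)
  res <- y - X %*% coef
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tval <- coef / se
  keep <- colnames(Xp)
  partial <- tval[keep] / sqrt(tval[keep]^2 + df)
  list(coefficients = coef[keep], se = se[keep], t = tval[keep],
       df = df, partial = partial, sigma = sqrt(sigma2),
       r_squared = 1 - sum(res^2) / sum(y^2),
       all_coefficients = coef)
}

#' Direct/indirect path decomposition of a diet effect on body mass
#'
#' Fits the two regressions of the mediation triangle on z-scored
#' variables: diversity ~ salix (+ adjusters) giving the path \code{a}, and
#' mass ~ salix + diversity (+ adjusters) giving the mediator path \code{b}
#' and the direct path \code{c'}.  The indirect (microbiome-mediated)
#' effect is the product \code{a * b} and the total effect
#' \code{c' + a * b}.
#'
#' @param salix per-sample relative read abundance of the focal diet item
#' @param diversity per-sample microbiome diversity (Shannon or Chao1)
#' @param mass per-sample body mass (kg)
#' @param adjusters optional data.frame of adjustment covariates for the
#'   mass (outcome) equation (e.g. valley, age); factors enter as dummy
#'   codings
#' @param diversityAdjusters adjusters for the diversity (mediator)
#'   equation; defaults to the same set.  Pass \code{NULL} explicitly when
#'   the covariates affect mass but not diversity given diet — adjusting
#'   the mediator equation for a covariate that is collinear with the diet
#'   variable but has no path into diversity only inflates the variance of
#'   the a estimate
#' @param metric label of the diversity metric, \code{"shannon"} or
#'   \code{"chao1"}
#' @return a [PathModelResult-class]
#' @seealso [pathModelFromCoefficients()] for assembling a result from
#'   already-estimated coefficients
#' @export
pathDecomposition <- function(salix, diversity, mass, adjusters = NULL,
                              diversityAdjusters = adjusters,
                              metric = c("shannon", "chao1")) {
  metric <- match.arg(metric)
  if (length(salix) != length(diversity) || length(salix) != length(mass))
    stop("salix, diversity and mass must have equal length")
  fitA <- standardizedOLS(diversity, data.frame(salix = salix),
                          diversityAdjusters)
  fitB <- standardizedOLS(mass,
                          data.frame(salix = salix, diversity = diversity),
                          adjusters)
  a <- unname(fitA$coefficients["salix"])
  b <- unname(fitB$coefficients["diversity"])
  cDir <- unname(fitB$coefficients["salix"])
  indirect <- a * b
  new("PathModelResult",
      a = a, b = b, cDirect = cDir,
      indirect = indirect, total = cDir + indirect,
      metric = metric,
      partials = c(salix = unname(fitB$partial["salix"]),
                   diversity = unname(fitB$partial["diversity"])),
      directExceedsIndirect = abs(cDir) > abs(indirect))
}

#' Assemble a path-model result from given coefficients
#'
#' Applies the product rule to already-estimated standardised path
#' coefficients: indirect = a * b, total = c' + a * b.  Useful for
#' recomputing published path products.
#'
#' @param a standardised salix -> diversity coefficient
#' @param b standardised diversity -> mass coefficient
#' @param cDirect standardised direct salix -> mass coefficient (may be NA
#'   when only the indirect product is of interest)
#' @param metric diversity metric label
#' @return a [PathModelResult-class]
#' @examples
#' pathModelFromCoefficients(0.29, -0.26, metric = "shannon")
#' @export
pathModelFromCoefficients <- function(a, b, cDirect = NA_real_,
                                      metric = c("shannon", "chao1", "none")) {
  metric <- match.arg(metric)
  indirect <- a * b
  new("PathModelResult",
      a = as.numeric(a), b = as.numeric(b), cDirect = as.numeric(cDirect),
      indirect = indirect, total = as.numeric(cDirect) + indirect,
      metric = metric, partials = numeric(0),
      directExceedsIndirect = abs(as.numeric(cDirect)) > abs(indirect))
}
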