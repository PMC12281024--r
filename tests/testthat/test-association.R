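test_that("Bray-Curtis hits its anchor cases and matches vegan", {
  m <- cbind(s1 = c(1, 0, 1), s2 = c(0, 1, 1), s3 = c(1, 0, 1))
  rownames(m) <- paste0("t", 1:3)
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["s1", "s3"], 0) # identical profiles
  expect_equal(d["s1", "s2"], 0.5) # (1+1+0)/(2+2)
  disj <- cbind(a = c(3, 0), b = c(0, 7))
  rownames(disj) <- c("t1", "t2")
  expect_equal(as.numeric(brayCurtis(disj)), 1) # disjoint supports
  # bounds and symmetry on random data, and agreement with vegan
  set.seed(8)
  r <- matrix(rpois(15 * 9, 12), 15, 9,
              dimnames = list(paste0("t", 1:15), paste0("s", 1:9)))
  dr <- as.matrix(brayCurtis(r))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_equal(dr, t(dr))
  expect_equal(unname(as.numeric(brayCurtis(r))),
               unname(as.numeric(vegan::vegdist(t(r), "bray"))),
               tolerance = 1e-12)
  z <- cbind(s1 = c(1, 1), s2 = c(0, 0))
  rownames(z) <- c("t1", "t2")
  expect_error(brayCurtis(z), "s2")
})

test_that("Mantel statistic: self-correlation, vegan agreement, relabelling", {
  set.seed(14)
  m <- matrix(rpois(10 * 12, 15), 10, 12,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:12)))
  m2 <- matrix(rpois(10 * 12, 15), 10, 12, dimnames = dimnames(m))
  d1 <- brayCurtis(m); d2 <- brayCurtis(m2)
  expect_equal(mantelTest(d1, d1, "pearson", nPerm = 9, seed = 1)@statistic, 1)
  for (meth in c("pearson", "spearman")) {
    ours <- mantelTest(d1, d2, meth, nPerm = 99, seed = 1)@statistic
    veg <- vegan::mantel(d1, d2, method = meth, permutations = 0)$statistic
    expect_equal(ours, veg, tolerance = 1e-12)
  }
  # identical relabelling of both matrices leaves the statistic unchanged
  p <- sample(12)
  m1p <- as.matrix(d1)[p, p]; m2p <- as.matrix(d2)[p, p]
  expect_equal(mantelTest(m1p, m2p, "pearson", nPerm = 9, seed = 1)@statistic,
               mantelTest(d1, d2, "pearson", nPerm = 9, seed = 1)@statistic,
               tolerance = 1e-12)
  # p-value bounds
  r <- mantelTest(d1, d2, "pearson", nPerm = 99, seed = 3)
  expect_gte(r@pValue, 1 / 100)
  expect_lte(r@pValue, 1)
  # mismatched ids are reported
  bad <- as.matrix(d2); rownames(bad) <- colnames(bad) <- paste0("x", 1:12)
  expect_error(mantelTest(d1, bad), "mismatch")
})

test_that("Mantel Monte-Carlo p agrees with exhaustive enumeration at n = 5", {
  set.seed(4)
  a <- matrix(runif(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 0
  b <- matrix(runif(25), 5, 5); b <- (b + t(b)) / 2; diag(b) <- 0
  dimnames(a) <- dimnames(b) <- list(paste0("s", 1:5), paste0("s", 1:5))
  lt <- lower.tri(a)
  obs <- cor(a[lt], b[lt])
  # independent oracle: enumerate all 5! simultaneous row/column permutations
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ,
                 drop = FALSE]
  nullAll <- apply(perms, 1, function(p) cor(a[lt], b[p, p][lt]))
  pExact <- mean(nullAll >= obs)
  r <- mantelTest(a, b, "pearson", nPerm = 9999, seed = 8)
  expect_equal(r@statistic, obs, tolerance = 1e-12)
  mcSe <- sqrt(pExact * (1 - pExact) / 9999)
  expect_lt(abs(r@pValue - pExact), 4 * mcSe + 2e-4)
})

test_that("PERMANOVA equals classical one-way ANOVA on a 1-D embedding", {
  # six samples on a line, two groups of three
  xcoord <- c(1.0, 1.4, 1.1, 3.2, 2.9, 3.4)
  ids <- paste0("s", 1:6)
  D <- as.matrix(dist(xcoord))
  dimnames(D) <- list(ids, ids)
  design <- data.frame(g = factor(rep(c("a", "b"), each = 3)),
                       row.names = ids)
  res <- permanovaSequential(D, design, terms = "g", nPerm = 99, seed = 1)
  tab <- permanovaTable(res)
  # classical ANOVA F computed directly from the embedded coordinate
  fit <- anova(lm(xcoord ~ design$g))
  expect_equal(tab["g", "F"], fit$`F value`[1], tolerance = 1e-10)
  expect_equal(tab["g", "SumOfSqs"], fit$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(tab["Residual", "SumOfSqs"], fit$`Sum Sq`[2], tolerance = 1e-10)
  expect_equal(tab["g", "Df"], 1)
  expect_equal(tab["Residual", "Df"], 4)
})

test_that("sequential PERMANOVA matches adonis2 and decomposes R-squared", {
  set.seed(19)
  m <- matrix(rpois(12 * 18, 10), 12, 18,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:18)))
  D <- brayCurtis(m)
  design <- data.frame(valley = factor(rep(1:3, 6)),
                       year = factor(rep(1:2, 9)),
                       salix = runif(18), row.names = colnames(m))
  res <- permanovaSequential(D, design, terms = c("valley", "year", "salix"),
                             nPerm = 99, seed = 5)
  tab <- permanovaTable(res)
  ref <- vegan::adonis2(D ~ valley + year + salix, data = design,
                        by = "terms", permutations = 99)
  for (term in c("valley", "year", "salix")) {
    expect_equal(tab[term, "SumOfSqs"], ref[term, "SumOfSqs"],
                 tolerance = 1e-10)
    expect_equal(tab[term, "F"], ref[term, "F"], tolerance = 1e-10)
    expect_equal(tab[term, "R2"], ref[term, "R2"], tolerance = 1e-10)
  }
  expect_equal(sum(tab[c("valley", "year", "salix", "Residual"), "R2"]), 1,
               tolerance = 1e-9)
  expect_equal(sum(tab[c("valley", "year", "salix", "Residual"), "Df"]),
               tab["Total", "Df"])
  # a term orthogonal to the structure explains almost nothing
  expect_lt(tab["salix", "R2"], 0.15)
  # rank-deficient cumulative design is reported with the term name
  design$dup <- design$salix
  expect_error(
    permanovaSequential(D, design, terms = c("salix", "dup"), nPerm = 9),
    "dup")
})

test_that("standardized OLS recovers coefficients and partial correlations", {
  set.seed(23)
  x <- rnorm(40)
  fit <- standardizedOLS(3 * x, data.frame(x = x))
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-12)
  expect_equal(unname(fit$partial), 1, tolerance = 1e-6)
  # oracle: explicit normal-equations solve on z-scored variables
  n <- 200
  x1 <- rnorm(n); x2 <- 0.6 * x1 + 0.8 * rnorm(n)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n)
  fit2 <- standardizedOLS(y, data.frame(x1 = x1, x2 = x2))
  z <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, z(x1), z(x2))
  beta <- solve(t(X) %*% X, t(X) %*% z(y))
  expect_equal(unname(fit2$coefficients), unname(beta[2:3, 1]),
               tolerance = 1e-10)
  # uncorrelated predictor drifts to zero with n
  set.seed(31)
  co <- vapply(1:20, function(i) {
    xx <- rnorm(400); yy <- rnorm(400)
    unname(standardizedOLS(yy, data.frame(x = xx))$coefficients)
  }, numeric(1))
  expect_lt(abs(mean(co)), 0.05)
  # collinear predictors are rejected
  expect_error(standardizedOLS(y, data.frame(a = x1, b = x1)), "ollinear")
  expect_error(standardizedOLS(y, data.frame(a = rep(1, n))), "constant")
})

test_that("path decomposition identities hold exactly and nulls stay null", {
  set.seed(41)
  s <- runif(80); dv <- 0.4 * scale(s) + rnorm(80); ms <- 50 + rnorm(80)
  p <- pathDecomposition(s, as.numeric(dv), ms)
  expect_identical(p@indirect, p@a * p@b)
  expect_identical(p@total, p@cDirect + p@indirect)
  # b = 0 generating model: indirect estimates centre on zero
  ind <- vapply(1:25, function(i) {
    sal <- runif(120)
    div <- 0.3 * as.numeric(scale(sal)) + rnorm(120)
    mass <- 50 + 2 * as.numeric(scale(sal)) + rnorm(120) # no diversity path
    pathDecomposition(sal, div, mass)@indirect
  }, numeric(1))
  expect_lt(abs(mean(ind)), 0.05)
})

test_that("path products of supplied coefficients follow the product rule", {
  p1 <- pathModelFromCoefficients(0.29, -0.26, metric = "shannon")
  expect_equal(p1@indirect, -0.0754)
  expect_equal(round(p1@indirect, 2), -0.08)
  p2 <- pathModelFromCoefficients(0.39, -0.31, metric = "chao1")
  expect_equal(round(p2@indirect, 2), -0.12)
  p3 <- pathModelFromCoefficients(0.3, -0.25, cDirect = 0.4)
  expect_identical(p3@total, 0.4 + 0.3 * -0.25)
  expect_true(p3@directExceedsIndirect)
})
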