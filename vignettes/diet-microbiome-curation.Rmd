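---
title: "Curating replicated metabarcoding diet data and decomposing diet effects on body mass"
author: "metabarDiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating replicated metabarcoding diet data and decomposing diet effects on body mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`metabarDiet` implements an analysis chain for replicated DNA-metabarcoding
diet data and matched gut-microbiome data from a wild herbivore population:

1. **Curation** of a MOTU-by-PCR-replicate read-count table: basic MOTU
   filters, an iterative replicate-outlier filter, replicate averaging into
   relative read abundances (RRA), abundance and best-identity filters, and
   taxonomic aggregation.
2. **Diversity**: Hill numbers, Shannon entropy, Chao1, common scaling of
   amplicon library sizes, and the arcsine square-root transform.
3. **Association**: Bray–Curtis distances, Mantel tests, sequential
   (by-terms) PERMANOVA, and a direct/indirect path decomposition of a diet
   effect on body mass mediated by microbiome diversity.
4. A **synthetic-study generator** that produces complete studies with known
   ground truth, so every stage has a recovery test.

The motivating system is the Svalbard reindeer: October rumen samples from
adult females across four valleys and seven years, a diet dominated by the
dwarf shrub *Salix polaris* whose dietary share tracks annual plant
productivity (maximum NDVI), a 16S rumen microbiome whose composition and
diversity covary with dietary *Salix*, and autumn body mass as the
fitness-related outcome.

```{r, eval = FALSE}
library(metabarDiet)
study <- simulateStudy(studyConfig(seed = 1))
curated <- curateDiet(dietReplicates(study))
```

# The curation model

## Basic MOTU filters

MOTUs with amplicons shorter than 10 nucleotides or with a dataset-wide
total of at most 10 reads are removed (`basicMotuFilter()`). The boundaries
are asymmetric on purpose: length strictly below 10 fails, a total of
exactly 10 fails. The read total is evaluated over the whole dataset, before
any sample-wise step, because the rule targets globally rare artefactual
sequences rather than locally rare taxa.

## The iterative replicate-outlier filter

Each sample is amplified in several PCR replicates (three in the emulated
design). A failed reaction produces a read profile unrelated to its
sample. The filter (`replicateOutlierFilter()`) formalises the expectation
that replicates of one sample should resemble each other more than two
different samples do:

* every replicate is converted to proportions (so replicates of different
  sequencing depth are comparable — the distance scale is a package choice,
  as counts, proportions and transformed proportions all have precedent);
* *dw* is the Euclidean distance of each replicate's proportion vector to
  its sample's average profile;
* *db* is the set of pairwise Euclidean distances between all sample
  averages;
* the dissimilarity threshold is the crossing point of Gaussian kernel
  density estimates of *dw* and *db* (Silverman's rule-of-thumb bandwidth),
  searched between the two distribution means; when no crossing lies there
  (well-separated or degenerate distributions, e.g. all *dw* equal to zero)
  the midpoint of the two means is used. Both choices are deterministic and
  behave sensibly at small n;
* replicates with *dw* strictly greater than the threshold are outliers;
  ties are kept (conservative removal).

**Removal schedule.** At most one replicate — the one with the largest
*dw* — is removed per sample per iteration, and the averages are recomputed
before the next pass; iteration stops when no replicate exceeds the
threshold. The one-at-a-time schedule matters. An outlying replicate drags
its own sample average towards itself: in a triplicate, the outlier sits at
about two thirds of its distance to the clean profile while its two
innocent sample-mates are pushed to about one third. Those two ranges
overlap *across* samples, so a global threshold applied in an
all-at-once sweep unavoidably discards a substantial share of innocent
replicates together with the true outliers (about 17% of innocents under
the default synthetic conditions). Removing only the worst replicate per
sample lets the innocents fall back under the threshold once the
contaminated average is repaired. The iteration count is bounded by the
number of replicates, since every iteration before convergence removes at
least one.

After convergence, samples retaining fewer than two replicates are dropped
whole — with a single replicate left there is no internal replication to
vouch for it. A sample that contained two planted outliers among three
replicates typically ends here: once one aberrant replicate is gone, the
remaining pair is symmetric (both replicates sit at equal distance from
their two-point average), the pair cannot be adjudicated, and the sample is
removed. Recovery of planted outliers is therefore scored on the filter's
output table: a planted outlier counts as purged whether it was flagged
individually or eliminated with its dropped sample.

The full audit trail — per-iteration thresholds, each removed replicate
with its iteration and *dw*, dropped samples — is kept in the
`CurationResult` object and written to the pipeline's audit log.

## Averaging, abundance and identity filters, aggregation

`collapseReplicates()` first normalises every replicate to proportions and
then takes the unweighted mean over a sample's replicates, so each
replicate carries equal weight regardless of depth. `rraIdentityFilter()`
then discards MOTUs that never reach 1% RRA in any sample and MOTUs whose
best-identity match against the reference database is below 94%. The 1%
rule is read as *discard unless the MOTU reaches at least 1% in at least
one sample* — the conventional reading; the literal alternative (discard
any MOTU ever below 1%) would discard essentially everything and is not
what such filters are for. Surviving rows are renormalised to sum to one;
the discarded mass per sample is logged so the un-renormalised table is
recoverable. `aggregateTaxonomy()` sums RRA within plant families (or
functional groups) with lexicographic group order, conserving column sums
exactly.

# Diversity and normalisation

* `hillNumber(p, q)` returns $(\sum_i p_i^q)^{1/(1-q)}$, with the $q = 1$
  case taken as its continuity limit $\exp(-\sum_i p_i \ln p_i)$.
  Zero-abundance categories are ignored and inputs are normalised
  internally, so counts and proportions give identical values.
* `chao1(counts)` uses $S_{obs} + F_1^2 / (2 F_2)$ and switches to the
  bias-corrected $S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$ when there are
  no doubletons, avoiding the division by zero. Chao1 is only defined on
  integer counts — singletons are meaningless on fractional values — so
  non-integer input is an error rather than silently rounded.
* `commonScale()` multiplies each sample's counts by (smallest library
  size / its library size), a deterministic alternative to rarefying by
  subsampling. Scaled counts are rounded half-to-even by default so that
  Chao1 downstream receives integers; the fractional variant is available
  with `round = FALSE` for sensitivity checks. Diversity metrics are
  computed after scaling, on the rounded values.
* `arcsineTransform()` is the variance-stabilising $\arcsin(\sqrt p)$; the
  square root is included because the plain arcsine is not the
  variance-stabilising form for proportions.

# Association statistics

All three multivariate statistics are implemented from first principles
(the vegan implementations serve as independent cross-checks in the test
suite, never as the implementation).

* `brayCurtis()`: $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$
  between sample profiles.
* `mantelTest()`: the statistic is the Pearson (or Spearman, via average
  ranks of the lower-triangle entries) correlation of the two lower
  triangles; the null is built by simultaneously permuting rows and
  columns of the second matrix; the p-value is one-sided upper-tail.
* `permanovaSequential()`: the Gower-centred inner-product matrix
  $G = -\tfrac12 J (D \circ D) J$ supplies sums of squares as traces of
  projected $G$; each term's sequential sum of squares is the gain in
  explained trace when its columns join the cumulative design;
  pseudo-$F$ = (SS~term~/df~term~)/(SS~resid~/df~resid~) and
  $R^2$ = SS~term~/SS~total~. Factors enter as full dummy codings with
  first-level reference. Significance permutes raw sample labels (free
  permutation), recomputing the full sequential table each time; restricted
  permutation within strata is not implemented and would be the one
  behavioural difference to flag against stratified designs.

All permutation p-values use the $(b + 1)/(m + 1)$ estimator with the
observed statistic included, so a p-value can never be exactly zero.

# The path decomposition

The mediation triangle diet → microbiome diversity → body mass is fitted as
two ordinary least-squares equations on z-scored variables
(`standardizedOLS()`, denominator $n - 1$):

* diversity ~ salix (+ mediator-equation adjusters) gives **a**;
* mass ~ salix + diversity (+ outcome-equation adjusters) gives **b**
  (diversity path) and **c′** (direct path).

The indirect effect is the product $a \cdot b$, the total effect
$c' + a \cdot b$; both identities are asserted exactly in the result
object. Partial correlations are derived from the t-statistics,
$r = t / \sqrt{t^2 + df}$, sign-matched to the coefficients. This is a
fixed-effects emulation of a piecewise structural equation model; a
year-level random intercept (which belongs to the body-mass model proper,
out of scope here) is not included and is the documented approximation.

The two equations accept different adjuster sets. In the synthetic truth,
valley and age act on body mass but not on diversity given diet; valley is
also strongly collinear with dietary *Salix* (valley means of the *Salix*
share range from about 0.25 to 0.92). Adjusting the *mediator* equation
for valley therefore adds no bias protection while inflating the variance
of the a estimate several-fold, whereas the *outcome* equation must adjust
for valley and age to avoid omitted-variable bias on c′. The recovery
simulations accordingly pass `adjusters` (valley, age, age²) to the mass
equation and `diversityAdjusters = NULL` to the mediator equation. On real
data the choice should follow the analyst's causal assumptions; the default
applies the same adjusters to both equations.

# The synthetic-study generator

`simulateStudy()` emulates the sampled design: by default 97 adult females
allocated round-robin over 4 valleys × 7 years, three PCR replicates each,
39 diet MOTUs in 14 plant families and 8 functional groups, and a
400-ASV microbiome. Its generative choices, and what they do and do not
emulate:

* **Diet truth.** Each sample's true composition is drawn from a Dirichlet
  distribution (concentration `overdispersion`, default 60) around a mean
  vector whose *Salix* share is logistic-linear in the year's maximum NDVI
  (slope 6 on the logit scale around the study-mean NDVI) on top of
  valley-specific baselines chosen to span the observed range of
  valley-mean *Salix* shares (~0.25–0.92), and whose grass share is
  logistic-linear in July temperature around a 4.5% baseline. The
  remaining mass is spread over the other MOTUs with a gentle geometric
  decay (ratio 0.97), so that in low-*Salix* valleys every real MOTU can
  clear the 1% RRA rule — a defect-free study is curated without losses,
  which gives the pipeline a clean null test. NDVI defaults rise over the
  years around a mean of 0.226; July temperatures fluctuate around 6.9 °C
  without trend.
* **Replicates.** Multinomial draws of the true composition at Poisson
  depths (mean 10,000 reads). With probability `outlierReplicateRate`
  (default 0.1) a replicate is instead drawn from a symmetric Dirichlet(1)
  over all MOTUs — maximally unlike a structured diet, so the planted
  ground truth is unambiguous.
* **Artefact MOTUs.** `spikeArtefacts()` adds MOTUs violating one curation
  rule each: length 8, a 10-read total, 94%-failing identity at high
  abundance, or sub-1% abundance everywhere with an unremarkable total.
  (A 10-read MOTU is necessarily also below 1% RRA — the rules are
  logically coupled there; it is removed by the basic filter before the
  abundance rule is consulted.)
* **Microbiome.** Each sample mixes two community archetypes — a flat,
  diverse one and a dominated, low-diversity one — with mixing weight
  equal to the sample's *Salix* share plus noise, then draws ASV counts
  multinomially at Poisson depth (mean 30,000). Expected microbiome
  diversity therefore increases with dietary *Salix*.
* **Hosts.** The latent standardised diversity is
  $a \cdot z(\text{Salix}) + \sqrt{1 - a^2}\,\varepsilon$ and body mass is
  generated on a standardised scale containing *every* systematic
  component — direct path, mediated path, optional lactation interaction,
  valley offsets and a quadratic age effect (the stand-in for a spline) —
  plus residual noise. The default residual standard deviation (0.758)
  completes the default configuration's total variance to one. This is
  deliberate: the truth coefficients are *standardised* coefficients, so
  the generated mass must have unit total variance on that scale for
  standardised least squares to have the truth as its estimand. One unit
  of the standardised scale is `massScaleKg` (default 5 kg) around a 49 kg
  baseline. The default lactation interaction is zero so that the default
  study is the plain mediation triangle the recovery simulations target.
* **Determinism.** One seed per study; each generation stage derives its
  own sub-seed, so adding a stage never perturbs earlier draws, and
  identical configurations give byte-identical output.

What the generator does **not** emulate: sequence-level error processes
(chimeras, tag jumps, PCR point errors), the mock-community positive
controls, taxonomic mis-assignment, compositional correlation between diet
and microbiome beyond the single *Salix*-driven axis, and year-level random
effects on mass. Passing recovery tests therefore demonstrate that the
algorithms recover *this* class of planted structure; they do not certify
performance against artefact classes the generator does not produce.

# Numerical choices and degenerate inputs

* Density intersection: 512-point common grid over the pooled range;
  crossings located by sign change of the density difference and refined by
  linear interpolation; first crossing between the means taken; midpoint
  fallback for fewer than two points, zero spread, or no crossing.
* Zero-read replicates cannot be normalised and are an error, as is a
  distance computation over fewer than two sample averages.
* Collinearity in `standardizedOLS()` is rejected at design condition
  number above 1e8; constant variables cannot be z-scored and error.
* Rounding in `commonScale()` is half-to-even (R's `round()`), and the
  post-scaling library sizes are guaranteed within ±0.5 × (number of ASVs)
  of the minimum depth.
* Group order after aggregation and sample order after collapsing are
  deterministic (lexicographic; first appearance).

# Problem sizes used by the tests

The test suite exercises the recovery and calibration claims at the sizes
the package's own validation protocol sets: 50 planted-defect studies for
the outlier filter, 200 studies of n = 96 for the path recovery, 500
replicates of n = 30 with 999 permutations for the type-I calibration of
Mantel and PERMANOVA, and exhaustive enumeration of all 120 permutations at
n = 5 for the Mantel oracle. Unit tests use smaller configurations (12–24
samples, reduced read depths) chosen to exercise the same code paths
quickly.

# Known limitations

* The replicate filter assumes at least two samples with two or more
  replicates and Euclidean geometry on proportions; heavily unbalanced
  replicate counts shift the *dw* distribution and have not been tuned for.
* PERMANOVA uses free permutation only; with strong block structure
  (valley, year) restricted permutation would be more exact.
* The path model is linear and fixed-effects; non-linear diet–mass
  relationships (the spline territory) and year-level random intercepts are
  out of scope.
* Chao1 after common scaling inherits the rounding convention; estimates on
  rounded scaled counts can differ slightly from estimates on raw counts.
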