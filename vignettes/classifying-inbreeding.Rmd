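---
title: "Classifying recent and ancient inbreeding: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying recent and ancient inbreeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The problem

A single inbreeding coefficient F treats all autozygosity alike, but the
age of autozygosity matters: haplotypes made identical by descent through a
*recent* common ancestor carry deleterious recessives that selection has not
yet had time to purge, while *old* autozygosity has passed through many
generations of selection. In a closed, deeply pedigreed population —
the setting this package targets — recent inbreeding is therefore expected
to depress growth traits more per unit of F than old inbreeding. The
practical question is where the boundary between "recent" and "old" lies,
and the package's central idea is that the boundary is *estimable per
trait*: scan candidate boundaries, fit both components' depression effects
jointly at each, and declare the first boundary at which the recent
component is at least as harmful as the old one.

## Partitioning total inbreeding

**Changing base generation (pedigree).** F of an animal is the kinship of
its parents, computed by the Meuwissen–Luo recursion. The partition at
*t* ancestral generations recomputes F on the pedigree in which every
ancestor exactly *t* generations above the focal animal has its parents set
unknown, so only coalescences within *t* generations contribute:
`f_new(t) = F_truncated(t)` and `f_old(t) = F − f_new(t)`. Truncation can
only remove ancestral paths, so `f_old(t) ≥ 0` and `f_new(t)` is
non-decreasing in *t* — both are asserted as package invariants.

Two semantic choices here were genuinely open:

* *Generation counting.* Parents are generation 1 above the focal animal,
  so `t = 1` keeps only the parents as founders.
* *Per-focal versus global truncation.* Truncation is defined per focal
  animal (each animal gets its own base generation *t* steps above
  itself), not as one global cohort cutoff. When the pedigree is
  *generation-layered* — a generation number exists with
  g(child) = g(parent) + 1 for every link, which `is_layered()` checks and
  the simulator guarantees — per-focal truncation collapses to a shared
  generation cutoff per cohort, and `truncated_inbreeding()` exploits this
  to run one Meuwissen–Luo sweep per (cohort, t) instead of one kinship
  recursion per animal. Non-layered pedigrees (e.g. a founder mated into a
  later generation) fall back to the literal per-focal truncation; the two
  paths are cross-checked against each other in the tests. For animals with
  an unknown parent F is reported as 0 and flagged `incomplete`, since
  their pedigree understates autozygosity.

**ROH length classes (genome).** `detect_roh()` finds, per animal and
chromosome, all maximal marker runs holding at most 2 heterozygous and 5
missing calls with no internal gap above 500 kb, then filters by a minimum
of 15 SNPs, 1 Mb length and one SNP per 500 kb density, and finally reduces
overlapping maximal runs to a non-overlapping set greedily (longest first,
leftmost on ties). These are the constraints recommended for medium-density
panels; the defaults are all exposed in `roh_params()`. The detector is a
deterministic maximal-run scan rather than an emulation of the PLINK
sliding-window heuristic: the windowed scan's window size and hit-rate
parameters are not part of the stated constraint set, and a deterministic
definition can be (and is) verified against an exhaustive
enumerate-all-runs oracle. Segment length is `end_bp − start_bp` (marker
positions, not +1), `L_AUTO` is the sum of per-chromosome first-to-last
marker spans, and a segment of exactly *m* Mb is classified *long* (recent):
longer segments are the recent ones, so the tie goes to the recent side.

**Length ↔ age.** An IBD tract coalescing *g* generations back has
exponential length with mean 1/(2g) Morgan; at the package's uniform-map
default of 1 cM/Mb this gives `g = 100 / (2 l_Mb)` and inversely
`l = 100 / (2 g)`. Both directions are exposed and exactly inverse.

**Model-based length classes.** `fit_length_mixture()` fits a
two-component unequal-variance Gaussian mixture by EM on **log10 segment
length** — raw ROH lengths are strongly right-skewed and mixtures of
near-symmetric components on the log scale describe them far better; the
scale choice is a documented package decision. Initialisation is seeded
k-means (10 starts), so the fit is reproducible; the log-likelihood trace
is retained and its monotonicity is tested. The short/long boundary is the
posterior-0.5 crossing between the component means, solved on the original
scale; if the components fuse the midpoint is used. A variance collapse
below 1e-10 aborts with a request for more data. The installed `mclust`
package is used in the test suite as an independent reference fit, never as
the implementation.

**Gene-dropping decomposition.** `gene_drop()` estimates, by single-locus
Monte-Carlo transmission of uniquely labelled founder alleles, the
probability of autozygosity split into *new* (the shared allele was never
IBD in any ancestor) and *ancestral* (it was). The bookkeeping is a sticky
"exposed" flag: set on an individual's allele copies whenever that
individual is autozygous, inherited with transmission, and read at the
moment autozygosity occurs. A Ballou-style column (probability either
inherited allele was exposed in an ancestor) is emitted alongside. An
exhaustive enumeration over all transmission patterns
(`exact_drop_small()`, up to 22 meioses) provides exact references, and the
Monte-Carlo estimator is required to agree within 3 Monte-Carlo standard
errors; its `f_hat` must also match the deterministic pedigree F.

## The depression model

The regression is `y = Xb + Zu + Wm + Sp + e`: fixed sex and birth-year
(factor) effects, an age covariate for the later growth traits, and the two
inbreeding covariates fitted **jointly** (they are correlated; fitting them
one at a time would bias both). Random terms are the direct genetic effect
and, for early-growth traits with a maternal component, maternal genetic
and maternal permanent-environment effects. Variance components are
configuration inputs, not estimated — REML estimation is out of scope — with
simulator defaults h² = 0.35 direct, 0.10 maternal, 0.05 maternal PE on a
unit phenotypic-variance scale, and the direct–maternal covariance fixed at
0 by default.

`fit_mixed()` assembles Henderson's mixed-model equations with the sparse
inverse numerator-relationship matrix from `build_a_inverse()` (Henderson's
rules with inbreeding, validated against the dense tabular method); when
both genetic effects are present the penalty is G⁻¹ ⊗ A⁻¹ for the 2×2
genetic covariance G. Fixed-effect standard errors come from the fixed
block of the inverse coefficient matrix times σ²_e. The solver is verified
against direct generalized least squares with the dense covariance
`V = ZAZ'σ²_u + WAW'σ²_m + SS'σ²_p + Iσ²_e` to 1e-6, and reduces to OLS as
the genetic variances vanish.

Before every fit the two inbreeding covariates are re-standardized to zero
mean and unit sample variance **within that analysis**: the variance of
`f_new(t)` changes with *t*, and standardization is what makes coefficients
comparable across thresholds. Effects are therefore reported per SD of the
covariate. A coefficient is "significant" when |β/SE| > 2, strictly, with
no multiple-testing adjustment — the convention the grid search inherits.

For fixed-effects-only fits the comparison criteria are adjusted R²,
RMSE = √(RSS/n), and AIC/BIC from the full Gaussian log-likelihood with the
residual variance counted as a parameter (the convention of `stats::AIC`,
against which the closed forms are tested). An AIC difference above 2 is
reported as a significant difference between methods.

## The grid search

`threshold_search()` scans from the most recent boundary outward —
*t* ascending for pedigree partitions, *m* descending for ROH partitions
(large *m* = recent) — and selects the first threshold at which
β_new ≤ β_old for a higher-is-better trait, ties selecting. The full
per-threshold trace (both coefficients, their SEs, skip flags and the rule
outcome) is retained so the selection is reproducible from the stored table
alone; if the coefficient curves cross more than once all crossings are
reported and the first in scan order is the selection. Thresholds at which
either covariate is constant are skipped with a warning and recorded;
thresholds where at least half the animals have `f_new = 0` are fitted but
flagged `low_information`, mirroring the data-sufficiency concern that very
long segment classes leave many animals without any long ROH. Default
grids are t ∈ {3,…,16} and m ∈ {3,5,7,9,11,13,15,17} Mb. Threshold search
defaults to the full mixed model; `compare_methods()` scores methods with
the fixed-effects-only model, where the information criteria are
well-defined.

## The synthetic test bed

No real herd data ship with the package; every empirical claim is made on
herds from `simulate_pedigree()` / `simulate_genomes()` /
`simulate_phenotypes()`, which emulate a small closed beef herd with deep
records: discrete generations, equal cohorts, a 29-autosome panel at 80 kb
spacing, recombination at 1 cM/Mb (Haldane, no interference), and founder
allele frequencies from a Beta(0.5, 0.5) truncated below at MAF 0.05 — so
chance homozygosity exists and short ROH are imperfect IBD proxies, as in
real panels.

**Mating design and identifiability.** The default herd (280 founders, 12
generations, 2 offspring per mating) rejects matings between pairs sharing
a common ancestor within 4 generations above the prospective offspring —
the kin-avoidance management typical of conserved herds. This choice is
what makes the threshold-recovery experiment meaningful: autozygosity
variation then begins at coalescence depth 5, and with the generative
boundary at t\* = 6 the recent class contains genuine variation at depths 5
and 6 while the old class holds the deeper drift background. Had shallow
consanguineous loops been left in, their large per-loop F (0.25 for sibs)
would dominate the variance and any shallow threshold would satisfy the
selection rule, making every recovery experiment trivially score the
shallowest fitted threshold. Deliberate close-kin matings
(`consanguinity_rate`, mixture of full-sib/half-sib/first-cousin) are
available and exercised in their own tests, and are used (with avoidance
off) for the IBD-age experiments, which need coalescences at all depths.

**Age-annotated IBD.** True autozygous intervals are intervals where an
animal's two haplotypes descend from the same founder haplotype. Their age
is found by ascending both allele lineages through the recorded meiosis
mosaics in lockstep until they meet at the same ancestral haplotype; the
number of ascents is the coalescence generation *g*. A tract is split only
where a crossover falls in one of the 2g meioses of the autozygosity loop
*below* the common ancestor: breakpoints inherited from above the meeting
point (inside the common ancestor's own mosaic) are re-merged by tracking
the full coalescence path of each piece. This distinction matters —
splitting at inherited breakpoints shortens apparent tracts well below
1/(2g) Morgan in deep pedigrees, while merging across genuine loop
crossovers inflates them; with path-aware merging the per-age mean lengths
match 100/(2g) Mb within Monte-Carlo error for g = 2 through 11. The
lockstep ascent assumes a generation-layered pedigree (all founders in
generation 0), which the simulator guarantees; for other pedigrees the
annotation is not guaranteed and a warning is issued.

**Phenotypes.** `y = μ + sex + year + β_new·z(f_new) + β_old·z(f_old) +
age slope + u (+ maternal terms) + e` with breeding values drawn by the
Mendelian-sampling recursion (variance damped by parental inbreeding) and
β_new = −0.8, β_old = −0.2 per SD of the true covariates on a unit
phenotypic-SD scale — recent inbreeding four times as deleterious as old.
The generative covariates default to the pedigree partition at t\*
(`simulate_herd()`); genomic ground truth via `true_partition()` of the
simulated IBD tracks is available when genomes are simulated.

## Problem sizes and what the experiments show

The shipped experiments use sizes chosen to give clear statistical
resolution while keeping a full run in minutes: threshold recovery on herds
of ~1,960 phenotyped animals (3,640-animal pedigrees) over t = 3…16, 20
replicates in the test suite; IBD-age checks on a 40-founder herd with 4
chromosomes of 1,250 Mb (long chromosomes keep edge-censoring bias well
under the Monte-Carlo error of the per-age means, from which censored
segments are excluded); ROH recall on a genotyped 3-chromosome herd;
oracle equivalences on 200-animal pedigrees, 1,000 random genotype vectors
and ≤ 50-record mixed models; 200 null fits for the calibration of the
|t| > 2 rule.

The null calibration deserves one note: it is run with the genetic variance
switched off, because the OLS t-statistic whose type-I rate is being
measured assumes independent residuals. With pedigree-structured residuals
left in the phenotype and ignored by the fixed-only fit, the t-statistics
are anticonservative — a real property of fixed-only depression analyses in
related populations, visible in the package if one re-runs the experiment
with h² > 0, and one reason the full mixed model is the default engine for
threshold search.

Passing these experiments shows the machinery is internally correct and
that the threshold is recoverable **under the simulator's assumptions**:
uniform recombination and marker spacing, no genotyping error (a missing
and heterozygote budget is still enforced in detection), no selection or
purging dynamics, phenotypes truly generated from a two-class age
partition, and variance components known rather than estimated. Real data
violate all of these to some degree; in particular the generative model
makes no claim that a sharp age boundary exists in any real population —
the grid search estimates the best boundary under the working assumption
that one does.

## Known limitations

* The ROH detector is deliberately not byte-compatible with PLINK's
  windowed heuristic; with medium-density panels and the shared constraint
  set the segment lists are expected to agree closely but not exactly.
* Variance components must be supplied; no REML/Gibbs estimation.
* Single-trait models only; no genomic relationship matrices; no sex
  chromosomes; no binary PLINK (.bed) input.
* `exact_drop_small()` is limited to 22 meioses by design; larger pedigrees
  must use the Monte-Carlo path.
* The coalescence-age annotation requires generation-layered pedigrees;
  simulator output always qualifies, arbitrary pedigrees may not.
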