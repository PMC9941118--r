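---
title: "Chip-naive polygenic score calibration and combined risk models"
author: "chipPGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chip-naive polygenic score calibration and combined risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipPGS)
```

## The problem

A polygenic score (PGS) is a weighted sum of allele dosages,
$\mathrm{PGS}_i = \sum_j x_{ij}\,\tilde\beta_j$, with weights derived from
GWAS summary statistics. Its absolute value depends on which variants enter
the sum. Two cohorts genotyped on different chips — sharing, say, only a
third of their markers — therefore produce raw scores on incomparable
scales: the same person would receive different numbers on different chips,
and a risk threshold learned on one chip is meaningless on another.

chipPGS implements a calibration that removes this chip dependence without
requiring any marker overlap between chips. The key idea is that the
*reference cohort is rescored for every chip*: whatever markers a chip
carries, the reference panel (whole-genome sequenced, so a superset of any
chip) is scored on exactly the same harmonized variant set, and each
cohort member's raw score is replaced by its percentile rank within that
chip-specific reference distribution. Percentiles from two GWAS p-value
thresholds ($p \le 0.01$ and $p \le 10^{-6}$) are added, giving the
"summed PGS" on the fixed scale $[2, 200]$. Because local linkage
disequilibrium (LD) makes any sufficiently dense marker subset tag the
same underlying genetic signal, the percentile of an individual is nearly
the same whichever chip measured them — the property the package's
acceptance suite verifies on synthetic data.

## The scoring model

For each p-value threshold the pipeline (`scorePipeline()`) performs:

1. **QC and harmonization** (`filterByQuality()`, `harmonizePanels()`).
   Variants with imputation $R^2 < 0.4$ and multi-allelic sites are
   removed at read time; the summary statistics, target cohort and
   reference panel are intersected on the canonical key
   (chromosome, position, sorted allele pair); dosages are re-coded so
   they always count the effect allele (a flip replaces $d$ with $2-d$
   and never touches $\beta$, so one weight vector serves every cohort).
   Strand-ambiguous A/T and C/G variants are excluded by default
   (`dropAmbiguous = FALSE` retains them), because without frequency
   information their orientation cannot be established.
2. **Infinitesimal shrinkage** (`infinitesimalReweight()`). Marginal GWAS
   effects $\hat\beta$ double-count LD neighbours. Under an infinitesimal
   model (every variant causal with small normal effects) the posterior
   mean given the local LD matrix $D$ is the ridge solution
   $$\tilde\beta = \left(D + \frac{M}{N h^2} I\right)^{-1} \hat\beta,$$
   where $M$ is the number of variants, $N$ the GWAS sample size and
   $h^2$ the assumed heritability. $D$ is estimated from reference-panel
   dosages (centred, denominator $n-1$) within non-overlapping windows of
   100 variants (configurable); monomorphic variants get unit
   self-correlation and zero cross-correlation, and the positive ridge
   term keeps every window non-singular. $h^2$ must be supplied per
   trait; the package performs no internal heritability estimation.
3. **Raw scores** (`computeRawPgs()`): the weighted dosage sum over the
   threshold subset, for the target cohort and the reference panel alike.
   Sporadically missing dosages are mean-imputed as twice the
   reference-panel effect-allele frequency, keeping scores comparable
   across samples. Scores whose summary statistics encode protection can
   be re-oriented with `orientScore()`; calibration always operates on
   risk-increasing scores.
4. **Percentile projection** (`percentileProject()`):
   $pct = \mathrm{clamp}(\lceil 100\,\#\{r \le s\}/|ref|\rceil, 1, 100)$.
   Ties with reference scores count as "at or below". Among the
   conventions compatible with an integer 1–100 score we chose the
   ceiling of the empirical CDF because it is monotone, attains both
   endpoints, and maps a score below every reference value to 1 rather
   than 0. Rank order within a cohort is preserved (ties may merge).
5. **Summed PGS** (`summedPgs()`): the two percentiles added, range
   $[2, 200]$, enforced by the class validity.

## Risk models

The combined model relates the outcome to BMI, smoking (two dummies
against never-smokers), days/week of moderate and vigorous physical
activity, sex, parental disease status (father and mother separately,
missing values set to "no reported illness" rather than dropping the
sample), the summed PGS, optionally age, and a PGS×BMI interaction, with
the first four genetic principal components and genotyping batch as
cohort-specific nuisance covariates. Two families are provided, because
both views of the same formula are useful: a Cox proportional-hazards fit
(`fitCox()`, Efron tie handling) for incidence — prevalent cases are
excluded by `buildAnalysisCohort()`, the event is a post-baseline
diagnosis and censoring is administrative — and a logistic fit
(`fitLogistic()`) for prevalence. Which family drives a given analysis is
a configuration switch, not a code change.

A trained model is applied to an external cohort with `applyModel()`.
Batch and PC terms are nuisance parameters of the training cohort; an
external cohort has no meaningful values for another study's genotyping
batches, so their contributions are set to zero (with a message) rather
than invented. This is a deliberate, documented contract; substantive
terms missing from the new data are an error, never silently zeroed.

Model comparison uses the likelihood-ratio test
(`likelihoodRatioTest()`, $\chi^2 = 2(\ell_1 - \ell_0)$ on the
coefficient-count difference). Discrimination is summarized by Harrell's
C (`concordanceIndex()`, ties counted one half, normal-approximation CI)
and stratification by deciles of the predicted risk score
(`assignDeciles()`): decile boundaries come from the evaluated cohort's
own score distribution, ties are broken by stable sample-id order, and
decile 10 is the highest risk. The headline effect measure is the
top-decile odds ratio (`topDecileOr()`): a logistic regression of the
outcome on the top-decile indicator, whose exponentiated slope equals
the 2×2 cross-product ratio exactly; zero cells fall back to the
Haldane–Anscombe 0.5 correction and are flagged. `modelOverlap()`
cross-tabulates two decile assignments (chance line 10%; for independent
assignments the expected fraction ranked ≥3 deciles apart is the
enumerated 56/100), and `bmiByRiskTable()` crosses WHO BMI categories
(normal [18.5, 25), overweight [25, 30), obese ≥ 30; underweight
excluded from the pairwise test) with genetic-risk strata
(low = decile 1, medium = 2–9, high = decile 10 of the PGS-only score),
reporting Fisher exact p-values and absolute risk differences.

## The synthetic-data generator

Everything above is exercised without real genotypes. `simulateStudy()`
draws, deterministically from one seed:

- a **reference panel** and an independent **cohort** on the same
  variants. LD is induced by a Gaussian copula: per haplotype and per
  block of 50 consecutive variants, a latent normal vector with
  exchangeable correlation 0.95 is thresholded at the allele-frequency
  quantile; dosages are the sum of two haplotypes, marginally
  Binomial(2, freq). Within a block, frequencies cluster around a common
  base value (jitter SD 0.02) because variants in tight LD share
  haplotype backgrounds; this yields a mean within-block dosage
  correlation of about 0.8, the level seen between QC-passing imputed
  neighbours. Allele pairs follow a 2:1 transition:transversion ratio,
  so about one variant in six is strand-ambiguous, as in real SNP sets.
- two **chips**: random variant subsets of the cohort genomes, each
  retaining 2/3 of the panel with 1/3 of the panel on both chips, and
  per-variant imputation $R^2 \sim U(0.3, 1)$ (so a realistic minority
  fails the 0.4 QC filter independently per chip).
- **GWAS summary statistics** with marginal effects: true per-allele
  effects are drawn for the causal fraction (default: all variants,
  i.e. infinitesimal), scaled to the target heritability
  ($h^2 = 0.15$), and reported as the marginal regression slope — the
  LD-weighted sum of neighbouring causal effects computed from
  reference-panel covariance — plus sampling noise with
  $SE = 1/\sqrt{N\,\mathrm{var}(d_j)}$ and Wald p-values. Marginal
  (rather than joint) effects are what a per-variant GWAS regression
  estimates under LD, and they are precisely what makes subsets of
  markers tag each other across chips; with zero block correlation the
  generator reduces to "causal effect + noise", which the unit tests
  check. The reported effect allele is randomized between REF and ALT to
  exercise allele alignment. The defaults $N = 10{,}000$, $h^2 = 0.15$,
  $M = 3{,}000$ keep the shrinkage constant $M/(N h^2) = 2$ at the
  magnitude real studies have ($M \sim 10^6$ intersected variants
  against $N h^2 \sim 10^4\text{–}10^5$).
- **covariates and outcomes**: BMI normal (mean 27.4, SD 4.8), sex and
  parental disease Bernoulli, smoking categorical
  (44.5/45.4/10.1% never/past/current), physical activity
  Binomial(7, mean/7) with means 3.4 and 1.7 days, age uniform on
  38–75, four standard-normal PCs and a two-level batch with zero true
  effect. Event times are exponential with hazard
  $\lambda_0 \exp(lp)$, where $lp$ combines the configured log-hazard
  coefficients with the standardized true genetic burden. $\lambda_0$
  and a pre-baseline exposure window are calibrated numerically
  (bisection on the rising branch of the hump-shaped incidence
  objective) so the expected prevalent fraction is 5% and the expected
  incident fraction over the 10-year horizon is 2.1%. Prevalent cases
  are events before baseline under the same hazard, which exercises the
  incidence-cohort exclusion logic.

What the generator does **not** emulate: recombination-map LD decay
(blocks are exchangeable, real LD decays with distance), population
structure (the PCs carry no ancestry signal), genotyping error,
imputation error beyond the assigned $R^2$ labels, competing risks, and
age-varying hazards. Passing tests therefore demonstrate the internal
consistency and calibration of the method under a faithful but idealized
LD and outcome model, not its performance on any real cohort.

## Numerical and design choices

- Variant key: chromosome, 1-based position, alphabetically sorted
  allele pair. Matching is position-based; rsIDs are never consulted.
- Records violating parse invariants are dropped and counted, never
  imputed; the one exception is the explicit parental-illness
  missing-to-zero rule. All records sharing a duplicated key are
  dropped, mirroring the "ambiguous key" exclusion at harmonization.
- LD window: 100 variants, non-overlapping, in panel order. The window
  size trades LD completeness against estimation noise in $D$ from a
  ~500-sample reference; 100 comfortably covers the generator's
  50-variant blocks and is configurable for real data.
- Deciles are undefined when every score is identical (fatal), and
  decile sizes differ by at most one by construction.
- Mann–Whitney comparisons use the exact null distribution when
  $\min(n_1, n_2) \le 8$ without ties, otherwise the tie-corrected
  normal approximation.
- Cross-validated concordance refolds (with a warning) when a training
  fold has no events; a held-out fold without comparable pairs yields
  NA and is excluded from the summary.
- Problem sizes in the test suite: the chip-invariance property is
  verified on 10 replicates of 500 reference + 2,000 cohort genomes and
  3,000 variants; Cox parameter recovery uses one cohort of 10,000;
  likelihood-ratio calibration uses 500 replicates of n = 400. These
  sizes give the properties comfortable statistical margins while
  keeping a full run in tens of seconds.

## Known limitations

- Only the infinitesimal (closed-form) effect-size prior is
  implemented; the Gibbs-sampled sparse prior of the wider LDpred family
  is out of scope.
- The percentile convention (ceiling, ties as ≤) is one of several
  defensible choices; alternatives shift scores by at most one
  percentile point.
- Calibration quality is bounded by the reference-panel size: with ~500
  reference genomes, percentile resolution is about 0.2 percentile
  points and chips with very sparse overlap in informative variants
  will calibrate noisily.
- `h2` and the GWAS sample size enter only through the shrinkage
  constant; misspecifying them rescales weights smoothly and mostly
  cancels in the percentile projection, but extreme values degrade the
  raw scores' signal-to-noise ratio.
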