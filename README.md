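# chipPGS

Polygenic scores (PGS) summarize common genetic risk as a weighted sum of
allele dosages, `PGS_i = Σ_j x_ij β̃_j`, with weights from GWAS summary
statistics. Raw PGS values are not comparable across genotyping chips:
chips measure different marker sets (often with only ~1/3 overlap), so the
same genome gets a different number on each chip, and a risk threshold
learned against one chip's reference data is meaningless for another. This
blocks practical use of PGS whenever a matched-chip reference cohort is
unavailable.

chipPGS implements a calibration that is *naive to the chip used*, plus the
risk-modelling layer that turns calibrated scores into actionable risk
strata. It is aimed at statistical geneticists and methods developers who
need a tested, self-contained implementation:

- **Chip-naive calibration.** For each of two GWAS p-value thresholds
  (`p ≤ 0.01`, `p ≤ 1e-6`), marginal GWAS effects are shrunk to
  infinitesimal-model posterior means using reference-panel LD,
  `β̃ = (D + (M/(N h²)) I)⁻¹ β̂`, scores are computed for the cohort *and*
  for a whole-genome reference panel on the same harmonized variant set,
  and each cohort score is replaced by its percentile (1–100) in the
  reference distribution. The two percentiles are summed: the
  **summed PGS**, range 2–200, comparable across chips.
- **Harmonization.** Three-way variant intersection (summary statistics ×
  cohort × reference) on a position + sorted-allele-pair key, effect-allele
  alignment by dosage flipping (`2 − d`, betas untouched), exclusion of
  strand-ambiguous and irreconcilable variants with a written log.
- **Risk models.** Cox (incidence; prevalent cases excluded) and logistic
  (prevalence) fits of the combined formula — BMI, smoking dummies,
  physical activity, sex, parental disease, summed PGS, optional age and
  PGS×BMI interaction, with PCs and genotyping batch as nuisance
  covariates — plus external application with nuisance terms dropped,
  likelihood-ratio tests, Harrell's C and 10-fold cross-validation.
- **Stratification.** Risk deciles, top-decile odds ratios (exact 2×2
  cross-product identity), per-decile absolute risk, decile-overlap tables
  between models, BMI × genetic-risk incidence tables with Fisher exact
  tests, Mann–Whitney rank comparisons.
- **Synthetic cohorts.** A fully seeded generator (reference panel, LD
  blocks via a Gaussian copula, two partially overlapping chips, marginal
  GWAS effects, covariates, calibrated time-to-event outcomes with
  prevalent cases) so every claim is testable offline, with ground truth
  serialized beside the data.

## Worked example

```r
library(chipPGS)

## simulate a study: WGS reference panel + cohort genotyped on two chips
cfg <- simulationConfig(seed = 7, nReference = 500, nCohort = 2000,
                        mVariants = 3000)
study <- simulateStudy(cfg)

## calibrated summed PGS for the same genomes, via either chip
resA <- scorePipeline(study@sumstats, study@chipA, study@reference,
                      h2 = 0.15, nGwas = 10000)
resB <- scorePipeline(study@sumstats, study@chipB, study@reference,
                      h2 = 0.15, nGwas = 10000)

rankCompare(scores(resA$raw[["p<=1e-02"]]),
            scores(resB$raw[["p<=1e-02"]]))$p   # raw scores: chip-biased
a <- scores(resA$summed); b <- scores(resB$summed)
rankCompare(as.numeric(a), as.numeric(b))$p     # summed PGS: comparable
cor(a, b[names(a)])

## combined genetic + questionnaire risk model, top-decile odds ratio
data <- buildAnalysisCohort(study@covariates, study@outcomes,
                            pgs = resA$summed, target = "incidence")
fit <- fitCox(data, modelSpec("T2D",
         c("BMI", "SmokerPast", "SmokerCurrent", "PAModerate",
           "PAVigorous", "Sex", "FatherDisease", "MotherDisease", "PGS"),
         covariateOnly = character(0)))
risk <- applyModel(fit, data)
topDecileOr(assignDeciles(risk), setNames(data$case, data$sample_id))
```

Output:

```
raw-score chip bias, Mann-Whitney p: 2.13e-100
summed PGS, Mann-Whitney p: 0.362
per-individual cross-chip correlation: 0.885
top-decile odds ratio: 4.34 (95% CI 2.31-8.14)
```

The raw scores from the two chips are distributed so differently that a
rank test rejects at p ≈ 1e-100 — the bias that makes raw PGS unusable
across chips — while the summed PGS distributions are statistically
indistinguishable (p = 0.36) and the *same individuals* receive strongly
correlated calibrated scores (r = 0.89) on either chip. The fitted
combined model then identifies a top risk decile with about 4-fold higher
incidence odds than the rest of the cohort.

File-based runs (`runSimulate`, `runScore`, `runTrain`, `runPredict`,
`runStratify`, or the `inst/scripts/chippgs` command-line wrapper) read a
YAML config and write TSV/JSON outputs plus a `run_report.json` with every
filter count and seed.

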