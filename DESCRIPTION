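Package: chipPGS
Title: Chip-Naive Polygenic Score Calibration and Combined Risk Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes polygenic scores (PGS) from GWAS summary statistics and
    genotype dosages at two p-value thresholds, shrinks marginal effects with
    an infinitesimal-model (LDpred-inf style) posterior mean using
    reference-panel linkage disequilibrium, and calibrates raw scores by
    projecting them onto the percentile scale of a whole-genome reference
    cohort so that scores from genotyping chips with different marker content
    become directly comparable (the "summed PGS", range 2-200). Also provides
    proportional-hazards and logistic risk models combining the calibrated
    score with questionnaire covariates (BMI, smoking, physical activity, sex,
    parental disease, age), decile-based risk stratification with top-decile
    odds ratios, model-overlap tables and BMI-by-genetic-risk incidence
    cross-tabulations, and a fully parameterised synthetic-cohort simulator
    (reference panel, partially overlapping chips, summary statistics,
    covariates, time-to-event outcomes) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Genetics,
    Survival, RiskAssessment
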