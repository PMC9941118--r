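#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## ---------------------------------------------------------------------------
## SummaryStats
## ---------------------------------------------------------------------------

#' GWAS summary statistics
#'
#' Per-variant marginal effect estimates from a genome-wide association study:
#' the variant key, the effect and other allele, the per-allele effect size
#' (log-odds scale for binary traits), the association p-value and the GWAS
#' sample size. Records violating the class invariants (p outside (0, 1],
#' identical alleles, non-finite effect, duplicated key) are dropped at
#' construction time and counted in the drop report.
#'
#' @slot stats data.frame with columns \code{key}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{p_value},
#'   \code{n_gwas}.
#' @slot dropReport named integer vector counting records dropped per reason.
#'
#' @export
setClass("SummaryStats",
    slots = c(stats = "data.frame", dropReport = "integer"))

setValidity("SummaryStats", function(object) {
    df <- object@stats
    need <- c("key", "chrom", "pos", "effect_allele", "other_allele",
              "beta", "p_value", "n_gwas")
    if (!all(need %in% names(df)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(df)), collapse = ", ")))
    if (nrow(df)) {
        if (anyDuplicated(df$key)) return("variant keys must be unique")
        if (any(df$p_value <= 0 | df$p_value > 1))
            return("p_value must lie in (0, 1]")
        if (any(df$effect_allele == df$other_allele))
            return("effect and other allele must differ")
        if (any(!is.finite(df$beta))) return("beta must be finite")
    }
    TRUE
})

#' @rdname SummaryStats-class
#' @param stats data.frame of per-variant records (see slots).
#' @param dropReport named integer vector of drop counts.
#' @export
SummaryStats <- function(stats, dropReport = integer(0)) {
    rownames(stats) <- NULL
    new("SummaryStats", stats = stats,
        dropReport = setNames(as.integer(dropReport), names(dropReport)))
}

setMethod("show", "SummaryStats", function(object) {
    cat("SummaryStats with", nrow(object@stats), "variants\n")
    if (length(object@dropReport) && sum(object@dropReport) > 0) {
        cat("  dropped at parse:",
            paste(names(object@dropReport), object@dropReport,
                  sep = "=", collapse = ", "), "\n")
    }
    if (nrow(object@stats)) {
        cat("  p-value range: [",
            format(min(object@stats$p_value), digits = 3), ", ",
            format(max(object@stats$p_value), digits = 3), "]\n", sep = "")
    }
})

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Genotype dosage matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} holding expected
#' alternate-allele counts (dosages in [0, 2]) for biallelic variants, one row
#' per variant and one column per sample, with per-variant imputation quality
#' (R-squared) and REF/ALT alleles in the row metadata. The single assay is
#' named \code{"DS"}.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    if (!"DS" %in% SummarizedExperiment::assayNames(object))
        return("assay 'DS' (dosage) is required")
    d <- SummarizedExperiment::assay(object, "DS")
    if (any(!is.na(d) & (d < -1e-9 | d > 2 + 1e-9)))
        return("dosages must lie in [0, 2]")
    rd <- SummarizedExperiment::rowData(object)
    need <- c("key", "ref", "alt", "r2")
    if (!all(need %in% names(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    if (anyDuplicated(rd$key)) return("variant keys must be unique")
    r2 <- rd$r2
    if (any(!is.na(r2) & (r2 < 0 | r2 > 1)))
        return("imputation r2 must lie in [0, 1]")
    TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix, variants x samples, values in [0, 2]
#'   (NA allowed for sporadically missing genotypes).
#' @param variants data.frame with columns \code{key}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} and optionally \code{r2}
#'   (defaults to 1, i.e. directly genotyped / sequenced).
#' @param sampleIds character vector of sample identifiers
#'   (defaults to \code{colnames(dosages)}).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosages, variants,
                           sampleIds = colnames(dosages)) {
    stopifnot(nrow(dosages) == nrow(variants))
    if (is.null(variants$r2)) variants$r2 <- rep(1, nrow(variants))
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(ncol(dosages)))
    gr <- GRanges(as.character(variants$chrom),
                  IRanges(start = as.integer(variants$pos), width = 1L))
    names(gr) <- variants$key
    mcols(gr) <- DataFrame(key = variants$key,
                           ref = as.character(variants$ref),
                           alt = as.character(variants$alt),
                           r2 = as.numeric(variants$r2))
    dimnames(dosages) <- list(variants$key, sampleIds)
    se <- SummarizedExperiment(assays = list(DS = dosages), rowRanges = gr,
                               colData = DataFrame(row.names = sampleIds))
    new("GenotypeMatrix", se)
}

## ---------------------------------------------------------------------------
## HarmonizedPanel
## ---------------------------------------------------------------------------

#' Three-way harmonized variant panel
#'
#' The intersection of GWAS summary statistics, target-cohort genotypes and
#' reference-panel genotypes, with both dosage matrices re-coded to count the
#' summary-statistics effect allele so that a single beta vector applies to
#' all genomes. Variants that could not be reconciled are kept in the
#' exclusion log with a reason, never in the panel.
#'
#' @slot variants data.frame, one row per retained variant, in panel order:
#'   key, alleles, aligned beta, p-value, per-source flip flags and the
#'   reference-panel effect-allele frequency.
#' @slot target numeric matrix, variants x samples (target cohort).
#' @slot reference numeric matrix, variants x samples (reference panel).
#' @slot exclusions data.frame with columns key, source, reason.
#' @slot aligned logical; TRUE once effect alleles have been aligned.
#'
#' @export
setClass("HarmonizedPanel",
    slots = c(variants = "data.frame", target = "matrix",
              reference = "matrix", exclusions = "data.frame",
              aligned = "logical"))

setValidity("HarmonizedPanel", function(object) {
    nv <- nrow(object@variants)
    if (nrow(object@target) != nv || nrow(object@reference) != nv)
        return("variant table and dosage matrices must agree in row count")
    if (nv && nrow(object@exclusions) &&
        any(object@variants$key %in% object@exclusions$key))
        return("a variant cannot be both retained and excluded")
    TRUE
})

setMethod("show", "HarmonizedPanel", function(object) {
    cat("HarmonizedPanel:", nrow(object@variants), "variants,",
        ncol(object@target), "target and", ncol(object@reference),
        "reference samples\n")
    cat("  effect alleles aligned:", object@aligned, "\n")
    if (nrow(object@exclusions)) {
        tab <- table(object@exclusions$reason)
        cat("  exclusions:",
            paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
            "\n")
    }
})

## ---------------------------------------------------------------------------
## Scores
## ---------------------------------------------------------------------------

#' Raw polygenic scores
#'
#' Per-sample weighted dosage sums at one p-value threshold, before
#' percentile calibration. The orientation flag records whether higher
#' scores mean higher risk ("risk") or protection ("protection").
#'
#' @export
setClass("RawPGS",
    slots = c(score = "numeric", threshold = "character",
              orientation = "character"))

setValidity("RawPGS", function(object) {
    if (any(!is.finite(object@score))) return("scores must be finite")
    if (is.null(names(object@score))) return("scores must be named by sample")
    if (!object@orientation %in% c("risk", "protection"))
        return("orientation must be 'risk' or 'protection'")
    TRUE
})

#' @rdname RawPGS-class
#' @param score named numeric vector of per-sample scores.
#' @param threshold character label, e.g. "p<=0.01".
#' @param orientation "risk" or "protection".
#' @export
RawPGS <- function(score, threshold, orientation = "risk")
    new("RawPGS", score = score, threshold = as.character(threshold),
        orientation = orientation)

setMethod("show", "RawPGS", function(object) {
    cat("RawPGS [", object@threshold, ", ", object@orientation, "]: ",
        length(object@score), " samples, mean ",
        format(mean(object@score), digits = 4), "\n", sep = "")
})

#' Empirical reference score distribution
#'
#' Sorted raw scores of the reference cohort at one threshold; the yardstick
#' against which target-cohort raw scores are converted to percentiles.
#'
#' @export
setClass("ReferenceDistribution",
    slots = c(values = "numeric", threshold = "character",
              orientation = "character"))

setValidity("ReferenceDistribution", function(object) {
    if (length(object@values) < 2)
        return("a reference distribution needs at least 2 samples")
    if (is.unsorted(object@values)) return("values must be sorted ascending")
    TRUE
})

#' Summed percentile-calibrated PGS
#'
#' Per-sample sum of the two percentile projections (one per p-value
#' threshold); each component lies in [1, 100], the sum in [2, 200].
#'
#' @export
setClass("SummedPGS",
    slots = c(sampleId = "character", components = "matrix",
              summed = "integer"))

setValidity("SummedPGS", function(object) {
    if (ncol(object@components) != 2)
        return("exactly two threshold components are required")
    if (nrow(object@components) != length(object@sampleId) ||
        length(object@summed) != length(object@sampleId))
        return("component rows, summed scores and sample ids must align")
    if (length(object@summed)) {
        if (any(object@components < 1 | object@components > 100))
            return("percentile components must lie in [1, 100]")
        if (any(object@summed < 2L | object@summed > 200L))
            return("summed PGS must lie in [2, 200]")
        if (any(object@summed != as.integer(rowSums(object@components))))
            return("summed score must equal the sum of its components")
    }
    TRUE
})

setMethod("show", "SummedPGS", function(object) {
    cat("SummedPGS:", length(object@summed), "samples; thresholds",
        paste(colnames(object@components), collapse = " + "), "\n")
    if (length(object@summed))
        cat("  summed score range: [", min(object@summed), ", ",
            max(object@summed), "]\n", sep = "")
})

## ---------------------------------------------------------------------------
## Risk models
## ---------------------------------------------------------------------------

#' Risk model specification
#'
#' Which terms of the combined genetic + questionnaire formula enter the
#' model, which cohort-specific nuisance covariates (principal components,
#' genotyping batch) are adjusted for, the model family and whether the model
#' targets incidence (time-to-event after baseline, prevalent cases excluded)
#' or prevalence (case status at baseline).
#'
#' @export
setClass("ModelSpec",
    slots = c(outcome = "character", terms = "character",
              covariateOnly = "character", family = "character",
              target = "character"))

.MODEL_TERMS <- c("BMI", "SmokerPast", "SmokerCurrent", "PAModerate",
                  "PAVigorous", "Sex", "FatherDisease", "MotherDisease",
                  "PGS", "Age", "PGSxBMI")

setValidity("ModelSpec", function(object) {
    if (!object@family %in% c("cox", "logistic"))
        return("family must be 'cox' or 'logistic'")
    if (!object@target %in% c("incidence", "prevalence"))
        return("target must be 'incidence' or 'prevalence'")
    bad <- setdiff(object@terms, .MODEL_TERMS)
    if (length(bad))
        return(paste("unknown terms:", paste(bad, collapse = ", ")))
    if ("PGSxBMI" %in% object@terms &&
        !all(c("PGS", "BMI") %in% object@terms))
        return("PGSxBMI requires both PGS and BMI in the term set")
    TRUE
})

setMethod("$", "ModelSpec", function(x, name) slot(x, name))

#' @rdname ModelSpec-class
#' @param outcome outcome label (e.g. "T2D").
#' @param terms character vector of model terms; see
#'   \code{chipPGS:::.MODEL_TERMS} for the full set.
#' @param covariateOnly nuisance covariates, default first 4 PCs and batch.
#' @param family "cox" or "logistic".
#' @param target "incidence" or "prevalence".
#' @export
modelSpec <- function(outcome, terms,
                      covariateOnly = c("PC1", "PC2", "PC3", "PC4", "batch"),
                      family = c("cox", "logistic"),
                      target = c("incidence", "prevalence")) {
    new("ModelSpec", outcome = outcome, terms = terms,
        covariateOnly = covariateOnly, family = match.arg(family),
        target = match.arg(target))
}

#' Fitted risk model
#'
#' Named coefficient vector of the combined risk formula together with its
#' variance matrix, the log-(partial-)likelihood at the optimum, the model
#' family and the number of samples used in the fit.
#'
#' @export
setClass("FittedRiskModel",
    slots = c(coefficients = "numeric", vcov = "matrix", family = "character",
              target = "character", terms = "character",
              covariateOnly = "character", logLik = "numeric", n = "integer"))

setValidity("FittedRiskModel", function(object) {
    if (any(!is.finite(object@coefficients)))
        return("coefficients must be finite")
    if (object@family == "logistic" && object@logLik > 1e-8)
        return("logistic log-likelihood must be <= 0")
    TRUE
})

setMethod("show", "FittedRiskModel", function(object) {
    cat("FittedRiskModel (", object@family, ", ", object@target, "): n = ",
        object@n, ", logLik = ", format(object@logLik, digits = 6),
        "\n", sep = "")
    print(round(object@coefficients, 5))
})

## ---------------------------------------------------------------------------
## Stratification
## ---------------------------------------------------------------------------

#' Decile assignment
#'
#' Per-sample risk decile (1 = lowest, 10 = highest risk) derived from a
#' vector of risk scores, with ties broken by stable sample-id order.
#'
#' @export
setClass("DecileAssignment", slots = c(decile = "integer"))

setValidity("DecileAssignment", function(object) {
    d <- object@decile
    if (is.null(names(d))) return("deciles must be named by sample")
    if (any(d < 1L | d > 10L)) return("deciles must lie in 1..10")
    sz <- tabulate(d, 10L)
    if (max(sz) - min(sz) > 1L)
        return("decile sizes may differ by at most 1")
    TRUE
})

setMethod("show", "DecileAssignment", function(object) {
    cat("DecileAssignment:", length(object@decile), "samples; sizes:",
        paste(tabulate(object@decile, 10L), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

#' Synthetic study configuration
#'
#' All parameters of the synthetic-cohort generator: panel and cohort sizes,
#' variant count, allele-frequency range, LD block structure, chip retention
#' and overlap fractions, the trait architecture (fraction causal, target
#' heritability, GWAS sample size), covariate effect sizes on the hazard
#' scale, incidence / prevalence calibration targets, follow-up horizon and
#' the mandatory RNG seed.
#'
#' @export
setClass("SimulationConfig",
    slots = c(nReference = "integer", nCohort = "integer",
              mVariants = "integer", freqRange = "numeric",
              blockSize = "integer", blockRho = "numeric",
              chipRetain = "numeric", chipOverlap = "numeric",
              fractionCausal = "numeric", h2 = "numeric", nGwas = "integer",
              effects = "numeric", bmiMean = "numeric", bmiSd = "numeric",
              ageRange = "numeric", sexP = "numeric", smokingP = "numeric",
              paModerateMean = "numeric", paVigorousMean = "numeric",
              parentP = "numeric", incidenceTarget = "numeric",
              prevalenceTarget = "numeric", followupYears = "numeric",
              chipR2Range = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    fr <- c(object@chipRetain, object@chipOverlap, object@fractionCausal,
            object@incidenceTarget, object@prevalenceTarget)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
    if (object@h2 <= 0 || object@h2 >= 1) return("h2 must lie in (0, 1)")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("a single integer seed is mandatory")
    if (object@mVariants < 2L * object@blockSize)
        return("mVariants must be at least twice the LD block size")
    if (abs(sum(object@smokingP) - 1) > 1e-8)
        return("smoking probabilities must sum to 1")
    TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: ", object@mVariants, " variants, ",
        object@nReference, " reference + ", object@nCohort,
        " cohort samples, seed ", object@seed, "\n", sep = "")
    cat("  LD blocks of ", object@blockSize, " (latent rho ",
        object@blockRho, "); chips retain ", round(object@chipRetain, 3),
        ", overlap ", round(object@chipOverlap, 3), "\n", sep = "")
    cat("  h2 = ", object@h2, ", GWAS n = ", object@nGwas,
        "; incidence target ", object@incidenceTarget,
        ", prevalence target ", object@prevalenceTarget, "\n", sep = "")
})

#' Synthetic cohort bundle
#'
#' Everything the pipeline consumes, generated with known ground truth:
#' the reference panel, the study cohort with two chip views of the same
#' genomes, simulated GWAS summary statistics, covariates and time-to-event
#' outcomes, plus the ground-truth parameter record.
#'
#' @export
setClass("SyntheticCohort",
    slots = c(reference = "GenotypeMatrix", cohort = "GenotypeMatrix",
              chipA = "GenotypeMatrix", chipB = "GenotypeMatrix",
              sumstats = "SummaryStats", covariates = "data.frame",
              outcomes = "data.frame", truth = "list",
              config = "SimulationConfig"))

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort (seed ", object@config@seed, ")\n", sep = "")
    cat("  reference:", nrow(object@reference), "variants x",
        ncol(object@reference), "samples\n")
    cat("  cohort:", ncol(object@cohort), "samples; chips A/B:",
        nrow(object@chipA), "/", nrow(object@chipB), "variants\n")
    cat("  outcomes:", sum(object@outcomes$prevalent), "prevalent,",
        sum(object@outcomes$event[!object@outcomes$prevalent]),
        "incident cases\n")
})
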