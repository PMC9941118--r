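#' Chip-naive scoring pipeline
#'
#' Runs the full calibration chain on in-memory objects: quality filter,
#' three-way harmonization, per-threshold infinitesimal reweighting, raw
#' scoring of both the target cohort and the reference panel on the *same*
#' harmonized variant set, percentile projection of the target against the
#' reference distribution, and the summed PGS. Exactly two p-value
#' thresholds are required. Scores are calibrated in the risk-increasing
#' orientation.
#'
#' @param ss a \linkS4class{SummaryStats}.
#' @param target,reference \linkS4class{GenotypeMatrix} objects.
#' @param thresholds two inclusive p-value thresholds
#'   (default \code{c(0.01, 1e-6)}).
#' @param h2 assumed heritability for the infinitesimal shrinkage.
#' @param nGwas GWAS sample size; defaults to the median \code{n} of the
#'   summary statistics.
#' @param window LD window in variants (default 100).
#' @param r2Min imputation-quality filter applied to the target
#'   (default 0.4).
#' @param dropAmbiguous exclude strand-ambiguous variants (default TRUE).
#' @param orientation orientation of the raw scores implied by the summary
#'   statistics; \code{"protection"} flips them to risk before calibration.
#' @return list with \code{summed} (a \linkS4class{SummedPGS}),
#'   \code{raw} (per-threshold target \linkS4class{RawPGS}),
#'   \code{rawReference} (same for the reference), \code{panel} (the
#'   aligned \linkS4class{HarmonizedPanel}) and \code{report} (filter
#'   counts).
#' @export
scorePipeline <- function(ss, target, reference,
                          thresholds = c(0.01, 1e-6), h2 = 0.3,
                          nGwas = NULL, window = 100L, r2Min = 0.4,
                          dropAmbiguous = TRUE,
                          orientation = c("risk", "protection")) {
    orientation <- match.arg(orientation)
    if (length(thresholds) != 2)
        stop("exactly two p-value thresholds are required")
    if (is.null(nGwas)) nGwas <- stats::median(ss@stats$n_gwas)
    target <- filterByQuality(target, r2Min)
    panel <- harmonizePanels(ss, target, reference,
                             dropAmbiguous = dropAmbiguous)
    labels <- paste0("p<=", format(thresholds))
    raw <- list(); rawRef <- list(); pcts <- list()
    for (i in 1:2) {
        sub <- subsetPanel(panel, thresholds[i])
        cfg <- infinitesimalConfig(h2 = h2, nGwas = nGwas, window = window)
        bt <- infinitesimalReweight(sub, cfg)
        rt <- computeRawPgs(sub, bt, "target", threshold = labels[i])
        rr <- computeRawPgs(sub, bt, "reference", threshold = labels[i])
        if (orientation == "protection") {
            rt@orientation <- "protection"; rr@orientation <- "protection"
            rt <- orientScore(rt, "risk"); rr <- orientScore(rr, "risk")
        }
        refDist <- buildReferenceDistribution(rr)
        pcts[[labels[i]]] <- percentileProject(rt, refDist)
        raw[[labels[i]]] <- rt
        rawRef[[labels[i]]] <- rr
    }
    report <- list(
        thresholds = thresholds, h2 = h2, nGwas = nGwas, window = window,
        r2Min = r2Min,
        variants = c(sumstats = nrow(ss@stats),
                     target_postQC = nrow(target),
                     harmonized = nrow(panelVariants(panel)),
                     excluded = nrow(exclusions(panel))),
        variantsPerThreshold = vapply(thresholds, function(t)
            sum(panelVariants(panel)$p_value <= t), numeric(1)))
    list(summed = summedPgs(pcts), raw = raw, rawReference = rawRef,
         panel = panel, report = report)
}

## ---------------------------------------------------------------------------
## run-directory commands (the shell entry points call these)
## ---------------------------------------------------------------------------

.readRunConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    defaults <- list(thresholds = c(0.01, 1e-6), h2 = 0.3, window = 100L,
                     r2_min = 0.4, drop_ambiguous = TRUE, seed = NULL,
                     model = list(family = "cox", target = "incidence",
                                  terms = c("BMI", "SmokerPast",
                                            "SmokerCurrent", "PAModerate",
                                            "PAVigorous", "Sex",
                                            "FatherDisease",
                                            "MotherDisease", "PGS")))
    cfg <- utils::modifyList(defaults, config)
    if (length(cfg$thresholds) != 2)
        stop("config must specify exactly two score thresholds")
    cfg
}

.writeRunReport <- function(outDir, command, cfg, extra = list()) {
    rep <- c(list(command = command, timestamp = as.character(Sys.time()),
                  package_version = as.character(
                      utils::packageVersion("chipPGS")),
                  config = cfg), extra)
    jsonlite::write_json(rep, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Run commands
#'
#' Thin, file-based entry points tying the modules into reproducible runs;
#' each writes its outputs plus a \code{run_report.json} (inputs,
#' parameters, seed, filter counts) into \code{outDir}. \code{runSimulate}
#' writes a complete synthetic study; \code{runScore} computes calibrated
#' summed PGS from a summary-statistics TSV and two VCFs; \code{runTrain}
#' fits the risk model and serializes it; \code{runPredict} applies a
#' stored model to a cohort; \code{runStratify} derives deciles, the
#' top-decile odds ratio and the per-decile risk curve from predictions.
#'
#' @param config list or path to a YAML file. Recognised keys (defaults in
#'   parentheses): \code{sumstats}, \code{target_vcf}, \code{reference_vcf},
#'   \code{covariates} (paths); \code{thresholds} (0.01, 1e-6); \code{h2}
#'   (0.3); \code{window} (100); \code{r2_min} (0.4); \code{seed};
#'   \code{model} (family, target, terms); \code{simulation} (arguments to
#'   \code{\link{simulationConfig}}).
#' @param outDir output directory, created if missing.
#' @return Paths of the written artifacts, invisibly.
#' @name runCommands
NULL

#' @rdname runCommands
#' @export
runSimulate <- function(config, outDir) {
    cfg <- .readRunConfig(config)
    if (is.null(cfg$seed)) stop("simulate requires a seed in the config")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    simArgs <- c(list(seed = cfg$seed), cfg$simulation)
    sc <- simulateStudy(do.call(simulationConfig, simArgs))
    paths <- writeCohort(sc, outDir)
    .writeRunReport(outDir, "simulate", cfg,
                    list(files = as.list(paths)))
    invisible(paths)
}

#' @rdname runCommands
#' @export
runScore <- function(config, outDir) {
    cfg <- .readRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (key in c("sumstats", "target_vcf", "reference_vcf"))
        if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
            stop("missing input file for '", key, "': ", cfg[[key]])
    ss <- readSumstats(cfg$sumstats)
    target <- readGenotypes(cfg$target_vcf, r2Min = cfg$r2_min)
    reference <- readGenotypes(cfg$reference_vcf, r2Min = 0)
    res <- scorePipeline(ss, target, reference,
                         thresholds = cfg$thresholds, h2 = cfg$h2,
                         window = cfg$window, r2Min = cfg$r2_min,
                         dropAmbiguous = cfg$drop_ambiguous)
    scorePath <- file.path(outDir, "summed_pgs.tsv")
    writeSummedPgs(res$summed, scorePath)
    writeExclusionLog(res$panel, file.path(outDir, "exclusions.tsv"))
    .writeRunReport(outDir, "score", cfg, res$report)
    invisible(scorePath)
}

#' @rdname runCommands
#' @param scoresPath TSV of calibrated scores (from \code{runScore}).
#' @export
runTrain <- function(config, scoresPath, outDir) {
    cfg <- .readRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cv <- readCovariates(cfg$covariates)
    sp <- .readSummedTsv(scoresPath)
    data <- buildAnalysisCohort(cv$covariates, cv$outcomes, pgs = sp,
                                target = cfg$model$target)
    spec <- modelSpec(cfg$model$outcome %||% "outcome",
                      terms = cfg$model$terms,
                      family = cfg$model$family,
                      target = cfg$model$target)
    fit <- if (spec@family == "cox") fitCox(data, spec)
           else fitLogistic(data, spec)
    modelPath <- file.path(outDir, "model.json")
    writeModel(fit, modelPath)
    .writeRunReport(outDir, "train", cfg,
                    list(n_fit = fit@n, logLik = fit@logLik))
    invisible(modelPath)
}

#' @rdname runCommands
#' @param modelPath serialized model (from \code{runTrain}).
#' @export
runPredict <- function(config, modelPath, scoresPath, outDir) {
    cfg <- .readRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    model <- readModel(modelPath)
    cv <- readCovariates(cfg$covariates)
    sp <- .readSummedTsv(scoresPath)
    data <- buildAnalysisCohort(cv$covariates, cv$outcomes, pgs = sp,
                                target = model@target)
    scoreVec <- applyModel(model, data)
    out <- data.frame(sample_id = names(scoreVec), risk_score = scoreVec)
    path <- file.path(outDir, "risk_scores.tsv")
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    .writeRunReport(outDir, "predict", cfg, list(n = nrow(out)))
    invisible(path)
}

#' @rdname runCommands
#' @param predictionsPath TSV of risk scores (from \code{runPredict}).
#' @export
runStratify <- function(config, predictionsPath, outDir) {
    cfg <- .readRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pred <- read.delim(predictionsPath, stringsAsFactors = FALSE)
    cv <- readCovariates(cfg$covariates)
    data <- buildAnalysisCohort(cv$covariates, cv$outcomes,
                                target = cfg$model$target)
    sc <- setNames(pred$risk_score, pred$sample_id)[data$sample_id]
    dec <- assignDeciles(sc)
    or <- topDecileOr(dec, setNames(data$case, data$sample_id))
    curve <- decileRiskCurve(dec, setNames(data$case, data$sample_id))
    writeStratTable(curve, file.path(outDir, "decile_risk.tsv"))
    orDf <- data.frame(or = or$or, ci_lower = or$ci[1],
                       ci_upper = or$ci[2], flagged = or$flagged)
    writeStratTable(orDf, file.path(outDir, "top_decile_or.tsv"))
    bmiTab <- bmiByRiskTable(setNames(data$bmi, data$sample_id), dec,
                             setNames(data$case, data$sample_id))
    writeStratTable(bmiTab$cells, file.path(outDir, "bmi_by_risk.tsv"))
    writeStratTable(bmiTab$tests,
                    file.path(outDir, "bmi_by_risk_tests.tsv"))
    .writeRunReport(outDir, "stratify", cfg,
                    list(top_decile_or = or$or))
    invisible(outDir)
}

.readSummedTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    comp <- as.matrix(df[, 2:3])
    rownames(comp) <- df$sample_id
    colnames(comp) <- sub("^pct_", "", colnames(comp))
    new("SummedPGS", sampleId = as.character(df$sample_id),
        components = comp, summed = as.integer(df$summed_pgs))
}
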