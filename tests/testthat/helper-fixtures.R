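## Shared fixture builders; everything is generated in code at test time.

.fixtureCache <- new.env(parent = emptyenv())

## A small synthetic study reused across test files (memoised per session).
smallStudy <- function() {
    if (is.null(.fixtureCache$study)) {
        cfg <- simulationConfig(seed = 424, nReference = 150L,
                                nCohort = 400L, mVariants = 500L,
                                incidenceTarget = 0.06)
        .fixtureCache$study <- simulateStudy(cfg)
    }
    .fixtureCache$study
}

## GenotypeMatrix from a plain dosage matrix (variants x samples).
toyGm <- function(dos, ref = NULL, alt = NULL, r2 = NULL,
                  pos = seq_len(nrow(dos)) * 100L, chrom = "1") {
    m <- nrow(dos)
    if (is.null(ref)) ref <- rep("A", m)
    if (is.null(alt)) alt <- rep("G", m)
    if (is.null(r2)) r2 <- rep(1, m)
    if (is.null(colnames(dos)))
        colnames(dos) <- paste0("S", seq_len(ncol(dos)))
    GenotypeMatrix(dos, data.frame(
        key = variantKey(chrom, pos, ref, alt), chrom = chrom, pos = pos,
        ref = ref, alt = alt, r2 = r2, stringsAsFactors = FALSE))
}

## SummaryStats from vectors, keyed consistently with toyGm().
toySs <- function(beta, p, ref = NULL, alt = NULL,
                  pos = seq_along(beta) * 100L, chrom = "1",
                  effectIsAlt = TRUE, n = 10000L) {
    m <- length(beta)
    if (is.null(ref)) ref <- rep("A", m)
    if (is.null(alt)) alt <- rep("G", m)
    effectIsAlt <- rep_len(effectIsAlt, m)
    ea <- ifelse(effectIsAlt, alt, ref)
    oa <- ifelse(effectIsAlt, ref, alt)
    SummaryStats(data.frame(
        key = variantKey(chrom, pos, ea, oa), chrom = chrom, pos = pos,
        effect_allele = ea, other_allele = oa, beta = beta, p_value = p,
        n_gwas = n, stringsAsFactors = FALSE))
}

## Hand-built aligned HarmonizedPanel for scoring-level tests.
toyPanel <- function(beta, target, reference, p = rep(0.5, length(beta))) {
    m <- length(beta)
    if (is.null(colnames(target)))
        colnames(target) <- paste0("S", seq_len(ncol(target)))
    if (is.null(colnames(reference)))
        colnames(reference) <- paste0("R", seq_len(ncol(reference)))
    v <- data.frame(
        key = paste0("1:", seq_len(m) * 100, ":A/G"), chrom = "1",
        pos = seq_len(m) * 100L, effect_allele = "G", other_allele = "A",
        beta = beta, p_value = p, n_gwas = 10000L,
        target_ref = "A", target_alt = "G", reference_ref = "A",
        reference_alt = "G", flipped_target = FALSE,
        flipped_reference = FALSE,
        eaf_reference = rowMeans(reference) / 2,
        stringsAsFactors = FALSE)
    rownames(target) <- v$key
    rownames(reference) <- v$key
    new("HarmonizedPanel", variants = v, target = target,
        reference = reference,
        exclusions = data.frame(key = character(0), source = character(0),
                                reason = character(0)),
        aligned = TRUE)
}

## Canonical covariate / outcome data.frames for risk-model tests.
toyCohortTables <- function(n, seed = 1, eventP = 0.2, prevalentP = 0) {
    withr::with_seed(seed, {
        cov <- data.frame(
            sample_id = sprintf("P%04d", seq_len(n)),
            bmi = rnorm(n, 26, 4), sex = rbinom(n, 1, 0.5),
            smoking = sample(c("never", "past", "current"), n, TRUE),
            pa_moderate = rbinom(n, 7, 0.5), pa_vigorous = rbinom(n, 7, 0.3),
            father_disease = rbinom(n, 1, 0.1),
            mother_disease = rbinom(n, 1, 0.1),
            age = runif(n, 40, 70), pc1 = rnorm(n), pc2 = rnorm(n),
            pc3 = rnorm(n), pc4 = rnorm(n),
            batch = sample(c("B1", "B2"), n, TRUE),
            stringsAsFactors = FALSE)
        prevalent <- rbinom(n, 1, prevalentP)
        event <- ifelse(prevalent == 1, 0L, rbinom(n, 1, eventP))
        out <- data.frame(
            sample_id = cov$sample_id, prevalent = prevalent,
            event = event,
            time_years = ifelse(prevalent == 1, 0,
                                ifelse(event == 1, runif(n, 0, 10), 10)),
            stringsAsFactors = FALSE)
        list(covariates = cov, outcomes = out)
    })
}

## Write a VCF fixture from raw lines.
writeVcfLines <- function(body, samples = c("S1", "S2"),
                          path = tempfile(fileext = ".vcf")) {
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=1>",
             paste0("##INFO=<ID=R2,Number=1,Type=Float,",
                    "Description=\"Imputation quality\">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, body), path)
    path
}

## Independent brute-force oracles ------------------------------------------

## percentile by explicit counting
oraclePercentile <- function(score, refValues) {
    n <- length(refValues)
    vapply(score, function(s) {
        cnt <- 0L
        for (r in refValues) if (r <= s) cnt <- cnt + 1L
        min(100L, max(1L, as.integer(ceiling(100 * cnt / n))))
    }, integer(1))
}

## two-sided Fisher p by full hypergeometric enumeration
oracleFisher <- function(tab) {
    a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    ks <- max(0L, c1 - (n - r1)):min(r1, c1)
    pr <- dhyper(ks, r1, n - r1, c1)
    pObs <- dhyper(a, r1, n - r1, c1)
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

## Harrell's C by exhaustive pairwise enumeration (continuous times)
oracleConcordance <- function(time, event, score) {
    num <- 0; den <- 0
    n <- length(time)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        ti <- time[i]; tj <- time[j]
        if (ti == tj) next
        sh <- if (ti < tj) i else j   # shorter time
        lo <- if (ti < tj) j else i
        if (event[sh] != 1) next      # usable only if shorter is an event
        den <- den + 1
        if (score[sh] > score[lo]) num <- num + 1
        else if (score[sh] == score[lo]) num <- num + 0.5
    }
    num / den
}

## 2x2 cross-product odds ratio
oracleCrossProduct <- function(tab)
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
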