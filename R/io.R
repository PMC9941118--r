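#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

#' Canonical variant key
#'
#' Chromosome, 1-based position and the alphabetically sorted allele pair,
#' joined as \code{"chrom:pos:A1/A2"}. Sorting the alleles makes the key
#' independent of which allele a file happens to call REF or effect allele,
#' so the same site matches across summary statistics, target genotypes and
#' the reference panel without an rsID.
#'
#' @param chrom,pos,a1,a2 vectors of equal length.
#' @return character vector of keys.
#' @export
variantKey <- function(chrom, pos, a1, a2) {
    a1 <- toupper(as.character(a1)); a2 <- toupper(as.character(a2))
    lo <- ifelse(a1 <= a2, a1, a2)
    hi <- ifelse(a1 <= a2, a2, a1)
    paste0(chrom, ":", pos, ":", lo, "/", hi)
}

## default column-name map for summary-statistics files
.SUMSTATS_DIALECT <- list(chrom = "chrom", pos = "pos",
                          effect_allele = "effect_allele",
                          other_allele = "other_allele",
                          beta = "beta", p_value = "p_value", n = "n")

#' Read GWAS summary statistics
#'
#' Parses a tab-separated summary-statistics file into a
#' \linkS4class{SummaryStats} object. Records that violate the invariants
#' (p-value outside (0, 1], identical alleles, non-finite beta, duplicated
#' variant key) are dropped and counted per reason; they are never silently
#' repaired.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect named list mapping canonical field names (\code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{p_value}, \code{n}) to the column names used in the file.
#' @return A \linkS4class{SummaryStats}; the drop report is available in the
#'   \code{dropReport} slot.
#' @export
readSumstats <- function(path, dialect = list()) {
    if (!file.exists(path)) stop("summary statistics file not found: ", path)
    dialect <- utils::modifyList(.SUMSTATS_DIALECT, dialect)
    raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(unlist(dialect), names(raw))
    if (length(missing))
        stop("mapped columns absent from ", path, ": ",
             paste(missing, collapse = ", "))
    df <- data.frame(
        chrom = as.character(raw[[dialect$chrom]]),
        pos = as.integer(raw[[dialect$pos]]),
        effect_allele = toupper(raw[[dialect$effect_allele]]),
        other_allele = toupper(raw[[dialect$other_allele]]),
        beta = as.numeric(raw[[dialect$beta]]),
        p_value = as.numeric(raw[[dialect$p_value]]),
        n_gwas = as.integer(raw[[dialect$n]]),
        stringsAsFactors = FALSE)
    df$key <- variantKey(df$chrom, df$pos, df$effect_allele, df$other_allele)

    drop <- c(bad_p = 0L, same_alleles = 0L, bad_beta = 0L,
              duplicate_key = 0L)
    bad <- is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1
    drop["bad_p"] <- sum(bad)
    same <- !bad & df$effect_allele == df$other_allele
    drop["same_alleles"] <- sum(same)
    nfin <- !bad & !same & !is.finite(df$beta)
    drop["bad_beta"] <- sum(nfin)
    keep <- !(bad | same | nfin)
    df <- df[keep, , drop = FALSE]
    dup <- df$key %in% df$key[duplicated(df$key)]
    drop["duplicate_key"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    if (!nrow(df)) stop("no valid summary-statistics records in ", path)
    SummaryStats(df[c("key", "chrom", "pos", "effect_allele", "other_allele",
                      "beta", "p_value", "n_gwas")], dropReport = drop)
}

#' Subset summary statistics at a p-value threshold
#'
#' Retains exactly the variants with \code{p_value <= pMax} (inclusive
#' boundary). An empty result is allowed — scoring zero variants yields a
#' score of 0 — and only warned about.
#'
#' @param ss a \linkS4class{SummaryStats}.
#' @param pMax threshold in (0, 1].
#' @return A \linkS4class{SummaryStats} with the retained records.
#' @export
thresholdSubset <- function(ss, pMax) {
    stopifnot(is(ss, "SummaryStats"), pMax > 0, pMax <= 1)
    keep <- ss@stats$p_value <= pMax
    if (!any(keep))
        warning("no variants at p <= ", pMax,
                "; downstream scores will be 0")
    SummaryStats(ss@stats[keep, , drop = FALSE], dropReport = ss@dropReport)
}

#' Read genotype dosages from a VCF
#'
#' Reads a VCF 4.x file into a \linkS4class{GenotypeMatrix}, applying the
#' record-level QC used throughout: multi-allelic sites are removed, sites
#' with imputation quality below \code{r2Min} are removed, and sites carrying
#' neither a dosage nor a genotype field are dropped with a warning. When the
#' per-genotype dosage field is present it is preferred; otherwise hard
#' genotypes are converted to dosages 0/1/2 (missing genotypes become NA).
#' Sites without the quality INFO field are treated as directly observed
#' (R-squared 1), appropriate for sequencing-based reference panels.
#'
#' @param path path to a VCF file.
#' @param r2Min minimum imputation R-squared; variants strictly below are
#'   removed (default 0.4).
#' @param dosageField FORMAT field holding dosages (default "DS").
#' @param r2Field INFO field holding imputation quality (default "R2").
#' @return A \linkS4class{GenotypeMatrix}; the QC counts are attached as
#'   attribute \code{"report"}.
#' @export
readGenotypes <- function(path, r2Min = 0.4, dosageField = "DS",
                          r2Field = "R2") {
    if (!file.exists(path)) stop("VCF not found: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    n0 <- nrow(vcf)

    multi <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) != 1L
    vcf <- vcf[!multi]

    inf <- VariantAnnotation::info(vcf)
    r2 <- if (r2Field %in% names(inf)) as.numeric(inf[[r2Field]])
          else rep(NA_real_, nrow(vcf))
    r2[is.na(r2)] <- 1
    lowq <- r2 < r2Min
    vcf <- vcf[!lowq]
    r2 <- r2[!lowq]

    gen <- VariantAnnotation::geno(vcf)
    ds <- if (dosageField %in% names(gen)) {
        d <- gen[[dosageField]]
        matrix(as.numeric(d), nrow = nrow(d), dimnames = dimnames(d))
    } else NULL
    gt <- if ("GT" %in% names(gen)) .gtToDosage(gen$GT) else NULL
    dosageSource <- if (!is.null(ds)) "dosage field" else "hard genotypes"
    if (is.null(ds)) {
        ds <- gt
    } else if (!is.null(gt)) {
        miss <- is.na(ds)          # fall back per genotype
        ds[miss] <- gt[miss]
    }
    if (is.null(ds))
        stop("VCF has neither a '", dosageField, "' nor a 'GT' field: ", path)

    noData <- rowSums(!is.na(ds)) == 0L
    if (any(noData)) {
        warning(sum(noData), " site(s) without dosage or genotype data ",
                "dropped")
        vcf <- vcf[!noData]; ds <- ds[!noData, , drop = FALSE]
        r2 <- r2[!noData]
    }

    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    variants <- data.frame(key = variantKey(chrom, pos, ref, alt),
                           chrom = chrom, pos = pos, ref = ref, alt = alt,
                           r2 = r2, stringsAsFactors = FALSE)
    dupk <- variants$key %in% variants$key[duplicated(variants$key)]
    if (any(dupk)) {
        warning(sum(dupk), " record(s) with duplicated variant key dropped")
        variants <- variants[!dupk, , drop = FALSE]
        ds <- ds[!dupk, , drop = FALSE]
    }
    gm <- GenotypeMatrix(ds, variants)
    attr(gm, "report") <- c(sites = n0, multiallelic = sum(multi),
                            low_r2 = sum(lowq), no_data = sum(noData),
                            retained = nrow(variants))
    attr(gm, "dosageSource") <- dosageSource
    gm
}

## "0/1", "1|1", "./." ... -> 0/1/2/NA; only biallelic codes expected
.gtToDosage <- function(gt) {
    u <- unique(as.vector(gt))
    val <- vapply(u, function(g) {
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".") || !length(al)) return(NA_real_)
        sum(al == "1")
    }, numeric(1))
    matrix(val[match(as.vector(gt), u)], nrow = nrow(gt),
           dimnames = dimnames(gt))
}

#' Filter a GenotypeMatrix by imputation quality
#'
#' In-memory counterpart of the read-time R-squared filter, for genotype
#' matrices that were constructed rather than read from disk.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param r2Min minimum imputation R-squared (default 0.4).
#' @return The filtered \linkS4class{GenotypeMatrix}.
#' @export
filterByQuality <- function(gm, r2Min = 0.4) {
    stopifnot(is(gm, "GenotypeMatrix"))
    r2 <- SummarizedExperiment::rowData(gm)$r2
    keep <- is.na(r2) | r2 >= r2Min
    gm[keep, ]
}

#' Write a GenotypeMatrix to VCF
#'
#' Emits a VCF 4.2 file with a GT and a DS FORMAT field and the imputation
#' quality as an INFO field. Dosages are written at three decimals; hard
#' genotypes are derived by rounding.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output path (plain-text \code{.vcf}).
#' @param dosageField,r2Field field names to write (defaults "DS", "R2").
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gm, path, dosageField = "DS", r2Field = "R2") {
    stopifnot(is(gm, "GenotypeMatrix"))
    vi <- variantInfo(gm)
    ds <- round(dosages(gm), 3)
    gtcode <- c("0/0", "0/1", "1/1")
    rd <- round(ds)
    gt <- matrix(ifelse(is.na(rd), "./.", gtcode[rd + 1L]),
                 nrow = nrow(ds), dimnames = dimnames(ds))
    gr <- GRanges(vi$chrom, IRanges(vi$pos, width = 1L))
    names(gr) <- vi$key
    hdr <- VariantAnnotation::VCFHeader(samples = colnames(ds))
    VariantAnnotation::geno(hdr) <- DataFrame(
        Number = c("1", "1"), Type = c("String", "Float"),
        Description = c("Genotype", "Estimated alternate allele dosage"),
        row.names = c("GT", dosageField))
    VariantAnnotation::info(hdr) <- DataFrame(
        Number = "1", Type = "Float",
        Description = "Imputation quality (R-squared)", row.names = r2Field)
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    geno <- stats::setNames(SimpleList(gt, ds), c("GT", dosageField))
    vcf <- VariantAnnotation::VCF(
        rowRanges = gr,
        fixed = DataFrame(REF = Biostrings::DNAStringSet(vi$ref),
                          ALT = Biostrings::DNAStringSetList(
                              as.list(vi$alt)),
                          QUAL = rep(NA_real_, nrow(vi)),
                          FILTER = rep("PASS", nrow(vi))),
        info = stats::setNames(DataFrame(round(vi$r2, 4)), r2Field),
        colData = DataFrame(row.names = colnames(ds)),
        exptData = list(header = hdr),
        geno = geno)
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}

#' Write summary statistics to TSV
#'
#' @param ss a \linkS4class{SummaryStats}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(ss, path) {
    stopifnot(is(ss, "SummaryStats"))
    df <- ss@stats
    out <- data.frame(chrom = df$chrom, pos = df$pos,
                      effect_allele = df$effect_allele,
                      other_allele = df$other_allele,
                      beta = df$beta, p_value = df$p_value, n = df$n_gwas)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## canonical covariate/outcome CSV columns
.COVARIATE_COLS <- c("sample_id", "bmi", "sex", "smoking", "pa_moderate",
                     "pa_vigorous", "father_disease", "mother_disease",
                     "age", "pc1", "pc2", "pc3", "pc4", "batch")
.OUTCOME_COLS <- c("sample_id", "prevalent", "event", "time_years")

#' Read the covariate / outcome table
#'
#' Reads the canonical CSV layout (columns \code{sample_id}, \code{bmi},
#' \code{sex}, \code{smoking} in \{never, past, current\},
#' \code{pa_moderate}, \code{pa_vigorous} in 0-7 days/week,
#' \code{father_disease}, \code{mother_disease}, \code{age},
#' \code{pc1}..\code{pc4}, \code{batch}, \code{prevalent}, \code{event},
#' \code{time_years}) and applies the record-level cleaning rules: missing
#' parental disease status is set to 0 (no reported illness), whereas samples
#' missing any other model covariate or the diagnosis/censoring time are
#' removed and counted.
#'
#' @param path path to a CSV file.
#' @return list with elements \code{covariates} (data.frame),
#'   \code{outcomes} (data.frame) and \code{report} (named removal counts).
#' @export
readCovariates <- function(path) {
    if (!file.exists(path)) stop("covariate file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- union(.COVARIATE_COLS, .OUTCOME_COLS)
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("covariate file lacks columns: ",
             paste(missing, collapse = ", "))

    nParentImputed <- sum(is.na(df$father_disease)) +
        sum(is.na(df$mother_disease))
    df$father_disease[is.na(df$father_disease)] <- 0
    df$mother_disease[is.na(df$mother_disease)] <- 0

    mustHave <- setdiff(need, c("father_disease", "mother_disease"))
    incomplete <- rowSums(is.na(df[mustHave])) > 0
    badSmoking <- !df$smoking %in% c("never", "past", "current")
    badPA <- df$pa_moderate < 0 | df$pa_moderate > 7 |
        df$pa_vigorous < 0 | df$pa_vigorous > 7
    badPA[is.na(badPA)] <- TRUE
    remove <- incomplete | badSmoking | badPA
    report <- c(total = nrow(df),
                parental_na_to_zero = nParentImputed,
                removed_missing = sum(incomplete),
                removed_invalid = sum(remove & !incomplete),
                retained = sum(!remove))
    df <- df[!remove, , drop = FALSE]
    if (!nrow(df)) stop("all samples removed during covariate cleaning")
    if (any(df$time_years < 0)) stop("negative follow-up times")
    df$sample_id <- as.character(df$sample_id)
    list(covariates = df[.COVARIATE_COLS],
         outcomes = data.frame(df[.OUTCOME_COLS],
                               stringsAsFactors = FALSE),
         report = report)
}

#' Write the covariate / outcome table
#'
#' @param covariates,outcomes data.frames as returned by
#'   \code{\link{readCovariates}} (joined on \code{sample_id}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCovariates <- function(covariates, outcomes, path) {
    df <- merge(covariates, outcomes, by = "sample_id", sort = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
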