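## Strand-ambiguous allele pairs cannot be oriented without frequency
## information, so they are excluded by default.
.AMBIGUOUS <- c("A/T", "C/G")

.pairLabel <- function(a1, a2) {
    lo <- ifelse(a1 <= a2, a1, a2)
    paste0(lo, "/", ifelse(a1 <= a2, a2, a1))
}

#' Three-way variant intersection
#'
#' Restricts the analysis to variants present (by canonical key) in all
#' three inputs: the GWAS summary statistics, the target-cohort genotypes
#' and the reference panel. Variants found in only some sources are logged
#' with the sources that lacked them; positions carrying more than one
#' distinct allele pair within a source are ambiguous keys and are excluded
#' outright. Dosages are carried over unmodified — effect-allele alignment
#' is a separate step (\code{\link{alignEffectAlleles}}).
#'
#' @param ss a \linkS4class{SummaryStats}.
#' @param target,reference \linkS4class{GenotypeMatrix} objects.
#' @return An unaligned \linkS4class{HarmonizedPanel}; variants follow the
#'   summary-statistics order.
#' @export
intersectPanels <- function(ss, target, reference) {
    stopifnot(is(ss, "SummaryStats"), is(target, "GenotypeMatrix"),
              is(reference, "GenotypeMatrix"))
    st <- ss@stats
    vt <- variantInfo(target)
    vr <- variantInfo(reference)
    if (!nrow(st) || !nrow(vt) || !nrow(vr))
        stop("all three inputs must be nonempty")

    excl <- list()
    dupPos <- function(df, source) {
        posKey <- paste0(df$chrom, ":", df$pos)
        dup <- posKey %in% posKey[duplicated(posKey)]
        if (any(dup))
            excl[[length(excl) + 1L]] <<- data.frame(
                key = df$key[dup], source = source,
                reason = "duplicate position", stringsAsFactors = FALSE)
        df$key[!dup]
    }
    kss <- dupPos(st, "sumstats")
    kt <- dupPos(vt, "target")
    kr <- dupPos(vr, "reference")

    shared <- kss[kss %in% kt & kss %in% kr]
    if (!length(shared))
        stop("empty three-way intersection (sumstats: ", length(kss),
             ", target: ", length(kt), ", reference: ", length(kr),
             " usable variants)")

    allKeys <- unique(c(kss, kt, kr))
    lost <- setdiff(allKeys, shared)
    if (length(lost)) {
        missFrom <- vapply(list(sumstats = kss, target = kt,
                                reference = kr),
                           function(k) !(lost %in% k), logical(length(lost)))
        missFrom <- matrix(missFrom, nrow = length(lost))
        lab <- apply(missFrom, 1L, function(z)
            paste(c("sumstats", "target", "reference")[z], collapse = "+"))
        excl[[length(excl) + 1L]] <- data.frame(
            key = lost, source = lab, reason = "absent from source",
            stringsAsFactors = FALSE)
    }

    st <- st[match(shared, st$key), , drop = FALSE]
    it <- match(shared, vt$key)
    ir <- match(shared, vr$key)
    variants <- data.frame(
        key = st$key, chrom = st$chrom, pos = st$pos,
        effect_allele = st$effect_allele, other_allele = st$other_allele,
        beta = st$beta, p_value = st$p_value, n_gwas = st$n_gwas,
        target_ref = vt$ref[it], target_alt = vt$alt[it],
        reference_ref = vr$ref[ir], reference_alt = vr$alt[ir],
        flipped_target = NA, flipped_reference = NA,
        eaf_reference = NA_real_, stringsAsFactors = FALSE)
    exclusions <- if (length(excl)) do.call(rbind, excl) else
        data.frame(key = character(0), source = character(0),
                   reason = character(0))
    new("HarmonizedPanel", variants = variants,
        target = dosages(target)[it, , drop = FALSE],
        reference = dosages(reference)[ir, , drop = FALSE],
        exclusions = exclusions, aligned = FALSE)
}

#' Align dosages to the effect allele
#'
#' Re-codes both dosage matrices so that every dosage counts copies of the
#' summary-statistics effect allele. Where a genotype source coded the
#' effect allele as REF, dosages become \code{2 - d} and the flip flag is
#' set; the beta vector is left untouched, so one weight vector applies to
#' every cohort. Variants whose allele pairs cannot be reconciled, and
#' (by default) strand-ambiguous A/T and C/G variants, are moved to the
#' exclusion log. The reference-panel effect-allele frequency is computed
#' after alignment and stored for mean-imputation of missing dosages.
#'
#' @param panel a \linkS4class{HarmonizedPanel} from
#'   \code{\link{intersectPanels}}.
#' @param dropAmbiguous exclude strand-ambiguous variants (default TRUE).
#' @return The aligned \linkS4class{HarmonizedPanel}.
#' @export
alignEffectAlleles <- function(panel, dropAmbiguous = TRUE) {
    stopifnot(is(panel, "HarmonizedPanel"))
    v <- panel@variants
    ssPair <- .pairLabel(v$effect_allele, v$other_allele)

    drop <- rep(NA_character_, nrow(v))
    if (dropAmbiguous)
        drop[ssPair %in% .AMBIGUOUS] <- "strand ambiguous"

    orient <- function(ea, oa, ref, alt) {
        flip <- ifelse(ea == alt & oa == ref, FALSE,
                       ifelse(ea == ref & oa == alt, TRUE, NA))
        flip
    }
    flipT <- orient(v$effect_allele, v$other_allele,
                    v$target_ref, v$target_alt)
    flipR <- orient(v$effect_allele, v$other_allele,
                    v$reference_ref, v$reference_alt)
    drop[is.na(drop) & (is.na(flipT) | is.na(flipR))] <- "allele mismatch"

    keep <- is.na(drop)
    excl <- panel@exclusions
    if (any(!keep))
        excl <- rbind(excl, data.frame(key = v$key[!keep],
                                       source = "harmonization",
                                       reason = drop[!keep],
                                       stringsAsFactors = FALSE))
    v <- v[keep, , drop = FALSE]
    tg <- panel@target[keep, , drop = FALSE]
    rf <- panel@reference[keep, , drop = FALSE]
    flipT <- flipT[keep]; flipR <- flipR[keep]
    if (any(flipT)) tg[flipT, ] <- 2 - tg[flipT, , drop = FALSE]
    if (any(flipR)) rf[flipR, ] <- 2 - rf[flipR, , drop = FALSE]
    v$flipped_target <- flipT
    v$flipped_reference <- flipR
    v$eaf_reference <- rowMeans(rf, na.rm = TRUE) / 2
    new("HarmonizedPanel", variants = v, target = tg, reference = rf,
        exclusions = excl, aligned = TRUE)
}

#' Intersect and align in one step
#'
#' @inheritParams intersectPanels
#' @inheritParams alignEffectAlleles
#' @return An aligned \linkS4class{HarmonizedPanel}.
#' @export
harmonizePanels <- function(ss, target, reference, dropAmbiguous = TRUE)
    alignEffectAlleles(intersectPanels(ss, target, reference),
                       dropAmbiguous = dropAmbiguous)

#' Subset a harmonized panel at a p-value threshold
#'
#' @param panel an aligned \linkS4class{HarmonizedPanel}.
#' @param pMax inclusive p-value threshold.
#' @return A \linkS4class{HarmonizedPanel} with the retained variants.
#' @export
subsetPanel <- function(panel, pMax) {
    stopifnot(is(panel, "HarmonizedPanel"), pMax > 0, pMax <= 1)
    keep <- panel@variants$p_value <= pMax
    new("HarmonizedPanel", variants = panel@variants[keep, , drop = FALSE],
        target = panel@target[keep, , drop = FALSE],
        reference = panel@reference[keep, , drop = FALSE],
        exclusions = panel@exclusions, aligned = panel@aligned)
}

#' Write the exclusion log
#'
#' @param panel a \linkS4class{HarmonizedPanel}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeExclusionLog <- function(panel, path) {
    write.table(exclusions(panel), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
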