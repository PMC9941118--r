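#' Build a reference score distribution
#'
#' Stores the sorted raw scores of the reference cohort at one threshold.
#' The reference must have been scored on the same harmonized variant set
#' and in the same orientation as the cohort it will calibrate — this is
#' exactly what makes the percentile projection chip-naive: whatever markers
#' a chip carries, reference and target always share them.
#'
#' @param refPgs a \linkS4class{RawPGS} computed on the reference samples.
#' @return A \linkS4class{ReferenceDistribution}.
#' @export
buildReferenceDistribution <- function(refPgs) {
    stopifnot(is(refPgs, "RawPGS"))
    if (length(refPgs@score) < 2)
        stop("at least 2 reference samples are required")
    new("ReferenceDistribution", values = sort(refPgs@score),
        threshold = refPgs@threshold, orientation = refPgs@orientation)
}

#' Project raw scores onto the reference percentile scale
#'
#' Converts each raw score into an integer percentile 1-100 relative to the
#' reference distribution:
#' \deqn{pct = \mathrm{clamp}(\lceil 100 \cdot \#\{r \le s\} / |ref|
#' \rceil, 1, 100).}
#' Ties with reference scores count as "at or below" (<=); the ceiling
#' convention is monotone non-decreasing in the score, integer-valued and
#' attains both endpoints.
#'
#' @param score numeric vector of raw scores (or a \linkS4class{RawPGS}).
#' @param ref a \linkS4class{ReferenceDistribution} in the same orientation.
#' @return integer vector of percentiles in [1, 100], named like the input.
#' @export
percentileProject <- function(score, ref) {
    stopifnot(is(ref, "ReferenceDistribution"))
    if (is(score, "RawPGS")) {
        if (score@orientation != ref@orientation)
            stop("score and reference orientation differ")
        score <- score@score
    }
    cnt <- findInterval(score, ref@values)  # #{ref <= score}
    pct <- as.integer(pmin(pmax(ceiling(100 * cnt / length(ref@values)),
                                1L), 100L))
    names(pct) <- names(score)
    pct
}

#' Summed percentile PGS
#'
#' Adds the two percentile projections (one per p-value threshold) into the
#' calibrated per-sample score in [2, 200]. Samples present at only one
#' threshold are excluded with a warning.
#'
#' @param pcts named list of two integer percentile vectors, one per
#'   threshold; list names are used as threshold labels.
#' @return A \linkS4class{SummedPGS}.
#' @export
summedPgs <- function(pcts) {
    if (length(pcts) != 2)
        stop("exactly two threshold percentile vectors are required")
    ids <- intersect(names(pcts[[1L]]), names(pcts[[2L]]))
    dropped <- length(union(names(pcts[[1L]]), names(pcts[[2L]]))) -
        length(ids)
    if (dropped > 0)
        warning(dropped, " sample(s) missing a threshold score excluded")
    if (!length(ids)) stop("no sample has scores at both thresholds")
    comp <- cbind(pcts[[1L]][ids], pcts[[2L]][ids])
    colnames(comp) <- if (!is.null(names(pcts))) names(pcts) else
        c("threshold1", "threshold2")
    new("SummedPGS", sampleId = ids, components = comp,
        summed = as.integer(rowSums(comp)))
}

#' Write calibrated scores to TSV
#'
#' @param sp a \linkS4class{SummedPGS}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSummedPgs <- function(sp, path) {
    stopifnot(is(sp, "SummedPGS"))
    df <- data.frame(sample_id = sp@sampleId, sp@components,
                     summed_pgs = sp@summed, check.names = FALSE)
    names(df)[2:3] <- paste0("pct_", colnames(sp@components))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
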