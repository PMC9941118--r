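#' Accessor generics
#'
#' Small accessor layer over the core classes: \code{dosages} returns the
#' variants x samples dosage matrix, \code{variantInfo} the per-variant
#' metadata (key, position, alleles, imputation quality), \code{sampleIds}
#' the sample identifiers, \code{scores} the per-sample score vector,
#' \code{scoreThreshold} the p-value threshold label a score set was computed
#' at, \code{exclusions} the harmonization exclusion log, \code{panelVariants}
#' the harmonized variant table and \code{deciles} the per-sample decile
#' vector.
#'
#' @param x object.
#' @return See the method-specific sections.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))

#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname accessors
#' @export
setGeneric("panelVariants", function(x) standardGeneric("panelVariants"))

#' @rdname accessors
#' @export
setGeneric("deciles", function(x) standardGeneric("deciles"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix",
    function(x) SummarizedExperiment::assay(x, "DS"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(key = rd$key,
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               ref = rd$ref, alt = rd$alt, r2 = rd$r2,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("scores", "RawPGS", function(x) x@score)

#' @rdname accessors
#' @export
setMethod("scores", "SummedPGS",
    function(x) setNames(x@summed, x@sampleId))

#' @rdname accessors
#' @export
setMethod("scoreThreshold", "RawPGS", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("scoreThreshold", "ReferenceDistribution", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("exclusions", "HarmonizedPanel", function(x) x@exclusions)

#' @rdname accessors
#' @export
setMethod("panelVariants", "HarmonizedPanel", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("deciles", "DecileAssignment", function(x) x@decile)

#' Percentile components of a summed PGS
#'
#' @param x a \linkS4class{SummedPGS}.
#' @return integer matrix, samples x 2 thresholds.
#' @export
pgsComponents <- function(x) {
    stopifnot(is(x, "SummedPGS"))
    structure(x@components, dimnames = list(x@sampleId,
                                            colnames(x@components)))
}

#' Coefficients of a fitted risk model
#'
#' @param object a \linkS4class{FittedRiskModel}.
#' @param ... ignored.
#' @return named numeric vector.
#' @export
setMethod("coef", "FittedRiskModel", function(object, ...)
    object@coefficients)

#' @describeIn FittedRiskModel-class variance-covariance matrix of the
#'   coefficient estimates.
#' @param object,... see \code{\link[stats]{vcov}}.
#' @export
setMethod("vcov", "FittedRiskModel", function(object, ...) object@vcov)

#' Log-likelihood at the optimum
#'
#' @param object a \linkS4class{FittedRiskModel}.
#' @param ... ignored.
#' @return numeric; partial log-likelihood for the Cox family.
#' @export
setMethod("logLik", "FittedRiskModel", function(object, ...) object@logLik)

#' 95\% Wald confidence intervals for model coefficients
#'
#' @param object a \linkS4class{FittedRiskModel}.
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param ... ignored.
#' @return matrix with columns \code{lower} and \code{upper}.
#' @export
setMethod("confint", "FittedRiskModel",
    function(object, parm = names(object@coefficients), level = 0.95, ...) {
        z <- stats::qnorm(1 - (1 - level) / 2)
        se <- sqrt(diag(object@vcov))[parm]
        est <- object@coefficients[parm]
        cbind(lower = est - z * se, upper = est + z * se)
    })
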