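#' Infinitesimal-model shrinkage configuration
#'
#' Parameters of the infinitesimal (LDpred-inf style) posterior-mean
#' reweighting: the assumed trait heritability h2, the GWAS sample size N,
#' the total variant count M entering the shrinkage constant M/(N h2), and
#' the LD window size (number of consecutive variants per block).
#'
#' @param h2 assumed heritability, in (0, 1).
#' @param nGwas GWAS sample size, > 0.
#' @param mTotal total variant count M; defaults (NA) to the number of
#'   variants in the panel being reweighted.
#' @param window LD window size in variants (default 100).
#' @return list of class \code{"InfinitesimalConfig"}.
#' @export
infinitesimalConfig <- function(h2, nGwas, mTotal = NA_integer_,
                                window = 100L) {
    if (!is.finite(h2) || h2 <= 0 || h2 >= 1)
        stop("h2 must lie in (0, 1)")
    if (nGwas <= 0) stop("nGwas must be positive")
    if (window < 1) stop("window must be >= 1")
    structure(list(h2 = h2, nGwas = as.numeric(nGwas),
                   mTotal = mTotal, window = as.integer(window)),
              class = "InfinitesimalConfig")
}

#' Posterior-mean effect sizes under the infinitesimal model
#'
#' Reweights marginal GWAS effects using reference-panel LD. Within each
#' non-overlapping window of \code{cfg$window} consecutive panel variants,
#' the posterior means solve
#' \deqn{(D + (M/(N h^2)) I)\,\tilde\beta = \hat\beta,}
#' where D is the correlation matrix of reference-panel dosages in the
#' window (computed on centred dosages, denominator n-1). Monomorphic
#' variants get self-correlation 1 and zero cross-correlation. The ridge
#' term M/(N h2) > 0 keeps the system non-singular.
#'
#' @param panel an aligned \linkS4class{HarmonizedPanel}.
#' @param cfg an \code{\link{infinitesimalConfig}}.
#' @return numeric vector of posterior-mean betas, in panel order.
#' @export
infinitesimalReweight <- function(panel, cfg) {
    stopifnot(is(panel, "HarmonizedPanel"),
              inherits(cfg, "InfinitesimalConfig"))
    if (!panel@aligned) stop("panel must be effect-allele aligned")
    m <- nrow(panel@variants)
    if (!m) return(numeric(0))
    M <- if (is.na(cfg$mTotal)) m else cfg$mTotal
    lambda <- M / (cfg$nGwas * cfg$h2)
    betaHat <- panel@variants$beta
    betaTilde <- numeric(m)
    starts <- seq(1L, m, by = cfg$window)
    for (s in starts) {
        idx <- s:min(s + cfg$window - 1L, m)
        block <- t(panel@reference[idx, , drop = FALSE])
        D <- suppressWarnings(stats::cor(block))
        D[!is.finite(D)] <- 0   # monomorphic: zero cross-correlation
        diag(D) <- 1            # ... and unit self-correlation
        betaTilde[idx] <- solve(D + diag(lambda, length(idx)),
                                betaHat[idx])
    }
    betaTilde
}

#' Raw polygenic score
#'
#' The weighted dosage sum \eqn{\mathrm{score}_i = \sum_j d_{ij}
#' \tilde\beta_j} over the panel variants. Missing dosages are mean-imputed
#' as twice the reference-panel effect-allele frequency, which keeps scores
#' comparable across samples with sporadic missingness.
#'
#' @param panel an aligned \linkS4class{HarmonizedPanel}.
#' @param betas numeric weight vector aligned to panel order (typically from
#'   \code{\link{infinitesimalReweight}}).
#' @param cohort score the \code{"target"} (default) or \code{"reference"}
#'   samples.
#' @param threshold label recorded on the result, e.g. \code{"p<=0.01"}.
#' @return A \linkS4class{RawPGS} with orientation \code{"risk"}.
#' @export
computeRawPgs <- function(panel, betas, cohort = c("target", "reference"),
                          threshold = "all") {
    stopifnot(is(panel, "HarmonizedPanel"))
    cohort <- match.arg(cohort)
    if (length(betas) != nrow(panel@variants))
        stop("length(betas) must equal the panel variant count")
    d <- if (cohort == "target") panel@target else panel@reference
    if (nrow(d) == 0)
        return(RawPGS(setNames(numeric(ncol(d)), colnames(d)), threshold))
    if (anyNA(d)) {
        fill <- 2 * panel@variants$eaf_reference
        na <- which(is.na(d), arr.ind = TRUE)
        d[na] <- fill[na[, 1L]]
    }
    RawPGS(setNames(as.numeric(crossprod(d, betas)), colnames(d)), threshold)
}

#' Switch score orientation
#'
#' Scores are multiplied by -1 when the requested orientation differs from
#' the stored one (a protection score becomes a risk score and vice versa);
#' requesting the current orientation is a no-op.
#'
#' @param pgs a \linkS4class{RawPGS}.
#' @param direction \code{"risk"} or \code{"protection"}.
#' @return A \linkS4class{RawPGS} in the requested orientation.
#' @export
orientScore <- function(pgs, direction = c("risk", "protection")) {
    stopifnot(is(pgs, "RawPGS"))
    direction <- match.arg(direction)
    if (direction == pgs@orientation) return(pgs)
    new("RawPGS", score = -pgs@score, threshold = pgs@threshold,
        orientation = direction)
}
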