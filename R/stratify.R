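#' @importFrom stats fisher.test wilcox.test binom.test quantile
NULL

#' Assign risk deciles
#'
#' Deciles are computed from the evaluated cohort's own score distribution:
#' samples are ranked (ties broken by stable sample-id order) and split into
#' ten groups whose sizes differ by at most one. Decile 10 is the highest
#' risk. A score vector with no variation at all admits no decile boundaries
#' and is an error.
#'
#' @param riskScores named numeric vector of risk scores.
#' @return A \linkS4class{DecileAssignment}.
#' @export
assignDeciles <- function(riskScores) {
    n <- length(riskScores)
    if (n < 10) stop("at least 10 samples are required")
    if (is.null(names(riskScores))) stop("scores must be named by sample")
    if (diff(range(riskScores)) == 0)
        stop("all scores identical; deciles are undefined")
    ord <- order(riskScores, names(riskScores))
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    dec <- as.integer(ceiling(10 * rk / n))
    names(dec) <- names(riskScores)
    new("DecileAssignment", decile = dec)
}

#' Top-decile odds ratio
#'
#' Odds of the outcome among the 10\% highest-risk samples versus everyone
#' else: a logistic regression of the outcome on the top-decile indicator,
#' whose exponentiated slope equals the 2x2 cross-product ratio exactly,
#' with a Wald 95\% CI. With a zero cell the Haldane-Anscombe 0.5
#' continuity correction is applied to all four cells and the result is
#' flagged.
#'
#' @param dec a \linkS4class{DecileAssignment}.
#' @param outcomes binary event vector named by sample (or aligned).
#' @return list with \code{or}, \code{ci}, \code{flagged} and the 2x2
#'   \code{table} (rows: top decile yes/no; columns: event yes/no).
#' @export
topDecileOr <- function(dec, outcomes) {
    stopifnot(is(dec, "DecileAssignment"))
    d <- deciles(dec)
    if (!is.null(names(outcomes))) outcomes <- outcomes[names(d)]
    stopifnot(length(outcomes) == length(d))
    top <- as.integer(d == 10L)
    y <- as.integer(outcomes)
    if (sum(y) == 0) stop("no events in either group")
    tab <- matrix(c(sum(top & y), sum(top & !y),
                    sum(!top & y), sum(!top & !y)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(top = c("yes", "no"),
                                  event = c("yes", "no")))
    if (any(tab == 0)) {
        ct <- tab + 0.5
        or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
        se <- sqrt(sum(1 / ct))
        list(or = or,
             ci = exp(log(or) + c(-1, 1) * qnorm(0.975) * se),
             flagged = TRUE, table = tab)
    } else {
        fit <- glm(y ~ top, family = binomial())
        sl <- stats::coef(fit)["top"]
        se <- sqrt(diag(stats::vcov(fit))["top"])
        list(or = unname(exp(sl)),
             ci = unname(exp(sl + c(-1, 1) * qnorm(0.975) * se)),
             flagged = FALSE, table = tab)
    }
}

#' Per-decile absolute risk
#'
#' Event fraction in each risk decile with exact (Clopper-Pearson) 95\%
#' binomial confidence intervals.
#'
#' @inheritParams topDecileOr
#' @return data.frame with decile, n, events, fraction, lower, upper.
#' @export
decileRiskCurve <- function(dec, outcomes) {
    stopifnot(is(dec, "DecileAssignment"))
    d <- deciles(dec)
    if (!is.null(names(outcomes))) outcomes <- outcomes[names(d)]
    y <- as.integer(outcomes)
    do.call(rbind, lapply(1:10, function(k) {
        n <- sum(d == k); e <- sum(y[d == k])
        ci <- if (n > 0) binom.test(e, n)$conf.int else c(NA, NA)
        data.frame(decile = k, n = n, events = e,
                   fraction = if (n > 0) e / n else NA_real_,
                   lower = ci[1], upper = ci[2])
    }))
}

#' Overlap between two decile assignments
#'
#' How the samples one model puts in its extreme deciles are distributed
#' over the other model's deciles, plus the overall fraction of samples the
#' two models rank at least three deciles apart. For independent
#' assignments the expected top-decile overlap is 10\% (the chance line)
#' and the expected >= 3-decile disagreement fraction is 0.56.
#'
#' @param decA,decB \linkS4class{DecileAssignment}s over the same samples.
#' @return list with \code{topOverlap} and \code{bottomOverlap} (fraction of
#'   A's decile-10 resp. decile-1 members per decile of B; each sums to 1),
#'   \code{disagreement} (fraction with |decA - decB| >= 3) and
#'   \code{chanceLine} (0.1).
#' @export
modelOverlap <- function(decA, decB) {
    a <- deciles(decA); b <- deciles(decB)
    if (length(a) != length(b) || !setequal(names(a), names(b)))
        stop("assignments must cover the same samples")
    b <- b[names(a)]
    spread <- function(sel) {
        tabulate(b[sel], 10L) / sum(sel)
    }
    list(topOverlap = spread(a == 10L), bottomOverlap = spread(a == 1L),
         disagreement = mean(abs(a - b) >= 3L), chanceLine = 0.1)
}

#' BMI category
#'
#' WHO-style categories: underweight (< 18.5), normal ([18.5, 25)),
#' overweight ([25, 30)), obese (>= 30 kg/m2).
#'
#' @param bmi numeric vector (kg/m2).
#' @return factor with the four ordered levels.
#' @export
bmiCategory <- function(bmi) {
    cut(bmi, c(-Inf, 18.5, 25, 30, Inf),
        labels = c("underweight", "normal", "overweight", "obese"),
        right = FALSE)
}

#' Incidence by BMI category and genetic risk stratum
#'
#' Cross-tabulates event fractions over BMI categories within three genetic
#' risk strata of a PGS-based decile assignment (low = decile 1,
#' medium = deciles 2-9, high = decile 10). Within each stratum the
#' normal-BMI and obese cells are compared with a two-sided Fisher exact
#' test, and the absolute risk difference (obese minus normal, in
#' percentage points) is reported. Underweight samples are tabulated but
#' excluded from the pairwise test.
#'
#' @param bmi numeric BMI vector named by sample.
#' @param dec a \linkS4class{DecileAssignment} from a PGS-only score.
#' @param outcomes binary event vector named by sample.
#' @return list with \code{cells} (data.frame: stratum, bmi_category, n,
#'   events, fraction) and \code{tests} (data.frame: stratum, p, flagged,
#'   abs_diff_pct).
#' @export
bmiByRiskTable <- function(bmi, dec, outcomes) {
    stopifnot(is(dec, "DecileAssignment"))
    d <- deciles(dec)
    ids <- names(d)
    if (!is.null(names(bmi))) bmi <- bmi[ids]
    if (!is.null(names(outcomes))) outcomes <- outcomes[ids]
    y <- as.integer(outcomes)
    stratum <- factor(ifelse(d == 1L, "low",
                      ifelse(d == 10L, "high", "medium")),
                      levels = c("low", "medium", "high"))
    cat <- bmiCategory(bmi)
    cells <- do.call(rbind, lapply(levels(stratum), function(s)
        do.call(rbind, lapply(levels(cat), function(cc) {
            sel <- stratum == s & cat == cc
            data.frame(stratum = s, bmi_category = cc, n = sum(sel),
                       events = sum(y[sel]),
                       fraction = if (sum(sel)) sum(y[sel]) / sum(sel)
                                  else NA_real_)
        }))))
    tests <- do.call(rbind, lapply(levels(stratum), function(s) {
        nrm <- cells[cells$stratum == s & cells$bmi_category == "normal", ]
        obe <- cells[cells$stratum == s & cells$bmi_category == "obese", ]
        if (nrm$n == 0 || obe$n == 0)
            return(data.frame(stratum = s, p = NA_real_, flagged = TRUE,
                              abs_diff_pct = NA_real_))
        tab <- matrix(c(nrm$events, nrm$n - nrm$events,
                        obe$events, obe$n - obe$events), nrow = 2,
                      byrow = TRUE)
        ft <- fisherExact(tab)
        data.frame(stratum = s, p = ft$p, flagged = ft$flagged,
                   abs_diff_pct = 100 * (obe$fraction - nrm$fraction))
    }))
    list(cells = cells, tests = tests)
}

#' Two-sided Fisher exact test
#'
#' Exact two-sided p-value for a 2x2 table: the sum, over all tables with
#' the observed margins, of hypergeometric probabilities no larger than that
#' of the observed table. A table with a zero margin carries no information
#' and returns p = 1, flagged.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list with \code{p} and \code{flagged}.
#' @export
fisherExact <- function(table) {
    table <- as.matrix(table)
    stopifnot(all(dim(table) == 2), all(table >= 0),
              all(table == round(table)))
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        return(list(p = 1, flagged = TRUE))
    list(p = fisher.test(table)$p.value, flagged = FALSE)
}

#' Mann-Whitney rank comparison of two score samples
#'
#' Two-sided Mann-Whitney U test. The exact null distribution is used for
#' small samples (min(n1, n2) <= 8) without ties; otherwise the
#' tie-corrected normal approximation.
#'
#' @param a,b numeric score vectors.
#' @return list with \code{U}, \code{p} and \code{exact}.
#' @export
rankCompare <- function(a, b) {
    stopifnot(length(a) > 0, length(b) > 0)
    exact <- min(length(a), length(b)) <= 8 &&
        !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = FALSE))
    list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Write a stratification table with its JSON twin
#'
#' @param x data.frame to emit.
#' @param path TSV path; a \code{.json} twin is written next to it.
#' @return \code{path}, invisibly.
#' @export
writeStratTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(x, sub("\\.tsv$", ".json", path), digits = NA,
                         dataframe = "rows")
    invisible(path)
}
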