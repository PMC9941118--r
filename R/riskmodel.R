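#' @importFrom survival coxph Surv concordance
#' @importFrom stats glm binomial pchisq qnorm as.formula model.matrix
NULL

## model term -> data column(s) and formula fragment
.TERM_COLS <- list(
    BMI = "bmi", SmokerPast = "smoker_past", SmokerCurrent = "smoker_current",
    PAModerate = "pa_moderate", PAVigorous = "pa_vigorous", Sex = "sex",
    FatherDisease = "father_disease", MotherDisease = "mother_disease",
    PGS = "pgs", Age = "age", PGSxBMI = c("pgs", "bmi"))
.TERM_EXPR <- c(BMI = "bmi", SmokerPast = "smoker_past",
    SmokerCurrent = "smoker_current", PAModerate = "pa_moderate",
    PAVigorous = "pa_vigorous", Sex = "sex",
    FatherDisease = "father_disease", MotherDisease = "mother_disease",
    PGS = "pgs", Age = "age", PGSxBMI = "pgs:bmi")
.COVONLY_COLS <- list(PC1 = "pc1", PC2 = "pc2", PC3 = "pc3", PC4 = "pc4",
                      batch = "batch")

.rhsFor <- function(terms, covariateOnly, data) {
    frag <- c(.TERM_EXPR[terms],
              unlist(.COVONLY_COLS[covariateOnly], use.names = FALSE))
    frag <- frag[!is.na(frag)]
    need <- unique(c(unlist(.TERM_COLS[terms], use.names = FALSE),
                     unlist(.COVONLY_COLS[covariateOnly],
                            use.names = FALSE)))
    miss <- setdiff(need, names(data))
    if (length(miss))
        stop("analysis data lacks columns: ", paste(miss, collapse = ", "))
    paste(frag, collapse = " + ")
}

#' Build an analysis cohort
#'
#' Joins covariates, outcomes and (optionally) calibrated scores into the
#' flat data set the model fitters consume. Smoking is expanded into two
#' dummies against the never-smoker baseline. For the incidence target,
#' prevalent cases (outcome present at first assessment) are excluded, the
#' event indicator marks post-baseline diagnoses and \code{time_years} is
#' the time from baseline to diagnosis or censoring; for the prevalence
#' target all samples are kept and the binary outcome \code{case} is the
#' prevalent flag.
#'
#' @param covariates,outcomes data.frames in the canonical layout
#'   (see \code{\link{readCovariates}}).
#' @param pgs optional \linkS4class{SummedPGS}; samples without a score are
#'   dropped from the analysis set.
#' @param target \code{"incidence"} or \code{"prevalence"}.
#' @return data.frame with attribute \code{"target"}; for incidence it
#'   carries \code{event} and \code{time_years} plus binary \code{case},
#'   for prevalence binary \code{case} only.
#' @export
buildAnalysisCohort <- function(covariates, outcomes, pgs = NULL,
                                target = c("incidence", "prevalence")) {
    target <- match.arg(target)
    df <- merge(covariates, outcomes, by = "sample_id", sort = FALSE)
    df$smoker_past <- as.integer(df$smoking == "past")
    df$smoker_current <- as.integer(df$smoking == "current")
    df$batch <- factor(df$batch)
    if (!is.null(pgs)) {
        sc <- scores(pgs)
        df <- df[df$sample_id %in% names(sc), , drop = FALSE]
        df$pgs <- as.numeric(sc[df$sample_id])
    }
    if (target == "incidence") {
        nPrev <- sum(df$prevalent == 1)
        df <- df[df$prevalent == 0, , drop = FALSE]
        if (!nrow(df))
            stop("all samples are prevalent cases; no incidence cohort")
        if (!sum(df$event))
            stop("zero events after excluding ", nPrev, " prevalent cases")
        df$case <- as.integer(df$event)
    } else {
        df$case <- as.integer(df$prevalent)
        if (!sum(df$case)) stop("zero prevalent cases")
    }
    attr(df, "target") <- target
    df
}

.newFittedModel <- function(cf, vc, family, target, spec, ll, n) {
    new("FittedRiskModel", coefficients = cf, vcov = vc, family = family,
        target = target, terms = spec@terms,
        covariateOnly = spec@covariateOnly, logLik = as.numeric(ll),
        n = as.integer(n))
}

#' Fit the proportional-hazards risk model
#'
#' Maximises the Cox partial likelihood (Efron tie handling) for the
#' requested term set on an incidence analysis cohort.
#'
#' @param data analysis cohort from \code{\link{buildAnalysisCohort}}
#'   (incidence target).
#' @param spec a \code{\link{modelSpec}} with \code{family = "cox"}.
#' @return A \linkS4class{FittedRiskModel}.
#' @export
fitCox <- function(data, spec) {
    stopifnot(is(spec, "ModelSpec"))
    if (spec@family != "cox") stop("spec family must be 'cox'")
    if (!all(c("time_years", "event") %in% names(data)))
        stop("Cox fitting needs an incidence cohort with time_years/event")
    if (sum(data$event) < 1) stop("at least one event is required")
    rhs <- .rhsFor(spec@terms, spec@covariateOnly, data)
    f <- as.formula(paste("Surv(time_years, event) ~", rhs))
    fit <- coxph(f, data = data, ties = "efron")
    cf <- stats::coef(fit)
    if (any(is.na(cf)))
        stop("Cox fit failed to converge; problematic terms: ",
             paste(names(cf)[is.na(cf)], collapse = ", "))
    se <- sqrt(diag(stats::vcov(fit)))
    if (any(!is.finite(se)) || any(abs(cf) > 50))
        stop("Cox fit unstable (separable or constant terms): ",
             paste(names(cf)[!is.finite(se) | abs(cf) > 50],
                   collapse = ", "))
    .newFittedModel(cf, stats::vcov(fit), "cox", attr(data, "target") %||%
                    "incidence", spec, fit$loglik[2L], fit$n)
}

#' Fit the logistic risk model
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' requested term set (the logit expansion of the same formula the Cox
#' family uses, plus an intercept).
#'
#' @param data analysis cohort with a binary \code{case} column.
#' @param spec a \code{\link{modelSpec}} with \code{family = "logistic"}.
#' @return A \linkS4class{FittedRiskModel}.
#' @export
fitLogistic <- function(data, spec) {
    stopifnot(is(spec, "ModelSpec"))
    if (spec@family != "logistic") stop("spec family must be 'logistic'")
    if (length(unique(data$case)) < 2)
        stop("both outcome classes must be present")
    rhs <- if (length(spec@terms) || length(spec@covariateOnly))
        .rhsFor(spec@terms, spec@covariateOnly, data) else "1"
    f <- as.formula(paste("case ~", rhs))
    sep <- FALSE
    fit <- withCallingHandlers(
        glm(f, data = data, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w))) {
                sep <<- TRUE
                invokeRestart("muffleWarning")
            }
        })
    cf <- stats::coef(fit)
    if (sep || !fit$converged || any(is.na(cf)) || any(abs(cf) > 50))
        stop("logistic fit did not converge (perfect separation?)")
    .newFittedModel(cf, stats::vcov(fit), "logistic",
                    attr(data, "target") %||% "prevalence", spec,
                    as.numeric(stats::logLik(fit)), stats::nobs(fit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a fitted model to (possibly external) data
#'
#' Computes the per-sample linear predictor from the stored coefficients.
#' Cohort-specific nuisance covariates (genotyping batch, principal
#' components) that do not exist in the new data contribute zero — an
#' external cohort has no meaningful values for another cohort's batches —
#' and are reported in a message. A missing substantive term is an error.
#'
#' @param model a \linkS4class{FittedRiskModel}.
#' @param data analysis cohort data.frame (see
#'   \code{\link{buildAnalysisCohort}}).
#' @return named numeric vector of linear predictors (risk scores).
#' @export
applyModel <- function(model, data) {
    stopifnot(is(model, "FittedRiskModel"))
    availCov <- model@covariateOnly[vapply(model@covariateOnly, function(t)
        all(unlist(.COVONLY_COLS[t]) %in% names(data)), logical(1))]
    missSub <- model@terms[!vapply(model@terms, function(t)
        all(unlist(.TERM_COLS[t]) %in% names(data)), logical(1))]
    if (length(missSub))
        stop("cannot resolve model term(s) in data: ",
             paste(missSub, collapse = ", "))
    rhs <- if (length(model@terms) || length(availCov))
        .rhsFor(model@terms, availCov, data) else "1"
    mm <- model.matrix(as.formula(paste("~", rhs)), data = data)
    cf <- model@coefficients
    ## interaction column names depend on term order; match on a
    ## canonical (sorted) form
    canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                                function(p) paste(sort(p), collapse = ":"),
                                character(1))
    colnames(mm) <- canon(colnames(mm))
    names(cf) <- canon(names(cf))
    used <- intersect(names(cf), colnames(mm))
    dropped <- setdiff(names(cf), used)
    if (length(dropped)) {
        nuisPat <- paste0("^(", paste(c("\\(Intercept\\)",
            unlist(.COVONLY_COLS[model@covariateOnly])), collapse = "|"),
            ")")
        if (any(!grepl(nuisPat, dropped)))
            stop("cannot resolve coefficient(s): ",
                 paste(dropped[!grepl(nuisPat, dropped)], collapse = ", "))
        message("nuisance coefficient(s) set to zero contribution: ",
                paste(dropped, collapse = ", "))
    }
    lp <- drop(mm[, used, drop = FALSE] %*% cf[used])
    names(lp) <- data$sample_id
    lp
}

#' Likelihood ratio test for nested risk models
#'
#' Twice the log-likelihood difference, referred to a chi-square with
#' degrees of freedom equal to the coefficient-count difference.
#'
#' @param full,reduced \linkS4class{FittedRiskModel}s fit on the same data
#'   with the same family; the reduced coefficient set must be nested in
#'   the full one.
#' @return list with \code{chi2}, \code{df} and \code{p}.
#' @export
likelihoodRatioTest <- function(full, reduced) {
    stopifnot(is(full, "FittedRiskModel"), is(reduced, "FittedRiskModel"))
    if (full@family != reduced@family)
        stop("models must share a family")
    if (full@n != reduced@n)
        stop("models must be fit on the same data")
    if (!all(names(reduced@coefficients) %in% names(full@coefficients)))
        stop("models are not nested")
    chi2 <- max(0, 2 * (full@logLik - reduced@logLik))
    df <- length(full@coefficients) - length(reduced@coefficients)
    p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
    list(chi2 = chi2, df = df, p = p)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs whose predicted risk ordering matches the
#' observed event ordering, with tied predictions counted one half. For an
#' incidence cohort the usual survival definition applies (pairs are usable
#' when the shorter time ends in an event); for a prevalence cohort the
#' index reduces to the area under the ROC curve. The 95\% confidence
#' interval uses the normal approximation with the infinitesimal-jackknife
#' variance.
#'
#' @param riskScores named numeric vector of risk scores (higher = riskier).
#' @param data analysis cohort the scores refer to.
#' @return list with \code{C}, \code{se}, \code{ci} (length 2) and
#'   \code{pairs} (usable pair count).
#' @export
concordanceIndex <- function(riskScores, data) {
    stopifnot(length(riskScores) == nrow(data))
    data <- data.frame(data, .score = as.numeric(riskScores))
    cc <- if (all(c("time_years", "event") %in% names(data)))
        concordance(Surv(time_years, event) ~ .score, data = data,
                    reverse = TRUE)
    else
        concordance(case ~ .score, data = data)
    cnt <- cc$count
    usable <- sum(cnt[c("concordant", "discordant", "tied.x")])
    if (usable == 0) stop("no comparable pairs")
    se <- sqrt(cc$var)
    list(C = unname(cc$concordance), se = unname(se),
         ci = unname(cc$concordance + c(-1, 1) * qnorm(0.975) * se),
         pairs = unname(usable))
}

#' k-fold cross-validated concordance
#'
#' Deterministic given the seed: samples are partitioned into k folds, the
#' model is refit on each training set and scored on the held-out fold.
#' A fold whose training set has no events triggers a reshuffle with a
#' warning.
#'
#' @param data analysis cohort.
#' @param spec a \code{\link{modelSpec}}.
#' @param k fold count (default 10).
#' @param seed RNG seed (mandatory).
#' @return list with \code{perFold} (data.frame of fold, n, C) and
#'   \code{meanC}, \code{sdC}.
#' @export
crossValidate <- function(data, spec, k = 10, seed) {
    stopifnot(k >= 2, !missing(seed))
    n <- nrow(data)
    fitFun <- if (spec@family == "cox") fitCox else fitLogistic
    for (attempt in 1:10) {
        folds <- withr::with_seed(seed + attempt - 1L,
                                  sample(rep_len(seq_len(k), n)))
        ok <- all(vapply(seq_len(k), function(f)
            sum(data$case[folds != f]) > 0, logical(1)))
        if (ok) break
        warning("fold without training events; refolding")
    }
    res <- lapply(seq_len(k), function(f) {
        train <- data[folds != f, , drop = FALSE]
        test <- data[folds == f, , drop = FALSE]
        m <- fitFun(train, spec)
        sc <- suppressMessages(applyModel(m, test))
        C <- tryCatch(concordanceIndex(sc, test)$C,
                      error = function(e) NA_real_)
        data.frame(fold = f, n = nrow(test), C = C)
    })
    perFold <- do.call(rbind, res)
    list(perFold = perFold, meanC = mean(perFold$C, na.rm = TRUE),
         sdC = sd(perFold$C, na.rm = TRUE), seed = seed)
}

#' @importFrom stats sd
NULL

#' Serialize / read a fitted model
#'
#' Key/value JSON document (versioned schema) holding the coefficient
#' vector, its variance matrix, the family, target, term sets,
#' log-likelihood and sample count.
#'
#' @param model a \linkS4class{FittedRiskModel}.
#' @param path JSON path.
#' @return \code{path} (write) or a \linkS4class{FittedRiskModel} (read).
#' @export
writeModel <- function(model, path) {
    stopifnot(is(model, "FittedRiskModel"))
    doc <- list(schema_version = "1.0",
                family = model@family, target = model@target,
                terms = model@terms, covariateOnly = model@covariateOnly,
                coefficients = as.list(model@coefficients),
                vcov = model@vcov, logLik = model@logLik, n = model@n)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$schema_version) || doc$schema_version != "1.0")
        stop("unsupported model schema version: ", doc$schema_version)
    cf <- unlist(doc$coefficients)
    vc <- matrix(as.numeric(doc$vcov), nrow = length(cf),
                 dimnames = list(names(cf), names(cf)))
    new("FittedRiskModel", coefficients = cf, vcov = vc,
        family = doc$family, target = doc$target,
        terms = as.character(unlist(doc$terms)),
        covariateOnly = as.character(unlist(doc$covariateOnly)),
        logLik = doc$logLik, n = as.integer(doc$n))
}
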