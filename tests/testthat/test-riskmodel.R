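test_that("analysis cohorts exclude prevalent cases for incidence", {
    tb <- toyCohortTables(10, seed = 2, eventP = 0.5, prevalentP = 0)
    tb$outcomes$prevalent[1:3] <- 1
    tb$outcomes$event[1:3] <- 0
    inc <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                               target = "incidence")
    expect_equal(nrow(inc), 7L)
    expect_true(all(inc$prevalent == 0))

    ## no prevalent cases: unchanged
    tb2 <- toyCohortTables(10, seed = 3, eventP = 0.5)
    inc2 <- buildAnalysisCohort(tb2$covariates, tb2$outcomes,
                                target = "incidence")
    expect_equal(nrow(inc2), 10L)

    ## all prevalent is fatal
    tb$outcomes$prevalent <- 1
    expect_error(buildAnalysisCohort(tb$covariates, tb$outcomes,
                                     target = "incidence"),
                 "prevalent")

    ## prevalence target keeps everyone, case = prevalent flag
    tb3 <- toyCohortTables(10, seed = 4, prevalentP = 0.4)
    prev <- buildAnalysisCohort(tb3$covariates, tb3$outcomes,
                                target = "prevalence")
    expect_equal(nrow(prev), 10L)
    expect_equal(prev$case, tb3$outcomes$prevalent)
})

test_that("Cox fit: null covariate CI covers zero", {
    withr::with_seed(51, {
        n <- 2000
        tb <- toyCohortTables(n, seed = 51, eventP = 0)
        tb$outcomes$time_years <- rexp(n, 0.1)
        tb$outcomes$event <- as.integer(tb$outcomes$time_years < 8)
        tb$outcomes$time_years <- pmin(tb$outcomes$time_years, 8)
    })
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "incidence")
    fit <- fitCox(data, modelSpec("toy", "BMI", covariateOnly = character(0)))
    ci <- confint(fit)["bmi", ]
    expect_true(ci["lower"] < 0 && ci["upper"] > 0)
})

test_that("Cox fit recovers a two-group rate ratio of 2", {
    withr::with_seed(52, {
        n <- 5000
        tb <- toyCohortTables(n, seed = 52, eventP = 0)
        x <- tb$covariates$sex
        t <- rexp(n, rate = 0.08 * 2^x)
        cens <- 6
        tb$outcomes$event <- as.integer(t < cens)
        tb$outcomes$time_years <- pmin(t, cens)
    })
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "incidence")
    fit <- fitCox(data, modelSpec("toy", "Sex", covariateOnly = character(0)))
    ## closed-form rate-ratio estimator from event counts and exposure time
    d1 <- sum(data$event[data$sex == 1]); T1 <- sum(data$time_years[data$sex == 1])
    d0 <- sum(data$event[data$sex == 0]); T0 <- sum(data$time_years[data$sex == 0])
    oracle <- log((d1 / T1) / (d0 / T0))
    expect_equal(unname(coef(fit)["sex"]), oracle, tolerance = 0.05)
    ci <- confint(fit)["sex", ]
    expect_true(ci["lower"] < log(2) && ci["upper"] > log(2))
})

test_that("logistic slope equals the 2x2 cross-product odds ratio", {
    ## exposed: 20 cases / 80 non-cases; unexposed: 45 / 855
    tb <- toyCohortTables(1000, seed = 53)
    tb$covariates$sex <- rep(c(1, 0), c(100, 900))
    tb$outcomes$prevalent <- c(rep(1, 20), rep(0, 80),
                               rep(1, 45), rep(0, 855))
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "prevalence")
    fit <- fitLogistic(data, modelSpec("toy", "Sex",
                                       covariateOnly = character(0),
                                       family = "logistic",
                                       target = "prevalence"))
    expect_equal(unname(exp(coef(fit)["sex"])), 4.75, tolerance = 1e-6)
    expect_equal(unname(exp(coef(fit)["sex"])),
                 oracleCrossProduct(matrix(c(20, 80, 45, 855), 2,
                                           byrow = TRUE)),
                 tolerance = 1e-6)

    ## identity on random tables
    withr::with_seed(54, {
        for (i in 1:20) {
            tab <- matrix(rpois(4, 40) + 1, 2)
            y <- c(rep(1, tab[1, 1]), rep(0, tab[1, 2]),
                   rep(1, tab[2, 1]), rep(0, tab[2, 2]))
            x <- rep(c(1, 0), c(sum(tab[1, ]), sum(tab[2, ])))
            sl <- coef(glm(y ~ x, family = binomial()))["x"]
            expect_equal(unname(exp(sl)), oracleCrossProduct(tab),
                         tolerance = 1e-6)
        }
    })
})

test_that("intercept-only logistic model equals the logit case fraction", {
    tb <- toyCohortTables(200, seed = 55, prevalentP = 0.3)
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "prevalence")
    fit <- fitLogistic(data, modelSpec("toy", character(0),
                                       covariateOnly = character(0),
                                       family = "logistic",
                                       target = "prevalence"))
    expect_equal(unname(coef(fit)["(Intercept)"]),
                 qlogis(mean(data$case)), tolerance = 1e-8)
})

test_that("model application expands terms and drops nuisance covariates", {
    mkModel <- function(cf, terms, covOnly = character(0))
        new("FittedRiskModel", coefficients = cf,
            vcov = diag(length(cf)), family = "cox", target = "incidence",
            terms = terms, covariateOnly = covOnly, logLik = -1, n = 10L)

    tb <- toyCohortTables(5, seed = 56, eventP = 0.6)
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "incidence")

    ## all-zero coefficients: constant scores
    m0 <- mkModel(c(bmi = 0, age = 0), c("BMI", "Age"))
    expect_true(diff(range(applyModel(m0, data))) == 0)

    ## single-term difference
    m1 <- mkModel(c(bmi = 0.1), "BMI")
    data2 <- data; data2$bmi <- c(30, 20, 25, 25, 25)
    sc <- applyModel(m1, data2)
    expect_equal(unname(sc[1] - sc[2]), 1.0)

    ## interaction expands to term-by-term sum
    m2 <- mkModel(c(bmi = 0.1, pgs = 0.02, `pgs:bmi` = 0.001),
                  c("BMI", "PGS", "PGSxBMI"))
    data2$pgs <- c(120, 80, 100, 100, 100)
    sc2 <- applyModel(m2, data2)
    expect_equal(unname(sc2[1]),
                 0.1 * 30 + 0.02 * 120 + 0.001 * 120 * 30)

    ## batch/PC coefficients without matching columns contribute zero
    m3 <- mkModel(c(bmi = 0.1, batchB2 = 0.5, pc1 = 0.2), "BMI",
                  covOnly = c("PC1", "batch"))
    slim <- data2[c("sample_id", "bmi")]
    expect_message(sc3 <- applyModel(m3, slim), "nuisance")
    expect_equal(unname(sc3), 0.1 * slim$bmi, ignore_attr = TRUE)

    ## a missing substantive term is fatal
    expect_error(applyModel(m2, slim), "PGS")
})

test_that("likelihood ratio test behaves as a chi-square comparison", {
    mk <- function(cf, ll) new("FittedRiskModel",
        coefficients = cf, vcov = diag(length(cf)), family = "logistic",
        target = "prevalence", terms = "BMI",
        covariateOnly = character(0), logLik = ll, n = 100L)
    full <- mk(c(`(Intercept)` = 0, bmi = 0.1), -98.08)
    red <- mk(c(`(Intercept)` = 0), -100)
    lrt <- likelihoodRatioTest(full, red)
    expect_equal(lrt$chi2, 3.84, tolerance = 1e-9)
    expect_equal(lrt$df, 1L)
    expect_equal(lrt$p, pchisq(3.84, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_true(abs(lrt$p - 0.05) < 0.001)

    ## identical models: chi2 = 0, p = 1
    same <- likelihoodRatioTest(full, full)
    expect_equal(same$chi2, 0)
    expect_equal(same$p, 1)

    ## non-nested models are fatal
    other <- mk(c(`(Intercept)` = 0, age = 0.1), -99)
    expect_error(likelihoodRatioTest(full, other), "not nested")
})

test_that("LRT statistic is invariant to affine covariate rescaling", {
    tb <- toyCohortTables(500, seed = 57, prevalentP = 0.25)
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "prevalence")
    specF <- modelSpec("toy", c("BMI", "Age"),
                       covariateOnly = character(0), family = "logistic",
                       target = "prevalence")
    specR <- modelSpec("toy", "Age", covariateOnly = character(0),
                       family = "logistic", target = "prevalence")
    l1 <- likelihoodRatioTest(fitLogistic(data, specF),
                              fitLogistic(data, specR))
    data2 <- data
    data2$bmi <- 10 * data2$bmi - 200
    l2 <- likelihoodRatioTest(fitLogistic(data2, specF),
                              fitLogistic(data2, specR))
    expect_equal(l1$chi2, l2$chi2, tolerance = 1e-6)
})

test_that("concordance matches exhaustive pairwise enumeration", {
    ## perfect ranking of three events
    d <- data.frame(sample_id = c("a", "b", "c"),
                    time_years = c(1, 2, 3), event = 1, case = 1)
    sc <- c(a = 3, b = 2, c = 1)
    expect_equal(concordanceIndex(sc, d)$C, 1.0)

    ## all tied scores
    expect_equal(concordanceIndex(c(a = 1, b = 1, c = 1), d)$C, 0.5)

    ## six-subject toy with censoring
    d6 <- data.frame(sample_id = letters[1:6],
                     time_years = c(2.1, 3.5, 1.2, 6.4, 5.5, 4.4),
                     event = c(1, 0, 1, 1, 0, 1), case = 1)
    sc6 <- c(a = 2, b = 1, c = 5, d = 0.5, e = 1.5, f = 2)
    expect_equal(concordanceIndex(sc6, d6)$C,
                 oracleConcordance(d6$time_years, d6$event, sc6))

    ## random data with score ties
    withr::with_seed(58, {
        n <- 40
        d40 <- data.frame(sample_id = paste0("s", 1:n),
                          time_years = rexp(n), event = rbinom(n, 1, 0.6),
                          case = 1)
        s40 <- setNames(round(rnorm(n), 1), d40$sample_id)
    })
    got <- concordanceIndex(s40, d40)
    expect_equal(got$C, oracleConcordance(d40$time_years, d40$event, s40))
    expect_true(got$ci[1] <= got$C && got$C <= got$ci[2])
})

test_that("concordance is invariant to monotone score transforms", {
    withr::with_seed(59, {
        n <- 60
        d <- data.frame(sample_id = paste0("s", 1:n), time_years = rexp(n),
                        event = rbinom(n, 1, 0.5), case = 1)
        s <- setNames(rnorm(n), d$sample_id)
    })
    expect_equal(concordanceIndex(s, d)$C,
                 concordanceIndex(exp(s / 2), d)$C)
})

test_that("cross-validation is seeded, deterministic and calibrated", {
    withr::with_seed(60, {
        n <- 600
        tb <- toyCohortTables(n, seed = 60, eventP = 0)
        lp <- 0.8 * scale(tb$covariates$bmi)[, 1]
        t <- rexp(n, rate = 0.05 * exp(lp))
        tb$outcomes$event <- as.integer(t < 10)
        tb$outcomes$time_years <- pmin(t, 10)
    })
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "incidence")
    spec <- modelSpec("toy", "BMI", covariateOnly = character(0))
    cv1 <- crossValidate(data, spec, k = 5, seed = 7)
    cv2 <- crossValidate(data, spec, k = 5, seed = 7)
    expect_identical(cv1$perFold, cv2$perFold)
    expect_true(cv1$meanC > 0.55)  # informative predictor

    ## pure-noise predictor hovers at 0.5
    dataN <- data
    withr::with_seed(61, dataN$bmi <- rnorm(n))
    cvN <- crossValidate(dataN, spec, k = 5, seed = 7)
    expect_true(abs(cvN$meanC - 0.5) < 0.06)
})

test_that("model serialization round-trips and checks its schema", {
    tb <- toyCohortTables(300, seed = 62, prevalentP = 0.3)
    data <- buildAnalysisCohort(tb$covariates, tb$outcomes,
                                target = "prevalence")
    fit <- fitLogistic(data, modelSpec("toy", c("BMI", "Sex"),
                                       covariateOnly = character(0),
                                       family = "logistic",
                                       target = "prevalence"))
    path <- tempfile(fileext = ".json")
    writeModel(fit, path)
    back <- readModel(path)
    expect_equal(coef(back), coef(fit))
    expect_equal(vcov(back), vcov(fit), tolerance = 1e-12)
    expect_equal(logLik(back), logLik(fit))
    expect_equal(back@n, fit@n)

    doc <- jsonlite::read_json(path)
    doc$schema_version <- "0.9"
    jsonlite::write_json(doc, path, auto_unbox = TRUE)
    expect_error(readModel(path), "schema version")
})
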