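test_that("simulation is fully deterministic given the seed", {
    cfg <- simulationConfig(seed = 99, nReference = 60L, nCohort = 80L,
                            mVariants = 120L, blockSize = 20L,
                            incidenceTarget = 0.2)
    s1 <- simulateStudy(cfg)
    s2 <- simulateStudy(cfg)
    expect_identical(dosages(s1@reference), dosages(s2@reference))
    expect_identical(dosages(s1@chipA), dosages(s2@chipA))
    expect_identical(s1@sumstats@stats, s2@sumstats@stats)
    expect_identical(s1@covariates, s2@covariates)
    expect_identical(s1@outcomes, s2@outcomes)

    cfg2 <- simulationConfig(seed = 100, nReference = 60L, nCohort = 80L,
                             mVariants = 120L, blockSize = 20L,
                             incidenceTarget = 0.2)
    expect_false(identical(dosages(simulateStudy(cfg2)@reference),
                           dosages(s1@reference)))
})

test_that("panel genotypes follow the configured marginals and LD", {
    ## freq pinned at 0.5: mean dosage ~ 1
    cfg <- simulationConfig(seed = 101, nReference = 400L, nCohort = 10L,
                            mVariants = 100L, blockSize = 10L,
                            freqRange = c(0.5, 0.5))
    gm <- simulatePanel(cfg, 400L)
    expect_true(all(dosages(gm) %in% 0:2))
    expect_equal(mean(dosages(gm)), 1, tolerance = 0.02)

    ## zero block correlation: empirical inter-variant correlation ~ 0
    cfg0 <- simulationConfig(seed = 102, nReference = 500L, nCohort = 10L,
                             mVariants = 60L, blockSize = 30L,
                             blockRho = 0)
    d0 <- dosages(simulatePanel(cfg0, 500L))
    cc <- cor(t(d0))
    off <- cc[upper.tri(cc)]
    expect_lt(mean(abs(off)), 0.05)

    ## high block correlation: strong within-block LD
    cfgH <- simulationConfig(seed = 103, nReference = 500L, nCohort = 10L,
                             mVariants = 60L, blockSize = 30L,
                             blockRho = 0.95)
    dH <- dosages(simulatePanel(cfgH, 500L))
    ccH <- cor(t(dH[1:30, ]))
    expect_gt(mean(ccH[upper.tri(ccH)]), 0.6)
})

test_that("chip derivation respects retention and overlap", {
    cfg <- simulationConfig(seed = 104, nReference = 30L, nCohort = 50L,
                            mVariants = 300L, blockSize = 30L)
    gm <- simulatePanel(cfg, 50L, idPrefix = "S")
    chips <- makeChips(gm, retain = 2 / 3, overlap = 1 / 3, seed = 7)
    kA <- variantInfo(chips$A)$key
    kB <- variantInfo(chips$B)$key
    expect_equal(length(kA), 200L)
    expect_equal(length(kB), 200L)
    expect_equal(length(intersect(kA, kB)), 100L)
    ## dosages identical to the panel at retained sites
    expect_identical(dosages(chips$A), dosages(gm)[kA, ])

    ## full overlap with full retention: identical chips
    same <- makeChips(gm, retain = 1, overlap = 1, seed = 7)
    expect_identical(variantInfo(same$A)$key, variantInfo(same$B)$key)
    expect_identical(dosages(same$A), dosages(same$B))

    ## infeasible requests are fatal
    expect_error(makeChips(gm, retain = 0.9, overlap = 0.1, seed = 7),
                 "infeasible")
    expect_error(makeChips(gm, retain = 0.5, overlap = 0.8, seed = 7),
                 "infeasible")
})

test_that("GWAS simulation reduces to the causal effects without LD", {
    ## no LD, huge N: reported effects converge to the causal effects
    cfg <- simulationConfig(seed = 105, nReference = 3000L, nCohort = 10L,
                            mVariants = 60L, blockSize = 30L,
                            blockRho = 0, nGwas = 1000000000L)
    panel <- simulatePanel(cfg, 3000L)
    ss <- simulateGwas(panel, cfg)
    truth <- attr(ss, "truth")
    ## orient reported betas to the ALT allele
    vi <- variantInfo(panel)
    st <- ss@stats[match(vi$key, ss@stats$key), ]
    betaAlt <- ifelse(st$effect_allele == vi$alt, st$beta, -st$beta)
    expect_gt(cor(betaAlt, truth$betaTrue), 0.97)
    fit <- lm(betaAlt ~ truth$betaTrue)
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)

    ## same seed: identical output
    ss2 <- simulateGwas(panel, cfg)
    expect_identical(ss@stats, ss2@stats)
})

test_that("null GWAS p-values are uniform", {
    cfg <- simulationConfig(seed = 106, nReference = 300L, nCohort = 10L,
                            mVariants = 2000L, blockSize = 50L,
                            blockRho = 0, fractionCausal = 0)
    panel <- simulatePanel(cfg, 300L)
    ss <- simulateGwas(panel, cfg)
    expect_true(all(attr(ss, "truth")$betaTrue == 0))
    ks <- suppressWarnings(ks.test(ss@stats$p_value, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("outcome calibration hits the incidence and prevalence targets", {
    cfg <- simulationConfig(seed = 107, nReference = 100L, nCohort = 4000L,
                            mVariants = 200L, blockSize = 20L,
                            incidenceTarget = 0.021,
                            prevalenceTarget = 0.05)
    sc <- simulateStudy(cfg)
    out <- sc@outcomes
    inc <- mean(out$event[out$prevalent == 0])
    ## realized fractions are binomial around the calibrated expectation
    tolInc <- 4 * sqrt(0.021 * 0.979 / nrow(out))
    expect_equal(mean(out$prevalent), 0.05,
                 tolerance = 4 * sqrt(0.05 * 0.95 / nrow(out)) / 0.05)
    expect_equal(inc * (1 - mean(out$prevalent)), 0.021,
                 tolerance = 3 * tolInc / 0.021)
    expect_true(all(out$time_years >= 0))
    expect_true(all(out$time_years <= cfg@followupYears))
})

test_that("null effects give a flat decile incidence profile", {
    eff0 <- setNames(rep(0, 11), names(chipPGS:::.DEFAULT_EFFECTS))
    cfg <- simulationConfig(seed = 108, nReference = 100L,
                            nCohort = 4000L, mVariants = 200L,
                            blockSize = 20L, effects = eff0,
                            incidenceTarget = 0.1, prevalenceTarget = 0)
    sc <- simulateStudy(cfg)
    data <- buildAnalysisCohort(sc@covariates, sc@outcomes,
                                target = "incidence")
    g <- setNames(sc@truth$gz, sc@covariates$sample_id)[data$sample_id]
    dec <- assignDeciles(g)
    curve <- decileRiskCurve(dec, setNames(data$case, data$sample_id))
    ## no association: counts consistent with a uniform rate
    cs <- suppressWarnings(chisq.test(cbind(curve$events,
                                            curve$n - curve$events)))
    expect_gt(cs$p.value, 0.01)
})

test_that("stronger BMI effects raise incidence in the obese stratum", {
    run <- function(bmiEff, seed) {
        cfg <- simulationConfig(seed = seed, nReference = 100L,
                                nCohort = 3000L, mVariants = 200L,
                                blockSize = 20L,
                                effects = c(bmi = bmiEff),
                                incidenceTarget = 0.08,
                                prevalenceTarget = 0)
        sc <- simulateStudy(cfg)
        obese <- sc@covariates$bmi >= 30
        mean(sc@outcomes$event[obese])
    }
    expect_gt(mean(vapply(201:203, function(s) run(0.16, s), numeric(1))),
              mean(vapply(201:203, function(s) run(0.08, s), numeric(1))))
})

test_that("cohort summaries reconstruct counts and percentages", {
    sc <- smallStudy()
    tab <- summarizeCohort(sc@covariates, sc@outcomes)
    n <- nrow(sc@covariates)
    expect_equal(tab$count[tab$metric == "n"], n)
    expect_equal(tab$count[tab$metric == "males"],
                 sum(sc@covariates$sex == 1))
    expect_equal(tab$pct[tab$metric == "males"],
                 100 * sum(sc@covariates$sex == 1) / n)
    expect_equal(tab$mean[tab$metric == "bmi"], mean(sc@covariates$bmi))
    expect_equal(tab$count[tab$metric == "incident"],
                 sum(sc@outcomes$event[sc@outcomes$prevalent == 0]))

    ## printed-percentage arithmetic
    expect_equal(pctOf(186493, 406159, 1), 45.9)
    expect_equal(pctOf(270, 36130, 2), 0.75)
    expect_equal(pctOf(8363, 406159, 1), 2.1)

    ## empty cohort: zero counts, NA percentages
    empty <- summarizeCohort(sc@covariates[0, ], sc@outcomes[0, ])
    expect_equal(empty$count[empty$metric == "n"], 0)
    expect_true(is.na(empty$pct[empty$metric == "males"]))
    expect_true(is.na(pctOf(5, 0)))
})

test_that("on-disk study round-trips through the io layer", {
    sc <- smallStudy()
    dir <- file.path(tempdir(), "studyfixture")
    paths <- writeCohort(sc, dir)
    expect_true(all(file.exists(paths)))

    ref <- readGenotypes(paths["reference"], r2Min = 0)
    expect_setequal(variantInfo(ref)$key, variantInfo(sc@reference)$key)
    k <- variantInfo(sc@reference)$key
    expect_equal(unname(dosages(ref)[k, ]),
                 unname(dosages(sc@reference)), tolerance = 1e-6)

    ss <- readSumstats(paths["sumstats"])
    expect_equal(nrow(ss@stats), nrow(sc@sumstats@stats))

    cv <- readCovariates(paths["covariates"])
    expect_equal(nrow(cv$covariates), nrow(sc@covariates))
    expect_equal(sum(cv$outcomes$event), sum(sc@outcomes$event))

    truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
    expect_equal(truth$seed, sc@config@seed)
    expect_equal(truth$betaTrue, sc@truth$betaTrue, tolerance = 1e-12)
})
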