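#' @importFrom stats rnorm runif rbinom rexp qnorm pnorm uniroot var cor
NULL

.DEFAULT_EFFECTS <- c(bmi = 0.08, smokerPast = 0.15, smokerCurrent = 0.4,
                      paModerate = -0.04, paVigorous = -0.06, sex = 0.3,
                      fatherDisease = 0.35, motherDisease = 0.35,
                      pgs = 0.35, age = 0.04, pgsBmi = 0)

#' Construct a simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is meant for: a
#' whole-genome reference panel of ~500 individuals, a cohort of 2,000
#' genotyped on two chips that each retain two thirds of the 3,000 panel
#' variants with one third of the panel shared, dense local LD (blocks of
#' 50 variants with high within-block correlation, as in imputed data),
#' a fully polygenic trait with h2 = 0.3 estimated in a GWAS of 50,000,
#' covariate marginals loosely matching a middle-aged European cohort
#' (BMI mean 27.4, SD 4.8; age 38-75) and hazard calibration targets of
#' 2.1\% incidence over 10 years of follow-up and 5\% baseline prevalence.
#'
#' @param seed mandatory integer RNG seed.
#' @param nReference,nCohort,mVariants panel sizes.
#' @param freqRange effect-allele frequency range (uniform draw).
#' @param blockSize,blockRho LD block length (variants) and latent Gaussian
#'   within-block correlation.
#' @param chipRetain fraction of panel variants each chip carries.
#' @param chipOverlap fraction of panel variants present on both chips.
#' @param fractionCausal,h2,nGwas trait architecture and GWAS sample size.
#' @param effects named hazard-scale coefficients (log hazard ratios per
#'   unit) for the covariate terms; \code{pgs} multiplies the standardized
#'   true genetic burden.
#' @param bmiMean,bmiSd,ageRange,sexP,smokingP,paModerateMean,
#'   paVigorousMean,parentP covariate marginals.
#' @param incidenceTarget,prevalenceTarget,followupYears outcome
#'   calibration.
#' @param chipR2Range uniform range for per-variant chip imputation R2.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed,
                             nReference = 500L, nCohort = 2000L,
                             mVariants = 3000L, freqRange = c(0.05, 0.5),
                             blockSize = 50L, blockRho = 0.95,
                             chipRetain = 2 / 3, chipOverlap = 1 / 3,
                             fractionCausal = 1, h2 = 0.15,
                             nGwas = 10000L, effects = .DEFAULT_EFFECTS,
                             bmiMean = 27.4, bmiSd = 4.8,
                             ageRange = c(38, 75), sexP = 0.459,
                             smokingP = c(never = 0.445, past = 0.454,
                                          current = 0.101),
                             paModerateMean = 3.4, paVigorousMean = 1.7,
                             parentP = 0.12, incidenceTarget = 0.021,
                             prevalenceTarget = 0.05, followupYears = 10,
                             chipR2Range = c(0.3, 1)) {
    if (missing(seed)) stop("a seed is mandatory")
    effects <- utils::modifyList(as.list(.DEFAULT_EFFECTS),
                                 as.list(effects))
    new("SimulationConfig", nReference = as.integer(nReference),
        nCohort = as.integer(nCohort), mVariants = as.integer(mVariants),
        freqRange = freqRange, blockSize = as.integer(blockSize),
        blockRho = blockRho, chipRetain = chipRetain,
        chipOverlap = chipOverlap, fractionCausal = fractionCausal,
        h2 = h2, nGwas = as.integer(nGwas),
        effects = unlist(effects), bmiMean = bmiMean, bmiSd = bmiSd,
        ageRange = ageRange, sexP = sexP, smokingP = smokingP,
        paModerateMean = paModerateMean, paVigorousMean = paVigorousMean,
        parentP = parentP, incidenceTarget = incidenceTarget,
        prevalenceTarget = prevalenceTarget,
        followupYears = followupYears, chipR2Range = chipR2Range,
        seed = as.integer(seed))
}

## Variant definitions (frequencies, positions, alleles, blocks) are a
## deterministic function of the config seed, so reference and cohort
## genomes are drawn against identical variants.
.variantDefs <- function(cfg) {
    withr::with_seed(cfg@seed, {
        m <- cfg@mVariants
        block <- (seq_len(m) - 1L) %/% cfg@blockSize + 1L
        ## variants in strong LD sit on shared haplotypes, so within a
        ## block allele frequencies cluster around a common base value
        base <- runif(max(block), cfg@freqRange[1], cfg@freqRange[2])
        freq <- pmin(pmax(base[block] + rnorm(m, 0, 0.02),
                          cfg@freqRange[1]), cfg@freqRange[2])
        pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                             alt = c("A", "C", "G", "T"),
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$ref != pairs$alt, ]
        ## transition:transversion ratio ~2, so ~1/6 of variants are
        ## strand-ambiguous (A/T, C/G), as in real SNP sets
        ti <- with(pairs, paste0(ref, alt) %in% c("AG", "GA", "CT", "TC"))
        w <- ifelse(ti, 2 / 3 / sum(ti), 1 / 3 / sum(!ti))
        pick <- sample.int(nrow(pairs), m, replace = TRUE, prob = w)
        data.frame(chrom = "1", pos = seq_len(m) * 1000L,
                   ref = pairs$ref[pick], alt = pairs$alt[pick],
                   freq = freq, block = block,
                   stringsAsFactors = FALSE)
    })
}

#' Simulate a genotype panel
#'
#' Draws diploid dosages for the config's variant set. LD is induced by a
#' Gaussian copula: per haplotype and LD block, a latent normal vector with
#' exchangeable correlation \code{blockRho} is thresholded at the allele
#' frequency quantile; the dosage is the sum of the two haplotype alleles,
#' so each variant is marginally Binomial(2, freq) with block-correlated
#' neighbours. Deterministic given the seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param n number of individuals (default \code{nReference}).
#' @param seed RNG seed for the genome draw (default derived from the
#'   config seed).
#' @param idPrefix sample-id prefix.
#' @return A \linkS4class{GenotypeMatrix} with r2 = 1 (sequencing-like).
#' @export
simulatePanel <- function(cfg, n = cfg@nReference, seed = cfg@seed + 1L,
                          idPrefix = "REF") {
    defs <- .variantDefs(cfg)
    m <- nrow(defs)
    dos <- withr::with_seed(seed, {
        d <- matrix(0, nrow = m, ncol = n)
        thr <- qnorm(defs$freq)
        for (b in unique(defs$block)) {
            idx <- which(defs$block == b)
            k <- length(idx)
            L <- chol(cfg@blockRho + diag(1 - cfg@blockRho, k))
            for (h in 1:2) {
                z <- matrix(rnorm(n * k), n, k) %*% L
                d[idx, ] <- d[idx, ] +
                    t(sweep(z, 2L, thr[idx], "<") * 1)
            }
        }
        d
    })
    variants <- data.frame(
        key = variantKey(defs$chrom, defs$pos, defs$ref, defs$alt),
        chrom = defs$chrom, pos = defs$pos, ref = defs$ref,
        alt = defs$alt, r2 = 1, stringsAsFactors = FALSE)
    colnames(dos) <- sprintf("%s%04d", idPrefix, seq_len(n))
    GenotypeMatrix(dos, variants)
}

#' Derive two partially overlapping chips
#'
#' Builds two genotyping-chip views of the same genomes: each chip retains
#' a fraction \code{retain} of the panel variants, and a fraction
#' \code{overlap} of the panel is present on both chips. Dosages at
#' retained sites are identical to the panel; per-variant imputation R2 is
#' drawn uniformly from \code{r2Range}. Requested fractions must be
#' feasible: \code{overlap <= retain} and \code{2 retain - overlap <= 1}.
#'
#' @param gm the cohort \linkS4class{GenotypeMatrix}.
#' @param retain fraction of variants per chip (default 2/3).
#' @param overlap fraction of panel variants shared (default 1/3).
#' @param seed RNG seed.
#' @param r2Range uniform range for chip imputation R2.
#' @return list with \linkS4class{GenotypeMatrix} elements \code{A} and
#'   \code{B}.
#' @export
makeChips <- function(gm, retain = 2 / 3, overlap = 1 / 3, seed,
                      r2Range = c(0.3, 1)) {
    stopifnot(is(gm, "GenotypeMatrix"), !missing(seed))
    if (overlap <= 0 || overlap > 1) stop("overlap must lie in (0, 1]")
    m <- nrow(gm)
    k <- round(m * retain)
    s <- round(m * overlap)
    if (s > k)
        stop("infeasible: overlap fraction exceeds retention fraction")
    ## absorb rounding slack of a single variant; anything more is a
    ## genuinely infeasible request
    if (2L * k - s == m + 1L) k <- k - 1L
    if (2L * k - s > m)
        stop("infeasible: chips need ", 2L * k - s,
             " distinct variants but the panel has ", m)
    withr::with_seed(seed, {
        perm <- sample.int(m)
        shared <- perm[seq_len(s)]
        aOnly <- perm[s + seq_len(k - s)]
        bOnly <- perm[s + (k - s) + seq_len(k - s)]
        mk <- function(idx) {
            idx <- sort(idx)
            chip <- gm[idx, ]
            SummarizedExperiment::rowData(chip)$r2 <-
                runif(length(idx), r2Range[1], r2Range[2])
            new("GenotypeMatrix", chip)
        }
        list(A = mk(c(shared, aOnly)), B = mk(c(shared, bOnly)))
    })
}

#' Simulate GWAS summary statistics
#'
#' Draws true per-allele effects for a configured fraction of causal
#' variants, scales them so the genetic variance equals the target
#' heritability, and reports the *marginal* association estimates a GWAS
#' would produce: the marginal slope of the trait on each variant's dosage
#' (which, under LD, sums the effects of correlated neighbours) plus
#' sampling noise with standard error \code{1/sqrt(N var(dosage))}, and the
#' corresponding Wald p-values. With uncorrelated variants the marginal
#' slope reduces to the causal effect itself. The reported effect allele is
#' chosen at random (ALT or REF) per variant, exercising downstream allele
#' alignment. Ground truth is attached as attribute \code{"truth"}.
#'
#' @param panel the reference \linkS4class{GenotypeMatrix} used as LD base.
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param seed RNG seed (default derived from the config seed).
#' @return A \linkS4class{SummaryStats}.
#' @export
simulateGwas <- function(panel, cfg, seed = cfg@seed + 3L) {
    stopifnot(is(panel, "GenotypeMatrix"))
    d <- dosages(panel)
    m <- nrow(d)
    vi <- variantInfo(panel)
    withr::with_seed(seed, {
        causal <- runif(m) < cfg@fractionCausal
        betaRaw <- rnorm(m) * causal
        g <- as.numeric(crossprod(d, betaRaw))
        vg <- var(g)
        if (any(causal) && vg <= 0)
            stop("degenerate genetic variance")
        sc <- if (any(causal)) sqrt(cfg@h2 / vg) else 0
        betaTrue <- betaRaw * sc
        g <- g * sc
        dc <- d - rowMeans(d)
        varj <- rowSums(dc^2) / (ncol(d) - 1L)
        marg <- ifelse(varj > 1e-12,
                       as.numeric(dc %*% (g - mean(g))) /
                           (ncol(d) - 1L) / pmax(varj, 1e-12), 0)
        se <- ifelse(varj > 1e-12, 1 / sqrt(cfg@nGwas * varj), Inf)
        betaHat <- marg + rnorm(m) * ifelse(is.finite(se), se, 0)
        p <- ifelse(is.finite(se), 2 * pnorm(-abs(betaHat / se)), 1)
        p <- pmax(p, .Machine$double.xmin)
        reportRef <- runif(m) < 0.5  # report effect on the REF allele
        df <- data.frame(
            chrom = vi$chrom, pos = vi$pos,
            effect_allele = ifelse(reportRef, vi$ref, vi$alt),
            other_allele = ifelse(reportRef, vi$alt, vi$ref),
            beta = ifelse(reportRef, -betaHat, betaHat),
            p_value = p, n_gwas = cfg@nGwas, stringsAsFactors = FALSE)
        df$key <- vi$key
        ss <- SummaryStats(df[c("key", "chrom", "pos", "effect_allele",
                                "other_allele", "beta", "p_value",
                                "n_gwas")])
        attr(ss, "truth") <- list(betaTrue = betaTrue, marginal = marg,
                                  causal = causal)
        ss
    })
}

#' Simulate covariates and time-to-event outcomes
#'
#' Covariates are drawn from documented marginals (BMI normal, sex and
#' parental disease Bernoulli, smoking categorical, physical activity
#' Binomial(7, mean/7), age uniform, 4 standard-normal PCs and a two-level
#' batch with zero effect). Event times are exponential with hazard
#' proportional to \code{exp(lp)}, where the linear predictor combines the
#' configured covariate effects with the standardized true genetic burden.
#' The baseline hazard and a pre-baseline exposure window are calibrated
#' numerically so the expected incident fraction over the follow-up horizon
#' and the expected prevalent fraction match the configured targets;
#' prevalent cases are events that occurred before baseline under the same
#' hazard. Censoring is administrative at the horizon.
#'
#' @param gm cohort \linkS4class{GenotypeMatrix} (full panel view).
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param betaTrue true per-allele effects (from
#'   \code{attr(simulateGwas(...), "truth")$betaTrue}).
#' @param seed RNG seed (default derived from the config seed).
#' @return list with \code{covariates}, \code{outcomes} and \code{truth}
#'   (genetic burden, linear predictor, baseline hazard, window).
#' @export
simulateCohort <- function(gm, cfg, betaTrue, seed = cfg@seed + 5L) {
    stopifnot(is(gm, "GenotypeMatrix"),
              length(betaTrue) == nrow(gm))
    n <- ncol(gm)
    ids <- sampleIds(gm)
    eff <- cfg@effects
    withr::with_seed(seed, {
        g <- as.numeric(crossprod(dosages(gm), betaTrue))
        gz <- if (sd(g) > 0) as.numeric(scale(g)) else rep(0, n)
        cov <- data.frame(
            sample_id = ids,
            bmi = rnorm(n, cfg@bmiMean, cfg@bmiSd),
            sex = rbinom(n, 1, cfg@sexP),
            smoking = sample(names(cfg@smokingP), n, replace = TRUE,
                             prob = cfg@smokingP),
            pa_moderate = rbinom(n, 7, cfg@paModerateMean / 7),
            pa_vigorous = rbinom(n, 7, cfg@paVigorousMean / 7),
            father_disease = rbinom(n, 1, cfg@parentP),
            mother_disease = rbinom(n, 1, cfg@parentP),
            age = runif(n, cfg@ageRange[1], cfg@ageRange[2]),
            pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
            batch = sample(c("B1", "B2"), n, replace = TRUE),
            stringsAsFactors = FALSE)
        lp <- eff["bmi"] * (cov$bmi - cfg@bmiMean) +
            eff["smokerPast"] * (cov$smoking == "past") +
            eff["smokerCurrent"] * (cov$smoking == "current") +
            eff["paModerate"] * (cov$pa_moderate - cfg@paModerateMean) +
            eff["paVigorous"] * (cov$pa_vigorous - cfg@paVigorousMean) +
            eff["sex"] * cov$sex +
            eff["fatherDisease"] * cov$father_disease +
            eff["motherDisease"] * cov$mother_disease +
            eff["age"] * (cov$age - mean(cfg@ageRange)) +
            eff["pgs"] * gz +
            eff["pgsBmi"] * gz * (cov$bmi - cfg@bmiMean)
        lp <- as.numeric(lp)
        ehl <- exp(lp)
        H <- cfg@followupYears
        ## calibrate baseline hazard and pre-baseline window to the targets
        lambda0 <- exp(uniroot(function(l)
            mean(1 - exp(-exp(l) * H * ehl)) - cfg@incidenceTarget,
            c(log(1e-12), log(1e3)))$root)
        W <- 0
        if (cfg@prevalenceTarget > 0) {
            ## the incidence objective is hump-shaped in lambda once W > 0:
            ## bracket the root on the rising branch from a log-scale grid
            solveRising <- function(f, l0) {
                ls <- l0 + seq(-25, 8, by = 0.25)
                vals <- vapply(ls, f, numeric(1))
                i <- which(vals[-length(vals)] <= 0 & vals[-1] > 0)[1L]
                if (is.na(i))
                    stop("incidence target unattainable at this ",
                         "prevalence target; lower one of them")
                uniroot(f, c(ls[i], ls[i + 1L]))$root
            }
            for (i in 1:15) {
                W <- uniroot(function(w)
                    mean(1 - exp(-lambda0 * w * ehl)) -
                        cfg@prevalenceTarget, c(0, 1e4))$root
                lambda0 <- exp(solveRising(function(l)
                    mean(exp(-exp(l) * W * ehl) -
                         exp(-exp(l) * (W + H) * ehl)) -
                        cfg@incidenceTarget, log(lambda0)))
            }
        }
        tTot <- rexp(n, rate = 1) / (lambda0 * ehl)
        prevalent <- tTot < W
        tPost <- tTot - W
        event <- !prevalent & tPost <= H
        out <- data.frame(
            sample_id = ids,
            prevalent = as.integer(prevalent),
            event = as.integer(event),
            time_years = ifelse(prevalent, 0, pmin(tPost, H)),
            stringsAsFactors = FALSE)
        if (!sum(out$event))
            stop("no incident events realised; increase incidenceTarget, ",
                 "followupYears or the cohort size")
        list(covariates = cov, outcomes = out,
             truth = list(g = g, gz = gz, lp = lp, lambda0 = lambda0,
                          window = W))
    })
}

#' Simulate a complete study
#'
#' Orchestrates the generator: the reference panel, an independent cohort
#' drawn on the same variants, two chip views of the cohort genomes, GWAS
#' summary statistics with marginal effects based on reference-panel LD,
#' and covariates with time-to-event outcomes driven by the true genetic
#' burden. Fully deterministic given the config seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SyntheticCohort}.
#' @export
simulateStudy <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    reference <- simulatePanel(cfg, cfg@nReference, seed = cfg@seed + 1L,
                               idPrefix = "REF")
    cohort <- simulatePanel(cfg, cfg@nCohort, seed = cfg@seed + 2L,
                            idPrefix = "S")
    ss <- simulateGwas(reference, cfg, seed = cfg@seed + 3L)
    truthGwas <- attr(ss, "truth")
    chips <- makeChips(cohort, retain = cfg@chipRetain,
                       overlap = cfg@chipOverlap, seed = cfg@seed + 4L,
                       r2Range = cfg@chipR2Range)
    sim <- simulateCohort(cohort, cfg, truthGwas$betaTrue,
                          seed = cfg@seed + 5L)
    new("SyntheticCohort", reference = reference, cohort = cohort,
        chipA = chips$A, chipB = chips$B, sumstats = ss,
        covariates = sim$covariates, outcomes = sim$outcomes,
        truth = c(truthGwas, sim$truth, list(seed = cfg@seed)),
        config = cfg)
}

#' Cohort summary table
#'
#' Counts, percentages, means and SDs in the style of a baseline
#' characteristics table: sample count, sex split, smoking status, BMI,
#' physical activity, and outcome prevalence (case at first assessment)
#' and incidence (new diagnosis during follow-up). Percentages are
#' unrounded; use \code{\link{pctOf}} for display rounding. An empty cohort
#' yields zero counts with NA percentages.
#'
#' @param covariates,outcomes canonical data.frames.
#' @return data.frame with columns metric, count, total, pct, mean, sd.
#' @export
summarizeCohort <- function(covariates, outcomes) {
    n <- nrow(covariates)
    pc <- function(k) if (n > 0) 100 * k / n else NA_real_
    cnt <- function(metric, k)
        data.frame(metric = metric, count = k, total = n, pct = pc(k),
                   mean = NA_real_, sd = NA_real_)
    ms <- function(metric, x)
        data.frame(metric = metric, count = NA_integer_, total = n,
                   pct = NA_real_,
                   mean = if (n) mean(x) else NA_real_,
                   sd = if (n) sd(x) else NA_real_)
    rbind(cnt("n", n),
          cnt("males", sum(covariates$sex == 1)),
          cnt("females", sum(covariates$sex == 0)),
          cnt("smoking_current", sum(covariates$smoking == "current")),
          cnt("smoking_past", sum(covariates$smoking == "past")),
          ms("bmi", covariates$bmi),
          ms("pa_moderate", covariates$pa_moderate),
          ms("pa_vigorous", covariates$pa_vigorous),
          cnt("prevalent", sum(outcomes$prevalent)),
          cnt("incident", sum(outcomes$event[outcomes$prevalent == 0])))
}

#' Percentage of a total
#'
#' \code{100 * count / total}, rounded to \code{digits}; NA with a zero
#' total.
#'
#' @param count,total counts.
#' @param digits decimals to round to (default 1).
#' @return numeric percentage.
#' @export
pctOf <- function(count, total, digits = 1) {
    if (total == 0) return(NA_real_)
    round(100 * count / total, digits)
}

#' Write a synthetic study to disk
#'
#' Emits the on-disk fixture tree: reference and chip VCFs, the
#' summary-statistics TSV, the covariate/outcome CSV and the ground-truth
#' JSON (all plain text).
#'
#' @param sc a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohort <- function(sc, dir) {
    stopifnot(is(sc, "SyntheticCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(reference = file.path(dir, "reference.vcf"),
               chipA = file.path(dir, "chipA.vcf"),
               chipB = file.path(dir, "chipB.vcf"),
               sumstats = file.path(dir, "sumstats.tsv"),
               covariates = file.path(dir, "covariates.csv"),
               truth = file.path(dir, "ground_truth.json"))
    writeGenotypes(sc@reference, paths["reference"])
    writeGenotypes(sc@chipA, paths["chipA"])
    writeGenotypes(sc@chipB, paths["chipB"])
    writeSumstats(sc@sumstats, paths["sumstats"])
    writeCovariates(sc@covariates, sc@outcomes, paths["covariates"])
    jsonlite::write_json(
        list(seed = sc@config@seed, h2 = sc@config@h2,
             betaTrue = sc@truth$betaTrue, lambda0 = sc@truth$lambda0,
             window = sc@truth$window,
             effects = as.list(sc@config@effects)),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
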