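#' @importFrom stats rnorm runif rbinom pnorm qnorm dnorm integrate uniroot
#'   median rexp
NULL

.strataNames <- c("metsNeg.crpLow", "metsNeg.crpHigh",
                  "metsPos.crpLow", "metsPos.crpHigh")

## Spearman <-> latent Pearson mapping for bivariate normals
.spearmanToPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)
.pearsonToSpearman <- function(rhoP) (6 / pi) * asin(rhoP / 2)

## Run expr with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    expr
}

#' Default stratum-specific interclass Spearman targets
#'
#' Interclass rank-correlation targets for the four MetS x CRP strata,
#' emulating the qualitative network differences the pipeline is designed to
#' detect: a healthy reference stratum with tight within-pathway coupling
#' (DCER-CER and HCER-LCER) and weak cross-pathway coupling; a high-CRP
#' non-MetS stratum where precursor ceramides couple to hexosylceramides
#' while the HCER-LCER link weakens; a MetS low-CRP stratum with a
#' strengthened DCER-CER link; and a MetS high-CRP stratum where all four
#' core classes tighten together.
#'
#' @return named list (one element per stratum) of named vectors keyed by
#'   sorted class pairs, e.g. \code{"CER-LCER"}.
#' @export
defaultInterclassRho <- function() {
    base <- c("CER-DCER" = 0.50, "HCER-LCER" = 0.50,
              "CER-HCER" = 0.15, "CER-LCER" = 0.10,
              "DCER-HCER" = 0.15, "DCER-LCER" = 0.10,
              "CER-SM" = 0.10, "DCER-SM" = 0.10,
              "HCER-SM" = 0.10, "LCER-SM" = 0.10)
    crpHigh <- base
    crpHigh["CER-HCER"] <- 0.35
    crpHigh["DCER-HCER"] <- 0.30
    crpHigh["HCER-LCER"] <- 0.30
    metsLow <- base
    metsLow["CER-DCER"] <- 0.65
    metsHigh <- base
    metsHigh[c("CER-DCER", "HCER-LCER")] <- 0.65
    metsHigh[c("CER-HCER", "CER-LCER", "DCER-HCER", "DCER-LCER")] <- 0.30
    list(metsNeg.crpLow = base, metsNeg.crpHigh = crpHigh,
         metsPos.crpLow = metsLow, metsPos.crpHigh = metsHigh)
}

.pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "-")
}

## Latent Pearson correlation matrix over species for one stratum,
## from Spearman-scale within-class and interclass targets.
.lipidCorrMatrix <- function(panel, withinClassRho, interRho) {
    k <- nrow(panel)
    cls <- panel$class_id
    R <- matrix(0, k, k, dimnames = list(panel$species_id, panel$species_id))
    within <- .spearmanToPearson(withinClassRho)
    for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
            if (cls[i] == cls[j]) {
                R[i, j] <- within
            } else {
                key <- .pairKey(cls[i], cls[j])
                rs <- interRho[[key]]
                if (is.null(rs) || is.na(rs))
                    stop("no interclass correlation target for class pair ", key)
                R[i, j] <- .spearmanToPearson(rs)
            }
        }
    }
    R <- R + t(R)
    diag(R) <- 1
    R
}

## PSD validation naming the offending class pair when one can be identified.
.checkPSD <- function(R, panel, stratum) {
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8)
        return(invisible(TRUE))
    cls <- panel$class_id
    for (pair in utils::combn(sort(unique(cls)), 2, simplify = FALSE)) {
        idx <- cls %in% pair
        sub <- R[idx, idx, drop = FALSE]
        if (min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
            stop("latent covariance for stratum '", stratum,
                 "' is not positive semidefinite; offending class pair: ",
                 .pairKey(pair[1], pair[2]))
    }
    stop("latent covariance for stratum '", stratum,
         "' is not positive semidefinite")
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of \code{\link{generateCohort}}. The
#' defaults emulate a midlife US biomarker cohort: MetS prevalence 0.375,
#' ceramide-pathway mean shifts upward and glycosphingolipid shifts downward
#' in MetS on the log scale, stratum-specific interclass correlations (see
#' \code{\link{defaultInterclassRho}}), and 5\% missing-completely-at-random
#' lipid values standing in for below-detection-limit losses.
#'
#' @param nSubjects number of subjects (> 0)
#' @param metsPrevalence target ATPIII MetS prevalence in (0, 1)
#' @param panel species panel data.frame; see \code{\link{defaultSpeciesPanel}}
#' @param classMeanShift named numeric, signed log-scale abundance shift per
#'   class applied to MetS subjects
#' @param interclassRho named list of per-stratum interclass Spearman targets
#' @param withinClassRho within-class Spearman target in [0, 1)
#' @param missingRate MCAR missingness rate in [0, 1)
#' @param sexProb,raceProb,educationProb categorical probabilities (must sum
#'   to 1)
#' @param ageMean,ageSD,ageRange normal age distribution, truncated to range
#' @param biomarkerEffects named log-scale shifts of inflammatory biomarkers
#'   (crp, il6, fibrinogen, sicam) for MetS subjects
#' @param factorLoading shared variance of the five latent MetS component
#'   scores (0, 1); governs how strongly components co-occur
#' @param seed integer seed (< 2^30)
#' @return validated list of class \code{cohortConfig}
#' @examples
#' cfg <- cohortConfig(nSubjects = 200, seed = 1)
#' @export
cohortConfig <- function(nSubjects = 2000,
                         metsPrevalence = 0.375,
                         panel = defaultSpeciesPanel(),
                         classMeanShift = c(DCER = 0.2, CER = 0.2, SM = 0,
                                            HCER = -0.2, LCER = -0.25),
                         interclassRho = defaultInterclassRho(),
                         withinClassRho = 0.6,
                         missingRate = 0.05,
                         sexProb = c(female = 0.55, male = 0.45),
                         raceProb = c(White = 0.748, Black = 0.177,
                                      Other = 0.075),
                         educationProb = c(hs_or_less = 0.24,
                                           some_college = 0.52,
                                           postgraduate = 0.24),
                         ageMean = 55.7, ageSD = 12.5, ageRange = c(25, 85),
                         biomarkerEffects = c(crp = 0.4, il6 = 0.3,
                                              fibrinogen = 0.15, sicam = 0.1),
                         factorLoading = 0.5,
                         seed = 1L) {
    stopifnot(nSubjects > 0, metsPrevalence > 0, metsPrevalence < 1,
              withinClassRho >= 0, withinClassRho < 1,
              missingRate >= 0, missingRate < 1,
              factorLoading > 0, factorLoading < 1,
              seed == as.integer(seed), abs(seed) < 2^30)
    for (p in list(sexProb, raceProb, educationProb))
        if (abs(sum(p) - 1) > 1e-8)
            stop("categorical probabilities must sum to 1")
    classes <- unique(panel$class_id)
    if (!all(classes %in% names(classMeanShift)))
        stop("classMeanShift must name every class in the panel")
    if (!all(.strataNames %in% names(interclassRho)))
        stop("interclassRho must name all four strata: ",
             paste(.strataNames, collapse = ", "))
    corr <- lapply(.strataNames, function(s)
        .lipidCorrMatrix(panel, withinClassRho, interclassRho[[s]]))
    names(corr) <- .strataNames
    for (s in .strataNames) .checkPSD(corr[[s]], panel, s)
    structure(list(nSubjects = as.integer(nSubjects),
                   metsPrevalence = metsPrevalence, panel = panel,
                   classMeanShift = classMeanShift,
                   interclassRho = interclassRho,
                   withinClassRho = withinClassRho,
                   missingRate = missingRate, sexProb = sexProb,
                   raceProb = raceProb, educationProb = educationProb,
                   ageMean = ageMean, ageSD = ageSD, ageRange = ageRange,
                   biomarkerEffects = biomarkerEffects,
                   factorLoading = factorLoading,
                   seed = as.integer(seed), .corr = corr),
              class = "cohortConfig")
}

## Threshold tau on the latent component scores such that
## P(at least 3 of 5 components abnormal) = target, under a one-factor
## model z_i = sqrt(lambda) f + sqrt(1 - lambda) e_i, abnormal iff z_i > tau.
.calibrateTau <- function(target, lambda) {
    prevalence <- function(tau) {
        f <- function(x) {
            s <- pnorm((sqrt(lambda) * x - tau) / sqrt(1 - lambda))
            tail3 <- 10 * s^3 * (1 - s)^2 + 5 * s^4 * (1 - s) + s^5
            dnorm(x) * tail3
        }
        integrate(f, -8, 8, rel.tol = 1e-10)$value
    }
    uniroot(function(tau) prevalence(tau) - target,
            lower = -4, upper = 4, tol = 1e-10)$root
}

#' Generate a seeded synthetic cohort
#'
#' Draws a clinical table and a lipid abundance matrix with the statistical
#' structure the downstream pipeline assumes. The five ATPIII component
#' measurements are monotone transforms of correlated latent Gaussian scores
#' thresholded exactly at the ATPIII cut-offs, so the classifier
#' (\code{\link{classifyMetS}}), not the generator, decides the diagnosis and
#' the target prevalence is met in expectation. Medication flags are drawn
#' only among subjects whose latent component is abnormal; half of the
#' medicated are "treated to target" (measured value pulled below threshold)
#' so the medication override is exercised without shifting prevalence.
#' Log-abundances are multivariate normal with within-class correlation
#' blocks and stratum-specific (MetS x CRP-median) interclass correlations on
#' the Spearman scale, exponentiated to lognormal abundances; MetS subjects'
#' class means are shifted by \code{classMeanShift}; cells are then masked
#' missing-completely-at-random at \code{missingRate}.
#'
#' @param config a \code{\link{cohortConfig}}
#' @return A \linkS4class{SphingolipidExperiment}; \code{colData()} holds the
#'   clinical table plus the generator's own MetS/CRP stratum labels
#'   (\code{stratum}), and \code{metadata()} records the config and seed.
#' @examples
#' se <- generateCohort(cohortConfig(nSubjects = 100, seed = 7))
#' table(colData(se)$stratum)
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "cohortConfig"))
    .withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
    n <- config$nSubjects
    panel <- config$panel
    lambda <- config$factorLoading
    tau <- .calibrateTau(config$metsPrevalence, lambda)

    id <- sprintf("S%05d", seq_len(n))
    sex <- sample(names(config$sexProb), n, TRUE, config$sexProb)
    age <- pmin(pmax(rnorm(n, config$ageMean, config$ageSD),
                     config$ageRange[1]), config$ageRange[2])
    race <- sample(names(config$raceProb), n, TRUE, config$raceProb)
    education <- sample(names(config$educationProb), n, TRUE,
                        config$educationProb)

    f <- rnorm(n)
    z <- sqrt(lambda) * f +
        sqrt(1 - lambda) * matrix(rnorm(5 * n), n, 5)
    abnormal <- z > tau

    ## medication flags only among latent-abnormal subjects; half of the
    ## medicated have measured values treated to below threshold
    med <- matrix(FALSE, n, 4)         # tg, hdl, htn, glycemia
    treated <- matrix(FALSE, n, 4)
    for (j in 1:4) {
        comp <- c(2, 3, 4, 5)[j]       # waist (1) has no medication override
        med[, j] <- abnormal[, comp] & runif(n) < 0.3
        treated[, j] <- med[, j] & runif(n) < 0.5
    }
    zEff <- z
    for (j in 1:4) {
        comp <- c(2, 3, 4, 5)[j]
        k <- which(treated[, j])
        zEff[k, comp] <- tau - abs(rnorm(length(k), 0.5, 0.2))
    }

    male <- sex == "male"
    waist <- ifelse(male, 102, 88) * exp(0.10 * (zEff[, 1] - tau))
    tg <- 150 * exp(0.45 * (zEff[, 2] - tau))
    hdl <- ifelse(male, 40, 50) * exp(-0.18 * (zEff[, 3] - tau))
    systolic <- 130 * exp(0.075 * (zEff[, 4] - tau))
    diastolic <- systolic * (85 / 130)  # single latent pressure driver
    glucose <- 100 * exp(0.13 * (zEff[, 5] - tau))

    insulin <- exp(log(8) + 0.55 * z[, 5] + 0.35 * rnorm(n))
    hba1c <- 5.4 + 0.35 * z[, 5] + 0.15 * rnorm(n)
    homaIR <- glucose * insulin / 405
    bmi <- waist * 0.28 + rnorm(n, 0, 1.8)
    ldl <- rnorm(n, 112, 30)
    oxhdl <- exp(rnorm(n, log(80), 0.3))

    clinical <- data.frame(
        subject_id = id, sex = sex, age = age, race = race,
        education = education, waist_cm = waist, bmi = bmi,
        systolic = systolic, diastolic = diastolic,
        triglycerides_mg_dl = tg, hdl_mg_dl = hdl, ldl_mg_dl = ldl,
        glucose_mg_dl = glucose, insulin_uiu_ml = insulin, hba1c = hba1c,
        homa_ir = homaIR, oxhdl = oxhdl,
        tg_medication = med[, 1], hdl_medication = med[, 2],
        htn_medication_with_history = med[, 3],
        glycemia_medication = med[, 4],
        stringsAsFactors = FALSE, row.names = id)

    status <- classifyMetS(clinical)
    mets <- status$diagnosis

    eff <- config$biomarkerEffects
    clinical$crp_ug_ml <- exp(rnorm(n, log(1.8), 0.6) + eff["crp"] * mets)
    clinical$il6_pg_ml <- exp(rnorm(n, log(2.5), 0.5) + eff["il6"] * mets)
    clinical$fibrinogen_mg_dl <-
        exp(rnorm(n, log(340), 0.15) + eff["fibrinogen"] * mets)
    clinical$sicam_ng_ml <-
        exp(rnorm(n, log(270), 0.25) + eff["sicam"] * mets)
    clinical$eselectin_ng_ml <- exp(rnorm(n, log(40), 0.3))

    crpHigh <- clinical$crp_ug_ml > median(clinical$crp_ug_ml)
    stratum <- .strataNames[1 + crpHigh + 2 * mets]

    ## lipid abundances: per-stratum latent MVN, lognormal on exp scale
    k <- nrow(panel)
    mu <- .speciesLogMeans(panel)
    shift <- config$classMeanShift[panel$class_id]
    logAb <- matrix(NA_real_, n, k,
                    dimnames = list(id, panel$species_id))
    for (s in .strataNames) {
        idx <- which(stratum == s)
        if (!length(idx)) next
        L <- chol(config$.corr[[s]])
        latent <- matrix(rnorm(length(idx) * k), length(idx), k) %*% L
        logAb[idx, ] <- sweep(0.5 * latent, 2, mu, "+")
        if (grepl("metsPos", s))
            logAb[idx, ] <- sweep(logAb[idx, ], 2, shift, "+")
    }
    abundances <- t(exp(logAb))

    se <- SphingolipidExperiment(abundances, panel,
                                 cbind(clinical, stratum = stratum,
                                       mets = mets))
    if (config$missingRate > 0)
        se <- injectMissingness(se, config$missingRate,
                                seed = config$seed + 1L)
    metadata(se)$config <- config
    metadata(se)$seed <- config$seed
    metadata(se)$tau <- tau
    se
}

## deterministic per-species log-scale means: class baseline plus a small
## chain-length trend
.speciesLogMeans <- function(panel) {
    base <- c(DCER = 0.5, CER = 2, SM = 10, HCER = 1, LCER = 0.8)
    mu <- log(base[panel$class_id]) + 0.03 * (panel$chain_carbons - 20)
    names(mu) <- panel$species_id
    mu
}

#' Simulate a class-blocked lognormal lipid matrix
#'
#' Draws species abundances for \code{n} subjects from a single multivariate
#' lognormal population: latent log-abundances are multivariate normal with
#' within-class correlation blocks and the given interclass rank-correlation
#' targets (Spearman scale, mapped to latent Pearson via
#' 2 sin(pi rho_S / 6)), then exponentiated. This is the building block the
#' cohort generator uses per stratum, exposed directly for simulation
#' studies of the network pipeline.
#'
#' @param n number of subjects
#' @param panel species panel (default \code{defaultSpeciesPanel(nSM = 0)},
#'   the ceramide-pathway classes the network stage analyzes)
#' @param withinClassRho within-class Spearman target in [0, 1)
#' @param interclassRho named vector of interclass Spearman targets keyed by
#'   sorted class pairs (\code{"CER-LCER"}), or a single number applied to
#'   every class pair
#' @param classMeanShift optional named log-scale mean shift per class
#' @param seed integer seed
#' @return species x subjects abundance matrix
#' @export
simulateLipidMatrix <- function(n, panel = defaultSpeciesPanel(nSM = 0),
                                withinClassRho = 0.6, interclassRho = 0.1,
                                classMeanShift = NULL, seed = 1L) {
    classes <- sort(unique(panel$class_id))
    if (length(interclassRho) == 1 && is.null(names(interclassRho))) {
        pairs <- utils::combn(classes, 2, function(p) .pairKey(p[1], p[2]))
        interclassRho <- stats::setNames(rep(interclassRho, length(pairs)),
                                         pairs)
    }
    R <- .lipidCorrMatrix(panel, withinClassRho, interclassRho)
    .checkPSD(R, panel, "simulated")
    mu <- .speciesLogMeans(panel)
    if (!is.null(classMeanShift))
        mu <- mu + classMeanShift[panel$class_id]
    .withSeed(seed, {
        latent <- matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% chol(R)
        t(exp(sweep(0.5 * latent, 2, mu, "+")))
    })
}

#' Inject missing-completely-at-random values
#'
#' Each cell of the raw abundance matrix is independently set missing with
#' probability \code{rate}; the mask is a deterministic function of
#' \code{seed}.
#'
#' @param x a \linkS4class{SphingolipidExperiment} or numeric matrix
#' @param rate missingness probability in [0, 1)
#' @param seed integer seed for the mask
#' @return object of the same type with \code{NA}s injected
#' @export
injectMissingness <- function(x, rate, seed) {
    if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
    m <- if (is(x, "SphingolipidExperiment")) assay(x, "raw") else x
    mask <- .withSeed(seed, matrix(runif(length(m)) < rate, nrow(m), ncol(m)))
    m[mask] <- NA_real_
    if (is(x, "SphingolipidExperiment")) {
        assay(x, "raw") <- m
        x
    } else m
}

#' Write a cohort to plain-text files
#'
#' Writes the clinical table and lipid matrix as TSV (subjects as rows,
#' missing cells empty), the species-to-class map as a 2-column TSV, the
#' generator configuration as YAML and a JSON provenance sidecar recording
#' the seed.
#'
#' @param se a \linkS4class{SphingolipidExperiment}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeCohort <- function(se, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, c("clinical.tsv", "lipids.tsv",
                              "species_classes.tsv", "config.yaml",
                              "provenance.json"))
    clin <- as.data.frame(colData(se))
    utils::write.table(clin, paths[1], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    lip <- as.data.frame(t(assay(se, "raw")))
    lip <- cbind(subject_id = rownames(lip), lip)
    utils::write.table(lip, paths[2], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    utils::write.table(
        data.frame(species_id = rownames(se),
                   class_id = lipidClasses(se)),
        paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- metadata(se)$config
    if (!is.null(cfg)) {
        flat <- cfg[setdiff(names(cfg), c(".corr", "panel"))]
        yaml::write_yaml(lapply(flat, unclass), paths[4])
        jsonlite::write_json(list(seed = cfg$seed, nSubjects = cfg$nSubjects,
                                  generated = format(Sys.time(), tz = "UTC")),
                             paths[5], auto_unbox = TRUE)
    }
    invisible(paths)
}

#' Read a cohort from plain-text files
#'
#' Real-data entry point: assembles a \linkS4class{SphingolipidExperiment}
#' from a clinical TSV/CSV, a subjects x species abundance TSV/CSV (first
#' column subject ids; empty cells read as missing) and a 2-column
#' species-to-class map.
#'
#' @param clinicalFile,lipidFile,classFile paths; delimiter inferred from the
#'   extension (.csv means comma, anything else tab)
#' @return A \linkS4class{SphingolipidExperiment}
#' @export
readSphingolipidData <- function(clinicalFile, lipidFile, classFile) {
    rd <- function(f) utils::read.table(f, header = TRUE,
                                        sep = if (grepl("\\.csv$", f)) "," else "\t",
                                        stringsAsFactors = FALSE,
                                        check.names = FALSE)
    clin <- rd(clinicalFile)
    rownames(clin) <- clin$subject_id
    lip <- rd(lipidFile)
    rownames(lip) <- lip$subject_id
    lip$subject_id <- NULL
    cmap <- rd(classFile)
    panel <- data.frame(species_id = cmap$species_id,
                        class_id = cmap$class_id,
                        stringsAsFactors = FALSE)
    common <- intersect(rownames(clin), rownames(lip))
    if (!length(common)) stop("no shared subject ids between tables")
    SphingolipidExperiment(as.matrix(lip[common, , drop = FALSE]),
                           panel, clin[common, , drop = FALSE])
}
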