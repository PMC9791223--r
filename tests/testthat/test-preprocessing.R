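test_that("ATPIII classification matches the worked examples", {
    # 3 abnormal measured components -> diagnosis
    s <- classifyMetS(subjectRecord(sex = "male", waist = 105, tg = 160,
                                    hdl = 45, sys = 120, dia = 80,
                                    glucose = 105))
    expect_equal(s$n_components, 3)
    expect_true(s$diagnosis)

    # all components below cut-offs -> no diagnosis
    s <- classifyMetS(subjectRecord(sex = "female", waist = 80, tg = 100,
                                    hdl = 60, sys = 110, dia = 70,
                                    glucose = 90))
    expect_equal(s$n_components, 0)
    expect_false(s$diagnosis)

    # medication overrides alone can satisfy three criteria
    s <- classifyMetS(subjectRecord(sex = "male", waist = 90, tg = 100,
                                    hdl = 55, sys = 120, dia = 70,
                                    glucose = 90, tg_medication = TRUE,
                                    hdl_medication = TRUE,
                                    htn_medication_with_history = TRUE))
    expect_equal(s$n_components, 3)
    expect_true(s$diagnosis)

    # sex-specific thresholds: waist 95 is abnormal for women only
    rec <- subjectRecord(sex = c("male", "female"), waist = 95)
    s <- classifyMetS(rec)
    expect_equal(s$abdominal_obesity, c(FALSE, TRUE))

    # missing required data errors name the field
    expect_error(classifyMetS(subjectRecord(glucose = NA)),
                 "glucose_mg_dl")
    expect_error(classifyMetS(subjectRecord()[-1]), "sex")
})

test_that("classification is monotone in the component values", {
    base <- subjectRecord(sex = "male", waist = 105, tg = 160, hdl = 45,
                          sys = 120, dia = 80, glucose = 105)
    expect_true(classifyMetS(base)$diagnosis)
    for (col in c("waist_cm", "triglycerides_mg_dl", "systolic",
                  "glucose_mg_dl")) {
        worse <- base
        worse[[col]] <- worse[[col]] * 1.5
        expect_true(classifyMetS(worse)$diagnosis)
    }
    worse <- base; worse$hdl_mg_dl <- 20
    expect_true(classifyMetS(worse)$diagnosis)
})

test_that("impaired glucoregulation requires both high glucose and insulin", {
    rec <- subjectRecord(sex = "male", glucose = c(110, 110, 95),
                         insulin_uiu_ml = c(30, 20, 30))
    s <- classifyMetS(rec)
    expect_equal(s$impaired_glucoregulation, c(TRUE, FALSE, FALSE))
})

test_that("CRP stratification splits at the median with ties to low", {
    expect_equal(crpStratify(c(1, 2, 3, 4, 5)),
                 c("low", "low", "low", "high", "high"))
    expect_equal(crpStratify(rep(2.5, 4)), rep("low", 4))
    expect_equal(crpStratify(c(1, NA, 3)), c("low", NA, "high"))
    expect_error(crpStratify(c(NA_real_, NA_real_)), "non-missing")
})

test_that("species filter applies the strict <20% missingness rule", {
    panel <- twoClassPanel(3, 2)
    m <- matrix(rexp(5 * 10), 5, 10,
                dimnames = list(panel$species_id, paste0("S", 1:10)))
    m[1, 1:2] <- NA      # exactly 20% -> dropped
    m[2, 1:3] <- NA      # 30% -> dropped
    m[3, 1] <- NA        # 10% -> retained
    se <- filterSpecies(SphingolipidExperiment(m, panel))
    expect_setequal(rownames(se), panel$species_id[3:5])
    dropped <- S4Vectors::metadata(se)$droppedSpecies
    expect_setequal(dropped$species_id, panel$species_id[1:2])
    expect_equal(sort(dropped$missing_fraction), c(0.2, 0.3))

    mAll <- m; mAll[] <- NA
    expect_error(filterSpecies(SphingolipidExperiment(mAll, panel)), "all")
})

test_that("log/z-scoring matches hand computation and normalizes exactly", {
    panel <- twoClassPanel(1, 1)
    m <- matrix(c(1, exp(1), exp(2), 2, 4, 8), 2, 3, byrow = TRUE,
                dimnames = list(panel$species_id, paste0("S", 1:3)))
    se <- logZscore(SphingolipidExperiment(m, panel))
    z <- SummarizedExperiment::assay(se, "zscore")
    expect_equal(unname(z[1, ]), c(-1, 0, 1))
    expect_equal(mean(z[2, ]), 0, tolerance = 1e-12)
    expect_equal(sd(z[2, ]), 1, tolerance = 1e-12)

    const <- m; const[1, ] <- 5
    expect_error(logZscore(SphingolipidExperiment(const, panel)),
                 panel$species_id[1], fixed = TRUE)
    neg <- m; neg[1, 1] <- 0
    expect_error(logZscore(SphingolipidExperiment(neg, panel)), "positive")
})

test_that("preprocessing commutes with subject reordering", {
    se <- generateCohort(cohortConfig(nSubjects = 80, seed = 61))
    perm <- sample(ncol(se))
    a <- SummarizedExperiment::assay(logZscore(filterSpecies(se)), "zscore")
    b <- SummarizedExperiment::assay(logZscore(filterSpecies(se[, perm])),
                                     "zscore")
    expect_equal(a[, colnames(b)], b)
})

test_that("ratio biomarkers follow the raw-total definitions", {
    panel <- defaultSpeciesPanel(nSM = 0)
    m <- matrix(1, nrow(panel), 4,
                dimnames = list(panel$species_id, paste0("S", 1:4)))
    se <- SphingolipidExperiment(m, panel)
    r <- computeRatios(se)
    # equal unit abundances: CER total 8, LCER total 7; integrative = 12/14
    expect_equal(r$ratio_cer_lcer, rep(8 / 7, 4))
    expect_equal(r$ratio_integrative, rep(12 / 14, 4))

    # global rescaling leaves ratios unchanged
    r2 <- computeRatios(SphingolipidExperiment(m * 37.5, panel))
    expect_equal(r2, r)

    # missing species are excluded from the class totals, no imputation
    m3 <- m; m3["LCER14", 1] <- NA
    r3 <- computeRatios(SphingolipidExperiment(m3, panel))
    expect_equal(r3$ratio_cer_lcer[1], 8 / 6)
})
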