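test_that("default species panel has the expected composition", {
    panel <- defaultSpeciesPanel()
    expect_false(anyDuplicated(panel$species_id) > 0)
    counts <- table(panel$class_id)
    expect_equal(counts[["DCER"]], 4)
    expect_equal(counts[["CER"]], 8)
    expect_equal(counts[["HCER"]], 7)
    expect_equal(counts[["LCER"]], 7)
    named <- c("CER18", "CER22:1", "CER26", "DCER22", "DCER22:2",
               "DCER24:1", "HCER22:1", "LCER14", "LCER16", "LCER18:1",
               "LCER24:1")
    expect_true(all(named %in% panel$species_id))
    expect_equal(panel$class_id[panel$species_id == "LCER14"], "LCER")
    expect_equal(panel$double_bonds[panel$species_id == "DCER22:2"], 2L)
    expect_equal(nrow(defaultSpeciesPanel(nSM = 0)), 26)
})

test_that("cohort generation is reproducible and prevalence-calibrated", {
    cfg <- cohortConfig(nSubjects = 300, seed = 11)
    se1 <- generateCohort(cfg)
    se2 <- generateCohort(cfg)
    expect_identical(SummarizedExperiment::assay(se1, "raw"),
                     SummarizedExperiment::assay(se2, "raw"))
    expect_identical(as.data.frame(SummarizedExperiment::colData(se1)),
                     as.data.frame(SummarizedExperiment::colData(se2)))

    # classifier-reproduced prevalence within the 99% binomial interval
    big <- generateCohort(cohortConfig(nSubjects = 10000,
                                       metsPrevalence = 0.37,
                                       missingRate = 0, seed = 21))
    status <- classifyMetS(as.data.frame(SummarizedExperiment::colData(big)))
    half <- 2.576 * sqrt(0.37 * 0.63 / 10000)
    expect_lt(abs(mean(status$diagnosis) - 0.37), half)
})

test_that("planted interclass Spearman targets are recovered", {
    # coherent planted structure: uniform background 0.3, CER-LCER at 0.6
    pairs <- combn(sort(unique(defaultSpeciesPanel()$class_id)), 2,
                   function(p) paste(p[1], p[2], sep = "-"))
    iv <- setNames(rep(0.3, length(pairs)), pairs)
    iv["CER-LCER"] <- 0.6
    inter <- lapply(defaultInterclassRho(), function(x) iv)
    se <- generateCohort(cohortConfig(nSubjects = 5000, interclassRho = inter,
                                      classMeanShift = c(DCER = 0, CER = 0,
                                                         SM = 0, HCER = 0,
                                                         LCER = 0),
                                      missingRate = 0, seed = 31))
    raw <- SummarizedExperiment::assay(se, "raw")
    rho <- cor(raw["CER18", ], raw["LCER16", ], method = "spearman")
    expect_lt(abs(rho - 0.6), 0.05)
})

test_that("rank correlations survive exponentiation of the latent scale", {
    m <- simulateLipidMatrix(400, interclassRho = 0.4, seed = 5)
    expect_true(all(m > 0))
    expect_equal(cor(m["CER16", ], m["LCER14", ], method = "spearman"),
                 cor(log(m["CER16", ]), log(m["LCER14", ]),
                     method = "spearman"))
})

test_that("non-PSD interclass targets are rejected naming the class pair", {
    inter <- defaultInterclassRho()
    # strong CER-HCER and CER-LCER with near-zero HCER-LCER is infeasible
    for (s in names(inter)) {
        inter[[s]]["CER-HCER"] <- 0.95
        inter[[s]]["CER-LCER"] <- 0.95
        inter[[s]]["HCER-LCER"] <- 0.0
    }
    expect_error(cohortConfig(nSubjects = 50, interclassRho = inter),
                 "positive semidefinite")
})

test_that("missingness injection is calibrated, seeded, and a no-op at 0", {
    m <- matrix(rexp(1000 * 26), 26, 1000,
                dimnames = list(defaultSpeciesPanel(nSM = 0)$species_id,
                                NULL))
    out <- injectMissingness(m, 0.25, seed = 7)
    expect_lt(abs(mean(is.na(out)) - 0.25), 0.02)
    expect_identical(out, injectMissingness(m, 0.25, seed = 7))
    expect_identical(m, injectMissingness(m, 0, seed = 7))
    expect_error(injectMissingness(m, 1, seed = 7), "rate")
})

test_that("null configuration produces no systematic group differences", {
    cfg <- cohortConfig(nSubjects = 400,
                        classMeanShift = c(DCER = 0, CER = 0, SM = 0,
                                           HCER = 0, LCER = 0),
                        interclassRho = {
                            i <- defaultInterclassRho()
                            lapply(i, function(x) i[[1]])
                        },
                        missingRate = 0, seed = 41)
    ps <- sapply(1:20, function(r) {
        cfg$seed <- 41L + r
        se <- generateCohort(cfg)
        mets <- SummarizedExperiment::colData(se)$mets
        raw <- SummarizedExperiment::assay(se, "raw")
        wilcoxonRankSum(raw["CER18", mets], raw["CER18", !mets])$p
    })
    # p-values roughly uniform: no pile-up near 0
    expect_gt(mean(ps > 0.05), 0.7)
    expect_gt(min(ps), 1e-4)
})

test_that("cohort round-trips through the plain-text writers", {
    se <- generateCohort(cohortConfig(nSubjects = 60, seed = 51))
    dir <- withr::local_tempdir()
    paths <- writeCohort(se, dir)
    expect_true(all(file.exists(paths)))
    back <- readSphingolipidData(file.path(dir, "clinical.tsv"),
                                 file.path(dir, "lipids.tsv"),
                                 file.path(dir, "species_classes.tsv"))
    expect_s4_class(back, "SphingolipidExperiment")
    expect_equal(dim(back), dim(se))
    expect_equal(SummarizedExperiment::assay(back, "raw")["CER18", 3],
                 SummarizedExperiment::assay(se, "raw")["CER18", 3],
                 tolerance = 1e-6)
})
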