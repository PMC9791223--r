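#' Pipeline configuration
#'
#' Single configuration object for the end-to-end analysis. Inputs are either
#' a \code{\link{cohortConfig}} (synthetic mode) or the three file paths of
#' \code{\link{readSphingolipidData}} (real-data mode).
#'
#' @param cohort a \code{\link{cohortConfig}} for synthetic mode, or NULL
#' @param clinicalFile,lipidFile,classFile input paths for real-data mode
#' @param alpha significance level for edges and masking (default 0.05)
#' @param fcThreshold volcano fold-change threshold (default 1.15)
#' @param nPerm permutations for the interclass tests (default 1000)
#' @param stratification \code{"mets.crp"} (MetS x CRP median) or
#'   \code{"mets.glucoregulation"} (MetS x impaired glucoregulation, glucose
#'   > 100 mg/dL and insulin >= 25 mIU/L)
#' @param covariates adjustment covariates for the association models
#' @param minStratumSize strata smaller than this are skipped with a warning
#' @param outputDir optional directory for the artifact bundle
#' @param seed integer seed
#' @return validated list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(cohort = NULL, clinicalFile = NULL,
                           lipidFile = NULL, classFile = NULL,
                           alpha = 0.05, fcThreshold = 1.15, nPerm = 1000,
                           stratification = c("mets.crp",
                                              "mets.glucoregulation"),
                           covariates = c("sex", "age", "race", "education"),
                           minStratumSize = 20, outputDir = NULL,
                           seed = 1L) {
    stratification <- match.arg(stratification)
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (fcThreshold <= 1) stop("fcThreshold must exceed 1")
    if (nPerm < 1) stop("nPerm must be a positive integer")
    if (is.null(cohort) && (is.null(clinicalFile) || is.null(lipidFile) ||
                            is.null(classFile)))
        stop("either a cohortConfig or the three input files are required")
    structure(list(cohort = cohort, clinicalFile = clinicalFile,
                   lipidFile = lipidFile, classFile = classFile,
                   alpha = alpha, fcThreshold = fcThreshold,
                   nPerm = as.integer(nPerm),
                   stratification = stratification,
                   covariates = covariates,
                   minStratumSize = minStratumSize,
                   outputDir = outputDir, seed = as.integer(seed)),
              class = "pipelineConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "': ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (MetS classification, CRP stratification, species
#' filtering, log/z-scoring, ratio biomarkers), volcano screening,
#' covariate-adjusted association matrices, per-stratum correlation-distance
#' networks with fast-greedy clustering and interclass distances, pairwise
#' interclass-distance permutation tests between strata, and pairwise
#' Steiger whole-network comparisons. When \code{outputDir} is set, writes
#' TSV/GraphML/JSON artifacts and a JSON run manifest.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return (invisibly) a list with the per-stage results
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    se <- .stage("input", {
        if (!is.null(config$cohort)) generateCohort(config$cohort)
        else readSphingolipidData(config$clinicalFile, config$lipidFile,
                                  config$classFile)
    })
    clinical <- as.data.frame(colData(se))

    status <- .stage("mets_classification", classifyMetS(clinical))
    clinical$mets <- status$diagnosis
    strata <- .stage("stratification", {
        if (config$stratification == "mets.crp") {
            s2 <- crpStratify(clinical$crp_ug_ml)
            ifelse(is.na(s2), NA_character_,
                   paste0(ifelse(clinical$mets, "metsPos", "metsNeg"),
                          ".crp", ifelse(s2 == "high", "High", "Low")))
        } else {
            ig <- status$impaired_glucoregulation
            if (is.null(ig)) stop("insulin values required for the ",
                                  "glucoregulation stratification")
            paste0(ifelse(clinical$mets, "metsPos", "metsNeg"),
                   ifelse(ig, ".igPos", ".igNeg"))
        }
    })

    filtered <- .stage("species_filter", filterSpecies(se))
    normalized <- .stage("log_zscore", logZscore(filtered))
    ratios <- .stage("ratios", computeRatios(filtered))

    volcano <- .stage("volcano",
        volcanoTable(filtered, clinical$mets,
                     fcThreshold = config$fcThreshold,
                     alpha = config$alpha))
    selected <- volcano$species_id[volcano$flagged %in% TRUE]
    if (length(selected) < 3) {
        warning("fewer than 3 species passed the volcano screen; ",
                "using all filtered species for the network stage")
        selected <- rownames(filtered)
    }

    associations <- .stage("association_models", {
        z <- t(assay(normalized, "zscore"))
        totals <- classTotals(filtered)
        logTotals <- log(totals)
        zTotals <- scale(logTotals)
        exposures <- cbind(as.data.frame(zTotals),
                           ratio_cer_lcer = as.numeric(
                               scale(log(ratios$ratio_cer_lcer))),
                           ratio_integrative = as.numeric(
                               scale(log(ratios$ratio_integrative))))
        biomarkers <- intersect(c("bmi", "waist_cm", "systolic",
                                  "triglycerides_mg_dl", "hdl_mg_dl",
                                  "ldl_mg_dl", "glucose_mg_dl",
                                  "insulin_uiu_ml", "homa_ir", "hba1c",
                                  "oxhdl", "crp_ug_ml", "il6_pg_ml",
                                  "fibrinogen_mg_dl", "sicam_ng_ml"),
                                colnames(clinical))
        outLinear <- as.data.frame(
            scale(log(as.matrix(clinical[biomarkers]))))
        covs <- clinical[intersect(config$covariates, colnames(clinical))]
        linear <- associationMatrix(exposures, outLinear, covs,
                                    model = "linear", alpha = config$alpha)
        logistic <- associationMatrix(
            exposures,
            data.frame(mets = clinical$mets,
                       status[c("abdominal_obesity", "high_triglycerides",
                                "low_hdl", "elevated_bp", "high_glucose")]),
            covs, model = "logistic", alpha = config$alpha)
        list(linear = linear, logistic = logistic)
    })

    strataLevels <- sort(unique(strata[!is.na(strata)]))
    networks <- list(); partitions <- list(); corrs <- list()
    for (s in strataLevels) {
        idx <- which(strata == s)
        if (length(idx) < config$minStratumSize) {
            warning("stratum ", s, " has ", length(idx),
                    " subjects (< ", config$minStratumSize, "); skipped")
            next
        }
        corrs[[s]] <- .stage(paste0("network_", s),
            spearmanMatrix(filtered[selected, ], subjects = idx))
        networks[[s]] <- buildDistanceNetwork(corrs[[s]], config$alpha)
        partitions[[s]] <- .stage(paste0("clustering_", s),
            fastGreedyPartition(networks[[s]]))
    }

    classMap <- lipidClasses(filtered)
    coreHere <- intersect(.coreClasses, unique(classMap[selected]))
    classPairs <- if (length(coreHere) >= 2)
        utils::combn(coreHere, 2, simplify = FALSE) else list()

    interclass <- lapply(networks, function(net)
        vapply(classPairs, function(pr)
            interclassDistance(net, classMap, pr[1], pr[2]), numeric(1)))
    interclass <- lapply(interclass, function(v) {
        names(v) <- vapply(classPairs, paste, "", collapse = "-"); v })

    stratumPairs <- if (length(networks) >= 2)
        utils::combn(names(networks), 2, simplify = FALSE) else list()
    permTests <- .stage("interclass_permutation", {
        out <- list()
        for (sp in stratumPairs) {
            for (pr in classPairs) {
                key <- paste(sp[1], "vs", sp[2], paste(pr, collapse = "-"))
                out[[key]] <- permutationInterclassTest(
                    filtered[selected, ],
                    which(strata == sp[1]), which(strata == sp[2]),
                    pr[1], pr[2], nPerm = config$nPerm,
                    seed = config$seed + length(out),
                    alpha = config$alpha)
            }
        }
        out
    })
    steiger <- .stage("steiger", {
        out <- list()
        for (sp in stratumPairs)
            out[[paste(sp[1], "vs", sp[2])]] <-
                steigerCompare(corrs[[sp[1]]], corrs[[sp[2]]])
        out
    })

    result <- list(experiment = normalized, status = status,
                   strata = strata, volcano = volcano,
                   selectedSpecies = selected, ratios = ratios,
                   associations = associations, correlations = corrs,
                   networks = networks, partitions = partitions,
                   interclassDistances = interclass,
                   permutationTests = permTests, steiger = steiger,
                   config = config)
    if (!is.null(config$outputDir))
        .stage("write_artifacts", .writeArtifacts(result, config$outputDir))
    invisible(result)
}

.writeArtifacts <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) utils::write.table(
        df, file.path(dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE, na = "")
    status <- cbind(subject_id = rownames(result$status), result$status,
                    stratum = result$strata)
    wt(status, "mets_status.tsv")
    wt(cbind(subject_id = rownames(result$ratios), result$ratios),
       "ratios.tsv")
    volcano <- result$volcano
    volcano$fc_stat <- attr(result$volcano, "fcStat")
    wt(volcano, "volcano.tsv")
    wt(result$associations$linear$cells, "association_linear.tsv")
    wt(result$associations$logistic$cells, "association_logistic.tsv")
    for (s in names(result$networks)) {
        wt(edgeList(result$networks[[s]]),
           paste0("network_", s, "_edges.tsv"))
        writeGraphML(result$networks[[s]],
                     file.path(dir, paste0("network_", s, ".graphml")))
        part <- result$partitions[[s]]
        wt(data.frame(species_id = names(clusterMembership(part)),
                      cluster = clusterMembership(part)),
           paste0("partition_", s, ".tsv"))
    }
    perm <- lapply(result$permutationTests, function(t)
        list(class_a = t@classA, class_b = t@classB,
             distance_a = t@distanceA, distance_b = t@distanceB,
             delta = t@delta, p = t@p, n_perm = t@nPerm, seed = t@seed))
    jsonlite::write_json(perm, file.path(dir, "interclass_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    st <- lapply(result$steiger, function(t)
        list(chisq = t@chisq, df = t@df, p = t@p, n1 = t@n1, n2 = t@n2))
    jsonlite::write_json(st, file.path(dir, "steiger_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- result$config
    manifest <- list(
        package = "sphingonet",
        version = as.character(utils::packageVersion("sphingonet")),
        r_version = R.version.string,
        seed = cfg$seed,
        parameters = list(alpha = cfg$alpha, fc_threshold = cfg$fcThreshold,
                          n_perm = cfg$nPerm,
                          stratification = cfg$stratification,
                          min_stratum_size = cfg$minStratumSize),
        synthetic = !is.null(cfg$cohort),
        inputs = if (is.null(cfg$cohort)) {
            files <- c(cfg$clinicalFile, cfg$lipidFile, cfg$classFile)
            as.list(tools::md5sum(files))
        } else list(cohort_seed = cfg$cohort$seed,
                    n_subjects = cfg$cohort$nSubjects))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
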