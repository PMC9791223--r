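#' ATPIII metabolic syndrome criteria
#'
#' Threshold set for the updated ATPIII definition: central adiposity (waist
#' > 102 cm men / > 88 cm women), elevated triglycerides (>= 150 mg/dL) or
#' lipid-lowering treatment, reduced HDL-c (< 40 mg/dL men / < 50 mg/dL
#' women) or treatment to raise HDL-c, elevated blood pressure (systolic
#' >= 130 or diastolic >= 85 mmHg) or antihypertensive treatment with a
#' hypertension history, and high fasting glucose (>= 100 mg/dL) or
#' glucose-lowering treatment. Diagnosis requires at least
#' \code{requiredCount} abnormal components out of five.
#'
#' @param waistMale,waistFemale waist cut-offs, cm (strict >)
#' @param triglycerides triglyceride cut-off, mg/dL (>=)
#' @param hdlMale,hdlFemale HDL-c cut-offs, mg/dL (strict <)
#' @param systolic,diastolic blood-pressure cut-offs, mmHg (>=)
#' @param glucose fasting glucose cut-off, mg/dL (>=)
#' @param requiredCount abnormal components required for diagnosis
#' @param file optional YAML file whose named entries override the above
#' @return list of class \code{metsCriteria}
#' @export
metsCriteria <- function(waistMale = 102, waistFemale = 88,
                         triglycerides = 150, hdlMale = 40, hdlFemale = 50,
                         systolic = 130, diastolic = 85, glucose = 100,
                         requiredCount = 3, file = NULL) {
    crit <- list(waistMale = waistMale, waistFemale = waistFemale,
                 triglycerides = triglycerides, hdlMale = hdlMale,
                 hdlFemale = hdlFemale, systolic = systolic,
                 diastolic = diastolic, glucose = glucose,
                 requiredCount = requiredCount)
    if (!is.null(file)) {
        ov <- yaml::read_yaml(file)
        unknown <- setdiff(names(ov), names(crit))
        if (length(unknown))
            stop("unknown criteria in ", file, ": ",
                 paste(unknown, collapse = ", "))
        crit[names(ov)] <- ov
    }
    structure(crit, class = "metsCriteria")
}

.requireFields <- function(clinical, fields) {
    absent <- setdiff(fields, colnames(clinical))
    if (length(absent))
        stop("missing required clinical field(s): ",
             paste(absent, collapse = ", "))
}

.componentFlag <- function(value, exceed, medication, field, ids) {
    flag <- exceed
    flag[medication] <- TRUE
    bad <- which(is.na(flag))
    if (length(bad))
        stop("missing value for field '", field, "' (subject ",
             ids[bad[1]], ") and no medication flag")
    flag
}

#' Classify metabolic syndrome by ATPIII criteria
#'
#' Evaluates the five ATPIII components per subject; a medication flag forces
#' the corresponding component abnormal regardless of the measured value.
#' Diagnosis is at least \code{requiredCount} (default 3) abnormal
#' components. When insulin is available, an impaired-glucoregulation flag
#' (glucose > 100 mg/dL and insulin >= 25 mIU/L) is added.
#'
#' @param clinical data.frame with columns \code{sex} ("male"/"female"),
#'   \code{waist_cm}, \code{triglycerides_mg_dl}, \code{hdl_mg_dl},
#'   \code{systolic}, \code{diastolic}, \code{glucose_mg_dl}; optional
#'   logical medication columns \code{tg_medication}, \code{hdl_medication},
#'   \code{htn_medication_with_history}, \code{glycemia_medication}
#'   (absent = no treatment) and \code{insulin_uiu_ml}
#' @param criteria a \code{\link{metsCriteria}} threshold set
#' @return data.frame with the five component flags, the abnormal-component
#'   count, \code{diagnosis}, and \code{impaired_glucoregulation} when
#'   insulin is present
#' @examples
#' subj <- data.frame(sex = "male", waist_cm = 105,
#'                    triglycerides_mg_dl = 160, hdl_mg_dl = 45,
#'                    systolic = 120, diastolic = 80, glucose_mg_dl = 105)
#' classifyMetS(subj)$diagnosis
#' @export
classifyMetS <- function(clinical, criteria = metsCriteria()) {
    clinical <- as.data.frame(clinical)
    .requireFields(clinical, c("sex", "waist_cm", "triglycerides_mg_dl",
                               "hdl_mg_dl", "systolic", "diastolic",
                               "glucose_mg_dl"))
    if (any(is.na(clinical$sex)))
        stop("missing value for field 'sex' (subject ",
             rownames(clinical)[which(is.na(clinical$sex))[1]], ")")
    if (!all(clinical$sex %in% c("male", "female")))
        stop("sex must be 'male' or 'female'")
    med <- function(col)
        if (col %in% colnames(clinical)) clinical[[col]] %in% TRUE
        else rep(FALSE, nrow(clinical))
    ids <- if (!is.null(rownames(clinical))) rownames(clinical)
           else as.character(seq_len(nrow(clinical)))
    male <- clinical$sex == "male"

    waistCut <- ifelse(male, criteria$waistMale, criteria$waistFemale)
    hdlCut <- ifelse(male, criteria$hdlMale, criteria$hdlFemale)
    obesity <- .componentFlag(clinical$waist_cm,
                              clinical$waist_cm > waistCut,
                              FALSE, "waist_cm", ids)
    highTG <- .componentFlag(clinical$triglycerides_mg_dl,
                             clinical$triglycerides_mg_dl >= criteria$triglycerides,
                             med("tg_medication"), "triglycerides_mg_dl", ids)
    lowHDL <- .componentFlag(clinical$hdl_mg_dl,
                             clinical$hdl_mg_dl < hdlCut,
                             med("hdl_medication"), "hdl_mg_dl", ids)
    highBP <- .componentFlag(clinical$systolic,
                             clinical$systolic >= criteria$systolic |
                                 clinical$diastolic >= criteria$diastolic,
                             med("htn_medication_with_history"),
                             "systolic/diastolic", ids)
    highGlu <- .componentFlag(clinical$glucose_mg_dl,
                              clinical$glucose_mg_dl >= criteria$glucose,
                              med("glycemia_medication"), "glucose_mg_dl", ids)

    count <- obesity + highTG + lowHDL + highBP + highGlu
    out <- data.frame(abdominal_obesity = obesity,
                      high_triglycerides = highTG, low_hdl = lowHDL,
                      elevated_bp = highBP, high_glucose = highGlu,
                      n_components = count,
                      diagnosis = count >= criteria$requiredCount,
                      row.names = ids)
    if ("insulin_uiu_ml" %in% colnames(clinical))
        out$impaired_glucoregulation <-
            clinical$glucose_mg_dl > 100 & clinical$insulin_uiu_ml >= 25
    out
}

#' Stratify subjects by the CRP median
#'
#' \code{"high"} for values strictly above the overall sample median of the
#' non-missing values, \code{"low"} otherwise (ties at the median go to
#' "low"); missing CRP gives \code{NA} and the subject is excluded from
#' stratified analyses.
#'
#' @param crp numeric vector of CRP values
#' @return character vector in \{"low", "high", NA\}
#' @examples
#' crpStratify(c(1, 2, 3, 4, 5))
#' @export
crpStratify <- function(crp) {
    if (all(is.na(crp))) stop("at least one non-missing CRP value required")
    m <- median(crp, na.rm = TRUE)
    ifelse(is.na(crp), NA_character_, ifelse(crp > m, "high", "low"))
}

#' Filter species by missingness
#'
#' Retains species whose fraction of missing values is strictly below
#' \code{maxMissing} (default 20\%); a species with exactly the threshold
#' fraction missing is dropped. The dropped-species report is stored in
#' \code{metadata()$droppedSpecies}.
#'
#' @param se a \linkS4class{SphingolipidExperiment}
#' @param maxMissing missingness threshold (strict <)
#' @return the filtered experiment
#' @export
filterSpecies <- function(se, maxMissing = 0.20) {
    raw <- assay(se, "raw")
    frac <- rowMeans(is.na(raw))
    keep <- frac < maxMissing
    if (!any(keep)) stop("all species exceed the missingness threshold")
    dropped <- data.frame(species_id = rownames(se)[!keep],
                          missing_fraction = frac[!keep])
    out <- se[keep, ]
    metadata(out)$droppedSpecies <- dropped
    out
}

#' Log-transform and z-score the abundance matrix
#'
#' Per species: x -> (log x - mean) / SD over the non-missing entries
#' (natural log); missing stays missing. Adds assays \code{"log"} and
#' \code{"zscore"}.
#'
#' @param se a \linkS4class{SphingolipidExperiment}
#' @return the experiment with the derived views attached
#' @export
logZscore <- function(se) {
    raw <- assay(se, "raw")
    if (any(raw <= 0, na.rm = TRUE))
        stop("log transform requires strictly positive abundances")
    lg <- log(raw)
    mu <- rowMeans(lg, na.rm = TRUE)
    sd <- apply(lg, 1, stats::sd, na.rm = TRUE)
    degenerate <- which(!is.na(sd) & sd == 0)
    if (length(degenerate))
        stop("constant species cannot be z-scored: ",
             paste(rownames(se)[degenerate], collapse = ", "))
    assay(se, "log") <- lg
    assay(se, "zscore") <- (lg - mu) / sd
    se
}

#' Ceramide / glycosphingolipid ratio biomarkers
#'
#' Two per-subject ratios on raw (untransformed) class totals: total CER over
#' total LCER, and the integrative ratio of precursor ceramides over
#' glycosylated ceramides, (DCER + CER) / (HCER + LCER). Class totals sum the
#' non-missing species of each class; a subject with no non-missing species
#' in a denominator class (or a zero total) gets \code{NA}.
#'
#' @param se a \linkS4class{SphingolipidExperiment}
#' @return data.frame with \code{ratio_cer_lcer} and
#'   \code{ratio_integrative}, one row per subject
#' @export
computeRatios <- function(se) {
    raw <- assay(se, "raw")
    cls <- lipidClasses(se)
    total <- function(classes) {
        idx <- cls %in% classes
        if (!any(idx)) stop("no species of class ",
                            paste(classes, collapse = "+"), " in the panel")
        tot <- colSums(raw[idx, , drop = FALSE], na.rm = TRUE)
        tot[colSums(!is.na(raw[idx, , drop = FALSE])) == 0] <- NA_real_
        tot
    }
    cer <- total("CER"); lcer <- total("LCER")
    num <- total(c("DCER", "CER")); den <- total(c("HCER", "LCER"))
    safeDiv <- function(a, b) ifelse(!is.na(b) & b > 0, a / b, NA_real_)
    data.frame(ratio_cer_lcer = safeDiv(cer, lcer),
               ratio_integrative = safeDiv(num, den),
               row.names = colnames(se))
}

#' Per-subject class totals
#'
#' Sums the non-missing raw abundances of each lipid class per subject.
#'
#' @param se a \linkS4class{SphingolipidExperiment}
#' @return subjects x classes numeric matrix (NA where a subject has no
#'   non-missing species of a class)
#' @export
classTotals <- function(se) {
    raw <- assay(se, "raw")
    cls <- lipidClasses(se)
    out <- sapply(unique(cls), function(cl) {
        idx <- cls == cl
        tot <- colSums(raw[idx, , drop = FALSE], na.rm = TRUE)
        tot[colSums(!is.na(raw[idx, , drop = FALSE])) == 0] <- NA_real_
        tot
    })
    rownames(out) <- colnames(se)
    out
}
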