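#' @importFrom stats lm glm binomial coef model.matrix complete.cases
NULL

.defaultReferences <- c(sex = "female", race = "White",
                        education = "hs_or_less")

## assemble the model frame with reference levels fixed; complete cases only
.designFrame <- function(outcome, exposure, covariates) {
    df <- data.frame(.outcome = outcome, .exposure = exposure)
    if (!is.null(covariates) && length(covariates)) {
        covariates <- as.data.frame(covariates)
        for (v in colnames(covariates)) {
            col <- covariates[[v]]
            if (is.character(col) || is.factor(col)) {
                col <- as.character(col)
                ref <- .defaultReferences[[v]]
                lev <- unique(col[!is.na(col)])
                if (!is.null(ref) && ref %in% lev)
                    col <- factor(col, levels = c(ref, setdiff(sort(lev), ref)))
                else col <- factor(col)
            }
            df[[v]] <- col
        }
    }
    df[complete.cases(df), , drop = FALSE]
}

.checkRank <- function(formula, df) {
    X <- model.matrix(formula, df)
    q <- qr(X)
    if (q$rank < ncol(X)) {
        drop <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(drop, collapse = ", "))
    }
    invisible(ncol(X))
}

.cell <- function(exposureId, outcomeId, beta, se, p, covariates, n,
                  logistic) {
    data.frame(exposure_id = exposureId, outcome_id = outcomeId,
               beta = beta, se = se, p_value = p,
               or_point = if (logistic) exp(beta) else NA_real_,
               ci_low = if (logistic) exp(beta - 1.96 * se) else
                   beta - 1.96 * se,
               ci_high = if (logistic) exp(beta + 1.96 * se) else
                   beta + 1.96 * se,
               n = n,
               adjusted_for = paste(covariates, collapse = ","),
               stringsAsFactors = FALSE)
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares fit of a (typically z-scored) outcome on a
#' (typically z-scored) lipid exposure, adjusting for covariates; returns the
#' exposure coefficient with its Wald two-sided p-value. Categorical
#' covariates are dummy-coded against fixed reference levels (sex "female",
#' race "White", education "hs_or_less"). Complete cases only.
#'
#' @param outcome numeric outcome vector
#' @param exposure numeric exposure vector
#' @param covariates optional data.frame of adjustment covariates (e.g. sex,
#'   age, race, education, and optionally MetS diagnosis)
#' @param exposureId,outcomeId labels carried into the result row
#' @return one-row data.frame (an association cell): \code{beta}, \code{se},
#'   \code{p_value}, 95\% CI, \code{n}, \code{adjusted_for}
#' @export
fitLinear <- function(outcome, exposure, covariates = NULL,
                      exposureId = "exposure", outcomeId = "outcome") {
    df <- .designFrame(outcome, exposure, covariates)
    if (nrow(df) <= ncol(df) + 1)
        stop("too few complete cases for the number of parameters")
    f <- .outcome ~ .
    .checkRank(~ ., df[setdiff(colnames(df), ".outcome")])
    fit <- lm(f, data = df)
    s <- summary(fit)$coefficients
    .cell(exposureId, outcomeId, s[".exposure", 1], s[".exposure", 2],
          s[".exposure", 4],
          setdiff(colnames(df), c(".outcome", ".exposure")), nrow(df),
          logistic = FALSE)
}

#' Covariate-adjusted logistic association
#'
#' Binary logistic regression of an outcome (e.g. MetS diagnosis or one of
#' its components) on a lipid exposure, adjusted for covariates. Exposures
#' are conventionally z-scored so \code{exp(beta)} is the odds ratio per 1-SD
#' increase; Wald 95\% CI.
#'
#' @inheritParams fitLinear
#' @param outcome binary (logical or 0/1) outcome vector with both levels
#'   present
#' @return one-row data.frame with \code{beta} (log-odds), \code{se},
#'   \code{p_value}, \code{or_point}, 95\% CI, \code{n}
#' @export
fitLogistic <- function(outcome, exposure, covariates = NULL,
                        exposureId = "exposure", outcomeId = "outcome") {
    outcome <- as.integer(outcome)
    if (!all(outcome %in% c(0L, 1L), na.rm = TRUE))
        stop("outcome must be binary")
    df <- .designFrame(outcome, exposure, covariates)
    if (length(unique(df$.outcome)) < 2)
        stop("both outcome levels must be present")
    .checkRank(~ ., df[setdiff(colnames(df), ".outcome")])
    fit <- withCallingHandlers(
        glm(.outcome ~ ., data = df, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                stop("logistic fit did not converge (perfect separation)")
            invokeRestart("muffleWarning")
        })
    if (!fit$converged)
        stop("logistic fit did not converge")
    s <- summary(fit)$coefficients
    if (abs(s[".exposure", 1]) > 15 || s[".exposure", 2] > 100)
        stop("logistic fit did not converge (perfect separation ",
             "or quasi-separation on the exposure)")
    .cell(exposureId, outcomeId, s[".exposure", 1], s[".exposure", 2],
          s[".exposure", 4],
          setdiff(colnames(df), c(".outcome", ".exposure")), nrow(df),
          logistic = TRUE)
}

#' Significance-masked association matrix
#'
#' Fits one adjusted model per exposure x outcome pair and assembles the
#' long-format table plus a coefficient matrix in which cells with
#' p >= alpha are masked to 0, the display convention for regression
#' coefficient matrices.
#'
#' @param exposures data.frame or matrix of exposure variables (columns)
#' @param outcomes data.frame or matrix of outcome variables (columns);
#'   binary columns for \code{model = "logistic"}
#' @param covariates optional adjustment covariate data.frame
#' @param model \code{"linear"} or \code{"logistic"}
#' @param alpha masking significance level (default 0.05)
#' @return list with \code{cells} (long-format data.frame) and \code{matrix}
#'   (exposures x outcomes masked coefficient matrix)
#' @export
associationMatrix <- function(exposures, outcomes, covariates = NULL,
                              model = c("linear", "logistic"),
                              alpha = 0.05) {
    model <- match.arg(model)
    exposures <- as.data.frame(exposures)
    outcomes <- as.data.frame(outcomes)
    if (nrow(exposures) != nrow(outcomes))
        stop("exposures and outcomes must share the subject index")
    fitFun <- if (model == "linear") fitLinear else fitLogistic
    cells <- list()
    for (ex in colnames(exposures))
        for (oc in colnames(outcomes))
            cells[[paste(ex, oc, sep = ".")]] <-
                fitFun(outcomes[[oc]], exposures[[ex]], covariates,
                       exposureId = ex, outcomeId = oc)
    cells <- do.call(rbind, c(cells, make.row.names = FALSE))
    mat <- matrix(0, ncol(exposures), ncol(outcomes),
                  dimnames = list(colnames(exposures), colnames(outcomes)))
    sig <- cells$p_value < alpha
    mat[cbind(cells$exposure_id[sig], cells$outcome_id[sig])] <-
        cells$beta[sig]
    list(cells = cells, matrix = mat)
}
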