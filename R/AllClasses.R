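#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- rowData colData
NULL

#' SphingolipidExperiment: abundances plus clinical covariates
#'
#' Container for a sphingolipidomic study: a species x subjects abundance
#' matrix (assay \code{"raw"}, nonnegative, \code{NA} for values below the
#' detection limit), the species-to-class map in \code{rowData()} (columns
#' \code{class_id}, \code{chain_carbons}, \code{double_bonds}) and the
#' subject-level clinical table in \code{colData()}. Derived views produced by
#' \code{\link{logZscore}} are stored as additional assays (\code{"log"},
#' \code{"zscore"}).
#'
#' @export
setClass("SphingolipidExperiment", contains = "SummarizedExperiment")

.validSphingolipidExperiment <- function(object) {
    msg <- NULL
    if (!"raw" %in% assayNames(object))
        msg <- c(msg, "assay 'raw' is required")
    else {
        raw <- assay(object, "raw")
        if (any(raw < 0, na.rm = TRUE))
            msg <- c(msg, "raw abundances must be nonnegative")
    }
    rd <- rowData(object)
    if (!"class_id" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a 'class_id' column")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "species ids (rownames) must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("SphingolipidExperiment", .validSphingolipidExperiment)

#' Construct a SphingolipidExperiment
#'
#' @param abundances numeric matrix of nonnegative abundances, either
#'   species x subjects or subjects x species (orientation is resolved against
#'   \code{panel}; a square matrix is taken as species x subjects).
#' @param panel data.frame with columns \code{species_id}, \code{class_id} and
#'   optionally \code{chain_carbons}, \code{double_bonds}; see
#'   \code{\link{defaultSpeciesPanel}}.
#' @param clinical data.frame of subject-level covariates, one row per
#'   subject, aligned with the subject dimension of \code{abundances}.
#' @return A \linkS4class{SphingolipidExperiment}.
#' @examples
#' panel <- defaultSpeciesPanel()
#' m <- matrix(rexp(nrow(panel) * 5), nrow(panel), 5,
#'             dimnames = list(panel$species_id, paste0("S", 1:5)))
#' se <- SphingolipidExperiment(m, panel)
#' @export
SphingolipidExperiment <- function(abundances, panel, clinical = NULL) {
    abundances <- as.matrix(abundances)
    ids <- panel$species_id
    if (!is.null(colnames(abundances)) && all(ids %in% colnames(abundances)) &&
        !all(ids %in% rownames(abundances)))
        abundances <- t(abundances)
    if (is.null(rownames(abundances)))
        stop("abundance matrix must carry species ids as dimnames")
    missing <- setdiff(rownames(abundances), ids)
    if (length(missing))
        stop("species absent from the panel: ", paste(missing, collapse = ", "))
    rd <- DataFrame(panel[match(rownames(abundances), ids), , drop = FALSE])
    rownames(rd) <- rownames(abundances)
    rd$species_id <- NULL
    if (is.null(clinical))
        clinical <- DataFrame(row.names = colnames(abundances))
    new("SphingolipidExperiment",
        SummarizedExperiment(assays = list(raw = abundances),
                             rowData = rd,
                             colData = DataFrame(clinical)))
}

#' @describeIn SphingolipidExperiment species-to-class map as a named factor
#'   (names are species ids).
#' @param x,object a \code{SphingolipidExperiment}
#' @export
lipidClasses <- function(x) {
    cl <- as.character(rowData(x)$class_id)
    names(cl) <- rownames(x)
    cl
}

#' @export
setMethod("show", "SphingolipidExperiment", function(object) {
    callNextMethod()
    cl <- table(lipidClasses(object))
    cat("lipid classes:",
        paste(names(cl), as.integer(cl), sep = ":", collapse = " "), "\n")
})

#' Pairwise Spearman correlation result
#'
#' Symmetric species x species Spearman correlation matrix with raw and
#' BH-adjusted p-values (adjustment family = strictly upper triangle) and the
#' pairwise-complete sample sizes.
#'
#' @slot rho symmetric correlation matrix, unit diagonal
#' @slot p raw two-sided p-value matrix (t approximation on n - 2 df)
#' @slot pAdjusted Benjamini-Hochberg adjusted p-value matrix
#' @slot nPairs integer matrix of pairwise-complete subject counts
#' @slot nSubjects number of subjects in the stratum
#' @export
setClass("CorrelationResult",
         representation(rho = "matrix", p = "matrix", pAdjusted = "matrix",
                        nPairs = "matrix", nSubjects = "integer"))

setValidity("CorrelationResult", function(object) {
    msg <- NULL
    r <- object@rho
    if (nrow(r) != ncol(r)) msg <- c(msg, "rho must be square")
    if (max(abs(r - t(r)), na.rm = TRUE) > 1e-8)
        msg <- c(msg, "rho must be symmetric")
    if (any(abs(diag(r) - 1) > 1e-8)) msg <- c(msg, "diag(rho) must be 1")
    off <- upper.tri(r)
    if (any(object@pAdjusted[off] + 1e-12 < object@p[off], na.rm = TRUE))
        msg <- c(msg, "adjusted p must be >= raw p")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "CorrelationResult", function(object) {
    k <- nrow(object@rho)
    cat("CorrelationResult:", k, "species,", object@nSubjects, "subjects\n")
    cat("  significant pairs (BH p < 0.05):",
        sum(object@pAdjusted[upper.tri(object@pAdjusted)] < 0.05,
            na.rm = TRUE), "/", k * (k - 1) / 2, "\n")
})

#' Correlation-distance network
#'
#' Distance d = 1 - |rho| for pairs significant after BH correction at
#' \code{alpha}; non-significant coefficients are zeroed, so d = 1 and the
#' pair carries no edge. Edge weights are |rho| for significant pairs.
#'
#' @slot distance species x species distance matrix in [0, 1], zero diagonal
#' @slot weight species x species edge-weight matrix (|rho|, 0 off-network)
#' @slot alpha significance level applied to the BH-adjusted p-values
#' @slot correlation the \linkS4class{CorrelationResult} the network was built
#'   from
#' @export
setClass("DistanceNetwork",
         representation(distance = "matrix", weight = "matrix",
                        alpha = "numeric", correlation = "CorrelationResult"))

setValidity("DistanceNetwork", function(object) {
    d <- object@distance
    msg <- NULL
    if (any(d < -1e-12 | d > 1 + 1e-12)) msg <- c(msg, "distances must lie in [0, 1]")
    if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal distances must be 0")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("show", "DistanceNetwork", function(object) {
    k <- nrow(object@distance)
    ne <- sum(object@weight[upper.tri(object@weight)] > 0)
    cat("DistanceNetwork:", k, "species,", ne, "edges (alpha =",
        object@alpha, ")\n")
})

#' @describeIn DistanceNetwork distance matrix accessor
#' @param x a \code{DistanceNetwork}
#' @export
distanceMatrix <- function(x) x@distance

#' @describeIn DistanceNetwork edge-weight (|rho|) matrix accessor
#' @export
edgeWeights <- function(x) x@weight

#' Partition of a network by greedy modularity optimization
#'
#' @slot membership named integer vector of cluster ids, one per species
#' @slot Q modularity of the partition on the weighted graph
#' @slot path data.frame of the merge path (step, merged clusters, Q after
#'   the merge)
#' @export
setClass("ModularityPartition",
         representation(membership = "integer", Q = "numeric",
                        path = "data.frame"))

#' @export
setMethod("show", "ModularityPartition", function(object) {
    cat("ModularityPartition:", length(unique(object@membership)),
        "clusters, Q =", round(object@Q, 4), "\n")
})

#' @describeIn ModularityPartition cluster membership accessor
#' @param x a \code{ModularityPartition}
#' @export
clusterMembership <- function(x) x@membership

#' Interclass-distance permutation test result
#'
#' @slot classA,classB the lipid classes compared
#' @slot distanceA,distanceB mean interclass distance in each stratum
#' @slot delta observed difference distanceA - distanceB
#' @slot nullDelta permutation null distribution of the difference
#' @slot p two-sided permutation p-value with add-one smoothing
#' @slot nPerm number of permutations
#' @slot seed seed used for the permutation stream
#' @export
setClass("InterclassTest",
         representation(classA = "character", classB = "character",
                        distanceA = "numeric", distanceB = "numeric",
                        delta = "numeric", nullDelta = "numeric",
                        p = "numeric", nPerm = "integer", seed = "integer"))

#' @export
setMethod("show", "InterclassTest", function(object) {
    cat(sprintf("InterclassTest %s-%s: d_A = %.3f, d_B = %.3f, delta = %+.3f, p = %.4g (%d permutations)\n",
                object@classA, object@classB, object@distanceA,
                object@distanceB, object@delta, object@p, object@nPerm))
})

#' Steiger-type comparison of two correlation matrices
#'
#' @slot chisq chi-square statistic over Fisher-z differences
#' @slot df degrees of freedom, k(k-1)/2 for k species
#' @slot p upper-tail p-value
#' @slot n1,n2 subjects in each stratum
#' @export
setClass("SteigerComparison",
         representation(chisq = "numeric", df = "integer", p = "numeric",
                        n1 = "integer", n2 = "integer"))

#' @export
setMethod("show", "SteigerComparison", function(object) {
    cat(sprintf("SteigerComparison: chi-square = %.3f on %d df, p = %.4g (n1 = %d, n2 = %d)\n",
                object@chisq, object@df, object@p, object@n1, object@n2))
})
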