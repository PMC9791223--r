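## Fast path for the interclass distance of one subject subset: Spearman on
## midranks -> t-approximation p -> BH over the upper triangle -> distance
## 1 - |rho| for significant pairs -> mean over cross-class pairs. Must agree
## with the assembled spearmanMatrix/buildDistanceNetwork/interclassDistance
## route (asserted in the test suite).
.meanInterclassD <- function(vm, aCols, bCols, alpha = 0.05) {
    if (anyNA(vm)) {
        rho <- cor(vm, method = "spearman", use = "pairwise.complete.obs")
        np <- crossprod(!is.na(vm))
    } else {
        r <- apply(vm, 2, rank)
        rho <- cor(r)
        np <- matrix(nrow(vm), ncol(vm), ncol(vm))
    }
    p <- .spearmanP(rho, np)
    ut <- upper.tri(p)
    padj <- p
    padj[ut] <- p.adjust(p[ut], method = "BH")
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    w <- abs(rho) * (padj < alpha)
    d <- 1 - w
    mean(d[aCols, bCols])
}

#' Permutation test for an interclass-distance difference between strata
#'
#' Tests whether the mean interclass distance between two lipid classes
#' differs between two subject strata. The observed statistic is
#' delta = d_A - d_B, each mean distance computed through the full network
#' pipeline (Spearman -> BH thresholding -> distance) within its stratum.
#' The null distribution is built by randomly reassigning the pooled
#' subjects to two pseudo-strata of the original sizes and recomputing delta
#' each repetition; the two-sided p-value uses add-one smoothing,
#' p = (1 + #\{|delta_perm| >= |delta_obs|\}) / (1 + nPerm).
#'
#' @param x a \linkS4class{SphingolipidExperiment} or species x subjects
#'   matrix (raw abundances; the BH family is all species pairs in \code{x})
#' @param subjectsA,subjectsB subject indices or names of the two strata
#' @param classA,classB the lipid classes whose interclass distance is
#'   compared
#' @param classMap named species-to-class map; taken from \code{x} when it
#'   is a SphingolipidExperiment
#' @param nPerm number of permutations (default 1000)
#' @param seed integer seed for the permutation stream
#' @param alpha edge significance level (default 0.05)
#' @return An \linkS4class{InterclassTest}
#' @export
permutationInterclassTest <- function(x, subjectsA, subjectsB, classA,
                                      classB, classMap = NULL, nPerm = 1000,
                                      seed = 1L, alpha = 0.05) {
    if (nPerm < 1) stop("nPerm must be positive")
    if (is(x, "SphingolipidExperiment")) {
        classMap <- lipidClasses(x)
        m <- assay(x, "raw")
    } else m <- x
    if (is.null(classMap)) stop("classMap is required for matrix input")
    vmAll <- t(m)
    aCols <- which(colnames(vmAll) %in% names(classMap)[classMap == classA])
    bCols <- which(colnames(vmAll) %in% names(classMap)[classMap == classB])
    if (!length(aCols) || !length(bCols))
        stop("both classes must have species in the matrix")
    vA <- vmAll[subjectsA, , drop = FALSE]
    vB <- vmAll[subjectsB, , drop = FALSE]
    nA <- nrow(vA); nB <- nrow(vB)
    if (nA < 4 || nB < 4)
        stop("each stratum needs at least 4 subjects for correlation")
    dA <- .meanInterclassD(vA, aCols, bCols, alpha)
    dB <- .meanInterclassD(vB, aCols, bCols, alpha)
    delta <- dA - dB
    pooled <- rbind(vA, vB)
    nullDelta <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
        idx <- sample.int(nA + nB, nA)
        .meanInterclassD(pooled[idx, , drop = FALSE], aCols, bCols, alpha) -
            .meanInterclassD(pooled[-idx, , drop = FALSE], aCols, bCols,
                             alpha)
    }, numeric(1)))
    p <- (1 + sum(abs(nullDelta) >= abs(delta) - 1e-12)) / (1 + nPerm)
    new("InterclassTest", classA = classA, classB = classB,
        distanceA = dA, distanceB = dB, delta = delta,
        nullDelta = nullDelta, p = p, nPerm = as.integer(nPerm),
        seed = as.integer(seed))
}
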