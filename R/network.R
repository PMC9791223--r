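#' @importFrom stats cor pt p.adjust pchisq cor.test
NULL

## two-sided p for a Spearman coefficient via the t approximation on n-2 df
.spearmanP <- function(rho, n) {
    p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
    ok <- !is.na(rho) & n > 2
    r <- pmin(pmax(rho[ok], -1), 1)
    tt <- r * sqrt((n[ok] - 2) / pmax(1 - r^2, .Machine$double.eps))
    p[ok] <- 2 * pt(-abs(tt), n[ok] - 2)
    p[!is.na(rho) & abs(rho) >= 1 - 1e-12] <- 0
    diag(p) <- 0
    p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, adj_(i) = min over j >= i of p_(j) * m / j, capped at 1 and
#' mapped back to input order.
#'
#' @param p vector of raw p-values in [0, 1] (NAs passed through)
#' @return adjusted p-values in input order
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Spearman correlation matrix with BH-adjusted p-values
#'
#' Pairwise Spearman rank correlation (midrank ties) across species on
#' pairwise-complete observations, with two-sided p-values from the
#' t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom, BH-adjusted over the strictly-upper-triangle family. For
#' \code{exact = TRUE} and at most 10 complete observations per pair, the
#' p-value is computed by full enumeration of rank permutations instead.
#'
#' @param x a \linkS4class{SphingolipidExperiment} or species x subjects
#'   matrix
#' @param subjects optional subject subset (indices or names), e.g. one
#'   stratum
#' @param exact use the exact permutation distribution for pairs with n <= 10
#' @return A \linkS4class{CorrelationResult}
#' @export
spearmanMatrix <- function(x, subjects = NULL, exact = FALSE) {
    m <- if (is(x, "SphingolipidExperiment")) assay(x, "raw") else x
    if (!is.null(subjects)) m <- m[, subjects, drop = FALSE]
    if (ncol(m) < 4) stop("at least 4 subjects are required")
    v <- t(m)                       # subjects x species
    constant <- apply(v, 2, function(col) {
        col <- col[!is.na(col)]
        length(col) > 0 && length(unique(col)) == 1
    })
    if (any(constant))
        stop("constant species, correlation undefined: ",
             paste(colnames(v)[constant], collapse = ", "))
    rho <- cor(v, method = "spearman", use = "pairwise.complete.obs")
    np <- crossprod(!is.na(v))
    p <- .spearmanP(rho, np)
    if (exact) {
        small <- which(np <= 10 & upper.tri(np), arr.ind = TRUE)
        for (r in seq_len(nrow(small))) {
            i <- small[r, 1]; j <- small[r, 2]
            ok <- complete.cases(v[, c(i, j)])
            pe <- .spearmanExactP(v[ok, i], v[ok, j])
            p[i, j] <- p[j, i] <- pe
        }
    }
    padj <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
    ut <- upper.tri(p)
    padj[ut] <- bhAdjust(p[ut])
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    diag(padj) <- 0
    new("CorrelationResult", rho = rho, p = p, pAdjusted = padj,
        nPairs = np, nSubjects = ncol(m))
}

## exact two-sided permutation p for one Spearman coefficient (n <= 10)
.spearmanExactP <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(cor(rx, ry))
    perms <- .permutations(n)
    cnt <- 0L
    for (i in seq_len(nrow(perms)))
        if (abs(cor(rx, ry[perms[i, ]])) >= obs - 1e-12) cnt <- cnt + 1L
    cnt / nrow(perms)
}

.permutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- .permutations(n - 1)
    out <- matrix(0L, n * nrow(sub), n)
    for (pos in seq_len(n)) {
        rows <- (pos - 1) * nrow(sub) + seq_len(nrow(sub))
        out[rows, pos] <- n
        out[rows, -pos] <- sub
    }
    out
}

#' Build the correlation-distance network
#'
#' Distance d = 1 - |rho| for species pairs significant after BH correction
#' at \code{alpha}; the coefficient of a non-significant pair is set to 0, so
#' its distance is 1 and it carries no edge. Edge weights are |rho|.
#'
#' @param corr a \linkS4class{CorrelationResult}
#' @param alpha significance level on the BH-adjusted p-values (default 0.05)
#' @return A \linkS4class{DistanceNetwork}
#' @export
buildDistanceNetwork <- function(corr, alpha = 0.05) {
    stopifnot(is(corr, "CorrelationResult"))
    sig <- corr@pAdjusted < alpha
    sig[is.na(sig)] <- FALSE
    w <- abs(corr@rho) * sig
    diag(w) <- 0
    d <- 1 - w
    diag(d) <- 0
    new("DistanceNetwork", distance = d, weight = w, alpha = alpha,
        correlation = corr)
}

#' Mean interclass distance
#'
#' Arithmetic mean of the network distances over all cross-class species
#' pairs (one species from each class; within-class pairs excluded).
#'
#' @param network a \linkS4class{DistanceNetwork}
#' @param classMap named character vector mapping species id to class
#' @param classA,classB the two lipid classes
#' @return mean distance in [0, 1]
#' @export
interclassDistance <- function(network, classMap, classA, classB) {
    d <- distanceMatrix(network)
    a <- intersect(rownames(d), names(classMap)[classMap == classA])
    b <- intersect(rownames(d), names(classMap)[classMap == classB])
    if (!length(a) || !length(b))
        stop("both classes must have species in the network")
    mean(d[a, b])
}

#' Steiger-type comparison of two correlation matrices
#'
#' Chi-square test for equality of two independent correlation matrices over
#' the same species: each off-diagonal coefficient is Fisher-z transformed,
#' and chi-square = sum over pairs of (z1 - z2)^2 / (1/(n1-3) + 1/(n2-3)) on
#' k(k-1)/2 degrees of freedom.
#'
#' @param corr1,corr2 \linkS4class{CorrelationResult} objects from two
#'   independent strata over the same species set
#' @return A \linkS4class{SteigerComparison}
#' @export
steigerCompare <- function(corr1, corr2) {
    stopifnot(is(corr1, "CorrelationResult"), is(corr2, "CorrelationResult"))
    if (!identical(rownames(corr1@rho), rownames(corr2@rho)))
        stop("the two results must cover the same species set")
    ut <- upper.tri(corr1@rho)
    r1 <- corr1@rho[ut]; r2 <- corr2@rho[ut]
    if (any(abs(r1) >= 1) || any(abs(r2) >= 1))
        stop("off-diagonal |rho| = 1: Fisher z is infinite")
    n1 <- corr1@nSubjects; n2 <- corr2@nSubjects
    z1 <- atanh(r1); z2 <- atanh(r2)
    chisq <- sum((z1 - z2)^2) / (1 / (n1 - 3) + 1 / (n2 - 3))
    df <- length(r1)
    new("SteigerComparison", chisq = chisq, df = as.integer(df),
        p = pchisq(chisq, df, lower.tail = FALSE),
        n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Export a network as an edge-list table
#'
#' @param network a \linkS4class{DistanceNetwork}
#' @return data.frame (source, target, rho, p_adj, distance, weight), one
#'   row per significant pair
#' @export
edgeList <- function(network) {
    w <- edgeWeights(network)
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    corr <- network@correlation
    data.frame(source = rownames(w)[idx[, 1]],
               target = colnames(w)[idx[, 2]],
               rho = corr@rho[idx],
               p_adj = corr@pAdjusted[idx],
               distance = network@distance[idx],
               weight = w[idx],
               stringsAsFactors = FALSE)
}

#' Write a network as GraphML
#'
#' Minimal GraphML serialization of the significant-edge graph (node ids,
#' edge weight = |rho|, edge distance).
#'
#' @param network a \linkS4class{DistanceNetwork}
#' @param file output path
#' @return invisibly, \code{file}
#' @export
writeGraphML <- function(network, file) {
    el <- edgeList(network)
    nodes <- rownames(distanceMatrix(network))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(
        '<?xml version="1.0" encoding="UTF-8"?>',
        '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
        '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
        '<key id="d" for="edge" attr.name="distance" attr.type="double"/>',
        '<graph edgedefault="undirected">'), con)
    writeLines(sprintf('<node id="%s"/>', nodes), con)
    if (nrow(el))
        writeLines(sprintf(
            '<edge source="%s" target="%s"><data key="w">%.10g</data><data key="d">%.10g</data></edge>',
            el$source, el$target, el$weight, el$distance), con)
    writeLines(c('</graph>', '</graphml>'), con)
    invisible(file)
}
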