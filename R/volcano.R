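#' @importFrom stats pwilcox pnorm sd
NULL

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The p-value is exact (from
#' the null distribution of the U statistic) when the smaller sample has at
#' most 8 observations and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. U counts pairs (i, j) with x_i > y_j (ties counted 1/2).
#'
#' @param x,y numeric samples (non-empty, no missing values)
#' @param method \code{"auto"} (the switching rule above), \code{"exact"} or
#'   \code{"normal"}
#' @return list with \code{U}, \code{p} and the \code{method} used
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
wilcoxonRankSum <- function(x, y, method = c("auto", "exact", "normal")) {
    method <- match.arg(method)
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    ties <- any(duplicated(c(x, y)))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    if (method == "auto")
        method <- if (min(n, m) <= 8 && !ties) "exact" else "normal"
    if (method == "exact") {
        if (ties) stop("exact p-value is not defined in the presence of ties")
        p <- min(1, 2 * min(pwilcox(U, n, m), 1 - pwilcox(U - 1, n, m)))
    } else {
        mu <- n * m / 2
        tab <- table(r)
        tieTerm <- sum(tab^3 - tab)
        N <- n + m
        sigma2 <- (n * m / 12) * ((N + 1) - tieTerm / (N * (N - 1)))
        if (sigma2 <= 0) {
            p <- 1
        } else {
            z <- sign(U - mu) * max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
            p <- min(1, 2 * pnorm(-abs(z)))
        }
    }
    list(U = U, p = p, method = method)
}

#' Volcano screening of species between groups
#'
#' Per-species fold change and two-sided Wilcoxon rank-sum p-value between
#' two groups, computed on untransformed abundances. A species is flagged
#' when the fold change exceeds the threshold in either direction
#' (FC > threshold or FC < 1/threshold) and p < alpha.
#'
#' @param x a \linkS4class{SphingolipidExperiment} or species x subjects
#'   matrix (raw abundances)
#' @param group logical or two-level vector along subjects; \code{TRUE} (or
#'   the second level) is the case group whose abundance enters the fold
#'   change numerator
#' @param fcThreshold fold-change threshold (default 1.15)
#' @param alpha significance level (default 0.05)
#' @param fcStat central statistic for the fold change: group
#'   \code{"mean"} (default) or \code{"median"}
#' @return data.frame with \code{species_id}, \code{fold_change},
#'   \code{log2_fc}, \code{p_value}, \code{flagged}; the statistic used is
#'   recorded in \code{attr(, "fcStat")}
#' @export
volcanoTable <- function(x, group, fcThreshold = 1.15, alpha = 0.05,
                         fcStat = c("mean", "median")) {
    fcStat <- match.arg(fcStat)
    m <- if (is(x, "SphingolipidExperiment")) assay(x, "raw") else x
    if (is.logical(group)) grp <- group
    else {
        lv <- if (is.factor(group)) levels(group) else sort(unique(group))
        if (length(lv) != 2) stop("group must have exactly two levels")
        grp <- group == lv[2]
    }
    if (length(grp) != ncol(m))
        stop("group length must match the number of subjects")
    stat <- match.fun(fcStat)
    rows <- lapply(rownames(m), function(sp) {
        xs <- m[sp, grp]; ys <- m[sp, !grp]
        xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
        if (length(xs) < 2 || length(ys) < 2) {
            warning("species ", sp, " has fewer than 2 observations per ",
                    "group; skipped")
            return(data.frame(species_id = sp, fold_change = NA_real_,
                              log2_fc = NA_real_, p_value = NA_real_,
                              flagged = FALSE))
        }
        fc <- stat(xs) / stat(ys)
        p <- wilcoxonRankSum(xs, ys)$p
        data.frame(species_id = sp, fold_change = fc, log2_fc = log2(fc),
                   p_value = p,
                   flagged = (fc > fcThreshold | fc < 1 / fcThreshold) &
                       p < alpha)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- out$species_id
    attr(out, "fcStat") <- fcStat
    out
}
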