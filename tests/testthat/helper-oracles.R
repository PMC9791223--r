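# Independent oracles used against the package implementations. These stay
# deliberately naive: direct definitions, enumeration, brute force.

# Benjamini-Hochberg step-up by direct definition: sort ascending,
# adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1, back to input order.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all C(n+m, n)
# assignments of the pooled ranks to the first sample (no ties assumed).
enumWilcoxP <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combos <- utils::combn(n + m, n)
    Us <- colSums(matrix(seq_len(n + m)[combos], nrow = n)) -
        n * (n + 1) / 2
    lower <- mean(Us <= U)
    upper <- mean(Us >= U)
    min(1, 2 * min(lower, upper))
}

# All set partitions of n elements as membership vectors (restricted growth
# strings); cached per n.
.partitionCache <- new.env()
allPartitions <- function(n) {
    key <- as.character(n)
    if (!is.null(.partitionCache[[key]])) return(.partitionCache[[key]])
    out <- list()
    grow <- function(prefix, maxUsed) {
        if (length(prefix) == n) {
            out[[length(out) + 1]] <<- prefix
            return(invisible())
        }
        for (v in seq_len(maxUsed + 1))
            grow(c(prefix, v), max(maxUsed, v))
    }
    grow(integer(0), 0L)
    .partitionCache[[key]] <- out
    out
}

# construct a no-ties two-sample dataset with a prescribed U statistic:
# choose the positions of x among the pooled order so that
# U = sum(positions) - n(n+1)/2.
datasetWithU <- function(n, m, U) {
    stopifnot(U >= 0, U <= n * m)
    a <- integer(n)
    r <- U
    for (i in n:1) {
        a[i] <- min(m, r)
        r <- r - a[i]
    }
    pos <- seq_len(n) + a
    list(x = as.numeric(pos),
         y = as.numeric(setdiff(seq_len(n + m), pos)))
}

# Newman modularity by direct double sum (independent of the package).
oracleQ <- function(w, membership) {
    tw <- sum(w)
    k <- rowSums(w)
    q <- 0
    for (i in seq_len(nrow(w)))
        for (j in seq_len(ncol(w)))
            if (membership[i] == membership[j])
                q <- q + w[i, j] / tw - k[i] * k[j] / tw^2
    q
}

bruteMaxQ <- function(w) {
    parts <- allPartitions(nrow(w))
    best <- -Inf; bestPart <- NULL
    tw <- sum(w)
    A <- w / tw
    k <- rowSums(A)
    for (p in parts) {
        same <- outer(p, p, "==")
        q <- sum(A[same]) - sum(tapply(k, p, sum)^2)
        if (q > best) { best <- q; bestPart <- p }
    }
    list(Q = best, membership = bestPart)
}

# random symmetric weighted graph on n nodes
randomGraph <- function(n, pEdge = 0.5) {
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    edges <- runif(sum(up)) < pEdge
    vals <- ifelse(edges, runif(sum(up), 0.1, 1), 0)
    w[up] <- vals
    w + t(w)
}

# a small ceramide-pathway fixture: 2 classes, known abundances
twoClassPanel <- function(nA = 8, nB = 7) {
    data.frame(
        species_id = c(paste0("CER", 14 + seq_len(nA)),
                       paste0("LCER", 14 + seq_len(nB))),
        class_id = rep(c("CER", "LCER"), c(nA, nB)),
        chain_carbons = c(14 + seq_len(nA), 14 + seq_len(nB)),
        double_bonds = 0L, stringsAsFactors = FALSE)
}

# adjusted Rand index (mclust is the environment's reference implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# clinical record helper for classifier tests
subjectRecord <- function(sex = "male", waist = 90, tg = 100, hdl = 55,
                          sys = 120, dia = 70, glucose = 90, ...) {
    data.frame(sex = sex, waist_cm = waist, triglycerides_mg_dl = tg,
               hdl_mg_dl = hdl, systolic = sys, diastolic = dia,
               glucose_mg_dl = glucose, ..., stringsAsFactors = FALSE)
}
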