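.weightMatrix <- function(x) {
    w <- if (is(x, "DistanceNetwork")) edgeWeights(x) else as.matrix(x)
    if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-10)
        stop("weight matrix must be square and symmetric")
    diag(w) <- 0
    w
}

#' Weighted Newman modularity
#'
#' Q = (1 / 2m) * sum_ij (w_ij - k_i k_j / (2m)) * delta(c_i, c_j), with m
#' the total edge weight and k_i the weighted degree.
#'
#' @param x a \linkS4class{DistanceNetwork} or symmetric weight matrix (zero
#'   diagonal)
#' @param membership cluster assignment along the nodes (any label type)
#' @return modularity Q in [-0.5, 1]
#' @examples
#' w <- matrix(0, 3, 3); w[upper.tri(w)] <- 1; w <- w + t(w)  # triangle
#' modularityScore(w, c(1, 1, 1))   # 0
#' modularityScore(w, c(1, 2, 3))   # -1/3
#' @export
modularityScore <- function(x, membership) {
    w <- .weightMatrix(x)
    if (length(membership) != nrow(w))
        stop("membership must cover all nodes")
    tw <- sum(w)
    if (tw <= 0) stop("modularity is undefined on an edgeless graph")
    A <- w / tw                      # normalized so sum(A) = 1 (= 2m scale)
    same <- outer(membership, membership, "==")
    k <- rowSums(A)
    sum(A[same]) - sum((tapply(k, membership, sum))^2)
}

#' Fast-greedy modularity clustering
#'
#' Agglomerative Clauset-Newman-Moore scheme on the weighted
#' significant-edge graph: starting from singleton clusters, repeatedly
#' merge the connected cluster pair giving the largest modularity increase
#' (ties broken deterministically toward the lexicographically smallest
#' cluster-index pair), and return the partition at the maximum modularity
#' along the merge path. Isolated nodes remain singleton clusters.
#'
#' @param x a \linkS4class{DistanceNetwork} or symmetric weight matrix
#' @return A \linkS4class{ModularityPartition}
#' @export
fastGreedyPartition <- function(x) {
    w <- .weightMatrix(x)
    n <- nrow(w)
    tw <- sum(w)
    if (tw <= 0) stop("cannot cluster an edgeless graph")
    A <- w / tw
    ## live cluster-aggregated matrix; cluster index = smallest member node
    M <- A
    live <- seq_len(n)
    members <- as.list(seq_len(n))
    a <- rowSums(M)
    Q <- -sum(a^2)                   # singleton partition
    bestQ <- Q
    bestStep <- 0L
    merges <- matrix(0L, 0, 2)
    repeat {
        k <- length(live)
        if (k <= 1) break
        sub <- M[live, live, drop = FALSE]
        asub <- a[live]
        gain <- 2 * (sub - outer(asub, asub))
        gain[sub <= 0] <- -Inf       # only merge connected clusters
        diag(gain) <- -Inf
        best <- max(gain)
        if (!is.finite(best)) break  # disconnected components remain
        hit <- which(gain == best, arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
        i <- live[hit[1, 1]]; j <- live[hit[1, 2]]
        ## merge j into i
        M[i, ] <- M[i, ] + M[j, ]
        M[, i] <- M[, i] + M[, j]
        M[i, i] <- M[i, i]           # within weight now includes cross term
        a[i] <- a[i] + a[j]
        live <- setdiff(live, j)
        members[[i]] <- c(members[[i]], members[[j]])
        members[[j]] <- integer(0)
        Q <- Q + best
        merges <- rbind(merges, c(i, j))
        if (Q > bestQ + 1e-12) {
            bestQ <- Q
            bestStep <- nrow(merges)
        }
    }
    ## replay merges up to the best step from singletons
    membership <- seq_len(n)
    if (bestStep > 0)
        for (s in seq_len(bestStep)) {
            pair <- merges[s, ]
            membership[membership == pair[2]] <- pair[1]
        }
    membership <- as.integer(factor(membership,
                                    levels = unique(membership)))
    names(membership) <- rownames(w)
    path <- data.frame(step = seq_len(nrow(merges)),
                       into = merges[, 1], from = merges[, 2])
    new("ModularityPartition", membership = membership,
        Q = modularityScore(w, membership), path = path)
}
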