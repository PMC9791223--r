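test_that("Spearman matrix handles monotone data, midrank ties, and NAs", {
    panel <- twoClassPanel(2, 1)
    x <- 1:20
    m <- rbind(x, x^3, rev(x))
    dimnames(m) <- list(panel$species_id, paste0("S", 1:20))
    corr <- spearmanMatrix(SphingolipidExperiment(m, panel))
    expect_equal(corr@rho[1, 2], 1)          # monotone invariance
    expect_equal(corr@rho[1, 3], -1)
    expect_equal(corr@p[1, 2], 0)

    # midrank ties: hand computation, cross-checked against stats::cor
    xs <- c(1, 2, 3, 4, 5); ys <- c(5, 6, 7, 8, 7)
    m2 <- rbind(xs, ys, abs(rnorm(5)) + 0.1)
    dimnames(m2) <- list(panel$species_id, paste0("S", 1:5))
    corr2 <- spearmanMatrix(SphingolipidExperiment(m2, panel))
    handRho <- 8 / sqrt(10 * 9.5)            # ranks of y: 1,2,3.5,5,3.5
    expect_equal(corr2@rho[1, 2], handRho)
    expect_equal(corr2@rho[1, 2], cor(xs, ys, method = "spearman"))

    # pairwise-complete observations
    m3 <- matrix(rlnorm(3 * 30), 3, 30,
                 dimnames = list(panel$species_id, paste0("S", 1:30)))
    m3[1, 1:5] <- NA
    corr3 <- spearmanMatrix(SphingolipidExperiment(m3, panel))
    expect_equal(corr3@nPairs[1, 2], 25)
    expect_equal(corr3@nPairs[2, 3], 30)
    ok <- !is.na(m3[1, ])
    expect_equal(corr3@rho[1, 2],
                 cor(m3[1, ok], m3[2, ok], method = "spearman"))

    # constant species are an explicit error naming the offender
    m4 <- m3; m4[2, ] <- 1
    expect_error(spearmanMatrix(SphingolipidExperiment(m4, panel)),
                 panel$species_id[2], fixed = TRUE)
    expect_error(spearmanMatrix(m3[, 1:3]), "4 subjects")
})

test_that("analytic Spearman p agrees with the permutation distribution", {
    set.seed(12)
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    rho <- cor(x, y, method = "spearman")
    tt <- rho * sqrt((10 - 2) / (1 - rho^2))
    pAnalytic <- 2 * pt(-abs(tt), 8)
    perm <- replicate(20000, {
        ys <- sample(y)
        abs(cor(x, ys, method = "spearman"))
    })
    pPerm <- mean(perm >= abs(rho) - 1e-12)
    expect_lt(abs(pAnalytic - pPerm), 0.02)

    # the exact option reproduces the full enumeration for tiny n
    panel <- twoClassPanel(1, 1)
    m <- rbind(exp(x[1:6]), exp(y[1:6]))
    dimnames(m) <- list(panel$species_id, paste0("S", 1:6))
    corrExact <- spearmanMatrix(SphingolipidExperiment(m, panel),
                                exact = TRUE)
    perms <- sphingonet:::.permutations(6)
    rx <- rank(x[1:6]); ry <- rank(y[1:6])
    obs <- abs(cor(rx, ry))
    pEnum <- mean(apply(perms, 1, function(p)
        abs(cor(rx, ry[p])) >= obs - 1e-12))
    expect_equal(corrExact@p[1, 2], pEnum)
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    set.seed(13)
    for (r in 1:25) {
        p <- runif(sample(2:50, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bruteBH(p))
        expect_true(all(adj >= p - 1e-15))
        o <- order(p)
        expect_true(all(diff(adj[o]) >= -1e-15))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("distance network zeroes non-significant pairs", {
    panel <- twoClassPanel(2, 1)
    rho <- matrix(c(1, 0.8, -0.9, 0.8, 1, 0.5, -0.9, 0.5, 1), 3, 3,
                  dimnames = list(panel$species_id, panel$species_id))
    p <- matrix(0, 3, 3, dimnames = dimnames(rho))
    padj <- matrix(c(0, 0.001, 0.01, 0.001, 0, 0.20, 0.01, 0.20, 0), 3, 3,
                   dimnames = dimnames(rho))
    corr <- new("CorrelationResult", rho = rho, p = p, pAdjusted = padj,
                nPairs = matrix(50L, 3, 3), nSubjects = 50L)
    net <- buildDistanceNetwork(corr)
    d <- distanceMatrix(net)
    expect_equal(d[1, 2], 0.2)                 # 1 - |0.8|
    expect_equal(d[1, 3], 0.1)                 # |-0.9| -> 0.1
    expect_equal(d[2, 3], 1)                   # non-significant -> 1
    expect_equal(edgeWeights(net)[2, 3], 0)    # and no edge
    expect_equal(nrow(edgeList(net)), 2)
    expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))

    # distance respects the correlation ordering among significant pairs
    expect_true(d[1, 3] < d[1, 2])
})

test_that("interclass distance averages all cross-class pairs", {
    panel <- twoClassPanel(2, 1)
    w <- matrix(0, 3, 3, dimnames = list(panel$species_id,
                                         panel$species_id))
    w[1, 3] <- w[3, 1] <- 0.8    # d = 0.2
    w[2, 3] <- w[3, 2] <- 0.6    # d = 0.4
    corr <- new("CorrelationResult", rho = diag(3), p = diag(3) * 0,
                pAdjusted = matrix(0, 3, 3), nPairs = matrix(10L, 3, 3),
                nSubjects = 10L)
    d <- 1 - w; diag(d) <- 0
    net <- new("DistanceNetwork", distance = d, weight = w, alpha = 0.05,
               correlation = corr)
    cmap <- setNames(panel$class_id, panel$species_id)
    expect_equal(interclassDistance(net, cmap, "CER", "LCER"), 0.3)
    expect_equal(interclassDistance(net, cmap, "LCER", "CER"), 0.3)
    # all cross pairs non-significant -> mean distance 1
    net@distance <- matrix(1, 3, 3, dimnames = dimnames(w))
    diag(net@distance) <- 0
    expect_equal(interclassDistance(net, cmap, "CER", "LCER"), 1)
    expect_error(interclassDistance(net, cmap, "CER", "SM"), "classes")
})

test_that("greedy modularity clustering agrees with igraph on real inputs", {
    skip_if_not_installed("igraph")
    set.seed(14)
    for (r in 1:10) {
        w <- randomGraph(10, 0.4)
        if (sum(w) == 0) next
        g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                                 weighted = TRUE)
        mem <- clusterMembership(fastGreedyPartition(w))
        expect_equal(modularityScore(w, mem),
                     igraph::modularity(g, mem,
                                        weights = igraph::E(g)$weight))
        # same optimum as igraph's fast-greedy on these instances
        ig <- igraph::cluster_fast_greedy(g)
        expect_equal(modularityScore(w, mem),
                     igraph::modularity(g, igraph::membership(ig),
                                        weights = igraph::E(g)$weight),
                     tolerance = 1e-9)
    }
})

test_that("Steiger comparison matches hand computation and symmetry", {
    panel <- twoClassPanel(1, 1)
    mk <- function(r, n) {
        rho <- matrix(c(1, r, r, 1), 2, 2,
                      dimnames = list(panel$species_id, panel$species_id))
        new("CorrelationResult", rho = rho, p = rho * 0,
            pAdjusted = rho * 0, nPairs = matrix(as.integer(n), 2, 2),
            nSubjects = as.integer(n))
    }
    c1 <- mk(0.5, 103); c2 <- mk(0.3, 103)
    res <- steigerCompare(c1, c2)
    z1 <- atanh(0.5); z2 <- atanh(0.3)
    expect_equal(res@chisq, (z1 - z2)^2 / (2 / 100), tolerance = 1e-6)
    expect_equal(res@chisq, 2.876, tolerance = 0.01)
    expect_equal(res@df, 1L)
    # equivalent two-sample correlation z-test oracle (k = 2)
    zStat <- (z1 - z2) / sqrt(1 / 100 + 1 / 100)
    expect_equal(res@p, 2 * pnorm(-abs(zStat)), tolerance = 1e-10)

    expect_equal(steigerCompare(c1, c1)@chisq, 0)
    expect_equal(steigerCompare(c1, c1)@p, 1)
    expect_error(steigerCompare(mk(1, 50), c2), "infinite|= 1")
})

test_that("permutation interclass test is exact-null on identical strata", {
    m <- simulateLipidMatrix(40, twoClassPanel(3, 3), interclassRho = 0.3,
                             seed = 15)
    cmap <- setNames(twoClassPanel(3, 3)$class_id,
                     twoClassPanel(3, 3)$species_id)
    res <- permutationInterclassTest(m, 1:40, 1:40, "CER", "LCER",
                                     classMap = cmap, nPerm = 50, seed = 16)
    expect_equal(res@delta, 0)
    expect_equal(res@p, 1)
    expect_error(permutationInterclassTest(m, 1:3, 4:40, "CER", "LCER",
                                           classMap = cmap, nPerm = 10,
                                           seed = 1),
                 "at least 4")
})

test_that("fast permutation path equals the assembled network pipeline", {
    panel <- defaultSpeciesPanel(nSM = 0)
    m <- simulateLipidMatrix(120, panel, seed = 17)
    m2 <- injectMissingness(m, 0.1, seed = 18)
    cmap <- setNames(panel$class_id, panel$species_id)
    for (mat in list(m, m2)) {
        res <- permutationInterclassTest(mat, 1:60, 61:120, "CER", "LCER",
                                         classMap = cmap, nPerm = 5,
                                         seed = 19)
        corrA <- spearmanMatrix(mat[, 1:60])
        dA <- interclassDistance(buildDistanceNetwork(corrA), cmap,
                                 "CER", "LCER")
        corrB <- spearmanMatrix(mat[, 61:120])
        dB <- interclassDistance(buildDistanceNetwork(corrB), cmap,
                                 "CER", "LCER")
        expect_equal(res@distanceA, dA)
        expect_equal(res@distanceB, dB)
    }
})
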