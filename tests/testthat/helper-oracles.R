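# Independent oracles used across the test suite. Each is a deliberately
# naive implementation (brute force / enumeration / closed form), kept
# separate from the package code paths it checks.

# Brute-force Benjamini-Hochberg by the step-up definition.
bruteForceBH <- function(p) {
    n <- length(p)
    ord <- order(p)
    adj <- numeric(n)
    running <- Inf
    for (i in n:1) {
        running <- min(running, p[ord[i]] * n / i)
        adj[ord[i]] <- min(running, 1)
    }
    adj
}

# Brute-force DPI: enumerate every node triple, and in each full triangle
# test every edge against its two partners under the printed inequalities;
# remove all marked edges simultaneously at the end.
bruteForceDPI <- function(M, eps, tau) {
    p <- nrow(M)
    W <- M
    diag(W) <- 0
    W[W <= eps] <- 0
    mark <- matrix(FALSE, p, p)
    fac <- 1 - tau
    triples <- combn(p, 3)
    for (t in seq_len(ncol(triples))) {
        i <- triples[1, t]; j <- triples[2, t]; k <- triples[3, t]
        if (W[i, j] == 0 || W[j, k] == 0 || W[i, k] == 0) next
        if (W[i, j] < W[j, k] * fac && W[i, j] < W[i, k] * fac)
            mark[i, j] <- mark[j, i] <- TRUE
        if (W[j, k] < W[i, j] * fac && W[j, k] < W[i, k] * fac)
            mark[j, k] <- mark[k, j] <- TRUE
        if (W[i, k] < W[i, j] * fac && W[i, k] < W[j, k] * fac)
            mark[i, k] <- mark[k, i] <- TRUE
    }
    W[mark] <- 0
    W
}

# Edge matrix of an MINetwork, for comparison with a brute-force result.
networkAdjacency <- function(net) {
    nodes <- net@nodes
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    e <- miEdges(net)
    if (nrow(e)) {
        W[cbind(e$from, e$to)] <- e$mi
        W[cbind(e$to, e$from)] <- e$mi
    }
    W
}

# All set partitions of 1..n (restricted growth strings), for exhaustive
# modularity search on small graphs.
allPartitions <- function(n) {
    out <- list()
    rec <- function(assign, maxUsed) {
        i <- length(assign) + 1L
        if (i > n) {
            out[[length(out) + 1L]] <<- assign
            return(invisible())
        }
        for (c in seq_len(maxUsed + 1L))
            rec(c(assign, c), max(maxUsed, c))
    }
    rec(integer(0), 0L)
    out
}

# Exhaustive best modularity over all partitions of a small network.
bestModularity <- function(net, resolution = 1) {
    n <- length(net@nodes)
    parts <- allPartitions(n)
    best <- -Inf
    for (p in parts) {
        q <- modularityScore(net, setNames(p, net@nodes), resolution)
        if (q > best) best <- q
    }
    best
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    e <- si * sj / choose(n, 2)
    (sij - e) / ((si + sj) / 2 - e)
}

# Exact hypergeometric upper tail by explicit enumeration of the support,
# usable for populations <= 15.
enumHyperTail <- function(k, K, M, nDraws) {
    kk <- max(k, 0):min(K, nDraws)
    sum(choose(K, kk) * choose(M - K, nDraws - kk)) / choose(M, nDraws)
}

# Small MINetwork built directly from an edge list data.frame(from, to, w)
# (no thresholding or pruning applied).
toyNetwork <- function(edges, nodes = NULL) {
    if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    methods::new("MINetwork", nodes = nodes,
                 edges = data.frame(from = edges$from, to = edges$to,
                                    mi = edges$w),
                 eps = 0, params = list(tau = 0))
}

# Fixture suite of small graphs (<= 8 nodes) for the Louvain oracle.
smallGraphSuite <- function() {
    g <- list()
    g$twoTriangles <- data.frame(
        from = c("a", "b", "a", "d", "e", "d"),
        to   = c("b", "c", "c", "e", "f", "f"), w = 1)
    g$completeK5 <- {
        cmb <- t(combn(letters[1:5], 2))
        data.frame(from = cmb[, 1], to = cmb[, 2], w = 1)
    }
    g$path4 <- data.frame(from = c("a", "b", "c"),
                          to = c("b", "c", "d"), w = 1)
    g$star6 <- data.frame(from = "hub", to = sprintf("v%d", 1:5), w = 1)
    g$ring8 <- data.frame(from = letters[1:8],
                          to = letters[c(2:8, 1)], w = 1)
    g$barbell <- data.frame(
        from = c("a", "b", "a", "d", "e", "d", "c"),
        to   = c("b", "c", "c", "e", "f", "f", "d"), w = 1)
    g$weightedPair <- data.frame(
        from = c("a", "a", "b", "c"),
        to   = c("b", "c", "c", "d"), w = c(3, 0.2, 2.5, 1.5))
    set.seed(404)
    rnd <- t(combn(letters[1:7], 2))
    keep <- runif(nrow(rnd)) < 0.45
    g$random7 <- data.frame(from = rnd[keep, 1], to = rnd[keep, 2],
                            w = round(runif(sum(keep), 0.2, 1), 2))
    lapply(g, toyNetwork)
}
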