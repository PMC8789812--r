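# Louvain partitions, the modularity formula, degree statistics with
# quartile placement, and DEM-community integration.

test_that("modularity formula: degenerate and closed-form cases", {
    suite <- smallGraphSuite()
    tri2 <- suite$twoTriangles
    # one community holding everything: Q = 1 - gamma
    all1 <- setNames(rep(1L, 6), tri2@nodes)
    expect_equal(modularityScore(tri2, all1, resolution = 1), 0)
    expect_equal(modularityScore(tri2, all1, resolution = 0.5), 0.5)
    # the planted two-triangle split: Q = 0.5 exactly
    split <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                      c("a", "b", "c", "d", "e", "f"))
    expect_equal(modularityScore(tri2, split), 0.5)
    # edgeless graph: Q = 0 by convention
    lonely <- methods::new("MINetwork", nodes = c("x", "y"),
                           edges = data.frame(from = character(),
                                              to = character(),
                                              mi = numeric()),
                           eps = 0, params = list())
    expect_equal(modularityScore(lonely, setNames(1:2, c("x", "y"))), 0)
    expect_error(modularityScore(tri2, split[1:3]), "cover")
})

test_that("our modularity agrees with igraph's at gamma 1", {
    set.seed(303)
    for (g in smallGraphSuite()) {
        memb <- membershipVector(louvainCommunities(g, seed = 1))
        ig <- asIgraph(g)
        expect_equal(modularityScore(g, memb),
                     igraph::modularity(ig,
                         memb[igraph::V(ig)$name],
                         weights = igraph::E(ig)$weight),
                     tolerance = 1e-12)
    }
})

test_that("Louvain solves the canonical small instances", {
    suite <- smallGraphSuite()
    part <- louvainCommunities(suite$twoTriangles, seed = 2)
    expect_identical(length(part@sizes), 2L)
    expect_equal(part@modularity, 0.5)
    m <- membershipVector(part)
    expect_identical(length(unique(m[c("a", "b", "c")])), 1L)
    expect_identical(length(unique(m[c("d", "e", "f")])), 1L)
    # complete graph: a single community at gamma 1
    k5 <- louvainCommunities(suite$completeK5, seed = 3)
    expect_identical(length(k5@sizes), 1L)
    expect_error(louvainCommunities(suite$completeK5, resolution = 0),
                 "positive")
})

test_that("Louvain is near-optimal on the whole small-graph suite", {
    for (g in smallGraphSuite()) {
        part <- louvainCommunities(g, seed = 11)
        qBest <- bestModularity(g)
        expect_gte(part@modularity, qBest - 0.05 * max(abs(qBest), 0.1))
        # never worse than the trivial one-community partition
        q1 <- modularityScore(g, setNames(rep(1L, length(g@nodes)),
                                          g@nodes))
        expect_gte(part@modularity, q1)
    }
})

test_that("partitions are stable across seeds on a planted design", {
    cfg <- simConfig(nMirnas = 60L,
                     groups = data.frame(group = "dnPD", site = "GOE",
                                         n = 50L),
                     moduleSpec = rep(list(c(15, 0.6)), 4), seed = 97L)
    sim <- simulateCohort(cfg)
    net <- buildNetwork(sim$experiment, "dnPD",
                        networkParams(estimator = "gaussian_copula",
                                      seed = 1))
    parts <- lapply(1:10, function(s)
        membershipVector(louvainCommunities(net, seed = s)))
    base <- parts[[1]]
    aris <- vapply(parts[-1], function(p)
        adjustedRand(base[net@nodes], p[net@nodes]), numeric(1))
    expect_true(all(aris >= 0.8))
    # determinism at fixed seed
    expect_identical(parts[[3]],
                     membershipVector(louvainCommunities(net, seed = 3)))
})

test_that("degree statistics: bookkeeping identities and quartile labels", {
    e <- data.frame(from = c("a", "a", "a", "b"),
                    to   = c("b", "c", "d", "c"),
                    w    = c(0.5, 0.4, 0.3, 0.2))
    net <- toyNetwork(e, nodes = c("a", "b", "c", "d", "iso"))
    part <- louvainCommunities(net, seed = 4)
    ds <- nodeDegrees(net, part)
    expect_identical(sum(ds$unweightedDegree), 2L * nrow(miEdges(net)))
    expect_equal(sum(ds$weightedDegree), 2 * sum(miEdges(net)$mi))
    expect_identical(ds$weightedDegree[ds$node == "iso"], 0)
    expect_identical(ds$unweightedDegree[ds$node == "iso"], 0L)
    # weighted degree equals the adjacency row sum
    W <- networkAdjacency(net)
    expect_equal(setNames(ds$weightedDegree, ds$node)[rownames(W)],
                 rowSums(W))
    # a community's maximal degree lies above the upper quartile
    oneComm <- methods::new("CommunityPartition",
                            membership = setNames(rep(1L, 5),
                                                  c("a", "b", "c", "d",
                                                    "iso")),
                            modularity = 0, resolution = 1,
                            sizes = c(`1` = 5L))
    ds1 <- nodeDegrees(net, oneComm)
    expect_identical(
        ds1$weightedLabel[which.max(ds1$weightedDegree)],
        "above_upper_quartile")
    expect_identical(
        ds1$weightedLabel[which.min(ds1$weightedDegree)],
        "below_median")
})

test_that("DEM-community integration reports the maximum overlap", {
    memb <- setNames(c(1L, 1L, 1L, 2L), c("a", "b", "x", "c"))
    part <- methods::new("CommunityPartition", membership = memb,
                         modularity = 0, resolution = 1,
                         sizes = c(`1` = 3L, `2` = 1L))
    res <- integrateDEMs(part, list(dem = c("a", "b", "c")))
    expect_identical(res$best$community, 1L)
    expect_identical(res$best$overlap, 2L)
    # DEM set equal to one community: minimal p at that community
    res2 <- integrateDEMs(part, list(dem = c("a", "b", "x")))
    ov <- res2$overlaps
    expect_identical(ov$community[which.min(ov$p)], 1L)
    expect_identical(res2$best$overlap, 3L)
    # disjoint set: flagged
    res3 <- integrateDEMs(part, list(dem = c("zz")))
    expect_true(res3$best$flagged)
    expect_identical(res3$best$overlap, 0L)
})

test_that("planted markers cluster into a single community end to end", {
    cfg <- simConfig(nMirnas = 80L,
                     groups = data.frame(group = "dnPD", site = "GOE",
                                         n = 60L),
                     moduleSpec = rep(list(c(20, 0.6)), 4), seed = 107L)
    sim <- simulateCohort(cfg)
    net <- buildNetwork(sim$experiment, "dnPD",
                        networkParams(estimator = "gaussian_copula",
                                      seed = 23))
    part <- louvainCommunities(net, seed = 29)
    tr <- sim$truth$moduleMembership[net@nodes]
    markers <- names(tr)[which(tr == 1L)][1:4]
    integ <- integrateDEMs(part, list(markers = markers))
    memb <- membershipVector(part)
    expect_identical(length(unique(memb[markers])), 1L)
    expect_identical(integ$best$community,
                     unname(unique(memb[markers])))
})
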