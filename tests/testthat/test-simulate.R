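# Synthetic-cohort generators: determinism, marginal fidelity, planted
# structure, and the read-record / Ct / MTI generators.

twoGroupConfig <- function(n = 50L, perGroup = 5L, seed = 1L, ...) {
    simConfig(nMirnas = n,
              groups = data.frame(group = c("dnPD", "CTR"), site = "GOE",
                                  n = perGroup),
              seed = seed, ...)
}

test_that("identical seeds give bit-identical cohorts", {
    cfg <- twoGroupConfig(seed = 42L, moduleSpec = list(c(5, 0.5)),
                          deFraction = c(dnPD = 0.2),
                          deLog2fc = c(dnPD = 1))
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(counts(a$experiment), counts(b$experiment))
    expect_identical(a$truth, b$truth)
    expect_identical(a$sampleSheet, b$sampleSheet)
    c <- simulateCohort(twoGroupConfig(seed = 43L))
    expect_false(identical(counts(a$experiment), counts(c$experiment)))
})

test_that("generator rejects invalid configurations", {
    expect_error(simConfig(groups = data.frame(group = "XX", site = "GOE",
                                               n = 5L)), "unknown group")
    expect_error(simConfig(groups = data.frame(group = "CTR", site = "GOE",
                                               n = 1L)), "n >= 2")
    expect_error(simConfig(moduleSpec = list(c(10, 1.0))), "rho")
    expect_error(simConfig(deFraction = c(dnPD = 0.1)), "named by the same")
})

test_that("counts are overdispersed when alpha > 0", {
    cfg <- simConfig(nMirnas = 100L,
                     groups = data.frame(group = "CTR", site = "GOE",
                                         n = 200L),
                     depthLogSd = 0, dispersion = 0.3, seed = 7L)
    cnt <- counts(simulateCohort(cfg)$experiment)
    m <- rowMeans(cnt)
    v <- apply(cnt, 1L, var)
    keep <- m > 5            # variance test is meaningless at tiny means
    expect_gt(mean(v[keep] > m[keep]), 0.9)
})

test_that("copula blocks plant rank correlation without distorting marginals", {
    base <- simConfig(nMirnas = 60L,
                      groups = data.frame(group = "CTR", site = "GOE",
                                          n = 2000L),
                      depthLogSd = 0, seed = 5L)
    blk <- simConfig(nMirnas = 60L,
                     groups = data.frame(group = "CTR", site = "GOE",
                                         n = 2000L),
                     depthLogSd = 0, moduleSpec = list(c(10, 0.8)),
                     seed = 5L)
    a <- simulateCohort(base)
    b <- simulateCohort(blk)
    # marginal means preserved within 5%; the two configs draw
    # independent count realizations, so restrict to rows whose mean is
    # estimated with < ~1% relative error (sampling noise would otherwise
    # dominate the comparison)
    ma <- rowMeans(counts(a$experiment))
    mb <- rowMeans(counts(b$experiment))
    keep <- ma > 20
    expect_lt(max(abs(mb[keep] / ma[keep] - 1)), 0.05)
    # planted block carries the target rank correlation
    members <- which(!is.na(b$truth$moduleMembership))
    S <- cor(t(counts(b$experiment)[members, ]), method = "spearman")
    expect_gt(mean(S[upper.tri(S)]), 0.7)
    expect_lt(mean(S[upper.tri(S)]), 0.9)
    others <- setdiff(seq_len(60L), members)
    Sx <- cor(t(counts(b$experiment)[members, ]),
              t(counts(b$experiment)[others, ]), method = "spearman")
    expect_lt(abs(mean(Sx)), 0.1)
})

test_that("null configuration yields exchangeable group labels", {
    cfg <- simConfig(nMirnas = 400L,
                     groups = data.frame(group = c("dnPD", "CTR"),
                                         site = "GOE", n = 30L),
                     dispersion = 0.1, seed = 21L)
    sim <- simulateCohort(cfg)
    x <- estimateSizeFactors(filterExpressed(sim$experiment))
    res <- waldTest(x, contrastSpec("null", "dnPD", "CTR"))
    pv <- res$pvalue[!is.na(res$pvalue)]
    expect_gt(mean(pv < 0.05), 0.01)
    expect_lt(mean(pv < 0.05), 0.10)
})

test_that("read records invert UMI collapse", {
    cfg <- twoGroupConfig(n = 20L, perGroup = 3L, seed = 9L)
    se <- simulateCohort(cfg)$experiment
    for (rate in c(0, 0.5, 2)) {
        rec <- simulateReadRecords(se, duplicationRate = rate, seed = 3L)
        back <- collapseUMIs(rec,
                             sampleSheet = data.frame(
                                 sample = colnames(se),
                                 group = se$group, site = se$site),
                             mirnaIds = rownames(se))
        expect_identical(counts(back), counts(se))
    }
})

test_that("read records have the exact molecule structure", {
    m <- matrix(c(3L, 0L), 1, 2,
                dimnames = list("miR-x", c("s1", "s2")))
    rec <- simulateReadRecords(m, duplicationRate = 0)
    expect_identical(nrow(rec), 3L)
    expect_identical(length(unique(rec$umi)), 3L)
    expect_true(all(rec$sample == "s1"))
    empty <- simulateReadRecords(matrix(0L, 1, 1,
        dimnames = list("miR-x", "s1")), 0)
    expect_identical(nrow(empty), 0L)
    expect_error(simulateReadRecords(m, duplicationRate = -1), ">= 0")
})

test_that("Ct generator plants exact effects at zero noise", {
    out <- simulateCtTable("miR-144-3p", c("CTR", "dnPD"),
                           plantedLog2fc = c("miR-144-3p" = -1),
                           noiseSd = 0, nPerGroup = 4L, seed = 2L)
    dct <- deltaCt(aggregateReplicates(out$ct), attr(out$ct, "controls"))
    rq <- relativeQuant(dct, "dnPD", "CTR")
    expect_equal(rq$RQ, 0.5, tolerance = 1e-12)
    # all-null table: delta-delta-Ct identically zero
    out0 <- simulateCtTable(c("t1", "t2"), c("CTR", "dnPD"),
                            noiseSd = 0, nPerGroup = 3L, seed = 2L)
    dct0 <- deltaCt(aggregateReplicates(out0$ct), attr(out0$ct, "controls"))
    rq0 <- relativeQuant(dct0, "dnPD", "CTR")
    expect_equal(rq0$deltaDeltaCt, c(0, 0), tolerance = 1e-12)
    expect_error(simulateCtTable("t", controls = character()),
                 "control")
})

test_that("Ct generator estimator spread is tight at moderate noise", {
    est <- vapply(1:25, function(s) {
        out <- simulateCtTable("t1", c("CTR", "dnPD"),
                               plantedLog2fc = c(t1 = -1), noiseSd = 0.2,
                               nPerGroup = 20L, seed = s)
        dct <- deltaCt(aggregateReplicates(out$ct),
                       attr(out$ct, "controls"))
        relativeQuant(dct, "dnPD", "CTR")$log2fc
    }, numeric(1))
    expect_true(all(abs(est + 1) < 0.3))
})

test_that("MTI generator honours density and evidence fractions", {
    empty <- simulateMtiTable(10, 20, density = 0, seed = 1L)
    expect_identical(nrow(empty), 0L)
    allStrong <- simulateMtiTable(10, 20, density = 0.5,
                                  strongFraction = 1, seed = 1L)
    expect_true(all(allStrong$evidence == "strong"))
    big <- simulateMtiTable(100, 500, density = 0.1, seed = 8L)
    expected <- 100 * 500 * 0.1
    sdv <- sqrt(100 * 500 * 0.1 * 0.9)
    expect_lt(abs(nrow(big) - expected), 3 * sdv)
    expect_error(simulateMtiTable(0, 5), "degenerate")
})
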