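# NB Wald differential expression: dispersion estimation, the IRLS fit,
# BH adjustment, DEM calling and the multi-contrast runner.

test_that("dispersion formula matches the hand evaluation", {
    # one group, normalized counts with mean 10 and variance 30
    m <- matrix(c(7L, 9L, 10L, 11L, 13L, 18L, 4L, 9L, 10L, 9L), 1,
                dimnames = list("miR-1", sprintf("s%d", 1:10)))
    sd <- data.frame(group = rep("CTR", 10), site = "GOE",
                     row.names = colnames(m))
    x <- MirnaExperiment(m, sd)
    sizeFactors(x) <- rep(1, 10)
    mn <- mean(m)
    vr <- var(as.numeric(m))
    expect_equal(unname(estimateDispersions(x, rep("CTR", 10))),
                 (vr - mn) / mn^2)
    # underdispersed rows hit the floor
    u <- matrix(rep(10L, 10), 1, dimnames = list("flat", colnames(m)))
    xu <- MirnaExperiment(u, sd)
    sizeFactors(xu) <- rep(1, 10)
    expect_equal(unname(estimateDispersions(xu, rep("CTR", 10))), 1e-8)
    expect_error(estimateDispersions(x, c("a", rep("b", 9))),
                 "at least 2 samples")
})

test_that("dispersion recovery on simulated data", {
    cfg <- simConfig(nMirnas = 300L,
                     groups = data.frame(group = c("dnPD", "CTR"),
                                         site = "GOE", n = 200L),
                     dispersion = 0.1, seed = 23L)
    sim <- simulateCohort(cfg)
    x <- estimateSizeFactors(filterExpressed(sim$experiment))
    a <- estimateDispersions(x, x$group)
    keep <- rowMeans(normCounts(x)) > 5
    expect_gt(median(a[keep]), 0.05)
    expect_lt(median(a[keep]), 0.2)
})

test_that("Wald test recovers planted effects and is antisymmetric", {
    cfg <- simConfig(nMirnas = 800L,
                     groups = data.frame(group = c("dnPD", "CTR"),
                                         site = "GOE", n = 30L),
                     dispersion = 0.1,
                     deFraction = c(dnPD = 0.1), deLog2fc = c(dnPD = 1),
                     deBalanced = TRUE, seed = 29L)
    sim <- simulateCohort(cfg)
    x <- estimateSizeFactors(filterExpressed(sim$experiment))
    fwd <- waldTest(x, contrastSpec("f", "dnPD", "CTR"))
    rev <- waldTest(x, contrastSpec("r", "CTR", "dnPD"))
    expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-6)
    expect_equal(fwd$pvalue, rev$pvalue, tolerance = 1e-6)
    tr <- sim$truth$deStatus[, "dnPD"]
    planted <- names(tr)[tr != 0]
    est <- fwd$log2fc[match(planted, fwd$mirna)]
    expect_lt(abs(mean(sign(tr[planted]) * est, na.rm = TRUE) - 1), 0.1)
})

test_that("all-zero rows carry missing p and finite rows converge", {
    m <- rbind(matrix(rnbinom(40, mu = 20, size = 10) + 1L, 2),
               rep(0L, 20))
    dimnames(m) <- list(c("a", "b", "zero"), sprintf("s%d", 1:20))
    sd <- data.frame(group = rep(c("dnPD", "CTR"), each = 10),
                     site = "GOE", row.names = colnames(m))
    x <- MirnaExperiment(m, sd)
    sizeFactors(x) <- rep(1, 20)
    res <- waldTest(x, contrastSpec("t", "dnPD", "CTR"))
    expect_true(is.na(res$pvalue[res$mirna == "zero"]))
    expect_true(all(res$converged[res$mirna != "zero"]))
    expect_true(all(is.finite(res$log2fc[res$mirna != "zero"])))
})

test_that("BH adjustment matches the brute-force step-up definition", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.04, 0.05)),
                 c(0.04, 0.04, 0.05, 0.05))
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
    set.seed(91)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(adjustBH(p), bruteForceBH(p))
    }
    # missing values excluded from the denominator
    p <- c(0.01, NA, 0.03)
    expect_equal(adjustBH(p), c(0.02, NA, 0.03))
    expect_error(adjustBH(c(0.5, 1.2)), "between 0 and 1")
})

test_that("DEM calling is strict at the threshold", {
    res <- data.frame(mirna = c("a", "b", "c"),
                      padj = c(0.049, 0.05, NA))
    expect_identical(callDEMs(res), "a")
    expect_identical(callDEMs(res[0, ]), character(0))
})

test_that("contrast runner respects sites, pooling and order independence", {
    cfg <- simConfig(nMirnas = 150L, seed = 37L,
                     groups = data.frame(
                         group = c("dnPD", "CTR", "CTR", "CENT"),
                         site = c("GOE", "GOE", "UNIBO", "UNIBO"),
                         n = c(8L, 8L, 8L, 8L)))
    sim <- simulateCohort(cfg)
    x <- estimateSizeFactors(filterExpressed(sim$experiment))
    specs <- list(contrastSpec("a", "dnPD", "CTR", refSite = "UNIBO"),
                  contrastSpec("b", "dnPD", c("CTR", "CENT")))
    r1 <- runContrasts(x, specs)
    r2 <- runContrasts(x, rev(specs))
    expect_equal(r1$a, r2$a)
    expect_equal(r1$b, r2$b)
    expect_error(contrastSpec("bad", "dnPD", c("dnPD", "CTR")), "overlap")
    expect_error(runContrasts(x, list(specs[[1]], specs[[1]])),
                 "duplicate")
    expect_error(waldTest(x, contrastSpec("e", "dnPD", "CTR",
                                          testSite = "UNIBO")), "empty")
})

test_that("a dnPD-only planted effect is detected there and not in the
           centenarian contrast", {
    cfg <- simConfig(nMirnas = 400L, seed = 41L, dispersion = 0.1,
                     groups = data.frame(
                         group = c("dnPD", "CTR", "CENT"),
                         site = c("GOE", "GOE", "UNIBO"),
                         n = c(30L, 30L, 30L)),
                     deFraction = c(dnPD = 0.05),
                     deLog2fc = c(dnPD = 1.5), deBalanced = TRUE)
    sim <- simulateCohort(cfg)
    x <- estimateSizeFactors(filterExpressed(sim$experiment))
    res <- runContrasts(x, list(
        contrastSpec("dnPD_vs_CTR", "dnPD", "CTR"),
        contrastSpec("CENT_vs_CTR", "CENT", "CTR")))
    dems <- lapply(res, callDEMs)
    tr <- sim$truth$deStatus[, "dnPD"]
    planted <- names(tr)[tr != 0]
    bm <- res$dnPD_vs_CTR$baseMean[match(planted, res$dnPD_vs_CTR$mirna)]
    detectable <- planted[bm > 5]
    expect_gte(mean(detectable %in% dems$dnPD_vs_CTR), 0.8)   # power
    expect_lte(length(intersect(planted, dems$CENT_vs_CTR)),
               ceiling(0.1 * length(planted)))
})

test_that("Wald agrees with DESeq2 on strong, well-expressed signals", {
    cfg <- simConfig(nMirnas = 200L, seed = 53L, dispersion = 0.05,
                     baseMeanLogMu = log(200), baseMeanLogSd = 0.5,
                     groups = data.frame(group = c("dnPD", "CTR"),
                                         site = "GOE", n = 20L),
                     deFraction = c(dnPD = 0.2), deLog2fc = c(dnPD = 1.5),
                     deBalanced = TRUE)
    sim <- simulateCohort(cfg)
    x <- estimateSizeFactors(filterExpressed(sim$experiment))
    ours <- waldTest(x, contrastSpec("t", "dnPD", "CTR"))
    dds <- DESeq2::DESeqDataSetFromMatrix(
        counts(x),
        colData = data.frame(condition = factor(
            ifelse(x$group == "dnPD", "B", "A"))),
        design = ~condition)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    drs <- DESeq2::results(dds)
    common <- intersect(ours$mirna, rownames(drs))
    lfcO <- ours$log2fc[match(common, ours$mirna)]
    lfcD <- drs$log2FoldChange[match(common, rownames(drs))]
    expect_gt(cor(lfcO, lfcD, use = "complete.obs"), 0.98)
    tr <- sim$truth$deStatus[, "dnPD"]
    planted <- intersect(names(tr)[tr != 0], common)
    expect_lt(mean(abs(lfcO[match(planted, common)] -
                       lfcD[match(planted, common)])), 0.1)
})
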