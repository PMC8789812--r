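# Synthetic-cohort generators: negative-binomial counts with planted
# differential expression, Gaussian-copula co-expression blocks, UMI-tagged
# read records, Ct tables and miRNA-target tables with known ground truth.

#' Build a simulation configuration
#'
#' Defaults emulate the structure of a multi-site serum miRNA-seq discovery
#' cohort: 165 samples in four (group, site) blocks -- dnPD at GOE (61),
#' CTR at GOE (58) and UNIBO (19), CENT at UNIBO (27) -- and 2500 expressed
#' miRNAs. Counts are negative binomial with log-normal baseline means and
#' sample size factors; co-expression blocks are induced by a Gaussian
#' copula with block-constant latent correlation, which plants the rank
#' dependence that mutual information detects without changing NB marginals.
#'
#' @param nMirnas number of miRNAs.
#' @param groups data.frame(group, site, n); groups must come from
#'   dnPD, CTR, CENT, adPD, PDsibs; each block needs n >= 2.
#' @param depthLogSd SD of log size factors (log-normal depth model).
#' @param baseMeanLogMu,baseMeanLogSd log-normal parameters of per-miRNA
#'   baseline mean expression.
#' @param dispersion NB dispersion alpha: scalar, per-miRNA vector, or
#'   `c(shape, rate)` with `dispersionGamma = TRUE`.
#' @param dispersionGamma draw per-miRNA dispersions from a gamma law.
#' @param deFraction named numeric, per non-baseline group: fraction of
#'   miRNAs carrying a planted effect in that group.
#' @param deLog2fc named numeric, per group: planted log2 fold-change
#'   (multiplicative on the group mean, 2^beta).
#' @param deBalanced alternate the sign of planted effects (half up, half
#'   down, deterministic alternation over the selected miRNAs). Balanced
#'   designs keep median-of-ratios normalization valid; one-sided designs
#'   shift the reference medians and are useful to study exactly that.
#' @param baselineGroup reference group for planted effects (default "CTR").
#' @param moduleSpec list of `c(size, rho)`: planted co-expression blocks
#'   with intra-block latent correlation rho (0 <= rho < 1).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nMirnas = 200, seed = 1,
#'                  moduleSpec = list(c(10, 0.8)))
#' cfg
#' @export
simConfig <- function(nMirnas = 2500L,
                      groups = data.frame(
                          group = c("dnPD", "CTR", "CTR", "CENT"),
                          site = c("GOE", "GOE", "UNIBO", "UNIBO"),
                          n = c(61L, 58L, 19L, 27L)),
                      depthLogSd = 0.4,
                      baseMeanLogMu = log(20), baseMeanLogSd = 1.5,
                      dispersion = 0.2, dispersionGamma = FALSE,
                      deFraction = numeric(), deLog2fc = numeric(),
                      deBalanced = FALSE, baselineGroup = "CTR",
                      moduleSpec = list(), seed = 1L) {
    if (length(deFraction) != length(deLog2fc) ||
        !identical(sort(names(deFraction)), sort(names(deLog2fc))))
        stop("deFraction and deLog2fc must be named by the same groups")
    methods::new("SimConfig", nMirnas = as.integer(nMirnas),
                 groups = as.data.frame(groups),
                 depthLogSd = depthLogSd, baseMeanLogMu = baseMeanLogMu,
                 baseMeanLogSd = baseMeanLogSd,
                 dispersion = as.numeric(dispersion),
                 dispersionGamma = isTRUE(dispersionGamma),
                 deFraction = deFraction, deLog2fc = deLog2fc,
                 deBalanced = isTRUE(deBalanced), baselineGroup = baselineGroup,
                 moduleSpec = moduleSpec, seed = as.integer(seed))
}

#' Generate a synthetic miRNA-seq cohort with known ground truth
#'
#' Counts are drawn as NB(mean = s_j * q_i * 2^beta_ig, dispersion alpha_i).
#' Co-expression blocks are induced by an exchangeable Gaussian-copula latent
#' layer mapped through the NB quantile function per miRNA, so planted blocks
#' carry rank correlation while marginal count laws are untouched.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return list with elements
#'   \describe{
#'     \item{experiment}{[MirnaExperiment-class] of counts + annotations}
#'     \item{sampleSheet}{data.frame(sample, group, site, age, sex)}
#'     \item{truth}{list: `deStatus` (miRNA x group matrix of planted
#'       log2FC, 0 if null), `moduleMembership` (named integer, NA = none),
#'       `sizeFactors` (named numeric, geometric mean 1)}
#'   }
#' @examples
#' sim <- simulateCohort(simConfig(nMirnas = 50, seed = 7,
#'     groups = data.frame(group = c("dnPD", "CTR"), site = "GOE", n = 5)))
#' sim$experiment
#' @export
simulateCohort <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    methods::validObject(config)
    withSeed(config@seed, {
        n <- config@nMirnas
        g <- config@groups
        m <- sum(g$n)
        mirnaIds <- sprintf("miR-%04d", seq_len(n))
        group <- rep(g$group, g$n)
        site <- rep(g$site, g$n)
        sampleIds <- sprintf("S%03d_%s_%s", seq_len(m), site, group)

        q <- rlnorm(n, config@baseMeanLogMu, config@baseMeanLogSd)
        alpha <- if (config@dispersionGamma) {
            rgamma(n, shape = config@dispersion[1], rate = config@dispersion[2])
        } else if (length(config@dispersion) == 1L) {
            rep(config@dispersion, n)
        } else {
            stopifnot(length(config@dispersion) == n)
            config@dispersion
        }
        s <- rlnorm(m, 0, config@depthLogSd)
        s <- s / geometricMean(s)

        deGroups <- names(config@deFraction)
        allGroups <- unique(g$group)
        deStatus <- matrix(0, n, length(allGroups),
                           dimnames = list(mirnaIds, allGroups))
        for (gr in deGroups) {
            if (!gr %in% allGroups) stop("unknown DE group: ", gr)
            nDe <- round(config@deFraction[gr] * n)
            if (nDe > 0) {
                rows <- sample.int(n, nDe)
                eff <- rep(config@deLog2fc[gr], nDe)
                if (config@deBalanced)
                    eff <- eff * rep_len(c(1, -1), nDe)
                deStatus[rows, gr] <- eff
            }
        }
        if (length(deGroups) && !config@baselineGroup %in% allGroups)
            stop("baseline group absent from the design")

        blockId <- rep(NA_integer_, n)
        if (length(config@moduleSpec)) {
            sizes <- vapply(config@moduleSpec, `[`, numeric(1), 1L)
            if (sum(sizes) > n) stop("co-expression blocks exceed nMirnas")
            pool <- sample.int(n, sum(sizes))
            at <- 0L
            for (b in seq_along(sizes)) {
                blockId[pool[at + seq_len(sizes[b])]] <- b
                at <- at + as.integer(sizes[b])
            }
        }
        names(blockId) <- mirnaIds

        # latent copula layer: z = sqrt(rho) u_b + sqrt(1 - rho) e
        e <- matrix(rnorm(n * m), n, m)
        z <- e
        if (length(config@moduleSpec)) {
            u <- matrix(rnorm(length(config@moduleSpec) * m),
                        length(config@moduleSpec), m)
            for (b in seq_along(config@moduleSpec)) {
                rho <- config@moduleSpec[[b]][2]
                rows <- which(blockId == b)
                z[rows, ] <- sqrt(rho) * matrix(u[b, ], length(rows), m,
                                                byrow = TRUE) +
                    sqrt(1 - rho) * e[rows, , drop = FALSE]
            }
        }

        beta <- deStatus[, group, drop = FALSE]     # n x m planted log2FC
        mu <- (q * 2^beta) * matrix(s, n, m, byrow = TRUE)
        U <- pnorm(z)
        cnt <- matrix(0L, n, m, dimnames = list(mirnaIds, sampleIds))
        pois <- alpha < 1e-12
        if (any(pois))
            cnt[pois, ] <- qpois(U[pois, , drop = FALSE],
                                 lambda = mu[pois, , drop = FALSE])
        if (any(!pois))
            cnt[!pois, ] <- qnbinom(U[!pois, , drop = FALSE],
                                    mu = mu[!pois, , drop = FALSE],
                                    size = 1 / alpha[!pois])
        storage.mode(cnt) <- "integer"

        age <- round(rnorm(m, mean = ifelse(group == "CENT", 105, 66),
                           sd = ifelse(group == "CENT", 3.5, 8)))
        sex <- sample(c("M", "F"), m, replace = TRUE)
        sheet <- data.frame(sample = sampleIds, group = group, site = site,
                            age = age, sex = sex)
        se <- MirnaExperiment(cnt, sheet)
        list(experiment = se, sampleSheet = sheet,
             truth = list(deStatus = deStatus,
                          moduleMembership = blockId,
                          sizeFactors = setNames(s, sampleIds)))
    })
}

#' @importFrom stats qpois
NULL

#' Expand a count matrix into UMI-tagged read records
#'
#' The inverse of [collapseUMIs()]: for each (miRNA, sample) cell with count
#' c, emits c records with the miRNA's pseudo-sequence and c distinct UMIs,
#' each record replicated `1 + Poisson(duplicationRate)` times to mimic PCR
#' duplication. UMIs are fixed-width base-36 encodings of the molecule index,
#' so collisions within a cell are impossible by construction.
#'
#' @param x a [MirnaExperiment-class] or integer count matrix with dimnames.
#' @param duplicationRate mean number of PCR copies added per molecule
#'   (>= 0).
#' @param seed optional seed for the duplication draw.
#' @return data.frame(sample, mirna, sequence, umi), one row per read.
#' @examples
#' m <- matrix(c(3L, 0L), 1, 2, dimnames = list("miR-a", c("s1", "s2")))
#' simulateReadRecords(m, duplicationRate = 0)
#' @export
simulateReadRecords <- function(x, duplicationRate = 0, seed = NULL) {
    if (methods::is(x, "MirnaExperiment")) x <- counts(x)
    if (duplicationRate < 0) stop("duplicationRate must be >= 0")
    stopifnot(isWholeNumber(as.vector(x)), all(x >= 0))
    idx <- which(x > 0, arr.ind = TRUE)
    if (!nrow(idx)) {
        return(data.frame(sample = character(), mirna = character(),
                          sequence = character(), umi = character()))
    }
    cvec <- x[idx]
    rows <- rep(idx[, 1L], cvec)
    cols <- rep(idx[, 2L], cvec)
    rec <- data.frame(
        sample = colnames(x)[cols],
        mirna = rownames(x)[rows],
        sequence = pseudoSequence(rows),
        umi = base36(sequence(cvec)))
    withSeed(seed, {
        copies <- 1L + rpois(nrow(rec), duplicationRate)
        rec <- rec[rep(seq_len(nrow(rec)), copies), , drop = FALSE]
    })
    rownames(rec) <- NULL
    rec
}

#' Generate a synthetic qPCR Ct table with planted fold-changes
#'
#' Ct values follow `Ct = baseline(target) - log2(relative expression) +
#' N(0, noiseSd)`, independently per replicate. Planted log2 fold-changes
#' apply in every non-reference group; endogenous controls are forced to a
#' planted effect of zero so that delta-Ct normalization recovers the truth.
#'
#' @param targets character vector of assayed miRNA targets (controls are
#'   appended if absent).
#' @param groups character vector of group labels; the first is the
#'   reference.
#' @param plantedLog2fc named numeric (by target): planted log2 fold-change
#'   of test groups versus the reference; unnamed targets default to 0.
#' @param noiseSd replicate-level Ct noise SD (cycles, >= 0).
#' @param nPerGroup samples per group.
#' @param nReplicates technical qPCR replicates per (sample, target).
#' @param controls endogenous control targets (planted effect 0).
#' @param seed integer seed.
#' @return list(ct = data.frame(sample, group, target, replicate, ct) with
#'   attribute `"controls"`, truth = named planted log2FC per target).
#' @examples
#' tab <- simulateCtTable("miR-144-3p", c("CTR", "dnPD"),
#'                        plantedLog2fc = c("miR-144-3p" = -1),
#'                        noiseSd = 0, nPerGroup = 3, seed = 1)
#' head(tab$ct)
#' @export
simulateCtTable <- function(targets, groups = c("CTR", "dnPD"),
                            plantedLog2fc = numeric(), noiseSd = 0.2,
                            nPerGroup = 20L, nReplicates = 2L,
                            controls = c("miR-16-5p", "miR-93-5p",
                                         "miR-186-5p"),
                            seed = NULL) {
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    if (!length(controls)) stop("missing control targets")
    if (any(controls %in% names(plantedLog2fc)) &&
        any(plantedLog2fc[intersect(controls, names(plantedLog2fc))] != 0))
        stop("endogenous controls must have planted log2FC = 0")
    allTargets <- union(targets, controls)
    lfc <- setNames(rep(0, length(allTargets)), allTargets)
    lfc[names(plantedLog2fc)] <- plantedLog2fc
    lfc[controls] <- 0
    withSeed(seed, {
        baseline <- setNames(rnorm(length(allTargets), 25, 2), allTargets)
        grid <- expand.grid(replicate = seq_len(nReplicates),
                            target = allTargets,
                            idx = seq_len(nPerGroup), group = groups,
                            stringsAsFactors = FALSE)
        grid$sample <- sprintf("V%s_%02d", grid$group, grid$idx)
        isRef <- grid$group == groups[1]
        eff <- ifelse(isRef, 0, lfc[grid$target])
        grid$ct <- baseline[grid$target] - eff +
            rnorm(nrow(grid), 0, noiseSd)
        ct <- grid[, c("sample", "group", "target", "replicate", "ct")]
        rownames(ct) <- NULL
        attr(ct, "controls") <- controls
        list(ct = ct, truth = lfc)
    })
}

#' Generate a random miRNA-target interaction table
#'
#' A bipartite Bernoulli(density) interaction table with evidence labels
#' drawn from the closed vocabulary non-functional / weak / strong. Strong
#' rows appear with probability `strongFraction`; the remaining mass is
#' split 9:1 between weak and non-functional.
#'
#' @param mirnas miRNA ids (character) or a count to auto-name.
#' @param genes gene ids (character) or a count to auto-name.
#' @param density inclusion probability per (miRNA, gene) pair between 0 and 1.
#' @param strongFraction probability that an included row is strong.
#' @param seed integer seed.
#' @return data.frame(mirna, gene, evidence).
#' @examples
#' simulateMtiTable(3, 5, density = 0.5, strongFraction = 1, seed = 1)
#' @export
simulateMtiTable <- function(mirnas, genes, density = 0.1,
                             strongFraction = 0.2, seed = NULL) {
    if (length(mirnas) == 1L && is.numeric(mirnas))
        mirnas <- sprintf("miR-%04d", seq_len(mirnas))
    if (length(genes) == 1L && is.numeric(genes))
        genes <- sprintf("GENE%04d", seq_len(genes))
    if (!length(mirnas) || !length(genes))
        stop("degenerate table dimensions")
    if (density < 0 || density > 1 || strongFraction < 0 ||
        strongFraction > 1)
        stop("density and strongFraction must lie between 0 and 1")
    withSeed(seed, {
        keep <- which(runif(length(mirnas) * length(genes)) < density)
        if (!length(keep)) {
            return(data.frame(mirna = character(), gene = character(),
                              evidence = character()))
        }
        mi <- mirnas[((keep - 1L) %% length(mirnas)) + 1L]
        ge <- genes[((keep - 1L) %/% length(mirnas)) + 1L]
        u <- runif(length(keep))
        ev <- ifelse(u < strongFraction, "strong",
                     ifelse(u < strongFraction + 0.9 * (1 - strongFraction),
                            "weak", "non-functional"))
        data.frame(mirna = mi, gene = ge, evidence = ev)
    })
}

#' Generate random gene sets (GMT-style collections)
#'
#' Convenience generator for exercising [genesetEnrichment()]: draws sets of
#' uniform random sizes from a gene universe.
#'
#' @param genes gene universe (character) or a count to auto-name.
#' @param nSets number of sets.
#' @param minSize,maxSize set size bounds.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
simulateGeneSets <- function(genes, nSets = 10L, minSize = 5L,
                             maxSize = 50L, seed = NULL) {
    if (length(genes) == 1L && is.numeric(genes))
        genes <- sprintf("GENE%04d", seq_len(genes))
    stopifnot(minSize >= 1, maxSize >= minSize, maxSize <= length(genes))
    withSeed(seed, {
        sizes <- sample(minSize:maxSize, nSets, replace = TRUE)
        sets <- lapply(sizes, function(k) sample(genes, k))
        names(sets) <- sprintf("SET%03d", seq_len(nSets))
        sets
    })
}
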