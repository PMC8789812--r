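#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor dist median p.adjust pnorm prcomp quantile qnorm
#'   qnbinom rnorm rpois rlnorm rgamma runif rbinom sd setNames t.test var
#'   phyper complete.cases
#' @importFrom utils head read.csv read.delim write.csv write.table
#'   packageVersion combn
NULL

#' MirnaExperiment: miRNA x sample UMI counts with cohort annotations
#'
#' The pipeline's central container: a
#' [SummarizedExperiment::SummarizedExperiment] whose `"counts"` assay holds
#' non-negative integer UMI counts (rows = miRNAs, columns = samples) and
#' whose `colData` carries at least `group` and `site` labels per sample.
#' Size factors, once estimated with [estimateSizeFactors()], live in
#' `colData(x)$sizeFactor`; [normCounts()] and [logCounts()] derive the
#' normalized and log2(normalized + 1) matrices from them on demand.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [MirnaExperiment()], [estimateSizeFactors()], [normCounts()]
#' @export
setClass("MirnaExperiment", contains = "SummarizedExperiment")

setValidity("MirnaExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (!isWholeNumber(as.vector(cnt)))
            msg <- c(msg, "counts must be integer-valued")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("group", "site"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate miRNA ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if ("sizeFactor" %in% colnames(cd)) {
        sf <- cd$sizeFactor
        if (any(!is.finite(sf)) || any(sf <= 0))
            msg <- c(msg, "size factors must be positive and finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MirnaExperiment
#'
#' @param counts integer matrix, miRNAs in rows (rownames = miRNA ids),
#'   samples in columns (colnames = sample ids).
#' @param sampleData data.frame with one row per sample and at least columns
#'   `group` and `site`; rownames (or a `sample` column) must match the count
#'   matrix columns.
#' @return A [MirnaExperiment-class] object.
#' @examples
#' m <- matrix(c(0L, 3L, 5L, 2L), 2, dimnames = list(c("miR-a", "miR-b"),
#'                                                   c("s1", "s2")))
#' sd <- data.frame(group = c("dnPD", "CTR"), site = "GOE",
#'                  row.names = c("s1", "s2"))
#' MirnaExperiment(m, sd)
#' @export
MirnaExperiment <- function(counts, sampleData) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have miRNA rownames and sample colnames")
    sampleData <- as.data.frame(sampleData)
    if ("sample" %in% colnames(sampleData) &&
        !identical(rownames(sampleData), colnames(counts)))
        rownames(sampleData) <- sampleData$sample
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sampleData))
    methods::new("MirnaExperiment", se)
}

#' @describeIn MirnaExperiment-class compact display
#' @param object a `MirnaExperiment`
#' @export
setMethod("show", "MirnaExperiment", function(object) {
    cat(sprintf("MirnaExperiment: %d miRNAs x %d samples\n",
                nrow(object), ncol(object)))
    grp <- table(SummarizedExperiment::colData(object)$group)
    cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
        "\n")
    cat("size factors:",
        if ("sizeFactor" %in% colnames(SummarizedExperiment::colData(object)))
            "estimated" else "not estimated", "\n")
})

#' Simulation configuration for synthetic serum-miRNA cohorts
#'
#' Parameters of the negative-binomial / Gaussian-copula cohort generator.
#' See [simConfig()] for defaults and units.
#'
#' @slot nMirnas number of miRNAs simulated.
#' @slot groups data.frame(group, site, n): one row per (group, site) block.
#' @slot depthLogSd SD of log-normal sample size factors.
#' @slot baseMeanLogMu,baseMeanLogSd log-normal parameters of baseline means.
#' @slot dispersion per-miRNA NB dispersion alpha: a single constant, a
#'   vector of length nMirnas, or `c(shape, rate)` of a gamma law when
#'   `dispersionGamma` is TRUE.
#' @slot dispersionGamma logical; draw dispersions from a gamma law.
#' @slot deFraction named numeric: per group, fraction of miRNAs with a
#'   planted effect relative to the baseline group.
#' @slot deLog2fc named numeric: per group, the planted log2 fold-change.
#' @slot deBalanced logical; alternate the sign of planted effects (half
#'   up-, half down-regulated), the balanced design that keeps
#'   median-of-ratios normalization valid.
#' @slot baselineGroup group against which effects are planted.
#' @slot moduleSpec list of `c(size, rho)` planted co-expression blocks.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
    nMirnas = "integer", groups = "data.frame", depthLogSd = "numeric",
    baseMeanLogMu = "numeric", baseMeanLogSd = "numeric",
    dispersion = "numeric", dispersionGamma = "logical",
    deFraction = "numeric", deLog2fc = "numeric", deBalanced = "logical",
    baselineGroup = "character",
    moduleSpec = "list", seed = "integer"))

knownGroups <- c("dnPD", "CTR", "CENT", "adPD", "PDsibs")

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nMirnas < 1L) msg <- c(msg, "nMirnas must be positive")
    g <- object@groups
    if (!all(c("group", "site", "n") %in% colnames(g)))
        msg <- c(msg, "groups needs columns group, site, n")
    else {
        if (!all(g$group %in% knownGroups))
            msg <- c(msg, sprintf("unknown group(s): %s",
                paste(setdiff(g$group, knownGroups), collapse = ", ")))
        if (any(g$n < 2)) msg <- c(msg, "each (group, site) block needs n >= 2")
    }
    if (object@depthLogSd < 0) msg <- c(msg, "depthLogSd must be >= 0")
    if (!all(is.finite(object@deLog2fc)))
        msg <- c(msg, "planted log2 fold-changes must be finite")
    if (any(object@deFraction < 0 | object@deFraction > 1))
        msg <- c(msg, "deFraction must lie in [0, 1]")
    for (blk in object@moduleSpec) {
        if (length(blk) != 2 || blk[1] < 2)
            msg <- c(msg, "each moduleSpec entry is c(size >= 2, rho)")
        else if (blk[2] < 0 || blk[2] >= 1)
            msg <- c(msg, "block correlation rho must satisfy 0 <= rho < 1")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class compact display
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d miRNAs, %d samples (%d group/site blocks)\n",
                object@nMirnas, sum(object@groups$n), nrow(object@groups)))
    cat(sprintf("planted DE groups: %s; co-expression blocks: %d; seed %d\n",
                if (length(object@deFraction))
                    paste(names(object@deFraction), collapse = ", ")
                else "none",
                length(object@moduleSpec), object@seed))
})

#' Mutual-information network
#'
#' Undirected weighted network over miRNA nodes: the edges that survive the
#' independence threshold and DPI pruning, weighted by mutual information in
#' nats.
#'
#' @slot nodes character vector of node ids.
#' @slot edges data.frame(from, to, mi) with `from < to` lexically and
#'   `mi > 0`.
#' @slot eps numeric independence threshold applied.
#' @slot params list of reconstruction parameters (estimator, tau, seed, ...).
#' @seealso [applyDPI()], [buildNetwork()], [asIgraph()]
#' @export
setClass("MINetwork", representation(
    nodes = "character", edges = "data.frame", eps = "numeric",
    params = "list"))

setValidity("MINetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "mi") %in% colnames(e)))
        msg <- c(msg, "edges needs columns from, to, mi")
    else if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        if (any(e$mi <= 0)) msg <- c(msg, "edge weights must be positive")
        if (!all(e$from %in% object@nodes & e$to %in% object@nodes))
            msg <- c(msg, "edge endpoints must be declared nodes")
    }
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
    if (length(msg)) msg else TRUE
})

#' @describeIn MINetwork-class compact display
#' @param object a `MINetwork`
#' @export
setMethod("show", "MINetwork", function(object) {
    cat(sprintf("MINetwork: %d nodes, %d edges (eps = %.4g, tau = %.3g)\n",
                length(object@nodes), nrow(object@edges), object@eps,
                if (is.null(object@params$tau)) NA_real_ else
                    object@params$tau))
})

#' Community partition of an MI network
#'
#' @slot membership named integer vector: node -> community id (consecutive
#'   integers starting at 1).
#' @slot modularity weighted modularity Q of the partition at `resolution`.
#' @slot resolution the resolution parameter gamma.
#' @slot sizes integer vector of community sizes, named by community id.
#' @seealso [louvainCommunities()], [modularityScore()]
#' @export
setClass("CommunityPartition", representation(
    membership = "integer", modularity = "numeric", resolution = "numeric",
    sizes = "integer"))

setValidity("CommunityPartition", function(object) {
    msg <- character()
    if (is.null(names(object@membership)))
        msg <- c(msg, "membership must be named by node id")
    m <- object@membership
    if (length(m) && !identical(sort(unique(as.integer(m))),
                                seq_len(max(m))))
        msg <- c(msg, "community ids must be consecutive integers from 1")
    if (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9)
        msg <- c(msg, "modularity must lie in [-0.5, 1]")
    if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn CommunityPartition-class compact display
#' @param object a `CommunityPartition`
#' @export
setMethod("show", "CommunityPartition", function(object) {
    cat(sprintf(
        "CommunityPartition: %d nodes in %d communities (Q = %.4f, gamma = %g)\n",
        length(object@membership), length(object@sizes), object@modularity,
        object@resolution))
})
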