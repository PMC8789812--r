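# End-to-end orchestration: discovery (preprocessing -> differential
# expression -> selection -> per-phenotype network -> communities ->
# DEM-community integration) and validation (delta-delta-Ct qPCR of the
# candidates), with a run manifest recording parameters, hashes and
# warnings.

#' Assemble a pipeline configuration
#'
#' @param counts a [MirnaExperiment-class], or a path to a counts TSV (then
#'   `sampleSheet` must be a CSV path).
#' @param sampleSheet sample sheet path when `counts` is a path.
#' @param contrasts list of [contrastSpec()]; default [defaultContrasts()].
#' @param demAlpha DEM FDR threshold (default 0.05).
#' @param exprFloor average normalized expression floor for candidates.
#' @param topK,nUnique,manual selection-rule parameters
#'   (see [selectCandidates()]).
#' @param networkGroups phenotype cohorts to reconstruct networks for.
#' @param network a [networkParams()] list.
#' @param resolution Louvain resolution gamma.
#' @param seed global seed; stage seeds are derived from it.
#' @param outDir optional output directory for TSV artifacts.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(counts, sampleSheet = NULL,
                           contrasts = defaultContrasts(),
                           demAlpha = 0.05, exprFloor = 5,
                           topK = 2L, nUnique = 2L, manual = character(),
                           networkGroups = c("dnPD", "CENT"),
                           network = networkParams(
                               estimator = "gaussian_copula"),
                           resolution = 1, seed = 1L, outDir = NULL) {
    if (is.character(counts)) {
        if (is.null(sampleSheet))
            stop("sampleSheet path required with a counts path")
        if (!file.exists(counts) || !file.exists(sampleSheet))
            stop("input file(s) missing at run start")
    }
    structure(list(counts = counts, sampleSheet = sampleSheet,
                   contrasts = contrasts, demAlpha = demAlpha,
                   exprFloor = exprFloor, topK = topK, nUnique = nUnique,
                   manual = manual, networkGroups = networkGroups,
                   network = network, resolution = resolution,
                   seed = as.integer(seed), outDir = outDir),
              class = "PipelineConfig")
}

deriveSeed <- function(seed, k) (as.integer(seed) * 1103L + 30269L * k) %%
    2147483587L

manifestStage <- function(manifest, stage, params) {
    manifest$stages[[stage]] <- list(
        stage = stage, paramHash = objectHash(params),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    manifest
}

#' Run the discovery pipeline
#'
#' Executes preprocessing (expressed filter + normalization), the contrast
#' scheme, DEM calling, intersection analysis, candidate selection, and the
#' per-phenotype network/community stages with DEM-community integration.
#' When `config$outDir` is set, each artifact is also written as a
#' header-stamped TSV.
#'
#' @param config a [pipelineConfig()].
#' @return list: experiment, results, demSets, intersections, candidates,
#'   networks, partitions, degreeStats, integration, manifest.
#' @export
runDiscovery <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    manifest <- list(stages = list(), warnings = character(),
                     seed = config$seed,
                     version = as.character(packageVersion("miRmarker")))
    wrn <- function(w) {
        manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
    }
    withCallingHandlers(warning = wrn, {
        x <- if (is.character(config$counts))
            readCountMatrix(config$counts, config$sampleSheet)
        else config$counts
        x <- filterExpressed(x)
        x <- estimateSizeFactors(x)
        manifest <- manifestStage(manifest, "preprocess",
                                  list(n = dim(x)))

        results <- runContrasts(x, config$contrasts)
        demSets <- lapply(results, callDEMs, alpha = config$demAlpha)
        manifest <- manifestStage(manifest, "diffexpr",
                                  list(contrasts = names(results),
                                       alpha = config$demAlpha))

        tbl <- intersectionMatrix(demSets)
        tbl <- intersectionSignificance(tbl, universeSize = nrow(x),
                                        seed = deriveSeed(config$seed, 1L))
        candidates <- selectCandidates(results, demSets, tbl,
                                       exprFloor = config$exprFloor,
                                       topK = config$topK,
                                       nUnique = config$nUnique,
                                       manual = config$manual)
        manifest <- manifestStage(manifest, "selection",
                                  list(floor = config$exprFloor,
                                       topK = config$topK,
                                       nUnique = config$nUnique))

        networks <- list()
        partitions <- list()
        degreeStats <- list()
        integration <- list()
        for (g in config$networkGroups) {
            np <- config$network
            np$seed <- deriveSeed(config$seed, 2L + match(g,
                                  config$networkGroups))
            net <- buildNetwork(x, g, np)
            part <- louvainCommunities(net, resolution = config$resolution,
                                       seed = np$seed)
            networks[[g]] <- net
            partitions[[g]] <- part
            degreeStats[[g]] <- nodeDegrees(net, part)
            integration[[g]] <- integrateDEMs(part, demSets)
        }
        manifest <- manifestStage(manifest, "network",
                                  list(groups = config$networkGroups,
                                       params = unclass(config$network),
                                       resolution = config$resolution))

        if (!is.null(config$outDir)) {
            dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
            h <- objectHash(unclass(config)[setdiff(names(config),
                                                    c("counts"))])
            out <- function(f) file.path(config$outDir, f)
            for (nm in names(results))
                writeResultTable(results[[nm]],
                                 out(sprintf("de_%s.tsv", nm)),
                                 seed = config$seed, paramHash = h)
            writeResultTable(tbl[, setdiff(colnames(tbl), "members")],
                             out("intersections.tsv"),
                             seed = config$seed, paramHash = h)
            writeResultTable(candidates, out("candidates.tsv"),
                             seed = config$seed, paramHash = h)
            for (g in names(networks)) {
                writeResultTable(miEdges(networks[[g]]),
                                 out(sprintf("network_%s.tsv", g)),
                                 seed = config$seed, paramHash = h)
                part <- partitions[[g]]
                writeResultTable(
                    data.frame(node = names(membershipVector(part)),
                               community = membershipVector(part)),
                    out(sprintf("communities_%s.tsv", g)),
                    seed = config$seed, paramHash = h)
                writeResultTable(degreeStats[[g]],
                                 out(sprintf("degrees_%s.tsv", g)),
                                 seed = config$seed, paramHash = h)
                writeResultTable(integration[[g]]$overlaps,
                                 out(sprintf("integration_%s.tsv", g)),
                                 seed = config$seed, paramHash = h)
            }
            manifest$outputs <- tools::md5sum(
                list.files(config$outDir, full.names = TRUE))
        }
    })
    list(experiment = x, results = results, demSets = demSets,
         intersections = tbl, candidates = candidates, networks = networks,
         partitions = partitions, degreeStats = degreeStats,
         integration = integration, manifest = manifest)
}

#' Run the qPCR validation pipeline
#'
#' Relative quantification of every candidate target for each test group
#' against the reference, with BH correction and the vendor significance
#' rule. Candidates absent from the Ct table are reported, not fatal.
#'
#' @param ct long Ct table (see [readCtTable()]).
#' @param candidates character vector of candidate targets.
#' @param testGroups character vector of test group labels.
#' @param referenceGroup reference group label(s); a vector pools groups.
#' @param controls endogenous control targets; defaults to the table's
#'   `"controls"` attribute.
#' @param welch use Welch's t-test.
#' @return list(results = combined data.frame with a testGroup column,
#'   missing = candidates absent from the table).
#' @export
runValidation <- function(ct, candidates, testGroups, referenceGroup,
                          controls = attr(ct, "controls"), welch = FALSE) {
    if (is.null(controls) || !length(controls))
        stop("endogenous controls must be declared")
    if (!length(candidates)) {
        warning("empty candidate list")
        return(list(results = data.frame(), missing = character()))
    }
    missing <- setdiff(candidates, unique(ct$target))
    present <- intersect(candidates, unique(ct$target))
    if (length(missing))
        message("candidate(s) absent from the Ct table: ",
                paste(missing, collapse = ", "))
    keep <- ct$target %in% c(present, controls)
    agg <- aggregateReplicates(ct[keep, , drop = FALSE])
    dct <- deltaCt(agg, controls)
    res <- lapply(testGroups, function(tg) {
        r <- rqTest(dct, tg, referenceGroup, welch = welch)
        data.frame(testGroup = tg, r)
    })
    list(results = do.call(rbind, res), missing = missing)
}
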