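# Plain-text readers and writers for the pipeline's external interfaces:
# count matrix TSV (first column the miRNA id), sample sheet CSV, read
# record TSV, Ct long CSV, MTI TSV, and GMT gene-set collections.

#' Read a count matrix and sample sheet into a MirnaExperiment
#'
#' @param countsFile TSV, first column miRNA id, remaining columns samples.
#' @param sampleSheetFile CSV with columns sample, group, site (age and sex
#'   optional).
#' @return a [MirnaExperiment-class].
#' @export
readCountMatrix <- function(countsFile, sampleSheetFile) {
    tab <- read.delim(countsFile, check.names = FALSE, comment.char = "#")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    storage.mode(m) <- "integer"
    sheet <- read.csv(sampleSheetFile, comment.char = "#")
    MirnaExperiment(m, sheet)
}

# File header recording provenance; every pipeline output starts with it.
outputHeader <- function(seed = NULL, paramHash = NULL) {
    sprintf("# miRmarker %s%s%s",
            as.character(packageVersion("miRmarker")),
            if (!is.null(seed)) sprintf(" | seed %s", seed) else "",
            if (!is.null(paramHash)) sprintf(" | params %s", paramHash)
            else "")
}

#' Write a MirnaExperiment to TSV + CSV
#'
#' @param x a [MirnaExperiment-class].
#' @param countsFile,sampleSheetFile output paths.
#' @param seed,paramHash optional provenance recorded in a header comment.
#' @return invisibly, the two paths.
#' @export
writeCountMatrix <- function(x, countsFile, sampleSheetFile = NULL,
                             seed = NULL, paramHash = NULL) {
    hdr <- outputHeader(seed, paramHash)
    con <- file(countsFile, "w")
    writeLines(hdr, con)
    tab <- data.frame(mirna = rownames(x), counts(x), check.names = FALSE)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    if (!is.null(sampleSheetFile)) {
        cd <- as.data.frame(SummarizedExperiment::colData(x))
        cd <- data.frame(sample = colnames(x), cd, check.names = FALSE)
        con <- file(sampleSheetFile, "w")
        writeLines(hdr, con)
        suppressWarnings(write.csv(cd, con, quote = FALSE,
                                   row.names = FALSE))
        close(con)
    }
    invisible(c(countsFile, sampleSheetFile))
}

#' Write a generic pipeline table with a provenance header
#'
#' @param tab data.frame (list-columns are collapsed with ";").
#' @param file output path; tab-separated.
#' @param seed,paramHash optional provenance.
#' @return invisibly, the path.
#' @export
writeResultTable <- function(tab, file, seed = NULL, paramHash = NULL) {
    listCols <- vapply(tab, is.list, logical(1))
    for (cl in which(listCols))
        tab[[cl]] <- vapply(tab[[cl]], paste, character(1), collapse = ";")
    con <- file(file, "w")
    writeLines(outputHeader(seed, paramHash), con)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    invisible(file)
}

#' Read UMI-tagged read records
#'
#' @param file TSV with columns sample, mirna, sequence, umi.
#' @return data.frame suitable for [collapseUMIs()].
#' @export
readReadRecords <- function(file) {
    read.delim(file, comment.char = "#",
               colClasses = c("character", "character", "character",
                              "character"))
}

#' Read a long-format Ct table
#'
#' @param file CSV with columns sample, group, target, replicate, ct.
#' @param controls declared endogenous control targets (attached as the
#'   `"controls"` attribute).
#' @return data.frame for [aggregateReplicates()].
#' @export
readCtTable <- function(file, controls = character()) {
    ct <- read.csv(file, comment.char = "#")
    attr(ct, "controls") <- controls
    ct
}

#' Read a miRNA-target interaction TSV
#'
#' @param file TSV with columns mirna, gene, evidence.
#' @return normalized MTI table (see [normalizeMti()]).
#' @export
readMtiTable <- function(file) {
    normalizeMti(read.delim(file, comment.char = "#"))
}

#' Read gene sets from a GMT file
#'
#' @param file GMT path (set name, description, genes...).
#' @return named list of character vectors.
#' @export
readGmt <- function(file) {
    fgsea::gmtPathways(file)
}

#' Write gene sets to a GMT file
#'
#' @param genesets named list of character vectors.
#' @param file output path.
#' @param description description column (recycled).
#' @return invisibly, the path.
#' @export
writeGmt <- function(genesets, file, description = "na") {
    lines <- vapply(names(genesets), function(nm)
        paste(c(nm, description, genesets[[nm]]), collapse = "\t"),
        character(1))
    writeLines(lines, file)
    invisible(file)
}
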