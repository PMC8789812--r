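# Preprocessing: UMI collapse, expressed-miRNA filter, median-of-ratios
# normalization, and PCA quality control.

#' Collapse UMI-tagged read records into a count matrix
#'
#' Per (sample, miRNA), the count is the number of distinct (sequence, UMI)
#' pairs: every set of reads sharing the same sequence and the same UMI
#' collapses to a single molecule. Deduplication is scoped per sample.
#'
#' @param records data.frame with columns sample, mirna, sequence, umi.
#' @param sampleSheet optional data.frame(sample, group, site, ...) declaring
#'   the full sample set (samples without reads get zero columns). When
#'   omitted, samples observed in `records` are used with group/site "NA".
#' @param mirnaIds optional character vector declaring the full miRNA set
#'   (rows without reads are all-zero).
#' @return a [MirnaExperiment-class].
#' @examples
#' rec <- data.frame(sample = "s1", mirna = "miR-a",
#'                   sequence = "ACGU", umi = c("U1", "U1", "U1", "U2"))
#' counts(collapseUMIs(rec))   # 2: three U1 reads collapse to one molecule
#' @export
collapseUMIs <- function(records, sampleSheet = NULL, mirnaIds = NULL) {
    req <- c("sample", "mirna", "sequence", "umi")
    if (!all(req %in% colnames(records)))
        stop("records must have columns ", paste(req, collapse = ", "))
    bad <- which(!nzchar(as.character(records$sequence)) |
                 !nzchar(as.character(records$umi)) |
                 is.na(records$sequence) | is.na(records$umi))
    if (length(bad))
        stop("malformed record(s) at index: ",
             paste(head(bad, 5L), collapse = ", "))
    if (is.null(sampleSheet)) {
        samples <- sort(unique(as.character(records$sample)))
        sampleSheet <- data.frame(sample = samples, group = NA_character_,
                                  site = NA_character_)
    }
    samples <- as.character(sampleSheet$sample)
    if (nrow(records) && !all(records$sample %in% samples))
        stop("records name samples absent from the sample sheet")
    if (is.null(mirnaIds))
        mirnaIds <- sort(unique(as.character(records$mirna)))
    if (length(mirnaIds) == 0L)
        stop("no miRNA ids declared and no records supplied")

    cnt <- matrix(0L, length(mirnaIds), length(samples),
                  dimnames = list(mirnaIds, samples))
    if (nrow(records)) {
        dedup <- unique(records[, req])
        tab <- table(factor(dedup$mirna, levels = mirnaIds),
                     factor(dedup$sample, levels = samples))
        cnt[] <- as.integer(tab)
    }
    rownames(sampleSheet) <- samples
    MirnaExperiment(cnt, sampleSheet)
}

#' Keep miRNAs expressed in at least one sample
#'
#' Retains exactly the rows with UMI count > 0 in at least one sample; the
#' column set is unchanged. Idempotent.
#'
#' @param x a [MirnaExperiment-class].
#' @return the filtered [MirnaExperiment-class].
#' @export
filterExpressed <- function(x) {
    stopifnot(methods::is(x, "MirnaExperiment"))
    keep <- rowSums(counts(x) > 0) > 0
    x[keep, ]
}

#' Median-of-ratios size factors
#'
#' Estimates per-sample sequencing-depth factors s_j as the median over
#' reference rows of counts_ij / geomean_i, where the reference rows are
#' those with all-positive counts (the standard median-of-ratios
#' convention; no further rescaling, so scaling one sample's column by c
#' scales its factor by exactly c). With `pseudoReference = TRUE`, row
#' geometric means are computed over positive entries only and each sample's
#' median runs over its positive counts -- a fallback for sparse matrices
#' with no all-positive row.
#'
#' @param x a [MirnaExperiment-class].
#' @param pseudoReference use the positive-entry pseudo-reference fallback.
#' @param excludePrefix rows whose id starts with this prefix (spike-ins)
#'   are ignored when computing the factors; `NULL` disables.
#' @return `x` with size factors set (see [sizeFactors()]).
#' @examples
#' m <- matrix(c(2L, 2L, 8L, 8L), 2, dimnames = list(c("g1", "g2"),
#'                                                   c("a", "b")))
#' sd <- data.frame(group = "CTR", site = "GOE", row.names = c("a", "b"))
#' sizeFactors(estimateSizeFactors(MirnaExperiment(m, sd)))  # 0.5, 2
#' @export
estimateSizeFactors <- function(x, pseudoReference = FALSE,
                                excludePrefix = "spike") {
    stopifnot(methods::is(x, "MirnaExperiment"))
    cnt <- counts(x)
    if (!is.null(excludePrefix)) {
        keep <- !startsWith(rownames(cnt), excludePrefix)
        cnt <- cnt[keep, , drop = FALSE]
    }
    lc <- log(cnt)
    if (!pseudoReference) {
        usable <- rowSums(cnt > 0) == ncol(cnt)
        if (!any(usable))
            stop("no miRNA is positive in all samples; re-run with ",
                 "pseudoReference = TRUE")
        geo <- rowMeans(lc[usable, , drop = FALSE])
        sf <- apply(lc[usable, , drop = FALSE], 2L,
                    function(col) exp(median(col - geo)))
    } else {
        geo <- apply(lc, 1L, function(r) mean(r[is.finite(r)]))
        ok <- is.finite(geo)
        sf <- apply(lc[ok, , drop = FALSE], 2L, function(col) {
            d <- col - geo[ok]
            exp(median(d[is.finite(d)]))
        })
    }
    sizeFactors(x) <- sf
    x
}

#' PCA quality control on log-normalized counts
#'
#' Principal components of the samples computed on the
#' `log2(normalized + 1)` matrix restricted to the most variable miRNAs.
#' Coordinates are centered; a diagnostic, not an inferential, transform.
#'
#' @param x a [MirnaExperiment-class] with size factors estimated.
#' @param nTopVariance number of top-variance rows used (default 500,
#'   capped at the row count).
#' @return list with `coordinates` (samples x PCs, centered),
#'   `explainedVariance` (per-PC variances) and `percentVar`.
#' @export
pcaQC <- function(x, nTopVariance = 500L) {
    stopifnot(methods::is(x, "MirnaExperiment"))
    if (ncol(x) < 3L) stop("PCA QC needs at least 3 samples")
    lm <- logCounts(x)
    rv <- apply(lm, 1L, var)
    top <- head(order(rv, decreasing = TRUE), min(nTopVariance, nrow(lm)))
    p <- prcomp(t(lm[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
    list(coordinates = p$x,
         explainedVariance = p$sdev^2,
         percentVar = p$sdev^2 / sum(p$sdev^2))
}
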