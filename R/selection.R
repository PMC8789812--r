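# Candidate-marker selection: exclusive (UpSet-style) DEM intersections,
# Monte-Carlo intersection significance, and the two selection rules
# (shared between the most significant contrasts / most significant and
# unique to a contrast), under an average-expression floor.

# Integer subset code of a logical membership matrix row (k <= 30 sets).
subsetCode <- function(memb) {
    as.integer(memb %*% 2^(seq_along(memb) - 1L))
}

#' Exclusive intersection table of DEM sets
#'
#' UpSet-style decomposition: for every non-empty family of contrasts, the
#' members belonging to exactly that family (and to no other set). The
#' exclusive rows partition the union of all sets.
#'
#' @param demSets named list of character vectors (one per contrast).
#' @param minDisplay rows smaller than this are flagged `belowDisplay`
#'   (kept in the table); mirrors plotting cutoffs.
#' @return data.frame(sets, degree, size, members, belowDisplay); `sets` is
#'   a "A+B"-style label, `members` a list-column of miRNA ids.
#' @examples
#' tb <- intersectionMatrix(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' tb[, c("sets", "size")]
#' @export
intersectionMatrix <- function(demSets, minDisplay = 10L) {
    if (length(demSets) < 2L) stop("need at least 2 DEM sets")
    if (is.null(names(demSets)) || anyDuplicated(names(demSets)))
        stop("duplicate or missing contrast names")
    k <- length(demSets)
    universe <- sort(unique(unlist(demSets)))
    memb <- vapply(demSets, function(s) universe %in% s,
                   logical(length(universe)))
    if (!is.matrix(memb)) memb <- matrix(memb, nrow = length(universe))
    codes <- as.integer(memb %*% 2^(0:(k - 1L)))
    combos <- lapply(seq_len(k), function(d)
        combn(k, d, simplify = FALSE))
    combos <- unlist(combos, recursive = FALSE)
    rows <- lapply(combos, function(idx) {
        code <- sum(2^(idx - 1L))
        mem <- universe[codes == code]
        data.frame(sets = paste(names(demSets)[idx], collapse = "+"),
                   degree = length(idx), size = length(mem))
    })
    out <- do.call(rbind, rows)
    out$members <- lapply(combos, function(idx) {
        code <- sum(2^(idx - 1L))
        universe[codes == code]
    })
    out$belowDisplay <- out$size < minDisplay
    attr(out, "setNames") <- names(demSets)
    attr(out, "setSizes") <- vapply(demSets, length, integer(1))
    attr(out, "unionSize") <- length(universe)
    out
}

#' Monte-Carlo significance of exclusive intersections
#'
#' Under the null, sets of the observed sizes are drawn independently and
#' uniformly from a universe of `universeSize` ids; the p-value of each
#' exclusive intersection row is `P(size >= observed)` with the add-one
#' Monte-Carlo estimator. For two-set families the hypergeometric tail of
#' the pairwise overlap is the exact reference (`pHyper` column).
#'
#' @param table an [intersectionMatrix()] result.
#' @param universeSize number of ids the sets were drawn from (>= every
#'   set size).
#' @param nDraws Monte-Carlo draws (default 10000).
#' @param seed integer seed.
#' @return the table with columns `p` and (degree-2 rows) `pHyper`.
#' @export
intersectionSignificance <- function(table, universeSize, nDraws = 10000L,
                                     seed = NULL) {
    sizes <- attr(table, "setSizes")
    if (is.null(sizes)) stop("table must come from intersectionMatrix()")
    if (universeSize < max(sizes) || universeSize < attr(table, "unionSize"))
        stop("universe smaller than the observed sets")
    k <- length(sizes)
    codes <- vapply(strsplit(table$sets, "+", fixed = TRUE), function(nm)
        sum(2^(match(nm, attr(table, "setNames")) - 1L)), numeric(1))
    exceed <- integer(nrow(table))
    withSeed(seed, {
        for (b in seq_len(nDraws)) {
            cvec <- integer(universeSize)
            for (j in seq_len(k)) {
                drawn <- sample.int(universeSize, sizes[j])
                cvec[drawn] <- cvec[drawn] + 2L^(j - 1L)
            }
            tab <- tabulate(factor(cvec[cvec > 0L], levels = codes),
                            nbins = nrow(table))
            exceed <- exceed + (tab >= table$size)
        }
    })
    table$p <- (1 + exceed) / (nDraws + 1)
    # exact pairwise reference: hypergeometric tail on the plain overlap
    table$pHyper <- NA_real_
    pairRows <- which(table$degree == 2L)
    for (r in pairRows) {
        idx <- which(bitwAnd(2^(seq_len(k) - 1L), codes[r]) > 0)
        ov <- sum(table$size[bitwAnd(codes, codes[r]) == codes[r]])
        table$pHyper[r] <- phyper(ov - 1L, sizes[idx[1]],
                                  universeSize - sizes[idx[1]],
                                  sizes[idx[2]], lower.tail = FALSE)
    }
    table
}

#' Select candidate marker miRNAs
#'
#' Codifies the two selection rules: (i) all DEMs in the `topK` most
#' significant multi-contrast exclusive intersections; (ii) per contrast,
#' the `nUnique` smallest-padj DEMs exclusive to that contrast (ties broken
#' by |log2fc| then id). Manually curated additions (e.g. literature
#' inflamma-miRs) are merged with reason "manual". Every candidate must
#' pass the average normalized expression floor.
#'
#' @param results named list of [waldTest()] results (one per contrast).
#' @param demSets named list of DEM id vectors, same names as `results`.
#' @param sigTable an [intersectionSignificance()] table for `demSets`.
#' @param exprFloor minimum baseMean (normalized counts, default 5).
#' @param topK number of top multi-contrast intersections for rule (i).
#' @param nUnique DEMs kept per single-contrast row for rule (ii).
#' @param manual character vector of manual additions.
#' @return data.frame(mirna, reason, contrasts, baseMean, flagged);
#'   `flagged` marks manual ids absent from the tested matrix.
#' @export
selectCandidates <- function(results, demSets, sigTable, exprFloor = 5,
                             topK = 2L, nUnique = 2L,
                             manual = character()) {
    stopifnot(identical(sort(names(results)), sort(names(demSets))))
    baseMean <- do.call(rbind, lapply(results, function(r)
        r[, c("mirna", "baseMean")]))
    bm <- tapply(baseMean$baseMean, baseMean$mirna, max)
    padjOf <- function(contrast, ids) {
        r <- results[[contrast]]
        r$padj[match(ids, r$mirna)]
    }
    lfcOf <- function(contrast, ids) {
        r <- results[[contrast]]
        abs(r$log2fc[match(ids, r$mirna)])
    }

    cand <- data.frame(mirna = character(), reason = character(),
                       contrasts = character(), stringsAsFactors = FALSE)
    # rule (i): top-K most significant multi-contrast exclusive rows
    multi <- sigTable[sigTable$degree >= 2L & sigTable$size > 0, ]
    if (nrow(multi) && topK > 0) {
        ord <- order(multi$p, -multi$size)
        take <- head(ord, topK)
        for (r in take) {
            cand <- rbind(cand, data.frame(
                mirna = multi$members[[r]],
                reason = "shared_top_intersections",
                contrasts = multi$sets[r]))
        }
    }
    # rule (ii): most significant DEMs unique to each contrast
    single <- sigTable[sigTable$degree == 1L & sigTable$size > 0, ]
    for (r in seq_len(nrow(single))) {
        ids <- single$members[[r]]
        ctr <- single$sets[r]
        ord <- order(padjOf(ctr, ids), -lfcOf(ctr, ids), ids)
        cand <- rbind(cand, data.frame(
            mirna = head(ids[ord], nUnique),
            reason = "top_unique", contrasts = ctr))
    }
    if (length(manual)) {
        cand <- rbind(cand, data.frame(mirna = manual, reason = "manual",
                                       contrasts = ""))
    }
    cand$flagged <- !(cand$mirna %in% names(bm))
    if (any(cand$flagged & cand$reason != "manual"))
        stop("non-manual candidate absent from results")
    if (any(cand$flagged))
        warning("manual candidate(s) absent from the matrix: ",
                paste(cand$mirna[cand$flagged], collapse = ", "))
    cand$baseMean <- unname(bm[cand$mirna])
    # expression floor (manual-but-absent rows kept, flagged)
    keep <- cand$flagged | (!is.na(cand$baseMean) &
                            cand$baseMean >= exprFloor)
    cand <- cand[keep, , drop = FALSE]
    # deduplicate, merging reasons/contrasts
    if (nrow(cand)) {
        agg <- lapply(split(cand, cand$mirna), function(d) data.frame(
            mirna = d$mirna[1],
            reason = paste(sort(unique(d$reason)), collapse = ";"),
            contrasts = paste(sort(unique(d$contrasts[nzchar(d$contrasts)])),
                              collapse = ";"),
            flagged = any(d$flagged), baseMean = d$baseMean[1]))
        cand <- do.call(rbind, agg)
        rownames(cand) <- NULL
    }
    cand
}
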