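# miRNA-target interaction handling and over-representation analysis:
# evidence-class tallies, hypergeometric target enrichment for a miRNA
# list, gene-set enrichment of target genes, and disease-association
# annotation -- all against user-supplied tables.

mtiVocabulary <- c("non-functional", "weak", "strong")

#' Normalize and validate an MTI table
#'
#' Lower-cases the evidence vocabulary (`non-functional`, `weak`,
#' `strong`), strips `"functional"` qualifiers, and drops duplicate
#' (mirna, gene, evidence) rows.
#'
#' @param table data.frame with columns mirna, gene, evidence.
#' @return the normalized table.
#' @export
normalizeMti <- function(table) {
    req <- c("mirna", "gene", "evidence")
    if (!all(req %in% colnames(table)))
        stop("MTI table needs columns ", paste(req, collapse = ", "))
    ev <- tolower(trimws(as.character(table$evidence)))
    ev[grepl("^non", ev)] <- "non-functional"
    ev[grepl("^strong", ev)] <- "strong"
    ev[grepl("^weak", ev)] <- "weak"
    bad <- setdiff(unique(ev), mtiVocabulary)
    if (length(bad))
        stop("unknown evidence class(es): ", paste(bad, collapse = ", "))
    out <- data.frame(mirna = table$mirna, gene = table$gene, evidence = ev)
    unique(out)
}

#' Tally target genes of a miRNA per evidence class
#'
#' Distinct target-gene counts per evidence class; a gene supported by
#' several classes counts once in each.
#'
#' @param table an MTI table (normalized on the fly).
#' @param mirna miRNA id.
#' @return named integer vector (non-functional, weak, strong).
#' @export
classifyMti <- function(table, mirna) {
    tb <- normalizeMti(table)
    out <- setNames(integer(3), mtiVocabulary)
    rows <- tb[tb$mirna == mirna, , drop = FALSE]
    if (!nrow(rows)) {
        warning("miRNA not present in the MTI table: ", mirna)
        return(out)
    }
    cnt <- vapply(mtiVocabulary, function(ev)
        length(unique(rows$gene[rows$evidence == ev])), integer(1))
    out[names(cnt)] <- cnt
    out
}

#' Hypergeometric target enrichment for a miRNA list
#'
#' Per gene g: population = distinct miRNAs in the (evidence-filtered)
#' table, successes = miRNAs targeting g, draws = the miRNAs of the list
#' present in the population, observed = targeting miRNAs in the list.
#' `p = P(X >= k)` (hypergeometric upper tail), BH across genes. Enriched
#' genes require `k >= minInteractions` and `fdr < fdrThreshold`.
#'
#' @param mirnaList character vector of query miRNAs.
#' @param table MTI table.
#' @param minInteractions minimum interactions from the list (default 2).
#' @param fdrThreshold FDR cutoff for the `enriched` flag (default 0.05).
#' @param strongOnly keep only strong-evidence interactions (default TRUE).
#' @return data.frame(gene, hits, targetingMirnas, expected, p, fdr,
#'   enriched, mirnas), one row per gene with >= 1 hit.
#' @export
targetEnrichment <- function(mirnaList, table, minInteractions = 2L,
                             fdrThreshold = 0.05, strongOnly = TRUE) {
    if (!length(mirnaList)) stop("empty miRNA list")
    tb <- normalizeMti(table)
    if (strongOnly) tb <- tb[tb$evidence == "strong", , drop = FALSE]
    tb <- unique(tb[, c("mirna", "gene")])
    population <- unique(tb$mirna)
    M <- length(population)
    listIn <- intersect(unique(mirnaList), population)
    nDraws <- length(listIn)
    if (!nDraws) {
        warning("miRNA list disjoint from the MTI table namespace")
        return(data.frame(gene = character(), hits = integer(),
                          targetingMirnas = integer(), expected = numeric(),
                          p = numeric(), fdr = numeric(),
                          enriched = logical(), mirnas = character()))
    }
    byGene <- split(tb$mirna, tb$gene)
    rows <- lapply(names(byGene), function(g) {
        targeting <- byGene[[g]]
        K <- length(targeting)
        hitMirnas <- intersect(targeting, listIn)
        k <- length(hitMirnas)
        if (k == 0L) return(NULL)
        data.frame(gene = g, hits = k, targetingMirnas = K,
                   expected = nDraws * K / M,
                   p = phyper(k - 1L, K, M - K, nDraws, lower.tail = FALSE),
                   mirnas = paste(sort(hitMirnas), collapse = ";"))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(gene = character(), hits = integer(),
                          targetingMirnas = integer(), expected = numeric(),
                          p = numeric(), fdr = numeric(),
                          enriched = logical(), mirnas = character()))
    out$fdr <- adjustBH(out$p)
    out$enriched <- out$hits >= minInteractions & out$fdr < fdrThreshold
    out <- out[order(out$p, out$gene),
               c("gene", "hits", "targetingMirnas", "expected", "p", "fdr",
                 "enriched", "mirnas")]
    rownames(out) <- NULL
    out
}

#' Gene-set over-representation of a gene list
#'
#' One-sided hypergeometric test per set against a declared universe, BH
#' across sets.
#'
#' @param genes character vector of query genes (must lie in `universe`).
#' @param genesets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of background genes.
#' @return data.frame(set, setSize, hits, expected, p, fdr, genes).
#' @export
genesetEnrichment <- function(genes, genesets, universe) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(universe)
    genes <- unique(genes)
    if (!all(genes %in% universe))
        stop("query genes must be contained in the universe")
    N <- length(universe)
    n <- length(genes)
    rows <- lapply(names(genesets), function(nm) {
        set <- intersect(unique(genesets[[nm]]), universe)
        K <- length(set)
        hit <- intersect(genes, set)
        k <- length(hit)
        data.frame(set = nm, setSize = K, hits = k, expected = n * K / N,
                   p = if (K) phyper(k - 1L, K, N - K, n,
                                     lower.tail = FALSE) else 1,
                   genes = paste(sort(hit), collapse = ";"))
    })
    out <- do.call(rbind, rows)
    out$fdr <- adjustBH(out$p)
    out <- out[order(out$p, out$set),
               c("set", "setSize", "hits", "expected", "p", "fdr", "genes")]
    rownames(out) <- NULL
    out
}

#' Disease-association annotation of a miRNA
#'
#' Deduplicates and filters a user-supplied association table and reports
#' the associations with summary counts (total, causal).
#'
#' @param mirna miRNA id.
#' @param associationTable data.frame(mirna, disease, causal).
#' @return list(associations = filtered rows, total, causal).
#' @export
annotateDisease <- function(mirna, associationTable) {
    req <- c("mirna", "disease", "causal")
    if (!all(req %in% colnames(associationTable)))
        stop("association table needs columns ",
             paste(req, collapse = ", "))
    tb <- unique(associationTable[, req])
    rows <- tb[tb$mirna == mirna, , drop = FALSE]
    rownames(rows) <- NULL
    list(associations = rows, total = nrow(rows),
         causal = sum(as.logical(rows$causal)))
}

#' Map a miRNA list onto pathway gene sets through its targets
#'
#' The tabular counterpart of a miRNA-augmented pathway diagram: for each
#' pathway, the pathway genes that are (strong-evidence) targets of a
#' miRNA in the list, with the repressing miRNAs.
#'
#' @param mirnaList character vector of miRNAs.
#' @param table MTI table.
#' @param genesets named list of pathway gene sets.
#' @param strongOnly restrict to strong-evidence interactions.
#' @return data.frame(pathway, gene, mirnas).
#' @export
augmentPathways <- function(mirnaList, table, genesets, strongOnly = TRUE) {
    tb <- normalizeMti(table)
    if (strongOnly) tb <- tb[tb$evidence == "strong", , drop = FALSE]
    tb <- tb[tb$mirna %in% mirnaList, c("mirna", "gene")]
    rows <- lapply(names(genesets), function(nm) {
        hit <- tb[tb$gene %in% genesets[[nm]], , drop = FALSE]
        if (!nrow(hit)) return(NULL)
        byGene <- split(hit$mirna, hit$gene)
        data.frame(pathway = nm, gene = names(byGene),
                   mirnas = vapply(byGene, function(m)
                       paste(sort(unique(m)), collapse = ";"),
                       character(1)))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(pathway = character(), gene = character(),
                          mirnas = character())
    rownames(out) <- NULL
    out
}
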