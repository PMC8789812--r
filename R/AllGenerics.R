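#' @importFrom BiocGenerics counts sizeFactors sizeFactors<-
NULL

#' Accessors for MirnaExperiment
#'
#' `counts()` returns the raw UMI count matrix; `sizeFactors()` the estimated
#' per-sample size factors (error if not yet estimated); `normCounts()` the
#' size-factor-normalized matrix; `logCounts()` its log2(x + 1) transform.
#'
#' @param object,x a [MirnaExperiment-class]
#' @param value numeric vector of positive size factors, one per sample
#' @return matrices (miRNA x sample) or a numeric vector of size factors.
#' @name mirna-accessors
NULL

#' @rdname mirna-accessors
#' @export
setMethod("counts", "MirnaExperiment", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

#' @rdname mirna-accessors
#' @export
setMethod("sizeFactors", "MirnaExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"sizeFactor" %in% colnames(cd))
        stop("size factors not estimated; call estimateSizeFactors() first")
    setNames(cd$sizeFactor, colnames(object))
})

#' @rdname mirna-accessors
#' @export
setReplaceMethod("sizeFactors", "MirnaExperiment", function(object, value) {
    stopifnot(length(value) == ncol(object), all(value > 0))
    SummarizedExperiment::colData(object)$sizeFactor <- as.numeric(value)
    methods::validObject(object)
    object
})

#' @rdname mirna-accessors
#' @export
setGeneric("normCounts", function(object) standardGeneric("normCounts"))

#' @rdname mirna-accessors
#' @export
setMethod("normCounts", "MirnaExperiment", function(object) {
    sweep(counts(object), 2L, sizeFactors(object), "/")
})

#' @rdname mirna-accessors
#' @export
setGeneric("logCounts", function(object) standardGeneric("logCounts"))

#' @rdname mirna-accessors
#' @export
setMethod("logCounts", "MirnaExperiment", function(object) {
    log2(normCounts(object) + 1)
})

#' Edge table and igraph view of an MINetwork
#'
#' @param object an [MINetwork-class]
#' @return `miEdges()` the edge data.frame (from, to, mi); `asIgraph()` an
#'   undirected weighted [igraph::igraph] including isolated nodes.
#' @export
setGeneric("miEdges", function(object) standardGeneric("miEdges"))

#' @rdname miEdges
#' @export
setMethod("miEdges", "MINetwork", function(object) object@edges)

#' @rdname miEdges
#' @export
setGeneric("asIgraph", function(object) standardGeneric("asIgraph"))

#' @rdname miEdges
#' @export
setMethod("asIgraph", "MINetwork", function(object) {
    e <- object@edges
    g <- igraph::graph_from_data_frame(
        data.frame(from = e$from, to = e$to, weight = e$mi),
        directed = FALSE,
        vertices = data.frame(name = object@nodes))
    g
})

#' Membership accessor for CommunityPartition
#'
#' @param object a [CommunityPartition-class]
#' @return named integer vector node -> community id.
#' @export
setGeneric("membershipVector",
           function(object) standardGeneric("membershipVector"))

#' @rdname membershipVector
#' @export
setMethod("membershipVector", "CommunityPartition",
          function(object) object@membership)
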