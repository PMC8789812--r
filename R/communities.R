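# Louvain community detection on the MI network, node-degree topology
# statistics with within-community quartile placement, and DEM-community
# integration.

#' Louvain community detection
#'
#' Greedy modularity optimization (node moves + aggregation passes) at
#' resolution gamma via igraph's Louvain implementation; the number of
#' communities is determined by the optimization. The seed controls the
#' node visiting order. Isolated nodes are retained (each its own
#' community if unconnected).
#'
#' @param network an [MINetwork-class].
#' @param resolution gamma > 0 (default 1).
#' @param seed integer seed.
#' @param nRestarts number of randomized restarts of the greedy optimizer;
#'   the partition with the highest Q is kept (Louvain is stochastic in its
#'   node visiting order, and restarts guard against shallow local optima
#'   on small graphs). Deterministic given `seed`.
#' @return a [CommunityPartition-class]; its modularity is computed by
#'   [modularityScore()] at the same resolution.
#' @examples
#' M <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
#' M[cbind(c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6))] <- 0.5
#' net <- applyDPI(pmax(M, t(M)), eps = 0, tau = 0)
#' louvainCommunities(net, seed = 1)   # two triangles: 2 communities, Q 0.5
#' @export
louvainCommunities <- function(network, resolution = 1, seed = NULL,
                               nRestarts = 10L) {
    stopifnot(methods::is(network, "MINetwork"))
    if (resolution <= 0) stop("resolution must be positive")
    if (!length(network@nodes)) stop("empty network")
    g <- asIgraph(network)
    memb <- NULL
    q <- -Inf
    withSeed(seed, {
        for (r in seq_len(max(1L, nRestarts))) {
            cl <- igraph::cluster_louvain(g, resolution = resolution)
            m <- igraph::membership(cl)[network@nodes]
            qr <- modularityScore(network, m, resolution = resolution)
            if (qr > q) {
                q <- qr
                memb <- m
            }
        }
    })
    memb <- setNames(as.integer(factor(as.integer(memb))), names(memb))
    memb <- memb[network@nodes]
    sizes <- as.integer(table(memb))
    names(sizes) <- names(table(memb))
    methods::new("CommunityPartition", membership = memb, modularity = q,
                 resolution = resolution, sizes = sizes)
}

#' Weighted modularity with resolution parameter
#'
#' `Q = sum_c [ w_c / W - gamma * (s_c / (2 W))^2 ]`, where `w_c` is the
#' intra-community edge weight, `s_c` the summed strength of the
#' community's nodes, and `W` the total edge weight. An edgeless network
#' has Q = 0 by convention.
#'
#' @param network an [MINetwork-class].
#' @param membership named integer vector covering all network nodes, or a
#'   [CommunityPartition-class].
#' @param resolution gamma (default 1).
#' @return numeric Q.
#' @export
modularityScore <- function(network, membership, resolution = 1) {
    stopifnot(methods::is(network, "MINetwork"))
    if (methods::is(membership, "CommunityPartition"))
        membership <- membershipVector(membership)
    if (!all(network@nodes %in% names(membership)))
        stop("membership must cover every network node")
    e <- network@edges
    if (!nrow(e)) return(0)
    W <- sum(e$mi)
    strength <- setNames(numeric(length(network@nodes)), network@nodes)
    agg <- tapply(c(e$mi, e$mi), c(e$from, e$to), sum)
    strength[names(agg)] <- agg
    comm <- membership[network@nodes]
    same <- membership[e$from] == membership[e$to]
    intra <- tapply(e$mi[same], membership[e$from][same], sum)
    wc <- setNames(numeric(length(unique(comm))), sort(unique(comm)))
    if (length(intra)) wc[names(intra)] <- intra
    sc <- tapply(strength, comm, sum)
    sum(wc / W) - resolution * sum((sc[names(wc)] / (2 * W))^2)
}

#' Node-degree statistics with community quartile placement
#'
#' Weighted degree = sum of incident MI weights; unweighted degree =
#' incident edge count. Each node is placed against its own community's
#' degree distribution using linear-interpolation quantiles: strictly above
#' Q3 = `above_upper_quartile`, at or above the median = `median_to_upper`,
#' otherwise `below_median`.
#'
#' @param network an [MINetwork-class].
#' @param partition a [CommunityPartition-class].
#' @return data.frame(node, weightedDegree, unweightedDegree, community,
#'   weightedLabel, unweightedLabel).
#' @export
nodeDegrees <- function(network, partition) {
    stopifnot(methods::is(network, "MINetwork"),
              methods::is(partition, "CommunityPartition"))
    memb <- membershipVector(partition)
    if (!all(network@nodes %in% names(memb)))
        stop("partition must cover every network node")
    nodes <- network@nodes
    e <- network@edges
    wdeg <- setNames(numeric(length(nodes)), nodes)
    udeg <- setNames(integer(length(nodes)), nodes)
    if (nrow(e)) {
        aggW <- tapply(c(e$mi, e$mi), c(e$from, e$to), sum)
        wdeg[names(aggW)] <- aggW
        aggU <- table(c(e$from, e$to))
        udeg[names(aggU)] <- as.integer(aggU)
    }
    placeLabel <- function(v, commOf) {
        out <- character(length(v))
        for (cm in unique(commOf)) {
            idx <- commOf == cm
            qs <- quantile(v[idx], c(0.5, 0.75), type = 7)
            out[idx] <- ifelse(v[idx] > qs[2], "above_upper_quartile",
                               ifelse(v[idx] >= qs[1], "median_to_upper",
                                      "below_median"))
        }
        out
    }
    comm <- unname(memb[nodes])
    data.frame(node = nodes,
               weightedDegree = unname(wdeg),
               unweightedDegree = unname(udeg),
               community = comm,
               weightedLabel = placeLabel(unname(wdeg), comm),
               unweightedLabel = placeLabel(as.numeric(udeg), comm))
}

#' Integrate DEM sets with network communities
#'
#' For every (DEM set, community) pair: the overlap count and the
#' hypergeometric enrichment tail P(X >= overlap) with the network's node
#' set as universe. The maximum-overlap community per DEM set is reported;
#' ties break toward the smaller community, then the lower community id.
#'
#' @param partition a [CommunityPartition-class].
#' @param demSets named list of miRNA id vectors.
#' @return list: `overlaps` data.frame(demSet, community, communitySize,
#'   overlap, p), `best` data.frame(demSet, community, overlap, flagged);
#'   a DEM set disjoint from the network is flagged.
#' @export
integrateDEMs <- function(partition, demSets) {
    stopifnot(methods::is(partition, "CommunityPartition"))
    memb <- membershipVector(partition)
    nodes <- names(memb)
    N <- length(nodes)
    comms <- sort(unique(memb))
    rows <- list()
    best <- list()
    for (nm in names(demSets)) {
        dem <- intersect(demSets[[nm]], nodes)
        k <- length(dem)
        ov <- vapply(comms, function(cm) sum(memb[dem] == cm), integer(1))
        csz <- vapply(comms, function(cm) sum(memb == cm), integer(1))
        p <- phyper(ov - 1L, csz, N - csz, k, lower.tail = FALSE)
        rows[[nm]] <- data.frame(demSet = nm, community = comms,
                                 communitySize = csz, overlap = ov, p = p)
        if (k == 0L) {
            best[[nm]] <- data.frame(demSet = nm, community = NA_integer_,
                                     overlap = 0L, flagged = TRUE)
        } else {
            ord <- order(-ov, csz, comms)
            best[[nm]] <- data.frame(demSet = nm, community = comms[ord[1]],
                                     overlap = ov[ord[1]], flagged = FALSE)
        }
    }
    list(overlaps = do.call(rbind, c(rows, make.row.names = FALSE)),
         best = do.call(rbind, c(best, make.row.names = FALSE)))
}
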