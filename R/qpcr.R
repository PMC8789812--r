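# Delta-delta-Ct relative quantification: replicate aggregation with QC,
# endogenous-control normalization, comparative-Ct group testing with BH
# correction and the vendor significance rule, and normalizer ranking.

#' Aggregate technical qPCR replicates
#'
#' Arithmetic mean Ct per (sample, target), flagged when the replicate
#' range exceeds `maxSpread` cycles.
#'
#' @param ct data.frame(sample, group, target, replicate, ct) with ct > 0.
#' @param maxSpread replicate range QC threshold in cycles (default 0.5).
#' @return data.frame(sample, group, target, ct, nReplicates, qcFlag).
#' @export
aggregateReplicates <- function(ct, maxSpread = 0.5) {
    req <- c("sample", "group", "target", "replicate", "ct")
    if (!all(req %in% colnames(ct)))
        stop("ct table needs columns ", paste(req, collapse = ", "))
    if (any(!is.finite(ct$ct) | ct$ct <= 0))
        stop("Ct values must be positive and finite")
    key <- interaction(ct$sample, ct$target, drop = TRUE)
    agg <- lapply(split(ct, key), function(d) data.frame(
        sample = d$sample[1], group = d$group[1], target = d$target[1],
        ct = mean(d$ct), nReplicates = nrow(d),
        qcFlag = diff(range(d$ct)) > maxSpread))
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
}

#' Delta-Ct normalization against endogenous controls
#'
#' Per (sample, target): `deltaCt = Ct(target) - mean(Ct(controls))` within
#' the sample (arithmetic mean of control Ct = geometric mean of control
#' expression). Samples missing any control are excluded with a message.
#' Invariant to sample-wide Ct shifts.
#'
#' @param ctMeans an [aggregateReplicates()] result.
#' @param controls character vector of endogenous control targets.
#' @return data.frame(sample, group, target, deltaCt) for non-control
#'   targets.
#' @export
deltaCt <- function(ctMeans, controls) {
    if (!length(controls)) stop("missing control targets")
    bySample <- split(ctMeans, ctMeans$sample)
    out <- lapply(bySample, function(d) {
        ctrl <- d$ct[match(controls, d$target)]
        if (anyNA(ctrl)) return(NULL)
        t <- d[!(d$target %in% controls), , drop = FALSE]
        if (!nrow(t)) return(NULL)
        data.frame(sample = t$sample, group = t$group, target = t$target,
                   deltaCt = t$ct - mean(ctrl))
    })
    dropped <- names(bySample)[vapply(out, is.null, logical(1))]
    if (length(dropped))
        message("excluded sample(s) missing controls or targets: ",
                paste(dropped, collapse = ", "))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Comparative-Ct point estimates
#'
#' `deltaDeltaCt = mean deltaCt(test) - mean deltaCt(reference)`,
#' `RQ = 2^(-deltaDeltaCt)`, `log2fc = -deltaDeltaCt`, per target.
#'
#' @param dct a [deltaCt()] table.
#' @param testGroup,referenceGroup group labels (both non-empty in `dct`).
#' @return data.frame(target, deltaDeltaCt, RQ, log2fc, nTest, nRef).
#' @export
relativeQuant <- function(dct, testGroup, referenceGroup) {
    te <- dct[dct$group %in% testGroup, , drop = FALSE]
    re <- dct[dct$group %in% referenceGroup, , drop = FALSE]
    if (!nrow(te) || !nrow(re)) stop("empty test or reference group")
    targets <- sort(unique(dct$target))
    rows <- lapply(targets, function(tg) {
        dt <- te$deltaCt[te$target == tg]
        dr <- re$deltaCt[re$target == tg]
        ddct <- mean(dt) - mean(dr)
        data.frame(target = tg, deltaDeltaCt = ddct, RQ = 2^(-ddct),
                   log2fc = -ddct, nTest = length(dt), nRef = length(dr))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Relative quantification with group testing and the significance rule
#'
#' Per target: a two-sample t-test on per-sample delta-Ct between test and
#' reference (Student's equal-variance by default, the vendor convention;
#' Welch with `welch = TRUE`), BH adjustment across targets within the
#' comparison, and the vendor significance rule: significant iff
#' `(RQ > 2 or RQ < 0.5) and padj < 0.05`.
#'
#' @param dct a [deltaCt()] table.
#' @param testGroup,referenceGroup group labels.
#' @param welch use Welch's t-test.
#' @param rqLow,rqHigh fold-change gates (default 0.5 / 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return [relativeQuant()] columns plus pvalue, padj, significant.
#'   Degenerate-variance targets carry missing p and are never significant.
#' @examples
#' sim <- simulateCtTable("miR-144-3p", c("CTR", "dnPD"),
#'                        plantedLog2fc = c("miR-144-3p" = -1.5),
#'                        noiseSd = 0.1, nPerGroup = 10, seed = 4)
#' dct <- deltaCt(aggregateReplicates(sim$ct), attr(sim$ct, "controls"))
#' rqTest(dct, "dnPD", "CTR")
#' @export
rqTest <- function(dct, testGroup, referenceGroup, welch = FALSE,
                   rqLow = 0.5, rqHigh = 2, alpha = 0.05) {
    out <- relativeQuant(dct, testGroup, referenceGroup)
    te <- dct[dct$group %in% testGroup, , drop = FALSE]
    re <- dct[dct$group %in% referenceGroup, , drop = FALSE]
    out$pvalue <- vapply(out$target, function(tg) {
        dt <- te$deltaCt[te$target == tg]
        dr <- re$deltaCt[re$target == tg]
        if (length(dt) < 2L || length(dr) < 2L) return(NA_real_)
        if (var(dt) == 0 && var(dr) == 0) return(NA_real_)
        t.test(dt, dr, var.equal = !welch)$p.value
    }, numeric(1))
    out$padj <- adjustBH(out$pvalue)
    out$significant <- !is.na(out$padj) & out$padj < alpha &
        (out$RQ > rqHigh | out$RQ < rqLow)
    out
}

#' Rank candidate endogenous normalizers by stability
#'
#' Candidates are ranked by the SD of their aggregated Ct across all
#' samples (ascending), ties broken by distance of the mean Ct from the
#' usable-range midpoint. Candidates missing in more than 20% of samples
#' are excluded with a message.
#'
#' @param ct raw Ct table (see [aggregateReplicates()]).
#' @param candidates character vector of candidate normalizer targets.
#' @param ctMid midpoint of the desired Ct range (default 25 cycles).
#' @return data.frame(target, sd, meanCt, nSamples, rank), ordered.
#' @export
rankNormalizers <- function(ct, candidates, ctMid = 25) {
    if (!length(candidates)) stop("empty candidate list")
    agg <- aggregateReplicates(ct)
    nSamples <- length(unique(agg$sample))
    rows <- lapply(candidates, function(tg) {
        d <- agg[agg$target == tg, , drop = FALSE]
        data.frame(target = tg, sd = if (nrow(d) > 1) sd(d$ct) else 0,
                   meanCt = mean(d$ct), nSamples = nrow(d))
    })
    out <- do.call(rbind, rows)
    excl <- out$nSamples < 0.8 * nSamples
    if (any(excl))
        message("excluded candidate(s) measured in < 80% of samples: ",
                paste(out$target[excl], collapse = ", "))
    out <- out[!excl, , drop = FALSE]
    out <- out[order(out$sd, abs(out$meanCt - ctMid)), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
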