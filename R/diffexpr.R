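# Negative-binomial Wald differential expression over a multi-contrast
# scheme. Dispersions are method-of-moments estimates pooled within groups;
# the two-group NB GLM (intercept + test indicator, log link, size-factor
# offsets) is fitted by IRLS at fixed dispersion, vectorized across miRNAs.

#' Specify a differential-expression contrast
#'
#' @param name contrast label.
#' @param test,reference character vectors of group labels; disjoint sets.
#'   A pooled reference (e.g. `c("CTR", "CENT")`) takes the union of the
#'   groups' samples.
#' @param testSite,refSite optional collection-site restriction applied to
#'   the test / reference side only (e.g. reference = CTR restricted to
#'   UNIBO).
#' @return a `ContrastSpec` (S3 list).
#' @examples
#' contrastSpec("dnPD_vs_CTR_UNIBO", "dnPD", "CTR", refSite = "UNIBO")
#' @export
contrastSpec <- function(name, test, reference, testSite = NULL,
                         refSite = NULL) {
    if (length(intersect(test, reference)))
        stop("test and reference groups overlap")
    structure(list(name = name, test = test, reference = reference,
                   testSite = testSite, refSite = refSite),
              class = "ContrastSpec")
}

#' @export
print.ContrastSpec <- function(x, ...) {
    fmt <- function(g, s) paste0(paste(g, collapse = "+"),
                                 if (!is.null(s)) paste0("@", s) else "")
    cat(sprintf("ContrastSpec %s: %s vs %s\n", x$name,
                fmt(x$test, x$testSite), fmt(x$reference, x$refSite)))
    invisible(x)
}

#' The default discovery contrast scheme
#'
#' Eight contrasts comparing de novo patients and centenarians against
#' controls (per site and pooled), patients against centenarians, and
#' patients against the pooled control + centenarian reference.
#'
#' @return list of [contrastSpec()] objects.
#' @export
defaultContrasts <- function() {
    list(
        contrastSpec("dnPD_vs_CTR_GOE",   "dnPD", "CTR", refSite = "GOE"),
        contrastSpec("dnPD_vs_CTR_UNIBO", "dnPD", "CTR", refSite = "UNIBO"),
        contrastSpec("dnPD_vs_CTR_ALL",   "dnPD", "CTR"),
        contrastSpec("CENT_vs_CTR_GOE",   "CENT", "CTR", refSite = "GOE"),
        contrastSpec("CENT_vs_CTR_UNIBO", "CENT", "CTR", refSite = "UNIBO"),
        contrastSpec("CENT_vs_CTR_ALL",   "CENT", "CTR"),
        contrastSpec("dnPD_vs_CENT",      "dnPD", "CENT"),
        contrastSpec("dnPD_vs_CTR_CENT",  "dnPD", c("CTR", "CENT")))
}

# Sample indices of one side of a contrast.
contrastSide <- function(x, groups, site) {
    cd <- SummarizedExperiment::colData(x)
    sel <- cd$group %in% groups
    if (!is.null(site)) sel <- sel & cd$site == site
    which(sel)
}

#' Method-of-moments NB dispersion estimates
#'
#' Per miRNA, `alpha = max((v - m) / m^2, floor)` where `m` is the mean of
#' the normalized counts over the contrast samples and `v` the pooled
#' within-group variance. Underdispersed rows are floored.
#'
#' @param x a [MirnaExperiment-class] with size factors.
#' @param groups factor/character of group membership, one per sample of
#'   `x`; each group needs >= 2 samples.
#' @param floor minimum dispersion (default 1e-8).
#' @return named numeric vector of dispersions.
#' @examples
#' # mean 10, pooled variance 30 -> alpha = 20 / 100 = 0.2
#' @export
estimateDispersions <- function(x, groups, floor = 1e-8) {
    stopifnot(methods::is(x, "MirnaExperiment"))
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(x))
    if (any(table(groups) < 2L))
        stop("every group needs at least 2 samples to estimate dispersion")
    nc <- normCounts(x)
    m <- rowMeans(nc)
    num <- 0
    den <- 0
    for (g in levels(groups)) {
        cols <- which(groups == g)
        v <- apply(nc[, cols, drop = FALSE], 1L, var)
        num <- num + (length(cols) - 1L) * v
        den <- den + (length(cols) - 1L)
    }
    pooled <- num / den
    alpha <- (pooled - m) / m^2
    alpha[!is.finite(alpha)] <- floor
    setNames(pmax(alpha, floor), rownames(x))
}

# Vectorized IRLS for the two-group NB GLM with log link and offsets.
# Y: counts (rows = miRNAs), sf: size factors, xind: 0/1 test indicator,
# alpha: per-row dispersion. Returns natural-log coefficients and SE(b1).
nbIRLS <- function(Y, sf, xind, alpha, maxit = 50L, tol = 1e-8,
                   betaCap = 20) {
    n <- ncol(Y)
    off <- matrix(log(sf), nrow(Y), n, byrow = TRUE)
    # start from group means of normalized counts (+0.5 to keep finite)
    nc <- sweep(Y, 2L, sf, "/")
    m0 <- rowMeans(nc[, xind == 0, drop = FALSE])
    m1 <- rowMeans(nc[, xind == 1, drop = FALSE])
    b0 <- log(m0 + 0.5)
    b1 <- log(m1 + 0.5) - b0
    conv <- rep(FALSE, nrow(Y))
    for (it in seq_len(maxit)) {
        eta <- b0 + outer(b1, xind) + off
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- (eta - off) + (Y - mu) / mu
        A <- rowSums(w)
        B <- rowSums(w * rep(xind, each = nrow(Y)))
        D <- B                       # x is 0/1 so sum w x^2 = sum w x
        r1 <- rowSums(w * z)
        r2 <- rowSums((w * z) * rep(xind, each = nrow(Y)))
        det <- A * D - B^2
        nb0 <- (D * r1 - B * r2) / det
        nb1 <- (A * r2 - B * r1) / det
        nb1 <- pmax(pmin(nb1, betaCap), -betaCap)
        delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
        b0 <- nb0
        b1 <- nb1
        conv <- conv | (delta < tol)
        if (all(conv, na.rm = TRUE)) break
    }
    eta <- b0 + outer(b1, xind) + off
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    A <- rowSums(w)
    B <- rowSums(w * rep(xind, each = nrow(Y)))
    det <- A * B - B^2
    se1 <- sqrt(A / det)
    list(b0 = b0, b1 = b1, se1 = se1,
         converged = conv & is.finite(b1) & abs(b1) < betaCap)
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits, per miRNA, the NB log-link GLM `count ~ test indicator` with
#' size-factor offsets at fixed dispersion, and reports the log2
#' fold-change (natural-log coefficient / ln 2), its standard error, the
#' two-sided normal Wald p, and the mean normalized count. All-zero rows
#' and non-converged fits carry missing p.
#'
#' @param x a [MirnaExperiment-class] with size factors.
#' @param contrast a [contrastSpec()].
#' @param dispersions optional named dispersion vector; re-estimated on the
#'   contrast samples when omitted.
#' @param floor dispersion floor passed to [estimateDispersions()].
#' @return data.frame(mirna, baseMean, log2fc, se, pvalue, padj, converged);
#'   `padj` is the BH adjustment over the non-missing p-values.
#' @export
waldTest <- function(x, contrast, dispersions = NULL, floor = 1e-8) {
    stopifnot(methods::is(x, "MirnaExperiment"),
              inherits(contrast, "ContrastSpec"))
    it <- contrastSide(x, contrast$test, contrast$testSite)
    ir <- contrastSide(x, contrast$reference, contrast$refSite)
    if (!length(it) || !length(ir))
        stop("contrast '", contrast$name,
             "' is empty after site restriction")
    cols <- c(ir, it)
    xs <- x[, cols]
    xind <- c(rep(0, length(ir)), rep(1, length(it)))
    if (is.null(dispersions)) {
        dispersions <- estimateDispersions(
            xs, ifelse(xind == 1, "test", "ref"), floor = floor)
    } else {
        stopifnot(!is.null(names(dispersions)))
        dispersions <- dispersions[rownames(xs)]
    }
    Y <- counts(xs)
    sf <- sizeFactors(xs)
    baseMean <- rowMeans(sweep(Y, 2L, sf, "/"))
    nz <- baseMean > 0
    res <- data.frame(mirna = rownames(Y), baseMean = baseMean,
                      log2fc = NA_real_, se = NA_real_, pvalue = NA_real_,
                      padj = NA_real_, converged = FALSE,
                      row.names = NULL)
    if (any(nz)) {
        fit <- nbIRLS(Y[nz, , drop = FALSE], sf, xind,
                      dispersions[rownames(Y)[nz]])
        log2fc <- fit$b1 / log(2)
        se <- fit$se1 / log(2)
        pv <- 2 * pnorm(-abs(fit$b1 / fit$se1))
        pv[!fit$converged] <- NA_real_
        res$log2fc[nz] <- log2fc
        res$se[nz] <- se
        res$pvalue[nz] <- pv
        res$converged[nz] <- fit$converged
    }
    res$padj <- adjustBH(res$pvalue)
    attr(res, "contrast") <- contrast
    res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over the non-missing p-values (missing entries are excluded
#' from the denominator and stay missing), capped at 1.
#'
#' @param pvals numeric vector of p-values between 0 and 1, possibly with NA.
#' @return adjusted p-values, same length and order.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.04, 0.05))   # 0.04 0.04 0.05 0.05
#' @export
adjustBH <- function(pvals) {
    ok <- !is.na(pvals)
    if (any(pvals[ok] < 0 | pvals[ok] > 1))
        stop("p-values must lie between 0 and 1")
    out <- rep(NA_real_, length(pvals))
    out[ok] <- p.adjust(pvals[ok], method = "BH")
    out
}

#' Call differentially expressed miRNAs
#'
#' DEMs are the miRNAs with adjusted p strictly below `alpha`.
#'
#' @param result a [waldTest()] result.
#' @param alpha FDR threshold (default 0.05).
#' @return character vector of miRNA ids.
#' @export
callDEMs <- function(result, alpha = 0.05) {
    sel <- !is.na(result$padj) & result$padj < alpha
    result$mirna[sel]
}

#' Run a set of contrasts
#'
#' One Wald test per contrast, under the shared (pooled) normalization of
#' `x`; dispersions are re-estimated per contrast on its samples.
#'
#' @param x a [MirnaExperiment-class]; size factors are estimated on the
#'   full matrix if absent.
#' @param specs list of [contrastSpec()]; default [defaultContrasts()].
#' @param ... passed to [waldTest()].
#' @return named list of result data.frames.
#' @export
runContrasts <- function(x, specs = defaultContrasts(), ...) {
    stopifnot(methods::is(x, "MirnaExperiment"))
    if (!"sizeFactor" %in%
        colnames(SummarizedExperiment::colData(x)))
        x <- estimateSizeFactors(x)
    nm <- vapply(specs, function(s) s$name, character(1))
    if (anyDuplicated(nm)) stop("duplicate contrast names")
    res <- lapply(specs, function(s) waldTest(x, s, ...))
    names(res) <- nm
    res
}
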