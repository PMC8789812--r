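# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG, evaluates `expr`, and restores the previous RNG state so
#' that library code never disturbs the caller's random stream. A `NULL` seed
#' evaluates `expr` in the current stream.
#' @noRd
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Normal-scores (rank copula) transform
#'
#' Maps a numeric vector to Gaussian quantiles of its ranks, the copula
#' transform used by the mutual-information estimators. Average ranks for
#' ties; denominator n + 1 keeps scores finite.
#' @noRd
normalScores <- function(x) {
    qnorm(rank(x, ties.method = "average") / (length(x) + 1L))
}

#' @noRd
geometricMean <- function(x) exp(mean(log(x)))

# Deterministic fixed-width base-36 labels, used for collision-free UMIs.
# Vectorized: builds one digit column at a time.
#' @noRd
base36 <- function(i, width = 8L) {
    alphabet <- c(0:9, letters)
    v <- as.integer(i)
    cols <- matrix("", nrow = length(v), ncol = width)
    for (d in width:1) {
        cols[, d] <- alphabet[(v %% 36L) + 1L]
        v <- v %/% 36L
    }
    apply(cols, 1L, paste, collapse = "")
}

# Deterministic pseudo-sequence for a miRNA row index: 22-mer over ACGU from
# the base-4 expansion of the index (distinct per index by construction).
#' @noRd
pseudoSequence <- function(i, len = 22L) {
    alphabet <- c("A", "C", "G", "U")
    v <- as.integer(i)
    cols <- matrix("", nrow = length(v), ncol = len)
    for (d in len:1) {
        cols[, d] <- alphabet[(v %% 4L) + 1L]
        v <- v %/% 4L
    }
    apply(cols, 1L, paste, collapse = "")
}

#' @noRd
isWholeNumber <- function(x, tol = 1e-8) {
    is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# MD5 of an R object, via its serialization written to a temp file
# (tools::md5sum is file-based). Used for manifest parameter hashes.
#' @noRd
objectHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2)
    unname(tools::md5sum(f))
}
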