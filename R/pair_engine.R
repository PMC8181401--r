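#' Filter genes by median absolute deviation
#'
#' Keeps genes whose raw MAD — the median of absolute deviations from the
#' median, with no consistency constant — strictly exceeds \code{threshold}.
#' For RNA-seq counts the dispersion is more interpretable on
#' \code{log2(x + 1)}; the \code{scale} argument controls this (the filter is
#' applied to transformed values, the returned matrix keeps the native scale).
#'
#' @param expr numeric matrix, genes x samples.
#' @param threshold strict lower bound on the per-gene MAD (default 0.5; a
#'   gene with MAD exactly equal to the threshold is removed).
#' @param scale \code{"native"} to compute MAD on the values as given,
#'   \code{"log2"} to compute it on \code{log2(x + 1)}.
#' @return the filtered matrix, gene order preserved.
#' @examples
#' m <- rbind(flat = rep(5, 4), var = c(1, 5, 9, 13))
#' colnames(m) <- paste0("s", 1:4)
#' rownames(madFilter(m))   # "var" only
#' @export
madFilter <- function(expr, threshold = 0.5, scale = c("native", "log2")) {
    scale <- match.arg(scale)
    if (ncol(expr) < 2L)
        stop("MAD filtering needs at least 2 samples")
    vals <- if (scale == "log2") log2(expr + 1) else expr
    mads <- apply(vals, 1L, function(x) stats::median(abs(x - stats::median(x))))
    expr[mads > threshold, , drop = FALSE]
}

#' Restrict an expression matrix to a gene list
#'
#' @param expr numeric matrix, genes x samples.
#' @param genes character vector of symbols (e.g. an immune-gene list).
#' @return the rows of \code{expr} whose symbol is in \code{genes}, input
#'   order preserved; the intersection size is reported via \code{message()}.
#' @export
restrictToGenes <- function(expr, genes) {
    keep <- rownames(expr) %in% genes
    if (!any(keep))
        stop("no overlap between expression matrix and gene list")
    message(sum(keep), " of ", nrow(expr),
            " genes retained after gene-list intersection")
    expr[keep, , drop = FALSE]
}

#' Binarize all gene pairs within each sample
#'
#' For every unordered pair of genes (canonical direction = input row order,
#' so geneA precedes geneB in the matrix) the indicator for sample s is 1 when
#' \code{expr[geneA, s] > expr[geneB, s]} and 0 otherwise — ties score 0. A
#' matrix of G genes yields G(G-1)/2 pairs. Because only within-sample order
#' matters, the result is invariant under any strictly increasing per-sample
#' transform of the expression values.
#'
#' @param expr numeric matrix, genes x samples, with unique rownames.
#' @return a [PairIndicatorMatrix-class].
#' @examples
#' m <- rbind(A = c(5, 1), B = c(3, 3), C = c(1, 5))
#' colnames(m) <- c("s1", "s2")
#' SummarizedExperiment::assay(binarizePairs(m))
#' @export
binarizePairs <- function(expr) {
    if (nrow(expr) < 2L)
        stop("pair binarization needs at least 2 genes")
    if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
        stop("expression matrix must have unique rownames")
    cmb <- utils::combn(nrow(expr), 2L)
    ind <- (expr[cmb[1L, ], , drop = FALSE] >
            expr[cmb[2L, ], , drop = FALSE]) + 0L
    colnames(ind) <- colnames(expr)
    PairIndicatorMatrix(ind,
                        geneA = rownames(expr)[cmb[1L, ]],
                        geneB = rownames(expr)[cmb[2L, ]])
}

#' Drop near-constant pairs by prevalence
#'
#' A pair whose indicator is (almost) always 1 or always 0 carries no
#' discriminating information; a pair is kept only when both states occur in
#' at least a fraction \code{minFrac} of samples, i.e.
#' \code{min(frac1, 1 - frac1) >= minFrac}. A pair at exactly the boundary is
#' kept (only prevalences strictly below the threshold are discarded).
#'
#' @param ind a [PairIndicatorMatrix-class].
#' @param minFrac minimum prevalence of the minority state (default 0.20).
#' @return the filtered [PairIndicatorMatrix-class], row order preserved.
#' @export
prevalenceFilter <- function(ind, minFrac = 0.20) {
    stopifnot(is(ind, "PairIndicatorMatrix"))
    if (ncol(ind) < 1L) stop("prevalence filter needs at least 1 sample")
    frac1 <- rowMeans(assay(ind, "indicator"))
    keep <- pmin(frac1, 1 - frac1) >= minFrac
    ind[keep, ]
}

#' Per-sample gene-pair risk score
#'
#' \code{score(s) = sum_k coef_k * indicator_k(s)} over the signature pairs.
#' Applied to a [PairIndicatorMatrix-class], each signature pair is matched
#' either directly as (geneA, geneB) or in reverse as (geneB, geneA) with the
#' indicator complemented (\code{1 - x}); applied to an expression matrix, the
#' needed indicators are computed on the fly, so a signature trained on one
#' platform scores another platform's matrix without any rescaling.
#'
#' @param x a [PairIndicatorMatrix-class] or a numeric expression matrix
#'   (genes x samples).
#' @param sig an [IRGPSignature-class].
#' @return named numeric vector of per-sample risk scores.
#' @examples
#' m <- rbind(A = c(5, 1), B = c(3, 3))
#' colnames(m) <- c("s1", "s2")
#' riskScore(m, IRGPSignature("A", "B", 2))
#' @export
setGeneric("riskScore", function(x, sig) standardGeneric("riskScore"))

#' @rdname riskScore
#' @export
setMethod("riskScore", "PairIndicatorMatrix", function(x, sig) {
    stopifnot(is(sig, "IRGPSignature"))
    ids <- pairIds(x)
    fwd <- match(paste(sig@geneA, sig@geneB, sep = "|"), ids)
    rev <- match(paste(sig@geneB, sig@geneA, sep = "|"), ids)
    missing <- is.na(fwd) & is.na(rev)
    if (any(missing))
        stop("signature pair(s) not resolvable in indicator matrix: ",
             paste(pairIds(sig)[missing], collapse = ", "))
    mat <- assay(x, "indicator")
    scores <- numeric(ncol(mat))
    for (k in seq_along(sig@coefficients)) {
        v <- if (!is.na(fwd[k])) mat[fwd[k], ] else 1 - mat[rev[k], ]
        scores <- scores + sig@coefficients[k] * v
    }
    stats::setNames(scores, colnames(mat))
})

#' @rdname riskScore
#' @export
setMethod("riskScore", "matrix", function(x, sig) {
    stopifnot(is(sig, "IRGPSignature"))
    genes <- unique(c(sig@geneA, sig@geneB))
    absent <- setdiff(genes, rownames(x))
    if (length(absent))
        stop("signature gene(s) absent from expression matrix: ",
             paste(absent, collapse = ", "))
    ind <- (x[sig@geneA, , drop = FALSE] > x[sig@geneB, , drop = FALSE]) + 0
    stats::setNames(as.numeric(crossprod(ind, sig@coefficients)), colnames(x))
})

#' Split samples into high- and low-risk groups
#'
#' @param scores named numeric vector of risk scores.
#' @param cutoff finite cutoff; scores strictly above it are "high", the rest
#'   (including the boundary) "low".
#' @return factor with levels \code{low}, \code{high}, named like
#'   \code{scores}.
#' @export
assignGroups <- function(scores, cutoff) {
    if (!is.finite(cutoff)) stop("cutoff must be finite")
    factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Write / read a pair-indicator matrix as TSV
#'
#' Column 1 holds the pair id \code{"GENEA|GENEB"}; remaining columns are the
#' 0/1 indicators per sample.
#'
#' @param ind a [PairIndicatorMatrix-class].
#' @param path output path.
#' @return \code{path} (writer, invisibly) or a
#'   [PairIndicatorMatrix-class] (reader).
#' @export
writePairMatrix <- function(ind, path) {
    stopifnot(is(ind, "PairIndicatorMatrix"))
    df <- data.frame(pair = pairIds(ind),
                     as.data.frame(assay(ind, "indicator")),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePairMatrix
#' @export
readPairMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    parts <- strsplit(df[[1L]], "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("pair ids must have the form GENEA|GENEB")
    mat <- as.matrix(df[, -1L, drop = FALSE])
    PairIndicatorMatrix(mat,
                        geneA = vapply(parts, `[`, "", 1L),
                        geneB = vapply(parts, `[`, "", 2L))
}
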