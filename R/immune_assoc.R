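#' Estimate immune-cell fractions by non-negative least squares
#'
#' For each bulk sample m, solves \eqn{\min_f \|B f - m\|_2} subject to
#' \eqn{f \ge 0} over the genes shared between the mixture matrix and the
#' cell-type basis (signature) matrix, then normalizes f to sum to 1. This is
#' a least-squares deconvolution of mixture profiles into cell-type
#' proportions; externally computed fraction tables (e.g. from a support
#' vector regression deconvolution service) can be used interchangeably in
#' the downstream association tests.
#'
#' @param mixture numeric matrix, genes x samples.
#' @param basis numeric matrix, genes x cell types, with linearly
#'   independent columns.
#' @return numeric matrix, samples x cell types; rows are non-negative and
#'   sum to 1.
#' @examples
#' basis <- cbind(T = c(10, 1, 1), B = c(1, 10, 1))
#' rownames(basis) <- paste0("g", 1:3)
#' mix <- cbind(s1 = 0.3 * basis[, 1] + 0.7 * basis[, 2])
#' deconvolve(mix, basis)
#' @export
deconvolve <- function(mixture, basis) {
    shared <- intersect(rownames(basis), rownames(mixture))
    if (length(shared) == 0L)
        stop("no genes shared between mixture and basis")
    B <- as.matrix(basis[shared, , drop = FALSE])
    M <- as.matrix(mixture[shared, , drop = FALSE])
    if (qr(B)$rank < ncol(B))
        stop("basis matrix is rank-deficient; cell-type profiles must be ",
             "linearly independent")
    K <- ncol(B)
    out <- matrix(0, nrow = ncol(M), ncol = K,
                  dimnames = list(colnames(M), colnames(B)))
    for (s in seq_len(ncol(M))) {
        f <- pracma::lsqnonneg(B, M[, s])$x
        tot <- sum(f)
        if (tot <= 0) {
            warning("sample '", colnames(M)[s],
                    "' has an all-zero solution; uniform fractions returned")
            f <- rep(1 / K, K)
        } else {
            f <- f / tot
        }
        out[s, ] <- f
    }
    out
}

#' Compare cell fractions between risk groups
#'
#' Two-sided Wilcoxon rank-sum test per cell type between the high- and
#' low-score groups, with group medians. Cell types with constant fractions
#' across all samples are flagged and given p = 1.
#'
#' @param fractions numeric matrix, samples x cell types.
#' @param groups per-sample labels with exactly two levels (e.g. high/low),
#'   named by sample id or aligned with the fraction rows; each group needs
#'   at least 3 samples.
#' @return data.frame with cell_type, median per group, p_value, note.
#' @export
compareGroups <- function(fractions, groups) {
    if (!is.null(names(groups)) && !is.null(rownames(fractions))) {
        if (!all(rownames(fractions) %in% names(groups)))
            stop("group label(s) missing for some samples")
        groups <- groups[rownames(fractions)]
    }
    groups <- factor(as.character(groups))
    if (nlevels(groups) != 2L)
        stop("compareGroups expects exactly 2 groups")
    if (any(table(groups) < 3L))
        stop("each group needs at least 3 samples")
    g1 <- levels(groups)[1L]; g2 <- levels(groups)[2L]
    res <- lapply(colnames(fractions), function(ct) {
        f <- fractions[, ct]
        m1 <- stats::median(f[groups == g1])
        m2 <- stats::median(f[groups == g2])
        if (stats::sd(f) == 0) {
            p <- 1; note <- "constant fractions"
        } else {
            p <- suppressWarnings(
                stats::wilcox.test(f[groups == g1], f[groups == g2],
                                   exact = FALSE)$p.value)
            note <- ""
        }
        out <- data.frame(cell_type = ct, m1 = m1, m2 = m2, p_value = p,
                          note = note, stringsAsFactors = FALSE)
        names(out)[2:3] <- paste0("median_", c(g1, g2))
        out
    })
    do.call(rbind, res)
}

#' Correlate cell fractions with the risk score
#'
#' Pearson correlation (with two-sided p-value) between each cell type's
#' fraction and the per-sample risk score.
#'
#' @param fractions numeric matrix, samples x cell types.
#' @param scores named numeric risk scores covering the fraction rows.
#' @return data.frame with cell_type, pearson_r, p_value, note (cell types
#'   with zero variance yield NA with a note).
#' @export
correlateWithScore <- function(fractions, scores) {
    if (!is.null(names(scores)) && !is.null(rownames(fractions))) {
        if (!all(rownames(fractions) %in% names(scores)))
            stop("score(s) missing for some samples")
        scores <- scores[rownames(fractions)]
    }
    if (length(scores) != nrow(fractions))
        stop("scores and fraction rows are not aligned")
    if (nrow(fractions) < 3L) stop("correlation needs at least 3 samples")
    if (stats::sd(scores) == 0) stop("risk scores have zero variance")
    res <- lapply(colnames(fractions), function(ct) {
        f <- fractions[, ct]
        if (stats::sd(f) == 0)
            return(data.frame(cell_type = ct, pearson_r = NA_real_,
                              p_value = NA_real_, note = "zero variance",
                              stringsAsFactors = FALSE))
        ct_test <- stats::cor.test(f, scores, method = "pearson")
        data.frame(cell_type = ct, pearson_r = unname(ct_test$estimate),
                   p_value = ct_test$p.value, note = "",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
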