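#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
NULL

#' PairIndicatorMatrix: binary gene-pair indicators per sample
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"indicator"},
#' whose rows are gene pairs and whose columns are samples. Entry (p, s) is 1
#' when the first gene of pair p is expressed more highly than the second gene
#' in sample s, and 0 otherwise (ties score 0). Because each entry depends only
#' on the within-sample rank of two genes, indicator matrices computed on two
#' platforms related by any strictly increasing per-sample transform are
#' identical.
#'
#' \code{rowData} carries \code{geneA} and \code{geneB}; row names are the pair
#' ids \code{"GENEA|GENEB"}.
#'
#' @seealso [binarizePairs()], [prevalenceFilter()], [riskScore()]
#' @export
setClass("PairIndicatorMatrix", contains = "SummarizedExperiment")

setValidity("PairIndicatorMatrix", function(object) {
    msg <- character()
    if (!"indicator" %in% assayNames(object))
        msg <- c(msg, "assay 'indicator' is required")
    else {
        ind <- assay(object, "indicator")
        if (!all(ind %in% c(0L, 1L)))
            msg <- c(msg, "indicator values must all be 0 or 1")
    }
    rd <- rowData(object)
    if (!all(c("geneA", "geneB") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'geneA' and 'geneB'")
    else {
        if (any(rd$geneA == rd$geneB))
            msg <- c(msg, "a pair cannot contain the same gene twice")
        ids <- paste(rd$geneA, rd$geneB, sep = "|")
        if (anyDuplicated(ids))
            msg <- c(msg, "duplicate gene pairs are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PairIndicatorMatrix
#'
#' @param indicator integer/numeric matrix of 0/1 values, pairs x samples.
#' @param geneA,geneB character vectors naming the first and second gene of
#'   each pair (one entry per row of \code{indicator}).
#' @return A [PairIndicatorMatrix-class] object.
#' @examples
#' ind <- PairIndicatorMatrix(matrix(c(1L, 0L, 0L, 1L), 2,
#'                                   dimnames = list(NULL, c("s1", "s2"))),
#'                            geneA = c("A", "A"), geneB = c("B", "C"))
#' pairIds(ind)
#' @export
PairIndicatorMatrix <- function(indicator, geneA, geneB) {
    indicator <- as.matrix(indicator)
    storage.mode(indicator) <- "integer"
    rownames(indicator) <- paste(geneA, geneB, sep = "|")
    se <- SummarizedExperiment(
        assays = list(indicator = indicator),
        rowData = DataFrame(geneA = as.character(geneA),
                            geneB = as.character(geneB)))
    new("PairIndicatorMatrix", se)
}

#' IRGPSignature: an ordered set of gene pairs with Cox coefficients
#'
#' The portable form of a gene-pair risk model: pairs (geneA, geneB), one
#' LASSO-Cox coefficient per pair, an optional risk-score cutoff separating
#' high- from low-risk patients, and free-form metadata (training cohort,
#' ROC horizon, penalty). The risk score of a sample is
#' \eqn{\sum_k coef_k \cdot I(expr_{A_k} > expr_{B_k})}.
#'
#' @slot geneA,geneB character vectors, one entry per pair.
#' @slot coefficients numeric vector of finite regression coefficients.
#' @slot cutoff numeric(1), the risk-score cutoff (NA when not set).
#' @slot metadata named list.
#' @export
setClass("IRGPSignature",
    representation(geneA = "character", geneB = "character",
                   coefficients = "numeric", cutoff = "numeric",
                   metadata = "list"),
    prototype(cutoff = NA_real_, metadata = list()))

setValidity("IRGPSignature", function(object) {
    msg <- character()
    n <- length(object@geneA)
    if (length(object@geneB) != n || length(object@coefficients) != n)
        msg <- c(msg, "geneA, geneB and coefficients must have equal length")
    if (n > 0L) {
        if (any(object@geneA == object@geneB))
            msg <- c(msg, "a pair cannot contain the same gene twice")
        if (anyDuplicated(paste(object@geneA, object@geneB, sep = "|")))
            msg <- c(msg, "duplicate pairs are not allowed")
        if (!all(is.finite(object@coefficients)))
            msg <- c(msg, "coefficients must be finite")
    }
    if (length(object@cutoff) != 1L)
        msg <- c(msg, "cutoff must have length 1 (use NA when unset)")
    if (length(msg)) msg else TRUE
})

#' Construct an IRGPSignature
#'
#' @param geneA,geneB character vectors naming the first and second gene of
#'   each pair.
#' @param coefficients numeric vector of regression coefficients, one per pair.
#' @param cutoff optional numeric(1) risk-score cutoff.
#' @param metadata named list of free-form annotations.
#' @return An [IRGPSignature-class] object.
#' @examples
#' sig <- IRGPSignature("APOD", "CD247", 0.4253)
#' sig
#' @export
IRGPSignature <- function(geneA, geneB, coefficients, cutoff = NA_real_,
                          metadata = list()) {
    new("IRGPSignature", geneA = as.character(geneA),
        geneB = as.character(geneB),
        coefficients = as.numeric(coefficients),
        cutoff = as.numeric(cutoff)[1L], metadata = metadata)
}

#' @describeIn IRGPSignature number of pairs in the signature.
#' @param x an IRGPSignature.
#' @export
setMethod("length", "IRGPSignature", function(x) length(x@geneA))

#' @describeIn IRGPSignature the coefficient vector, named by pair id.
#' @param object an IRGPSignature.
#' @param ... ignored.
#' @export
setMethod("coef", "IRGPSignature", function(object, ...) {
    stats::setNames(object@coefficients, pairIds(object))
})

#' Pair identifiers of a signature or indicator matrix
#'
#' @param x an [IRGPSignature-class] or [PairIndicatorMatrix-class].
#' @return character vector of ids \code{"GENEA|GENEB"}.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname pairIds
#' @export
setMethod("pairIds", "IRGPSignature", function(x)
    paste(x@geneA, x@geneB, sep = "|"))

#' @rdname pairIds
#' @export
setMethod("pairIds", "PairIndicatorMatrix", function(x)
    paste(rowData(x)$geneA, rowData(x)$geneB, sep = "|"))

#' Risk-score cutoff of a signature
#' @param x an IRGPSignature.
#' @return numeric(1), NA when unset.
#' @export
setGeneric("sigCutoff", function(x) standardGeneric("sigCutoff"))

#' @rdname sigCutoff
#' @export
setMethod("sigCutoff", "IRGPSignature", function(x) x@cutoff)

#' @describeIn IRGPSignature coerce to a three-column data.frame
#'   (gene_a, gene_b, coefficient).
#' @export
setMethod("as.data.frame", "IRGPSignature", function(x, ...) {
    data.frame(gene_a = x@geneA, gene_b = x@geneB,
               coefficient = x@coefficients, stringsAsFactors = FALSE)
})

setMethod("show", "IRGPSignature", function(object) {
    cat(sprintf("IRGPSignature with %d gene pair(s) (%d unique genes)\n",
                length(object),
                length(unique(c(object@geneA, object@geneB)))))
    if (!is.na(object@cutoff))
        cat(sprintf("  risk-score cutoff: %.4f\n", object@cutoff))
    n <- length(object)
    if (n > 0L) {
        shown <- seq_len(min(n, 5L))
        for (i in shown)
            cat(sprintf("  %s|%s  %+.5f\n", object@geneA[i], object@geneB[i],
                        object@coefficients[i]))
        if (n > 5L) cat(sprintf("  ... and %d more\n", n - 5L))
    }
    invisible(NULL)
})
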