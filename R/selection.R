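#' @importFrom survival Surv coxph survfit survdiff
#' @importFrom glmnet cv.glmnet glmnet
NULL

#' SelectionResult: pair-selection frequencies from resampled LASSO-Cox
#'
#' @slot pairFrequencies named numeric in [0, 1]: for each candidate pair,
#'   the fraction of resampling iterations in which its L1-penalized Cox
#'   coefficient was nonzero.
#' @slot selectedPairs character vector of pair ids meeting the default
#'   selection rule, ordered by descending frequency.
#' @slot nIterations integer, number of resampling iterations.
#' @slot seed integer master seed.
#' @export
setClass("SelectionResult",
    representation(pairFrequencies = "numeric", selectedPairs = "character",
                   nIterations = "integer", seed = "integer"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    f <- object@pairFrequencies
    if (length(f) && (any(f < 0) || any(f > 1)))
        msg <- c(msg, "frequencies must lie in [0, 1]")
    if (!all(object@selectedPairs %in% names(f)))
        msg <- c(msg, "selectedPairs must be a subset of the candidates")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d candidate pairs, %d iterations (seed %d)\n",
                length(object@pairFrequencies), object@nIterations,
                object@seed))
    cat(sprintf("  %d pair(s) selected at the default rule\n",
                length(object@selectedPairs)))
    invisible(NULL)
})

#' Selection frequencies of a SelectionResult
#' @param x a SelectionResult.
#' @return named numeric vector of per-pair selection frequencies.
#' @export
setGeneric("pairFrequencies", function(x) standardGeneric("pairFrequencies"))

#' @rdname pairFrequencies
#' @export
setMethod("pairFrequencies", "SelectionResult", function(x) x@pairFrequencies)

#' @describeIn pairFrequencies pairs passing the default selection rule.
#' @export
setGeneric("selectedPairs", function(x) standardGeneric("selectedPairs"))

#' @rdname pairFrequencies
#' @export
setMethod("selectedPairs", "SelectionResult", function(x) x@selectedPairs)

# align indicator matrix columns with the clinical table by sample_id;
# returns list(x = samples x pairs design matrix, time, status)
.alignDesign <- function(ind, surv) {
    stopifnot(is(ind, "PairIndicatorMatrix"))
    idx <- match(surv$sample_id, colnames(ind))
    if (anyNA(idx))
        stop("clinical sample(s) absent from indicator matrix: ",
             paste(surv$sample_id[is.na(idx)], collapse = ", "))
    x <- t(assay(ind, "indicator")[, idx, drop = FALSE])
    rownames(x) <- surv$sample_id
    colnames(x) <- pairIds(ind)
    list(x = x, time = surv$time, status = surv$status)
}

# deterministic per-iteration seeds derived from one master seed
.iterationSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max, n)
}

#' Stability selection: resampled L1-penalized Cox over pair indicators
#'
#' Repeatedly subsamples the cohort (default 80\% without replacement), fits
#' an L1-penalized Cox model to the pair indicators with the penalty chosen
#' by internal cross-validation, and records which pairs receive a nonzero
#' coefficient. A pair's frequency is the fraction of iterations selecting
#' it; pairs the survival signal supports consistently accumulate high
#' frequencies while noise pairs do not. Fully deterministic given
#' \code{seed}.
#'
#' A drawn subsample must contain at least \code{nfolds} events (each
#' cross-validation fold needs an event for the partial likelihood);
#' otherwise it is redrawn, with a bounded number of retries.
#'
#' @param ind a [PairIndicatorMatrix-class] of candidate pairs.
#' @param surv clinical data.frame with sample_id, time, status; needs at
#'   least 30 samples and 10 events.
#' @param nIter number of resampling iterations (default 1000).
#' @param subsampleFrac fraction of samples drawn per iteration.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param nfolds folds for the internal cross-validation.
#' @param minFreq frequency rule used to populate \code{selectedPairs}.
#' @param nlambda length of the penalty path handed to glmnet.
#' @return a [SelectionResult-class].
#' @seealso [selectTop()], [fitFinal()]
#' @export
resampledLasso <- function(ind, surv, nIter = 1000, subsampleFrac = 0.8,
                           seed = 1L, nfolds = 5L, minFreq = 0.5,
                           nlambda = 100L) {
    d <- .alignDesign(ind, surv)
    n <- nrow(d$x)
    if (n < 30L) stop("resampled selection needs at least 30 samples")
    if (sum(d$status) < 10L) stop("resampled selection needs at least 10 events")
    if (ncol(d$x) < 2L) stop("need at least 2 candidate pairs")
    nSub <- max(2L, floor(subsampleFrac * n))
    seeds <- .iterationSeeds(seed, nIter)
    counts <- stats::setNames(numeric(ncol(d$x)), colnames(d$x))
    for (it in seq_len(nIter)) {
        set.seed(seeds[it])
        sub <- NULL
        for (try in seq_len(50L)) {
            cand <- sample.int(n, nSub)
            if (sum(d$status[cand]) >= nfolds) { sub <- cand; break }
        }
        if (is.null(sub))
            stop("could not draw a subsample with enough events (iteration ",
                 it, ")")
        foldid <- sample(rep_len(seq_len(nfolds), nSub))
        y <- Surv(d$time[sub], d$status[sub])
        fit <- cv.glmnet(d$x[sub, , drop = FALSE], y, family = "cox",
                         foldid = foldid, nlambda = nlambda)
        beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
        counts[beta != 0] <- counts[beta != 0] + 1
    }
    freq <- counts / nIter
    res <- new("SelectionResult", pairFrequencies = freq,
               selectedPairs = character(), nIterations = as.integer(nIter),
               seed = as.integer(seed))
    sel <- tryCatch(selectTop(res, minFreq = minFreq),
                    error = function(e) character())
    res@selectedPairs <- sel
    res
}

#' Pick the highest-frequency pairs
#'
#' Orders pairs by descending selection frequency, breaking ties
#' lexicographically by pair id, then applies either a frequency floor or a
#' top-k rule.
#'
#' @param result a [SelectionResult-class].
#' @param minFreq keep pairs with frequency >= \code{minFreq} (default 0.5).
#' @param topK alternatively, keep the k highest-frequency pairs.
#' @return character vector of pair ids (descending frequency).
#' @export
selectTop <- function(result, minFreq = 0.5, topK = NULL) {
    freq <- pairFrequencies(result)
    if (!length(freq)) stop("no candidate pairs in selection result")
    ord <- order(-freq, names(freq), method = "radix")
    ranked <- freq[ord]
    out <- if (is.null(topK)) names(ranked)[ranked >= minFreq]
           else names(ranked)[seq_len(min(topK, length(ranked)))]
    if (!length(out)) stop("selection rule matched zero pairs")
    out
}

#' Final coefficient fit for the selected pairs
#'
#' One L1-penalized Cox fit on the full training cohort restricted to the
#' selected pairs, at the cross-validation-optimal penalty; pairs whose final
#' coefficient is exactly zero are dropped (reported via \code{message()}).
#' With a single selected pair an unpenalized Cox model is fitted instead
#' (the penalized path needs two or more columns).
#'
#' @param ind a [PairIndicatorMatrix-class] containing the selected pairs.
#' @param surv clinical data.frame with sample_id, time, status.
#' @param pairs character vector of pair ids to fit.
#' @param seed seed for the cross-validation fold assignment.
#' @param nfolds folds for the penalty cross-validation.
#' @return an [IRGPSignature-class] with fitted coefficients and metadata
#'   (penalty, seed, sample and event counts).
#' @export
fitFinal <- function(ind, surv, pairs, seed = 1L, nfolds = 5L) {
    if (length(pairs) < 1L) stop("no pairs selected")
    d <- .alignDesign(ind, surv)
    missing <- setdiff(pairs, colnames(d$x))
    if (length(missing))
        stop("selected pair(s) absent from indicator matrix: ",
             paste(missing, collapse = ", "))
    x <- d$x[, pairs, drop = FALSE]
    y <- Surv(d$time, d$status)
    meta <- list(seed = as.integer(seed), n_samples = nrow(x),
                 n_events = sum(d$status))
    if (length(pairs) == 1L) {
        fit <- coxph(y ~ x, ties = "breslow")
        beta <- stats::setNames(as.numeric(stats::coef(fit)), pairs)
        meta$fit <- "coxph"
    } else {
        set.seed(seed)
        foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
        cv <- cv.glmnet(x, y, family = "cox", foldid = foldid)
        beta <- stats::setNames(as.numeric(stats::coef(cv, s = "lambda.min")),
                                pairs)
        meta$fit <- "glmnet"
        meta$lambda <- cv$lambda.min
    }
    if (any(!is.finite(beta)))
        stop("final Cox fit did not converge: non-finite coefficient(s) for ",
             paste(pairs[!is.finite(beta)], collapse = ", "))
    zero <- beta == 0
    if (any(zero))
        message(sum(zero), " pair(s) dropped with zero final coefficient: ",
                paste(pairs[zero], collapse = ", "))
    beta <- beta[!zero]
    if (!length(beta)) stop("all final coefficients are zero")
    parts <- strsplit(names(beta), "|", fixed = TRUE)
    IRGPSignature(geneA = vapply(parts, `[`, "", 1L),
                  geneB = vapply(parts, `[`, "", 2L),
                  coefficients = as.numeric(beta), metadata = meta)
}
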