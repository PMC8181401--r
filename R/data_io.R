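#' Read a gene-expression matrix, collapsing duplicate symbols
#'
#' Reads a genes-x-samples matrix from TSV or CSV (extension-detected). The
#' first column holds gene or probe symbols; the header holds sample ids.
#' When several probes map to the same symbol their rows are collapsed by the
#' arithmetic mean on the native scale, and the collapsed row keeps the
#' position of the symbol's first occurrence.
#'
#' @param path path to a TSV/CSV file.
#' @param collapse collapsing strategy for duplicate symbols; only
#'   \code{"mean"} is provided.
#' @return numeric matrix (genes x samples) with unique rownames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "TP53\t2\t4", "TP53\t4\t6", "EGFR\t1\t1"), tf)
#' readExpression(tf)   # TP53 collapsed to (3, 5)
#' @export
readExpression <- function(path, collapse = c("mean")) {
    collapse <- match.arg(collapse)
    raw <- .readTable(path)
    if (nrow(raw) == 0L)
        stop("expression file '", path, "' contains no data rows")
    symbols <- as.character(raw[[1L]])
    sampleIds <- colnames(raw)[-1L]
    if (length(sampleIds) == 0L)
        stop("expression file '", path, "' has no sample columns")
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ids in header: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    values <- as.matrix(raw[, -1L, drop = FALSE])
    vals <- values
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals)) {
        bad <- which(is.na(vals), arr.ind = TRUE)
        stop(sprintf("non-numeric expression value at row %d, column '%s'",
                     bad[1L, 1L], sampleIds[bad[1L, 2L]]))
    }
    values <- vals
    if (any(!is.finite(values)))
        stop("expression values must be finite")
    if (any(values < 0))
        stop("expression values must be non-negative")
    collapsed <- collapseProbes(values, symbols)
    colnames(collapsed) <- sampleIds
    collapsed
}

#' Collapse duplicate-symbol rows by arithmetic mean
#'
#' @param values numeric matrix, one row per probe.
#' @param symbols character vector of symbols, one per row of \code{values};
#'   defaults to \code{rownames(values)}.
#' @return numeric matrix with one row per unique symbol, in first-occurrence
#'   order. Idempotent: a matrix with unique symbols is returned unchanged.
#' @export
collapseProbes <- function(values, symbols = rownames(values)) {
    if (is.null(symbols))
        stop("no symbols supplied and 'values' has no rownames")
    order1st <- unique(symbols)
    grp <- factor(symbols, levels = order1st)
    sums <- rowsum(values, grp, reorder = FALSE)
    counts <- as.integer(table(grp))
    out <- sums / counts
    rownames(out) <- order1st
    out
}

#' Read a clinical survival table
#'
#' Expects a TSV with required columns \code{sample_id}, \code{time} and
#' \code{status} (1 = death, 0 = censored); any further columns (age, gender,
#' t_stage, n_stage, m_stage, grade, ...) are carried through as covariates.
#' Times are canonicalized to months (1 year = 12 months, 1 month = 30.44
#' days). Rows with missing time or status are dropped and the count is
#' reported via \code{message()}.
#'
#' @param path path to a TSV file.
#' @param time_unit unit of the \code{time} column in the file.
#' @return data.frame with columns sample_id, time (months), status and any
#'   covariates, plus attribute \code{"n_dropped"}.
#' @export
readSurvival <- function(path, time_unit = c("months", "days", "years")) {
    time_unit <- match.arg(time_unit)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    required <- c("sample_id", "time", "status")
    missingCols <- setdiff(required, colnames(df))
    if (length(missingCols))
        stop("clinical table is missing required column(s): ",
             paste(missingCols, collapse = ", "))
    df$time <- suppressWarnings(as.numeric(df$time))
    df$status <- suppressWarnings(as.numeric(df$status))
    keep <- !is.na(df$time) & !is.na(df$status)
    nDropped <- sum(!keep)
    if (nDropped > 0L)
        message(nDropped, " row(s) dropped for missing time or status")
    df <- df[keep, , drop = FALSE]
    if (any(df$time <= 0))
        stop("survival times must be positive")
    if (!all(df$status %in% c(0, 1)))
        stop("status must be 0 (censored) or 1 (death)")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample ids in clinical table")
    df$time <- switch(time_unit,
        months = df$time,
        days   = df$time / 30.44,
        years  = df$time * 12)
    rownames(df) <- NULL
    attr(df, "n_dropped") <- nDropped
    df
}

#' Read an immune (or any) gene list
#'
#' Plain text, one symbol per line; blank lines are skipped and duplicates
#' removed.
#'
#' @param path path to the list file.
#' @return character vector of unique symbols.
#' @export
readGeneList <- function(path) {
    symbols <- trimws(readLines(path, warn = FALSE))
    symbols <- unique(symbols[nzchar(symbols)])
    if (length(symbols) == 0L)
        stop("gene list '", path, "' is empty")
    symbols
}

#' Read a gene-pair signature
#'
#' Accepts the package's JSON layout
#' (\code{\{pairs: [\{gene_a, gene_b, coefficient\}], cutoff, metadata\}}) or a
#' three-column TSV with header \code{gene_a}, \code{gene_b},
#' \code{coefficient}.
#'
#' @param path path ending in \code{.json} or a TSV path.
#' @return an [IRGPSignature-class].
#' @examples
#' sig <- readSignature(system.file("extdata", "hnscc_irgp22_signature.tsv",
#'                                  package = "irgpairs"))
#' signatureSummary(sig)
#' @export
readSignature <- function(path) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
        pairs <- obj$pairs
        cutoff <- if (!is.null(obj$cutoff)) as.numeric(obj$cutoff) else NA_real_
        meta <- if (!is.null(obj$metadata)) as.list(obj$metadata) else list()
    } else {
        pairs <- utils::read.delim(path, stringsAsFactors = FALSE)
        cutoff <- NA_real_
        meta <- list()
    }
    required <- c("gene_a", "gene_b", "coefficient")
    if (!all(required %in% colnames(pairs)))
        stop("signature file must provide columns gene_a, gene_b, coefficient")
    coefs <- suppressWarnings(as.numeric(pairs$coefficient))
    if (anyNA(coefs))
        stop("unparseable coefficient at signature row ",
             which(is.na(coefs))[1L])
    ids <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
    if (anyDuplicated(ids))
        stop("duplicate pair in signature: ", ids[duplicated(ids)][1L])
    IRGPSignature(pairs$gene_a, pairs$gene_b, coefs, cutoff = cutoff,
                  metadata = meta)
}

#' Write a gene-pair signature
#'
#' JSON (\code{.json} extension) preserves the cutoff and metadata; the TSV
#' dialect is tab-separated with a header and coefficients serialized with six
#' decimals. \code{readSignature(writeSignature(sig, path))} is an identity on
#' pairs and coefficients.
#'
#' @param sig an [IRGPSignature-class].
#' @param path output path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
writeSignature <- function(sig, path) {
    stopifnot(is(sig, "IRGPSignature"))
    df <- as.data.frame(sig)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        obj <- list(pairs = df)
        if (!is.na(sig@cutoff)) obj$cutoff <- sig@cutoff
        if (length(sig@metadata)) obj$metadata <- sig@metadata
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    } else {
        df$coefficient <- sprintf("%.6f", df$coefficient)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
    }
    invisible(path)
}

#' Summarize a signature
#'
#' @param sig an [IRGPSignature-class].
#' @return list with \code{n_pairs}, \code{n_unique_genes}, \code{min_coef},
#'   \code{max_coef}.
#' @export
signatureSummary <- function(sig) {
    stopifnot(is(sig, "IRGPSignature"))
    list(n_pairs = length(sig),
         n_unique_genes = length(unique(c(sig@geneA, sig@geneB))),
         min_coef = min(sig@coefficients),
         max_coef = max(sig@coefficients))
}

#' Stratified cohort characteristics table
#'
#' Builds the standard clinical "Table 1": per group, the sample count, age
#' summaries (mean, median, min, max) and for each categorical covariate the
#' level counts with within-group percentages to one decimal, including an
#' explicit "Missing" row whenever values are absent.
#'
#' @param surv survival/clinical data.frame as returned by [readSurvival()].
#' @param groups character/factor of per-sample group labels, named by
#'   sample id or aligned with \code{surv} rows.
#' @param categorical columns of \code{surv} to tabulate; defaults to every
#'   non-numeric covariate column.
#' @return data.frame with columns \code{variable}, \code{level}, then one
#'   formatted \code{"count (pct)"} column per group.
#' @examples
#' surv <- data.frame(sample_id = paste0("s", 1:6),
#'                    time = c(5, 8, 12, 3, 9, 20),
#'                    status = c(1, 0, 1, 1, 0, 0),
#'                    age = c(61, 58, 70, 64, 55, 49),
#'                    gender = c("Male", "Male", "Female", "Male",
#'                               "Female", "Male"))
#' cohortTable(surv, groups = c("low", "low", "high", "high", "low", "high"))
#' @export
cohortTable <- function(surv, groups, categorical = NULL) {
    if (!is.null(names(groups))) {
        if (!all(surv$sample_id %in% names(groups)))
            stop("groups do not cover all samples")
        groups <- groups[surv$sample_id]
    }
    if (length(groups) != nrow(surv))
        stop("groups must have one label per sample")
    groups <- as.character(groups)
    lvls <- unique(groups)
    reserved <- c("sample_id", "time", "status", "age")
    if (is.null(categorical)) {
        categorical <- setdiff(colnames(surv), reserved)
        categorical <- categorical[!vapply(surv[categorical], is.numeric,
                                           logical(1L))]
    }
    rows <- list()
    addRow <- function(variable, level, cells)
        rows[[length(rows) + 1L]] <<- c(list(variable = variable,
                                             level = level), cells)
    cellsFor <- function(f) {
        out <- lapply(lvls, function(g) f(surv[groups == g, , drop = FALSE]))
        names(out) <- lvls
        out
    }
    addRow("N", "", cellsFor(function(d) as.character(nrow(d))))
    if ("age" %in% colnames(surv)) {
        addRow("Age", "Mean", cellsFor(function(d)
            sprintf("%.1f", mean(d$age, na.rm = TRUE))))
        addRow("Age", "Median (min, max)", cellsFor(function(d)
            sprintf("%g (%g, %g)", stats::median(d$age, na.rm = TRUE),
                    min(d$age, na.rm = TRUE), max(d$age, na.rm = TRUE))))
    }
    for (var in categorical) {
        vals <- as.character(surv[[var]])
        vals[is.na(vals) | !nzchar(vals)] <- "Missing"
        levels <- unique(vals[vals != "Missing"])
        if ("Missing" %in% vals) levels <- c(levels, "Missing")
        for (lev in levels) {
            addRow(var, lev, cellsFor(function(d) {
                v <- as.character(d[[var]])
                v[is.na(v) | !nzchar(v)] <- "Missing"
                formatCountPct(sum(v == lev), nrow(d))
            }))
        }
    }
    do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
}

# "214 (74.8%)" style cell; zero counts print "0 (0%)" and whole percentages
# drop the trailing ".0" (so 21/21 prints "21 (100%)").
formatCountPct <- function(count, total) {
    if (count == 0L || total == 0L) return("0 (0%)")
    pct <- sprintf("%.1f", 100 * count / total)
    pct <- sub("\\.0$", "", pct)
    sprintf("%d (%s%%)", count, pct)
}

# shared TSV/CSV reader: comma for .csv, tab otherwise
.readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) stop("file '", path, "' is empty")
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
}
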