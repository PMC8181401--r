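suppressPackageStartupMessages(library(SummarizedExperiment))

# random positive expression matrix with unique gene symbols
randomExpr <- function(nGenes, nSamples, seed) {
    set.seed(seed)
    matrix(round(runif(nGenes * nSamples, 0, 100), 3), nrow = nGenes,
           dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                           sprintf("s%03d", seq_len(nSamples))))
}

writeTsv <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}

# independent oracle: per-gene MAD as the literal median of absolute
# deviations from the median
oracleMad <- function(x) median(abs(x - median(x)))

# independent oracle: exhaustive pairwise within-sample comparison
oracleBinarize <- function(expr) {
    G <- nrow(expr)
    rows <- list(); ga <- character(); gb <- character()
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
        rows[[length(rows) + 1L]] <-
            as.integer(expr[i, ] > expr[j, ])
        ga <- c(ga, rownames(expr)[i]); gb <- c(gb, rownames(expr)[j])
    }
    out <- do.call(rbind, rows)
    dimnames(out) <- list(paste(ga, gb, sep = "|"), colnames(expr))
    out
}

# independent oracle: plain binary ROC (labels 0/1), thresholds at unique
# score values, positive = score > threshold
oracleBinaryRoc <- function(scores, labels) {
    thr <- sort(unique(scores))
    sens <- vapply(thr, function(c) mean(scores[labels == 1] > c), 0)
    spec <- vapply(thr, function(c) mean(scores[labels == 0] <= c), 0)
    list(thresholds = thr, sensitivity = sens, specificity = spec)
}

# independent oracle: two-group log-rank by explicit hypergeometric tally
oracleLogrank <- function(time, status, group) {
    group <- as.integer(factor(group)) - 1L   # 0/1
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[status == 1]))) {
        atRisk <- time >= t
        n <- sum(atRisk); n1 <- sum(atRisk & group == 1)
        d <- sum(time == t & status == 1)
        d1 <- sum(time == t & status == 1 & group == 1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    chisq <- (O - E)^2 / V
    list(statistic = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# strictly increasing per-sample transform families used in the invariance
# checks; each sample of a matrix gets its own family member
monotoneDistort <- function(expr, seed) {
    set.seed(seed)
    fams <- sample(3, ncol(expr), replace = TRUE)
    out <- expr
    for (s in seq_len(ncol(expr))) {
        x <- expr[, s]
        out[, s] <- switch(fams[s],
                           2 * x + 7,
                           x^3,
                           log(x + 1))
    }
    out
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))
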