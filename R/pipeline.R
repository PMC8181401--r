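#' Run the full gene-pair signature pipeline from a config
#'
#' Executes the study's stages in order — cohort acquisition (simulated or
#' read from disk), pair binarization with MAD and prevalence filtering,
#' resampled LASSO-Cox training, risk scoring, survival evaluation
#' (time-dependent ROC cutoff, Kaplan-Meier, log-rank, Cox models) and,
#' optionally, immune-fraction association — writing each stage's artifacts
#' under \code{outdir} and finally a run manifest with the config snapshot,
#' md5 digests of every input consumed, the seed, package version, per-stage
#' timings and output paths.
#'
#' With \code{resume = TRUE}, a stage whose outputs already exist is loaded
#' from disk instead of recomputed, so stage-by-stage execution equals a
#' single-shot run on identical inputs and seed.
#'
#' @param config path to a YAML file or an equivalent named list. Required
#'   fields: \code{seed}, \code{outdir}, and either \code{simulate} (passed
#'   to [simSpec()]: n_samples, n_genes, n_informative_pairs,
#'   censoring_rate, distortion) or \code{inputs} (\code{expression} and
#'   \code{clinical} paths, optional \code{gene_list}, \code{time_unit}).
#'   Optional blocks \code{binarize} (mad_threshold 0.5, mad_scale,
#'   prevalence_min 0.20), \code{train} (iterations 1000, subsample_frac
#'   0.8, min_freq 0.5), \code{evaluate} (cutoff_horizon 36,
#'   validation_horizon 60) and \code{immune} (\code{simulate: true} or a
#'   \code{basis}/\code{mixture} pair of paths) override the defaults.
#' @param resume reuse existing stage outputs when present.
#' @return the run manifest, invisibly (also written to
#'   \code{outdir/manifest.json}).
#' @examples
#' \donttest{
#' cfg <- list(seed = 7, outdir = tempfile(),
#'             simulate = list(n_samples = 120, n_genes = 25),
#'             train = list(iterations = 20))
#' manifest <- runPipeline(cfg)
#' names(manifest$stages)
#' }
#' @export
runPipeline <- function(config, resume = FALSE) {
    cfg <- .validateConfig(config)
    outdir <- cfg$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stages <- list()
    digests <- list()
    outputs <- list()
    tic <- function() proc.time()[["elapsed"]]
    record <- function(name, t0, files) {
        stages[[name]] <<- list(seconds = round(tic() - t0, 3),
                                outputs = unname(files))
        outputs[[name]] <<- files
    }
    p <- function(...) file.path(outdir, ...)

    ## stage 1: cohort (simulate or ingest) --------------------------------
    t0 <- tic()
    exprPath <- p("expression.tsv"); clinPath <- p("clinical.tsv")
    if (!is.null(cfg$simulate)) {
        if (resume && file.exists(exprPath) && file.exists(clinPath)) {
            expr <- readExpression(exprPath)
            surv <- readSurvival(clinPath)
        } else {
            sim <- cfg$simulate
            spec <- simSpec(nSamples = sim$n_samples %||% 300L,
                            nGenes = sim$n_genes %||% 100L,
                            nInformativePairs = sim$n_informative_pairs %||% 5L,
                            censoringRate = sim$censoring_rate %||% 0.3,
                            distortion = sim$distortion %||% "exp",
                            seed = cfg$seed)
            cohort <- simulateCohort(spec)
            expr <- cohort$expression
            surv <- cohort$survival
            .writeMatrix(expr, exprPath, "gene")
            utils::write.table(surv, clinPath, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            jsonlite::write_json(
                list(informative_pairs = cohort$truth$informativePairs,
                     coefficients = cohort$truth$coefficients,
                     censoring_rate = cohort$truth$censoringRateRealized),
                p("truth.json"), auto_unbox = TRUE, digits = NA)
        }
    } else {
        digests$expression <- unname(tools::md5sum(cfg$inputs$expression))
        digests$clinical <- unname(tools::md5sum(cfg$inputs$clinical))
        expr <- readExpression(cfg$inputs$expression)
        surv <- readSurvival(cfg$inputs$clinical,
                             time_unit = cfg$inputs$time_unit %||% "months")
        if (!is.null(cfg$inputs$gene_list)) {
            digests$gene_list <- unname(tools::md5sum(cfg$inputs$gene_list))
            expr <- restrictToGenes(expr, readGeneList(cfg$inputs$gene_list))
        }
        .writeMatrix(expr, exprPath, "gene")
        utils::write.table(surv, clinPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    record("cohort", t0, c(expression = exprPath, clinical = clinPath))

    ## stage 2: binarize ----------------------------------------------------
    t0 <- tic()
    pairsPath <- p("pairs.tsv")
    bz <- cfg$binarize %||% list()
    if (resume && file.exists(pairsPath)) {
        ind <- readPairMatrix(pairsPath)
    } else {
        kept <- madFilter(expr, threshold = bz$mad_threshold %||% 0.5,
                          scale = bz$mad_scale %||% "native")
        message(nrow(kept), " of ", nrow(expr), " genes pass the MAD filter")
        ind <- binarizePairs(kept)
        ind <- prevalenceFilter(ind, minFrac = bz$prevalence_min %||% 0.20)
        message(nrow(ind), " pairs pass the prevalence filter")
        writePairMatrix(ind, pairsPath)
    }
    record("binarize", t0, c(pairs = pairsPath))

    ## stage 3: train -------------------------------------------------------
    t0 <- tic()
    sigPath <- p("signature.json"); freqPath <- p("frequencies.tsv")
    tr <- cfg$train %||% list()
    if (resume && file.exists(sigPath)) {
        sig <- readSignature(sigPath)
    } else {
        sel <- resampledLasso(ind, surv,
                              nIter = tr$iterations %||% 1000L,
                              subsampleFrac = tr$subsample_frac %||% 0.8,
                              seed = cfg$seed,
                              minFreq = tr$min_freq %||% 0.5)
        utils::write.table(
            data.frame(pair = names(pairFrequencies(sel)),
                       frequency = pairFrequencies(sel)),
            freqPath, sep = "\t", quote = FALSE, row.names = FALSE)
        sig <- fitFinal(ind, surv, selectedPairs(sel), seed = cfg$seed)
        writeSignature(sig, sigPath)
    }
    record("train", t0, c(signature = sigPath, frequencies = freqPath))

    ## stage 4: score -------------------------------------------------------
    t0 <- tic()
    scoresPath <- p("scores.tsv")
    scores <- riskScore(ind, sig)
    utils::write.table(data.frame(sample_id = names(scores),
                                  risk_score = sprintf("%.10g", scores)),
                       scoresPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("score", t0, c(scores = scoresPath))

    ## stage 5: evaluate ----------------------------------------------------
    t0 <- tic()
    ev <- cfg$evaluate %||% list()
    roc <- tdRoc(scores, surv, horizon = ev$cutoff_horizon %||% 36)
    groups <- assignGroups(scores, roc$optimal_cutoff)
    km <- kmCurve(surv, groups)
    lr <- logrankTest(surv, groups)
    survCox <- surv
    survCox$risk_group <- groups
    covs <- intersect(c("risk_group", "age", "gender", "t_stage", "n_stage",
                        "grade"), colnames(survCox))
    cox <- suppressWarnings(coxModels(survCox, covs))
    rocPath <- p("roc.tsv"); kmPath <- p("km.tsv"); coxPath <- p("cox.tsv")
    sumPath <- p("summary.json")
    utils::write.table(data.frame(threshold = roc$thresholds,
                                  sensitivity = roc$sensitivity,
                                  specificity = roc$specificity),
                       rocPath, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(km, kmPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cox, coxPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(
        auc = roc$auc, cutoff = roc$optimal_cutoff,
        sensitivity = roc$optimal_sens, specificity = roc$optimal_spec,
        logrank_statistic = lr$statistic, logrank_p = lr$p_value,
        n_high = sum(groups == "high"), n_low = sum(groups == "low")),
        sumPath, auto_unbox = TRUE, digits = NA)
    record("evaluate", t0, c(roc = rocPath, km = kmPath, cox = coxPath,
                             summary = sumPath))

    ## stage 6: immune association (optional) -------------------------------
    if (!is.null(cfg$immune)) {
        t0 <- tic()
        im <- cfg$immune
        if (isTRUE(im$simulate)) {
            spec <- simSpec(seed = cfg$seed)
            imm <- simulateImmune(spec, scores)
            mixture <- imm$mixture; basis <- imm$basis
        } else {
            digests$basis <- unname(tools::md5sum(im$basis))
            basis <- as.matrix(.readTable(im$basis)[, -1L, drop = FALSE])
            rownames(basis) <- .readTable(im$basis)[[1L]]
            mixture <- if (!is.null(im$mixture)) {
                digests$mixture <- unname(tools::md5sum(im$mixture))
                readExpression(im$mixture)
            } else expr
        }
        fractions <- deconvolve(mixture, basis)
        tests <- compareGroups(fractions, groups)
        cors <- correlateWithScore(fractions, scores)
        frPath <- p("fractions.tsv"); gtPath <- p("group_tests.tsv")
        crPath <- p("correlations.tsv")
        .writeMatrix(t(fractions), frPath, "cell_type")
        utils::write.table(tests, gtPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(cors, crPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record("immune_assoc", t0, c(fractions = frPath, group_tests = gtPath,
                                     correlations = crPath))
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("irgpairs")),
        seed = cfg$seed,
        config = cfg,
        input_digests = digests,
        stages = stages,
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeMatrix <- function(mat, path, idCol) {
    df <- data.frame(rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idCol
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# minimal schema check with errors naming the offending field
.validateConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a YAML file path or a list")
    problems <- character()
    if (is.null(config$seed)) problems <- c(problems, "missing field: seed")
    if (is.null(config$outdir))
        problems <- c(problems, "missing field: outdir")
    if (is.null(config$simulate) && is.null(config$inputs))
        problems <- c(problems,
                      "one of 'simulate' or 'inputs' must be present")
    if (!is.null(config$inputs)) {
        for (f in c("expression", "clinical"))
            if (is.null(config$inputs[[f]]))
                problems <- c(problems,
                              sprintf("missing field: inputs.%s", f))
    }
    if (length(problems))
        stop("invalid pipeline config:\n  ",
             paste(problems, collapse = "\n  "))
    config$seed <- as.integer(config$seed)
    config
}
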