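#' Specification of a synthetic survival-expression cohort
#'
#' Bundles every knob of the generator. The defaults emulate the structure
#' of a multi-platform tumor-cohort study: a few hundred patients, ~100
#' candidate genes, a handful of truly prognostic gene pairs with log-hazard
#' effects of magnitude 1, a Weibull baseline hazard (shape 1.2, so the
#' proportional-hazards fit is non-trivial but correct), ~30\% independent
#' right censoring, and per-sample strictly monotone distortions of the
#' latent expression standing in for platform/normalization differences.
#'
#' @param nSamples number of patients.
#' @param nGenes number of genes.
#' @param nInformativePairs number of gene pairs whose indicators drive the
#'   hazard.
#' @param pairCoefficients true log-hazard coefficients, recycled to
#'   \code{nInformativePairs}; defaults to alternating +1/-1.
#' @param weibullShape,weibullScale baseline Weibull hazard parameters
#'   (scale in months).
#' @param censoringRate target fraction of censored subjects, in (0, 1).
#' @param distortion per-sample monotone transform family: \code{"exp"}
#'   (x -> exp(bx + c)), \code{"power"} (shifted power), \code{"affine"},
#'   \code{"none"}, or \code{"broken"} — a deliberately non-monotone map
#'   that demonstrates when rank-based features fail.
#' @param immune immune-simulation settings: \code{nCellTypes},
#'   \code{markersPerType}, \code{noiseSd} (relative to mean signal),
#'   \code{concentration} (Dirichlet), \code{plantedCorrelations} (numeric,
#'   one target Pearson r per cell type against the risk score).
#' @param seed integer master seed; the generator is fully deterministic
#'   given this specification object.
#' @return list of class \code{"SimulationSpec"}.
#' @export
simSpec <- function(nSamples = 300L, nGenes = 100L, nInformativePairs = 5L,
                    pairCoefficients = NULL,
                    weibullShape = 1.2, weibullScale = 60,
                    censoringRate = 0.3,
                    distortion = c("exp", "power", "affine", "none", "broken"),
                    immune = list(), seed = 1L) {
    distortion <- match.arg(distortion)
    if (is.null(pairCoefficients) && nInformativePairs > 0L)
        pairCoefficients <- rep_len(c(1, -1), nInformativePairs)
    if (nInformativePairs > 0L)
        pairCoefficients <- rep_len(pairCoefficients, nInformativePairs)
    if (nInformativePairs > nGenes * (nGenes - 1) / 2)
        stop("more informative pairs requested than pairs exist")
    if (censoringRate <= 0 || censoringRate >= 1)
        stop("censoringRate must be in (0, 1)")
    imm <- utils::modifyList(
        list(nCellTypes = 5L, markersPerType = 20L, noiseSd = 0.05,
             concentration = 5, plantedCorrelations = NULL), immune)
    if (is.null(imm$plantedCorrelations))
        imm$plantedCorrelations <- rep(0, imm$nCellTypes)
    structure(list(nSamples = as.integer(nSamples),
                   nGenes = as.integer(nGenes),
                   nInformativePairs = as.integer(nInformativePairs),
                   pairCoefficients = pairCoefficients,
                   weibullShape = weibullShape, weibullScale = weibullScale,
                   censoringRate = censoringRate, distortion = distortion,
                   immune = imm, seed = as.integer(seed)),
              class = "SimulationSpec")
}

# gene population: means, dispersions and the identity of the informative
# pairs. Kept separate from sample draws so independent cohorts (training /
# validation / extra replicates) can share one ground truth.
.simPopulation <- function(spec) {
    set.seed(spec$seed)
    G <- spec$nGenes
    mu <- stats::runif(G, 2, 8)
    sd <- stats::runif(G, 0.5, 1.5)
    genes <- sprintf("IRG%03d", seq_len(G))
    pairs <- matrix(integer(), nrow = 0L, ncol = 2L)
    if (spec$nInformativePairs > 0L) {
        # informative pairs drawn so the indicator is not near-constant:
        # latent prevalence P(A > B) kept inside [0.25, 0.75]
        seen <- character()
        tries <- 0L
        while (nrow(pairs) < spec$nInformativePairs) {
            tries <- tries + 1L
            if (tries > 20000L)
                stop("could not find enough balanced informative pairs")
            ij <- sort(sample.int(G, 2L))
            key <- paste(ij, collapse = "-")
            if (key %in% seen) next
            prev <- stats::pnorm((mu[ij[1L]] - mu[ij[2L]]) /
                                 sqrt(sd[ij[1L]]^2 + sd[ij[2L]]^2))
            if (prev < 0.25 || prev > 0.75) next
            seen <- c(seen, key)
            pairs <- rbind(pairs, ij)
        }
    }
    list(mu = mu, sd = sd, genes = genes, pairs = pairs,
         coefficients = spec$pairCoefficients)
}

# strictly increasing per-sample transforms ("broken" is intentionally not)
.distort <- function(latent, family) {
    n <- ncol(latent)
    shift <- min(latent) - 0.1
    out <- switch(family,
        none   = latent - shift,
        exp    = {
            b <- stats::runif(n, 0.5, 1.5); c <- stats::runif(n, -1, 1)
            exp(sweep(sweep(latent, 2L, b, `*`), 2L, c, `+`))
        },
        power  = {
            p <- stats::runif(n, 0.8, 1.4); k <- stats::runif(n, 0.5, 2)
            sweep(sweep(latent - shift, 2L, rep(1, n), `*`)^
                      rep(p, each = nrow(latent)), 2L, k, `*`)
        },
        affine = {
            b <- stats::runif(n, 0.5, 3); c <- stats::runif(n, 0, 5)
            sweep(sweep(latent - shift, 2L, b, `*`), 2L, c, `+`)
        },
        broken = abs(sweep(latent, 2L, apply(latent, 2L, stats::median))))
    dimnames(out) <- dimnames(latent)
    out
}

# exponential censoring rate solved so the expected censored fraction over
# the realized event times matches the target
.censoringRate <- function(eventTimes, target) {
    f <- function(lr) mean(1 - exp(-exp(lr) * eventTimes)) - target
    r <- stats::uniroot(f, lower = -30, upper = 30, extendInt = "yes")
    exp(r$root)
}

.simClinical <- function(n, sampleIds, time, status) {
    age <- pmin(pmax(round(stats::rnorm(n, 61, 10)), 19), 90)
    pick <- function(levels, prob) sample(levels, n, TRUE, prob)
    holes <- function(x, rate = 0.03)
        replace(x, stats::runif(n) < rate, NA)
    data.frame(sample_id = sampleIds, time = time, status = status,
               age = age,
               gender = pick(c("Male", "Female"), c(0.75, 0.25)),
               t_stage = holes(pick(c("T1-2", "T3-4"), c(0.4, 0.6))),
               n_stage = holes(pick(c("N-", "N+"), c(0.45, 0.55))),
               m_stage = holes(pick(c("M0", "M1"), c(0.97, 0.03))),
               grade = pick(c("I-II", "III-IV"), c(0.25, 0.75)),
               stringsAsFactors = FALSE)
}

#' Simulate a survival cohort with planted prognostic gene pairs
#'
#' Draws latent per-gene Gaussian log-expression, designates
#' \code{nInformativePairs} gene pairs, computes their within-sample
#' indicators, and generates right-censored survival from a Cox-Weibull
#' model whose linear predictor is \code{sum(coef * indicator)}. Censoring is
#' independent exponential with the rate solved numerically for the target
#' censoring fraction. The observed expression is a per-sample strictly
#' monotone distortion of the latent values, so cross-platform heterogeneity
#' is present but the pair indicators are unaffected.
#'
#' @param spec a [simSpec()] object.
#' @param population optional population record (from a previous cohort's
#'   \code{truth$population}) to reuse the same genes, informative pairs and
#'   coefficients for an independent replicate.
#' @param seed overrides \code{spec$seed} for the sample draw (the
#'   population stays tied to \code{spec$seed} unless given explicitly).
#' @return list with \code{expression} (genes x samples, observed scale),
#'   \code{survival} (clinical data.frame with covariates and missingness)
#'   and \code{truth} (informative pairs, true coefficients, true
#'   indicators, latent matrix, linear predictor, realized censoring rate,
#'   population record).
#' @examples
#' cohort <- simulateCohort(simSpec(nSamples = 50, nGenes = 20, seed = 7))
#' dim(cohort$expression)
#' mean(cohort$survival$status == 0)   # ~ censoring target
#' @export
simulateCohort <- function(spec, population = NULL, seed = spec$seed) {
    stopifnot(inherits(spec, "SimulationSpec"))
    if (is.null(population)) population <- .simPopulation(spec)
    set.seed(seed)
    n <- spec$nSamples; G <- spec$nGenes
    sampleIds <- sprintf("S%04d", seq_len(n))
    latent <- matrix(stats::rnorm(G * n, population$mu, population$sd),
                     nrow = G, dimnames = list(population$genes, sampleIds))
    pairs <- population$pairs
    if (nrow(pairs) > 0L) {
        Z <- (latent[pairs[, 1L], , drop = FALSE] >
              latent[pairs[, 2L], , drop = FALSE]) + 0L
        rownames(Z) <- paste(population$genes[pairs[, 1L]],
                             population$genes[pairs[, 2L]], sep = "|")
        lp <- as.numeric(crossprod(Z, population$coefficients))
    } else {
        Z <- matrix(integer(), 0L, n)
        lp <- numeric(n)
    }
    lp <- lp - mean(lp)
    eventT <- spec$weibullScale *
        (-log(stats::runif(n)) / exp(lp))^(1 / spec$weibullShape)
    rate <- .censoringRate(eventT, spec$censoringRate)
    censT <- stats::rexp(n, rate)
    time <- pmin(eventT, censT)
    status <- as.integer(eventT <= censT)
    surv <- .simClinical(n, sampleIds, time, status)
    expression <- .distort(latent, spec$distortion)
    truth <- list(
        informativePairs = if (nrow(pairs)) rownames(Z) else character(),
        coefficients = population$coefficients,
        indicators = Z, latent = latent, linearPredictor = lp,
        censoringRateRealized = mean(status == 0),
        censoringRateTarget = spec$censoringRate,
        population = population)
    list(expression = expression, survival = surv, truth = truth)
}

#' Simulate a two-platform study (training + validation)
#'
#' One gene population generates two independent cohorts whose observed
#' expression passes through different monotone distortion families
#' (exponential vs shifted-power) — the training/validation situation of a
#' cross-platform study where no renormalization is possible. Each platform
#' additionally carries private genes absent from the other, so the gene
#' supersets differ while the core genes (and hence the signature pairs)
#' are shared.
#'
#' @param spec a [simSpec()]; \code{nSamples} is the size of each cohort.
#' @param nExtraGenes number of platform-private noise genes added to each
#'   matrix.
#' @return list with \code{training} and \code{validation} (each holding
#'   \code{expression} and \code{survival}) plus the shared \code{truth}.
#' @export
simulateTwoPlatform <- function(spec, nExtraGenes = 10L) {
    stopifnot(inherits(spec, "SimulationSpec"))
    population <- .simPopulation(spec)
    specA <- spec; specA$distortion <- "exp"
    specB <- spec; specB$distortion <- "power"
    a <- simulateCohort(specA, population = population, seed = spec$seed + 1L)
    b <- simulateCohort(specB, population = population, seed = spec$seed + 2L)
    b$survival$sample_id <- sub("^S", "V", b$survival$sample_id)
    colnames(b$expression) <- b$survival$sample_id
    colnames(b$truth$indicators) <- b$survival$sample_id
    addPrivate <- function(expr, prefix, seed) {
        set.seed(seed)
        extra <- matrix(stats::runif(nExtraGenes * ncol(expr),
                                     min(expr), max(expr)),
                        nrow = nExtraGenes,
                        dimnames = list(sprintf("%s%03d", prefix,
                                                seq_len(nExtraGenes)),
                                        colnames(expr)))
        rbind(expr, extra)
    }
    if (nExtraGenes > 0L) {
        a$expression <- addPrivate(a$expression, "PLTA", spec$seed + 3L)
        b$expression <- addPrivate(b$expression, "PLTB", spec$seed + 4L)
    }
    list(training = list(expression = a$expression, survival = a$survival,
                         indicators = a$truth$indicators),
         validation = list(expression = b$expression, survival = b$survival,
                           indicators = b$truth$indicators),
         truth = a$truth)
}

#' Simulate bulk mixtures with known immune-cell fractions
#'
#' Builds a marker-block basis matrix (each cell type over-expresses its own
#' marker genes), draws per-sample fractions from a Dirichlet distribution,
#' exponentially tilts selected cell types so their fractions attain the
#' planted Pearson correlations with the supplied risk scores, and mixes:
#' \code{mixture = basis \%*\% t(fractions) + noise}.
#'
#' @param spec a [simSpec()]; the \code{immune} element supplies cell-type
#'   count, marker count, Dirichlet concentration, relative noise SD and
#'   planted correlations.
#' @param scores named numeric risk scores, one per sample.
#' @param seed overrides \code{spec$seed}.
#' @return list with \code{mixture} (genes x samples), \code{fractions}
#'   (samples x cell types, the ground truth) and \code{basis} (genes x
#'   cell types).
#' @export
simulateImmune <- function(spec, scores, seed = spec$seed) {
    stopifnot(inherits(spec, "SimulationSpec"))
    imm <- spec$immune
    n <- length(scores)
    if (is.null(names(scores)))
        names(scores) <- sprintf("S%04d", seq_len(n))
    set.seed(seed)
    K <- imm$nCellTypes
    rho <- rep_len(imm$plantedCorrelations, K)
    if (any(abs(rho) > 0.8))
        stop("planted correlation magnitude above 0.8 is not inducible ",
             "with a Dirichlet fraction model")
    cellTypes <- sprintf("CellType%02d", seq_len(K))
    G <- K * imm$markersPerType
    genes <- sprintf("MRK%03d", seq_len(G))
    basis <- matrix(stats::runif(G * K, 0.1, 1), nrow = G,
                    dimnames = list(genes, cellTypes))
    for (k in seq_len(K)) {
        rows <- ((k - 1L) * imm$markersPerType + 1L):(k * imm$markersPerType)
        basis[rows, k] <- basis[rows, k] + stats::runif(imm$markersPerType,
                                                        8, 12)
    }
    F <- matrix(stats::rgamma(n * K, shape = imm$concentration), nrow = n)
    F <- F / rowSums(F)
    dimnames(F) <- list(names(scores), cellTypes)
    z <- as.numeric(scale(scores))
    tilt <- function(F, k, alpha) {
        F[, k] <- F[, k] * exp(alpha * z)
        F / rowSums(F)
    }
    # tilting one type perturbs the others through renormalization, so the
    # calibration sweeps the planted types a few times until each settles
    for (sweep in seq_len(if (sum(rho != 0) > 1L) 3L else 1L)) {
        for (k in which(rho != 0)) {
            obj <- function(alpha) stats::cor(tilt(F, k, alpha)[, k],
                                              scores) - rho[k]
            sol <- tryCatch(stats::uniroot(obj, lower = -25, upper = 25),
                            error = function(e)
                                stop("planted correlation ", rho[k],
                                     " for ", cellTypes[k],
                                     " is not attainable at this ",
                                     "concentration"))
            F <- tilt(F, k, sol$root)
        }
    }
    mixture <- basis %*% t(F)
    if (imm$noiseSd > 0) {
        noise <- matrix(stats::rnorm(length(mixture), 0,
                                     imm$noiseSd * mean(mixture)),
                        nrow = nrow(mixture))
        mixture <- pmax(mixture + noise, 0)
    }
    dimnames(mixture) <- list(genes, names(scores))
    list(mixture = mixture, fractions = F, basis = basis)
}
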