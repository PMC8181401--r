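#' Time-dependent ROC (cumulative/dynamic, Kaplan-Meier reweighted)
#'
#' Evaluates a risk score against survival status at a fixed horizon. Cases
#' are subjects with an event by the horizon; controls are subjects known to
#' survive past it. A subject censored before the horizon is split between
#' the two classes using the Kaplan-Meier estimate of the survival function:
#' conditional on being alive at the censoring time c, it contributes case
#' mass \eqn{1 - S(t)/S(c)} and control mass \eqn{S(t)/S(c)} (redistribution
#' to the right). Sensitivity and specificity are then the weighted binary
#' ROC of the score, which makes sensitivity non-increasing and specificity
#' non-decreasing in the threshold by construction, and reduces exactly to
#' the empirical binary ROC when no censoring occurs before the horizon.
#'
#' The AUC is the trapezoidal area over (1 - specificity, sensitivity). The
#' optimal cutoff maximizes the Youden index (sensitivity + specificity - 1)
#' over the observed score values; ties are broken toward the lower cutoff,
#' giving the larger high-risk group.
#'
#' @param scores named numeric risk scores.
#' @param surv clinical data.frame with sample_id, time (months), status.
#' @param horizon evaluation horizon in months (e.g. 36 for the 3-year
#'   cutoff, 60 for 5-year validation AUC).
#' @return list of class \code{"tdROC"}: \code{horizon}, \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{auc},
#'   \code{optimal_cutoff}, \code{optimal_sens}, \code{optimal_spec}.
#' @examples
#' surv <- data.frame(sample_id = paste0("s", 1:6),
#'                    time = c(10, 20, 30, 50, 60, 70),
#'                    status = c(1, 1, 1, 0, 0, 0))
#' sc <- stats::setNames(-surv$time, surv$sample_id)
#' tdRoc(sc, surv, horizon = 36)$auc   # perfect ranking -> 1
#' @export
tdRoc <- function(scores, surv, horizon) {
    x <- .alignScores(scores, surv)
    time <- x$time; status <- x$status; scores <- x$scores
    km <- survfit(Surv(time, status) ~ 1)
    S <- stats::stepfun(km$time, c(1, km$surv))
    St <- S(horizon)
    caseW <- ifelse(time <= horizon & status == 1, 1, 0)
    ctrlW <- ifelse(time > horizon, 1, 0)
    cens <- time <= horizon & status == 0
    if (any(cens)) {
        Sc <- S(time[cens])
        w <- ifelse(Sc > 0, St / Sc, 0)     # P(T > horizon | T > c)
        ctrlW[cens] <- w
        caseW[cens] <- ifelse(Sc > 0, 1 - w, 0)
    }
    if (sum(caseW) == 0) stop("no events before the horizon")
    if (sum(ctrlW) == 0) stop("no controls surviving past the horizon")
    thr <- sort(unique(scores))
    grid <- c(-Inf, thr)
    sens <- spec <- numeric(length(grid))
    for (i in seq_along(grid)) {
        pos <- scores > grid[i]
        sens[i] <- sum(caseW[pos]) / sum(caseW)
        spec[i] <- sum(ctrlW[!pos]) / sum(ctrlW)
    }
    fpr <- 1 - spec
    ord <- order(fpr, sens)
    auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
    finite <- is.finite(grid)
    j <- sens[finite] + spec[finite] - 1
    best <- which(j == max(j))[1L]          # grid ascending: first = lowest
    structure(list(horizon = horizon, thresholds = thr,
                   sensitivity = sens[finite], specificity = spec[finite],
                   auc = auc,
                   optimal_cutoff = thr[best],
                   optimal_sens = sens[finite][best],
                   optimal_spec = spec[finite][best]),
              class = "tdROC")
}

#' @export
print.tdROC <- function(x, ...) {
    cat(sprintf("Time-dependent ROC at %g months: AUC = %.3f\n",
                x$horizon, x$auc))
    cat(sprintf("  Youden cutoff %.4f (sensitivity %.3f, specificity %.3f)\n",
                x$optimal_cutoff, x$optimal_sens, x$optimal_spec))
    invisible(x)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimate of the survival function within each group;
#' censored subjects leave the risk set without producing a step.
#'
#' @param surv clinical data.frame with time and status.
#' @param groups per-sample group labels (aligned with \code{surv} rows, or
#'   named by sample id).
#' @return data.frame with columns group, time, n_risk, n_event, n_censor,
#'   survival.
#' @export
kmCurve <- function(surv, groups = NULL) {
    if (is.null(groups)) groups <- rep("all", nrow(surv))
    groups <- .alignGroups(groups, surv)
    if (any(table(groups) == 0L) || anyNA(groups))
        stop("every group must be non-empty")
    fit <- survfit(Surv(surv$time, surv$status) ~ groups)
    if (is.null(fit$strata)) {
        grp <- rep(as.character(groups[1L]), length(fit$time))
    } else {
        grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
    }
    data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               survival = fit$surv, stringsAsFactors = FALSE)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank statistic: at each distinct event time the observed
#' events per group are compared with the expectation under the null, with
#' hypergeometric variance; the summed discrepancy is referred to a
#' chi-square distribution (df = groups - 1).
#'
#' @param surv clinical data.frame with time and status.
#' @param groups per-sample group labels; at least two non-empty groups.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
logrankTest <- function(surv, groups) {
    groups <- .alignGroups(groups, surv)
    groups <- factor(as.character(groups))
    if (nlevels(groups) < 2L) stop("log-rank test needs at least 2 groups")
    if (sum(surv$status) < 1L) stop("log-rank test needs at least 1 event")
    sd <- survdiff(Surv(surv$time, surv$status) ~ groups)
    df <- length(sd$n) - 1L
    list(statistic = as.numeric(sd$chisq), df = df,
         p_value = stats::pchisq(as.numeric(sd$chisq), df,
                                 lower.tail = FALSE))
}

#' Univariate and multivariate Cox proportional-hazards reports
#'
#' Fits each covariate alone (univariate) and all covariates jointly
#' (multivariate) with Breslow tie handling, and reports hazard ratios with
#' Wald 95\% confidence intervals and p-values — the layout of a standard
#' forest plot. Non-convergence or separation is reported per covariate as
#' NA rows with a note rather than an error.
#'
#' @param surv clinical data.frame with time, status and the covariate
#'   columns named in \code{covariates}.
#' @param covariates character vector of covariate column names; risk group
#'   or score can be included by adding the column to \code{surv} first.
#' @param conf_level Wald confidence level.
#' @return data.frame with columns model, term, hazard_ratio, ci_low,
#'   ci_high, p_value, note.
#' @export
coxModels <- function(surv, covariates, conf_level = 0.95) {
    absent <- setdiff(covariates, colnames(surv))
    if (length(absent))
        stop("covariate column(s) not in table: ",
             paste(absent, collapse = ", "))
    nEvents <- sum(surv$status)
    if (nEvents < 10L * length(covariates))
        warning(sprintf(
            "only %d events for %d covariate(s); estimates may be unstable",
            nEvents, length(covariates)))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    extract <- function(fit, model) {
        s <- summary(fit)$coefficients
        data.frame(model = model, term = rownames(s),
                   hazard_ratio = exp(s[, "coef"]),
                   ci_low = exp(s[, "coef"] - z * s[, "se(coef)"]),
                   ci_high = exp(s[, "coef"] + z * s[, "se(coef)"]),
                   p_value = s[, "Pr(>|z|)"], note = "",
                   stringsAsFactors = FALSE, row.names = NULL)
    }
    failRow <- function(model, term, msg)
        data.frame(model = model, term = term, hazard_ratio = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                   note = msg, stringsAsFactors = FALSE)
    fitOne <- function(fml, model, label) {
        tryCatch(extract(coxph(fml, data = surv, ties = "breslow"), model),
                 error = function(e) failRow(model, label, conditionMessage(e)),
                 warning = function(w) {
                     fit <- suppressWarnings(coxph(fml, data = surv,
                                                   ties = "breslow"))
                     out <- extract(fit, model)
                     out$note <- conditionMessage(w)
                     out
                 })
    }
    uni <- do.call(rbind, lapply(covariates, function(v)
        fitOne(stats::reformulate(v, response = "Surv(time, status)"),
               "univariate", v)))
    multi <- fitOne(stats::reformulate(covariates,
                                       response = "Surv(time, status)"),
                    "multivariate", paste(covariates, collapse = " + "))
    rbind(uni, multi)
}

# scores/groups alignment helpers ------------------------------------------

.alignScores <- function(scores, surv) {
    if (!is.null(names(scores))) {
        if (!all(surv$sample_id %in% names(scores)))
            stop("score(s) missing for sample(s): ",
                 paste(setdiff(surv$sample_id, names(scores)), collapse = ", "))
        scores <- scores[surv$sample_id]
    } else if (length(scores) != nrow(surv)) {
        stop("scores must be named by sample id or aligned with the table")
    }
    list(scores = as.numeric(scores), time = surv$time, status = surv$status)
}

.alignGroups <- function(groups, surv) {
    if (!is.null(names(groups))) {
        if (!all(surv$sample_id %in% names(groups)))
            stop("group label(s) missing for sample(s): ",
                 paste(setdiff(surv$sample_id, names(groups)), collapse = ", "))
        groups <- groups[surv$sample_id]
    } else if (length(groups) != nrow(surv)) {
        stop("groups must be named by sample id or aligned with the table")
    }
    groups
}
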