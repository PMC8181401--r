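test_that("Kaplan-Meier matches the closed form without censoring", {
    surv <- data.frame(sample_id = c("a", "b", "c"), time = 1:3, status = 1)
    km <- kmCurve(surv)
    expect_equal(km$survival, c(2/3, 1/3, 0))
})

test_that("Kaplan-Meier handles censoring as risk-set reduction", {
    # times 1+ (censored), 2, 3: S(2) = 1/2, S(3) = 0
    surv <- data.frame(sample_id = c("a", "b", "c"), time = 1:3,
                       status = c(0, 1, 1))
    km <- kmCurve(surv)
    expect_equal(km$survival[km$time == 2], 1/2)
    expect_equal(km$survival[km$time == 3], 0)
})

test_that("all-censored data gives a flat survival curve at 1", {
    surv <- data.frame(sample_id = letters[1:5], time = 1:5, status = 0)
    expect_true(all(kmCurve(surv)$survival == 1))
})

test_that("Kaplan-Meier equals 1 - ECDF when there is no censoring", {
    set.seed(31)
    surv <- data.frame(sample_id = sprintf("s%02d", 1:40),
                       time = round(rexp(40, 0.05), 2), status = 1)
    km <- kmCurve(surv)
    F <- ecdf(surv$time)
    expect_equal(km$survival, 1 - F(km$time))
})

test_that("log-rank is null for identical groups and matches the hand tally", {
    surv <- data.frame(sample_id = sprintf("s%d", 1:8),
                       time = rep(c(2, 5, 7, 9), 2),
                       status = rep(c(1, 0, 1, 1), 2))
    lr <- logrankTest(surv, rep(c("A", "B"), each = 4))
    expect_equal(lr$statistic, 0, tolerance = 1e-12)
    expect_equal(lr$p_value, 1)

    # six-subject worked example, tallied by the hypergeometric oracle
    surv6 <- data.frame(sample_id = sprintf("s%d", 1:6),
                        time = c(1, 3, 4, 2, 5, 8),
                        status = c(1, 1, 0, 1, 1, 1))
    grp <- rep(c("A", "B"), each = 3)
    lr6 <- logrankTest(surv6, grp)
    oracle <- oracleLogrank(surv6$time, surv6$status, grp)
    expect_equal(lr6$statistic, oracle$statistic, tolerance = 1e-8)
    expect_equal(lr6$p_value, oracle$p_value, tolerance = 1e-8)
    expect_error(logrankTest(surv6, rep("A", 6)), "2 groups")
})

test_that("strong group separation is detected", {
    set.seed(7)
    n <- 200
    grp <- rep(c("high", "low"), each = n / 2)
    haz <- ifelse(grp == "high", 4 * 0.03, 0.03)
    time <- rexp(n, haz)
    cens <- rexp(n, 0.01)
    surv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                       time = pmin(time, cens),
                       status = as.integer(time <= cens))
    expect_lt(logrankTest(surv, grp)$p_value, 0.001)
})

test_that("a perfect marker gives time-dependent AUC 1", {
    surv <- data.frame(sample_id = sprintf("s%02d", 1:20),
                       time = seq(2, 120, length.out = 20), status = 1)
    sc <- stats::setNames(-surv$time, surv$sample_id)
    roc <- tdRoc(sc, surv, horizon = 36)
    expect_equal(roc$auc, 1)
})

test_that("without censoring the td-ROC equals the plain binary ROC", {
    set.seed(12)
    n <- 60
    surv <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       time = round(rexp(n, 1 / 40), 1), status = 1)
    sc <- stats::setNames(-surv$time + rnorm(n, 0, 15), surv$sample_id)
    roc <- tdRoc(sc, surv, horizon = 36)
    oracle <- oracleBinaryRoc(unname(sc), as.integer(surv$time <= 36))
    expect_equal(roc$thresholds, oracle$thresholds)
    expect_equal(roc$sensitivity, oracle$sensitivity)
    expect_equal(roc$specificity, oracle$specificity)
})

test_that("sensitivity decreases and specificity increases along thresholds", {
    co <- simulateCohort(simSpec(nSamples = 150, nGenes = 20, seed = 9))
    sc <- stats::setNames(co$truth$linearPredictor + rnorm(150, 0, 0.5),
                          co$survival$sample_id)
    roc <- tdRoc(sc, co$survival, horizon = 36)
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$specificity) >= -1e-12))
    expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
})

test_that("no threshold beats the returned Youden cutoff", {
    set.seed(23)
    n <- 100
    surv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                       time = rexp(n, 1 / 50),
                       status = rbinom(n, 1, 0.8))
    surv$time <- pmax(surv$time, 0.5)
    sc <- stats::setNames(-surv$time + rnorm(n, 0, 20), surv$sample_id)
    roc <- tdRoc(sc, surv, horizon = 36)
    j <- roc$sensitivity + roc$specificity - 1
    jBest <- j[match(roc$optimal_cutoff, roc$thresholds)]
    expect_true(all(j <= jBest + 1e-12))
    # ties break toward the lower cutoff
    expect_equal(roc$optimal_cutoff,
                 min(roc$thresholds[abs(j - jBest) < 1e-12]))
})

test_that("td-ROC rejects degenerate horizons", {
    surv <- data.frame(sample_id = c("a", "b"), time = c(50, 60), status = 1)
    sc <- c(a = 1, b = 2)
    expect_error(tdRoc(sc, surv, horizon = 10), "no events")
    expect_error(tdRoc(sc, surv, horizon = 100), "no controls")
})

test_that("Cox models recover a planted hazard ratio of 4", {
    set.seed(19)
    n <- 400
    grp <- rep(c(1, 0), each = n / 2)
    time <- rexp(n, 0.02 * exp(log(4) * grp))
    cens <- rexp(n, 0.008)
    surv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                       time = pmin(time, cens),
                       status = as.integer(time <= cens),
                       risk_group = factor(ifelse(grp == 1, "high", "low"),
                                           levels = c("low", "high")))
    rep_ <- coxModels(surv, "risk_group")
    hrUni <- rep_$hazard_ratio[rep_$model == "univariate"]
    expect_gt(hrUni, 3); expect_lt(hrUni, 5.3)
    expect_true(all(rep_$ci_low <= rep_$hazard_ratio + 1e-12))
    expect_true(all(rep_$hazard_ratio <= rep_$ci_high + 1e-12))
})

test_that("a null covariate's confidence interval covers 1", {
    set.seed(3)
    n <- 300
    surv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                       time = rexp(n, 0.03), status = 1,
                       noise = rnorm(n))
    rep_ <- coxModels(surv, "noise")
    expect_true(rep_$ci_low[1] <= 1 && 1 <= rep_$ci_high[1])
})

test_that("with exponential hazards the HR approaches the rate ratio", {
    set.seed(8)
    n <- 4000
    grp <- rep(c(1, 0), each = n / 2)
    time <- rexp(n, 0.02 * ifelse(grp == 1, 2, 1))
    surv <- data.frame(sample_id = sprintf("s%04d", 1:n),
                       time = time, status = 1, g = grp)
    rep_ <- coxModels(surv, "g")
    expect_equal(rep_$hazard_ratio[1], 2, tolerance = 0.1)
})

test_that("too few events per covariate triggers a warning", {
    surv <- data.frame(sample_id = sprintf("s%02d", 1:30),
                       time = rexp(30, 0.05) + 1,
                       status = c(rep(1, 5), rep(0, 25)),
                       age = rnorm(30, 60))
    expect_warning(coxModels(surv, "age"), "events")
})
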