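test_that("duplicate probes collapse to the per-symbol arithmetic mean", {
    tf <- writeTsv(c("gene\ts1\ts2",
                     "TP53\t2\t4",
                     "TP53\t4\t6",
                     "EGFR\t1\t9"))
    m <- readExpression(tf)
    expect_equal(m["TP53", ], c(s1 = 3, s2 = 5))
    expect_equal(m["EGFR", ], c(s1 = 1, s2 = 9))
    expect_equal(rownames(m), c("TP53", "EGFR"))  # first-occurrence order
})

test_that("a matrix with unique symbols is returned unchanged and collapse is idempotent", {
    m <- randomExpr(6, 4, seed = 1)
    tf <- writeTsv(c(paste(c("gene", colnames(m)), collapse = "\t"),
                     paste(rownames(m), apply(m, 1, paste, collapse = "\t"),
                           sep = "\t")))
    expect_equal(readExpression(tf), m)
    expect_equal(collapseProbes(m), m)
    expect_equal(collapseProbes(collapseProbes(m)), collapseProbes(m))
})

test_that("five probes over three symbols collapse to hand-computed means", {
    # values 1..10 over symbols A,A,B,B,C; oracle: group means by hand
    tf <- writeTsv(c("gene\ts1\ts2",
                     "A\t1\t2", "A\t3\t4", "B\t5\t6", "B\t7\t8", "C\t9\t10"))
    m <- readExpression(tf)
    expect_equal(m, rbind(A = c(s1 = 2, s2 = 3),
                          B = c(s1 = 6, s2 = 7),
                          C = c(s1 = 9, s2 = 10)))
})

test_that("expression parse errors name the offending cell or column", {
    expect_error(readExpression(writeTsv(c("gene\ts1", "A\tx"))),
                 "row 1, column 's1'")
    expect_error(readExpression(writeTsv(c("gene\ts1\ts1", "A\t1\t2"))),
                 "duplicate sample ids")
    empty <- tempfile(); file.create(empty)
    expect_error(readExpression(empty), "empty")
    expect_error(readExpression(writeTsv(c("gene\ts1", "A\t-3"))),
                 "non-negative")
})

test_that("survival times are canonicalized to months", {
    tf <- writeTsv(c("sample_id\ttime\tstatus",
                     "s1\t3\t1", "s2\t1\t0"))
    expect_equal(readSurvival(tf, time_unit = "years")$time, c(36, 12))
    expect_equal(readSurvival(tf, time_unit = "days")$time,
                 c(3, 1) / 30.44)
    expect_equal(readSurvival(tf, time_unit = "months")$time, c(3, 1))
})

test_that("rows with missing time or status are dropped and counted", {
    rows <- c("sample_id\ttime\tstatus",
              sprintf("s%d\t%d\t%d", 1:8, 1:8, rep(0:1, 4)),
              "s9\t\t1", "s10\t5\t")
    tf <- writeTsv(rows)
    surv <- quietly(readSurvival(tf))
    expect_equal(nrow(surv), 8)
    expect_equal(attr(surv, "n_dropped"), 2)
})

test_that("survival table validation rejects bad inputs", {
    expect_error(readSurvival(writeTsv(c("sample_id\ttime", "s1\t3"))),
                 "status")
    expect_error(readSurvival(writeTsv(c("sample_id\ttime\tstatus",
                                         "s1\t-2\t1"))), "positive")
    expect_error(readSurvival(writeTsv(c("sample_id\ttime\tstatus",
                                         "s1\t2\t3"))), "status")
})

test_that("signature writer/reader round-trips in both dialects", {
    sig <- IRGPSignature(c("A", "B"), c("C", "D"), c(0.123456, -1.5),
                         cutoff = 0.7, metadata = list(horizon = 36))
    tsv <- tempfile(fileext = ".tsv")
    writeSignature(sig, tsv)
    back <- readSignature(tsv)
    expect_equal(pairIds(back), pairIds(sig))
    expect_equal(unname(coef(back)), unname(coef(sig)), tolerance = 1e-6)
    js <- tempfile(fileext = ".json")
    writeSignature(sig, js)
    back2 <- readSignature(js)
    expect_equal(unname(coef(back2)), unname(coef(sig)))
    expect_equal(sigCutoff(back2), 0.7)
    expect_equal(back2@metadata$horizon, 36)
})

test_that("signature parsing rejects duplicates and bad coefficients", {
    expect_error(readSignature(writeTsv(c("gene_a\tgene_b\tcoefficient",
                                          "A\tB\t0.5", "A\tB\t0.2"))),
                 "duplicate pair")
    expect_error(readSignature(writeTsv(c("gene_a\tgene_b\tcoefficient",
                                          "A\tB\tzz"))),
                 "unparseable coefficient")
    expect_error(IRGPSignature("A", "A", 0.5), "same gene")
})

test_that("signatureSummary counts pairs, unique genes and extremes", {
    sig <- IRGPSignature("A", "B", 0.5)
    expect_equal(signatureSummary(sig),
                 list(n_pairs = 1L, n_unique_genes = 2L,
                      min_coef = 0.5, max_coef = 0.5))
})

test_that("cohortTable percentages sum to 100 within rounding, Missing included", {
    set.seed(42)
    n <- 120
    surv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                       time = runif(n, 1, 60), status = rbinom(n, 1, 0.5),
                       age = round(rnorm(n, 60, 8)),
                       t_stage = replace(sample(c("T1-2", "T3-4"), n, TRUE),
                                         1:5, NA),
                       stringsAsFactors = FALSE)
    groups <- sample(c("low", "high"), n, TRUE)
    tab <- cohortTable(surv, groups)
    cnt <- function(cell) as.numeric(sub(" .*", "", cell))
    for (g in c("low", "high")) {
        rows <- tab$variable == "t_stage"
        counts <- vapply(tab[[g]][rows], cnt, 0)
        expect_equal(sum(counts), sum(groups == g))
        pcts <- as.numeric(sub(".*\\((.*)%\\).*", "\\1",
                               tab[[g]][rows][counts > 0]))
        expect_lt(abs(sum(pcts) - 100), 0.2)
    }
    expect_true("Missing" %in% tab$level)
})

test_that("a level absent from one group prints 0 (0%)", {
    surv <- data.frame(sample_id = paste0("s", 1:6),
                       time = 1:6, status = rep(1, 6),
                       gender = c("Male", "Male", "Male",
                                  "Male", "Female", "Female"))
    tab <- cohortTable(surv, groups = rep(c("A", "B"), each = 3))
    femaleA <- tab$A[tab$variable == "gender" & tab$level == "Female"]
    expect_equal(femaleA, "0 (0%)")
})
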