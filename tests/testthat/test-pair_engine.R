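test_that("MAD filter drops constant genes and uses a strict threshold", {
    m <- rbind(flat = rep(5, 6),
               boundary = c(1, 1, 1, 2, 2, 2),   # MAD exactly 0.5
               keep = c(0, 2, 4, 6, 8, 10))
    colnames(m) <- paste0("s", 1:6)
    expect_equal(oracleMad(m["boundary", ]), 0.5)
    out <- madFilter(m, threshold = 0.5)
    expect_equal(rownames(out), "keep")
    expect_error(madFilter(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("MAD filter agrees with the brute-force oracle on random data", {
    m <- randomExpr(10, 8, seed = 7)
    for (scale in c("native", "log2")) {
        vals <- if (scale == "log2") log2(m + 1) else m
        expected <- rownames(m)[apply(vals, 1, oracleMad) > 0.5]
        expect_equal(rownames(madFilter(m, 0.5, scale = scale)), expected)
    }
})

test_that("gene-list restriction keeps exactly the intersection", {
    m <- randomExpr(20, 3, seed = 2)
    shared <- rownames(m)[c(3, 8, 11, 19)]
    lst <- c(shared, "NOTHERE1", "NOTHERE2", "NOTHERE3")
    out <- quietly(restrictToGenes(m, lst))
    expect_equal(rownames(out), shared)
    expect_equal(quietly(restrictToGenes(m, rownames(m))), m)
    expect_error(restrictToGenes(m, c("X1", "X2")), "no overlap")
})

test_that("pair binarization follows the within-sample comparison rule", {
    m <- rbind(a = c(5, 2), b = c(3, 2))
    colnames(m) <- c("s1", "s2")
    ind <- assay(binarizePairs(m), "indicator")
    expect_equal(ind["a|b", "s1"], 1L)   # 5 > 3
    expect_equal(ind["a|b", "s2"], 0L)   # tie scores 0
    expect_error(binarizePairs(m[1, , drop = FALSE]), "at least 2 genes")
})

test_that("binarization equals the exhaustive pairwise oracle", {
    m <- randomExpr(4, 5, seed = 3)
    ind <- binarizePairs(m)
    expect_equal(nrow(ind), 6)           # 4 genes -> 6 pairs
    expect_identical(assay(ind, "indicator"), oracleBinarize(m))
    m2 <- randomExpr(9, 12, seed = 13)
    expect_identical(assay(binarizePairs(m2), "indicator"),
                     oracleBinarize(m2))
})

test_that("prevalence filter discards near-constant pairs, boundary kept", {
    ind <- PairIndicatorMatrix(
        rbind(c(1, rep(0, 9)),               # 10% ones -> discarded
              rep(1, 10),                    # all ones -> discarded
              c(1, 1, rep(0, 8)),            # exactly 20% -> kept
              c(rep(1, 5), rep(0, 5))),      # balanced -> kept
        geneA = c("A", "A", "A", "B"), geneB = c("B", "C", "D", "C"))
    colnames(ind) <- paste0("s", 1:10)
    out <- prevalenceFilter(ind, 0.20)
    expect_equal(pairIds(out), c("A|D", "B|C"))
    frac <- rowMeans(assay(out, "indicator"))
    expect_true(all(frac >= 0.2 & frac <= 0.8))
})

test_that("risk score is the coefficient-weighted indicator sum", {
    ind <- PairIndicatorMatrix(rbind(c(0L, 1L), c(0L, 1L)),
                               geneA = c("A", "C"), geneB = c("B", "D"))
    colnames(ind) <- c("s1", "s2")
    sig <- IRGPSignature(c("A", "C"), c("B", "D"), c(0.5, -2))
    expect_equal(riskScore(ind, sig), c(s1 = 0, s2 = -1.5))
    expect_error(riskScore(ind, IRGPSignature("A", "Z", 1)),
                 "not resolvable")
})

test_that("a reversed signature pair scores via the complement rule", {
    m <- randomExpr(6, 10, seed = 9)
    ind <- binarizePairs(m)
    fwd <- IRGPSignature("G001", "G004", 0.8)
    rev <- IRGPSignature("G004", "G001", 0.8)
    sFwd <- riskScore(ind, fwd)
    sRev <- riskScore(ind, rev)
    # indicator(b,a) = 1 - indicator(a,b) on tie-free data
    expect_equal(sRev, 0.8 - sFwd)
})

test_that("risk score is linear in the coefficients", {
    m <- randomExpr(5, 8, seed = 21)
    ind <- binarizePairs(m)
    ga <- c("G001", "G002", "G003"); gb <- c("G004", "G005", "G005")
    c1 <- c(0.3, -1, 2); c2 <- c(-0.7, 0.4, 1.1)
    expect_equal(riskScore(ind, IRGPSignature(ga, gb, c1 + c2)),
                 riskScore(ind, IRGPSignature(ga, gb, c1)) +
                     riskScore(ind, IRGPSignature(ga, gb, c2)))
})

test_that("scoring an expression matrix equals scoring its indicator matrix", {
    m <- randomExpr(8, 15, seed = 5)
    sig <- IRGPSignature(c("G002", "G007", "G001"),
                         c("G005", "G003", "G008"), c(1, -0.5, 0.25))
    expect_equal(riskScore(m, sig), riskScore(binarizePairs(m), sig))
    expect_error(riskScore(m, IRGPSignature("G001", "NOPE", 1)), "absent")
})

test_that("group assignment sends the boundary to the low-risk group", {
    sc <- c(a = -1, b = 0, c = 1)
    expect_equal(as.character(assignGroups(sc, 0)), c("low", "low", "high"))
    expect_true(all(assignGroups(sc, 5) == "low"))
    set.seed(1)
    sc2 <- rnorm(50)
    expect_equal(assignGroups(sc2, 0.3) == "high", sc2 > 0.3,
                 ignore_attr = TRUE)
})

test_that("binarization and risk scores are invariant under strictly increasing per-sample transforms", {
    sig <- IRGPSignature(c("G001", "G003"), c("G002", "G004"), c(1.5, -0.5))
    for (seed in 1:5) {
        m <- randomExpr(6, 12, seed = seed)
        d <- monotoneDistort(m, seed = seed + 100)
        expect_identical(assay(binarizePairs(m), "indicator"),
                         assay(binarizePairs(d), "indicator"))
        expect_identical(riskScore(m, sig), riskScore(d, sig))
    }
})

test_that("indicators are antisymmetric on tie-free data", {
    m <- randomExpr(7, 9, seed = 11)       # continuous draws: no ties
    ind <- assay(binarizePairs(m), "indicator")
    rev <- assay(binarizePairs(m[rev(seq_len(nrow(m))), ]), "indicator")
    for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
        a <- rownames(m)[i]; b <- rownames(m)[j]
        expect_true(all(ind[paste(a, b, sep = "|"), ] +
                        rev[paste(b, a, sep = "|"), ] == 1))
    }
})

test_that("pair matrix TSV export round-trips", {
    m <- randomExpr(5, 6, seed = 8)
    ind <- binarizePairs(m)
    tf <- tempfile(fileext = ".tsv")
    writePairMatrix(ind, tf)
    back <- readPairMatrix(tf)
    expect_equal(pairIds(back), pairIds(ind))
    expect_equal(assay(back, "indicator"), assay(ind, "indicator"))
})
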