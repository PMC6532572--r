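test_that("median-of-ratios size factors match hand-computed cases", {
    # two identical samples -> (1, 1)
    m <- cbind(s1 = c(3, 10, 7), s2 = c(3, 10, 7))
    expect_equal(unname(medianOfRatios(m)), c(1, 1))
    # sample B = 2 x sample A on 5 genes -> proportional to (1, 2);
    # after geometric-mean-1 rescaling: (2^-0.5, 2^0.5)
    a <- c(4, 9, 25, 12, 30)
    m2 <- cbind(A = a, B = 2 * a)
    expect_equal(unname(medianOfRatios(m2)), c(2^-0.5, 2^0.5))
    # a gene with a zero is excluded from the medians: equals brute-force
    # recomputation on the remaining genes
    m3 <- matrix(rpois(20, 30) + 1, nrow = 10)
    m3[4, 1] <- 0
    expect_equal(medianOfRatios(m3), medianOfRatios(m3[-4, ]))
    # all-zero matrix is unusable
    expect_error(medianOfRatios(matrix(0, 3, 2)), "no gene")
})

test_that("size factors agree with the DESeq2 estimator up to rescaling", {
    skip_if_not_installed("DESeq2")
    set.seed(21)
    m <- matrix(rnbinom(600, mu = 50, size = 5) + 1, nrow = 100)
    ours <- medianOfRatios(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(ours / ours[1], unname(ref / ref[1]), tolerance = 1e-10)
})

test_that("fpkm follows the defining formula", {
    # count 100, length 1000 bp, library total 1e6 -> FPKM 100
    ice <- makeIce(matrix(c(100L, 999900L), nrow = 2, ncol = 4),
                   lengths = c(1000L, 1000L), nReps = 1)
    expect_equal(fpkm(ice)[1, 1], 100, ignore_attr = TRUE)
    # length enters inversely
    ice2 <- makeIce(matrix(c(100L, 999900L), nrow = 2, ncol = 4),
                    lengths = c(500L, 1000L), nReps = 1)
    expect_equal(fpkm(ice2)[1, 1], 200, ignore_attr = TRUE)
    # zero count -> 0; doubling all counts leaves FPKM unchanged
    expect_equal(fpkm(makeIce(matrix(c(0L, 10L), 2, 4), nReps = 1))[1, 1],
                 0, ignore_attr = TRUE)
    set.seed(17)
    ice3 <- makeIce(matrix(rpois(8, 40) + 1L, 2, 4), nReps = 1)
    ice4 <- makeIce(2L * counts(ice3), nReps = 1)
    expect_equal(fpkm(ice3), fpkm(ice4))
    # zero library total is an error
    zc <- matrix(c(5L, 3L), 2, 4); zc[, 2] <- 0L
    expect_error(fpkm(makeIce(zc, nReps = 1)), "library total")
})

test_that("fold changes follow the pseudocount rule and are normalization-invariant", {
    set.seed(31)
    m <- matrix(rpois(10 * 12, 60) + 1L, nrow = 10)
    ice <- makeIce(m)
    fc <- foldChanges(ice)
    # delta always reproduces lfc_clf - lfc_wt bit-exactly and lfc = log2(fc)
    expect_identical(fc$delta, fc$lfc_clf - fc$lfc_wt)
    expect_identical(fc$lfc_wt, log2(fc$fc_wt))
    # all-zero gene -> fc exactly 1
    m2 <- m; m2[3, ] <- 0L
    fc2 <- foldChanges(makeIce(m2))
    expect_equal(fc2$fc_wt[3], 1)
    expect_equal(fc2$fc_clf[3], 1)
    # identical normalized means in both conditions -> fc 1, lfc 0
    m3 <- matrix(50L, nrow = 3, ncol = 12)
    m3[2, ] <- 10L; m3[3, ] <- 77L
    fc3 <- foldChanges(makeIce(m3))
    expect_equal(fc3$fc_wt, rep(1, 3))
    expect_equal(fc3$lfc_clf, rep(0, 3))
    # multiplying a column by its own size factor is removed by
    # normalization (up to the pseudocount's interaction with the
    # geometric-mean-1 rescaling, a relative effect of order 1e-4 here;
    # an uncorrected 2x column shift would move lfc by a full unit)
    m4 <- m; m4[, 1] <- m[, 1] * 2L
    expect_equal(foldChanges(makeIce(m4)), foldChanges(ice), tolerance = 1e-3)
})

test_that("missing design cells are reported by name", {
    m <- matrix(rpois(5 * 12, 30), nrow = 5)
    ice <- makeIce(m)
    sub <- ice[, sampleCondition(ice) != "minusFe" |
                 sampleGenotype(ice) != "clf"]
    expect_error(foldChanges(sub), "clf/minusFe")
})

test_that("fold-change estimator recovers the reported IRT1-in-clf induction", {
    sp <- simGeneSpec("IRT1", 200, 11.3, 22.4)
    fc <- foldChanges(simulateCounts(sp, simDesign(nReps = 100, seed = 2)),
                      sf = rep(1, 400))
    expect_lt(abs(fc$fc_clf - 22.4) / 22.4, 0.10)
})

test_that("median estimated fold change approaches truth as replication grows", {
    # background-dominated gene pool (6% induced): median-of-ratios
    # normalization assumes most genes are not differentially expressed
    est <- function(nr, seed) {
        sc <- defaultScenario(10, 10, 300, nReps = nr, seed = seed)
        ice <- simulateCounts(sc$specs, sc$design)
        fc <- foldChanges(ice)
        fit <- sc$specs$set_label == "FIT"
        median(abs(log2(fc$fc_clf[fit]) - log2(sc$specs$induction_clf[fit])))
    }
    expect_lt(est(100, 13), est(3, 13))
})
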