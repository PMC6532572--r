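test_that("above-diagonal proportion counts strict positives only", {
    # the three reported FIT pairs all lie above the diagonal
    lfcWt <- log2(c(3.9, 13.7, 11.3))
    lfcClf <- log2(c(5.0, 40.8, 22.4))
    d <- setNames(lfcClf - lfcWt, c("FIT", "FRO2", "IRT1"))
    expect_equal(proportionAboveDiagonal(d, names(d)), 1)
    # ties (delta = 0) count as not above
    d2 <- c(a = 1, b = -1, c = 0, d = 2)
    expect_equal(proportionAboveDiagonal(d2, names(d2)), 0.5)
    expect_equal(proportionAboveDiagonal(c(x = 0), "x"), 0)
    expect_error(proportionAboveDiagonal(d2, c("a", "zz")), "zz")
})

test_that("randomization p matches exhaustive enumeration on small pools", {
    # 2 positive focal vs 2 negative comparator: exact tail = 1/6
    d <- c(f1 = 1, f2 = 2, c1 = -1, c2 = -2)
    res <- randomizationTest(d, c("f1", "f2"), c("c1", "c2"),
                             nPerm = 20000, seed = 3, mw = FALSE)
    q <- 1 / 6
    se <- sqrt(q * (1 - q) / 20000)
    expect_lt(abs(randomizationP(res) - q), 3 * se + 1e-4)
    # generic pools <= 12: exhaustive oracle by full label enumeration
    set.seed(55)
    for (trial in 1:3) {
        dd <- setNames(rnorm(12), paste0("g", 1:12))
        foc <- paste0("g", 1:5); com <- paste0("g", 6:12)
        obs <- proportionAboveDiagonal(dd, foc)
        combos <- combn(12, 5)
        pos <- dd > 0
        nullStats <- apply(combos, 2, function(ix) mean(pos[ix]))
        q <- mean(nullStats >= obs)
        res <- randomizationTest(dd, foc, com, nPerm = 1e5, seed = trial,
                                 mw = FALSE)
        se <- sqrt(max(q * (1 - q), 1e-6) / 1e5)
        expect_lt(abs(randomizationP(res) - q), 3 * se + 2e-5)
    }
})

test_that("randomization respects the add-one rule and one-sided tails", {
    # observed proportion 0 -> p = 1 one-sided
    d <- c(f1 = -1, f2 = -2, c1 = 1, c2 = 2, c3 = -3)
    res <- randomizationTest(d, c("f1", "f2"), c("c1", "c2", "c3"),
                             nPerm = 500, seed = 1, mw = FALSE)
    expect_equal(randomizationP(res), 1)
    # p never below 1/(nPerm + 1)
    d2 <- setNames(c(rep(1, 10), rep(-1, 10)), paste0("g", 1:20))
    res2 <- randomizationTest(d2, paste0("g", 1:10), paste0("g", 11:20),
                              nPerm = 99, seed = 2, mw = FALSE)
    expect_gte(randomizationP(res2), 1 / 100)
})

test_that("randomization result is seed-deterministic and rank-invariant", {
    set.seed(77)
    d <- setNames(rnorm(30), paste0("g", 1:30))
    foc <- paste0("g", 1:12); com <- paste0("g", 13:30)
    r1 <- asymmetryTest(d, foc, com, nPerm = 2000, seed = 42)
    r2 <- asymmetryTest(d, foc, com, nPerm = 2000, seed = 42)
    expect_identical(as.list(r1), as.list(r2))
    # strictly increasing sign-preserving transforms leave the
    # randomization p unchanged (only signs and labels matter)
    for (f in list(function(x) 2 * x, function(x) x^3)) {
        r3 <- randomizationTest(f(d), foc, com, nPerm = 2000, seed = 42,
                                mw = FALSE)
        expect_identical(randomizationP(r3), randomizationP(r1))
    }
})

test_that("set validation rejects overlap and empty sets", {
    d <- c(a = 1, b = -1, c = 2)
    expect_error(randomizationTest(d, c("a", "b"), c("b", "c")), "disjoint")
    expect_error(randomizationTest(d, character(), "c"), "non-empty")
})

test_that("Mann-Whitney U and p match enumeration and brute force", {
    # complete separation of 3 vs 3: U = 9, exact one-sided p = 1/20
    res <- mannWhitney(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
    expect_equal(res$U, 9)
    expect_equal(res$p, 0.05)
    expect_equal(res$method, "exact")
    # identical samples: U = n^2/2, two-sided p = 1
    res2 <- mannWhitney(1:4, 1:4, alternative = "two.sided")
    expect_equal(res2$U, 8)
    expect_equal(res2$p, 1)
    # U equals the brute-force pairwise count on 100 random instances
    set.seed(99)
    for (i in 1:100) {
        n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
        x <- if (i %% 3 == 0) sample(1:5, n1, replace = TRUE) else rnorm(n1)
        y <- if (i %% 3 == 0) sample(1:5, n2, replace = TRUE) else rnorm(n2)
        bruteU <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
        expect_equal(mannWhitney(x, y)$U, bruteU)
    }
    expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("Mann-Whitney p agrees with the reference implementation", {
    set.seed(101)
    # exact branch (no ties, small samples)
    x <- rnorm(8); y <- rnorm(9)
    ours <- mannWhitney(x, y, "greater")
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    # tie-corrected normal branch
    x2 <- sample(1:6, 30, replace = TRUE)
    y2 <- sample(1:6, 35, replace = TRUE)
    ours2 <- mannWhitney(x2, y2, "two.sided")
    ref2 <- wilcox.test(x2, y2, alternative = "two.sided", exact = FALSE,
                        correct = TRUE)
    expect_equal(ours2$p, ref2$p.value, tolerance = 1e-12)
})

test_that("asymmetry tables carry the scatter rows and complete histograms", {
    fcVals <- data.frame(
        gene_id = c("FIT", "FRO2", "IRT1", "PYE", "BTS", "FRO3"),
        fc_wt = c(3.9, 13.7, 11.3, 4.9, 5.9, 17.5),
        fc_clf = c(5.0, 40.8, 22.4, 4.6, 5.7, 16.4))
    fcVals$lfc_wt <- log2(fcVals$fc_wt)
    fcVals$lfc_clf <- log2(fcVals$fc_clf)
    fcVals$delta <- fcVals$lfc_clf - fcVals$lfc_wt
    sets <- GeneSets(FIT = c("FIT", "FRO2", "IRT1"),
                     PYE = c("PYE", "BTS", "FRO3"))
    tabs <- asymmetryTables(fcVals, sets)
    expect_equal(nrow(tabs$scatter), 6)
    expect_equal(tabs$scatter$lfc_clf[tabs$scatter$gene_id == "FRO2"],
                 log2(40.8))
    # histogram bin counts sum to set size
    cnt <- tapply(tabs$density$count, tabs$density$set, sum)
    expect_equal(as.vector(cnt[c("FIT", "PYE")]), c(3L, 3L))
    # empty sets give empty tables with headers preserved
    empty <- asymmetryTables(fcVals, GeneSets(none = "absent_gene"))
    expect_equal(nrow(empty$scatter), 0)
    expect_named(empty$scatter,
                 c("gene_id", "set", "lfc_wt", "lfc_clf", "delta"))
})
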