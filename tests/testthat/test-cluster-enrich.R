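test_that("row z-scores use the n-1 denominator and drop constant rows", {
    z <- zscoreRows(rbind(a = c(1, 3), b = c(2, 8)))
    expect_equal(z["a", ], c(-1, 1) / sqrt(2), ignore_attr = TRUE)
    # every row has mean 0, sd 1 to tight tolerance
    set.seed(61)
    m <- matrix(rnorm(40, sd = 4), 10, 4,
                dimnames = list(paste0("g", 1:10), NULL))
    z2 <- zscoreRows(m)
    expect_lt(max(abs(rowMeans(z2))), 1e-12)
    expect_lt(max(abs(apply(z2, 1, sd) - 1)), 1e-12)
    # constant rows are dropped and recorded
    m2 <- rbind(m, const = rep(5, 4))
    expect_message(z3 <- zscoreRows(m2), "const")
    expect_false("const" %in% rownames(z3))
    expect_equal(attr(z3, "dropped"), "const")
    expect_error(zscoreRows(matrix(1:3, ncol = 1)), "2 columns")
})

test_that("condition means average replicates of each design cell", {
    sc <- defaultScenario(2, 2, 2, seed = 3)
    ice <- simulateCounts(sc$specs, sc$design)
    cm <- conditionMeans(ice)
    expect_equal(colnames(cm), c("wildtype_plusFe", "wildtype_minusFe",
                                 "clf_plusFe", "clf_minusFe"))
    norm <- normalizedCounts(ice)
    sel <- sampleGenotype(ice) == "clf" & sampleCondition(ice) == "minusFe"
    expect_equal(cm[, "clf_minusFe"], rowMeans(norm[, sel]))
})

test_that("average-linkage heights match a brute-force agglomeration", {
    # two identical rows merge at height 0
    z <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
    cr <- hierarchicalCluster(z)
    expect_equal(cr@height[1], 0)
    # two tight pairs merge first
    m <- rbind(p1 = c(0, 0), p2 = c(0.1, 0), q1 = c(10, 10),
               q2 = c(10, 10.1))
    cr2 <- hierarchicalCluster(m, k = 2)
    expect_equal(sort(cr2@height[1:2]), c(0.1, 0.1))
    expect_equal(unname(clusterAssignments(cr2)[c("p1", "p2")]),
                 rep(clusterAssignments(cr2)[["p1"]], 2))
    # heights equal the brute-force all-pairs agglomeration oracle
    set.seed(71)
    for (trial in 1:3) {
        m3 <- matrix(rnorm(8 * 4), 8, 4,
                     dimnames = list(paste0("g", 1:8), NULL))
        cr3 <- hierarchicalCluster(m3)
        expect_equal(sort(cr3@height), sort(bruteAverageLinkHeights(m3)),
                     tolerance = 1e-10)
    }
    expect_error(hierarchicalCluster(rbind(c(1, NA), c(0, 1))), "finite")
})

test_that("leaf order is invariant to input row permutation", {
    set.seed(81)
    m <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(sprintf("g%02d", 1:12), NULL))
    cr <- hierarchicalCluster(m)
    perm <- sample(12)
    crP <- hierarchicalCluster(m[perm, ])
    expect_equal(sort(cr@height), sort(crP@height), tolerance = 1e-12)
    expect_identical(geneOrder(cr), geneOrder(crP))
})

test_that("hypergeometric over-representation matches exact enumeration", {
    universe <- paste0("u", 1:20)
    ann <- data.frame(gene_id = paste0("u", 1:5), term = "T")
    res <- overRepresentation(paste0("u", 1:5), ann, universe)
    expect_equal(res$p_value, 1 / choose(20, 5))
    # term covering the whole universe has p = 1
    annAll <- data.frame(gene_id = universe, term = "all")
    expect_equal(overRepresentation(paste0("u", 1:4), annAll,
                                    universe)$p_value, 1)
    # random configurations vs binomial-coefficient enumeration oracle
    set.seed(91)
    for (trial in 1:5) {
        N <- sample(10:25, 1)
        uni <- paste0("g", seq_len(N))
        K <- sample(2:(N - 2), 1)
        n <- sample(2:(N - 2), 1)
        termGenes <- sample(uni, K)
        cluster <- sample(uni, n)
        k <- length(intersect(termGenes, cluster))
        res <- overRepresentation(cluster,
                                  data.frame(gene_id = termGenes, term = "t"),
                                  uni)
        expect_equal(res$p_value, enumHyperP(k, K, N, n), tolerance = 1e-12)
    }
    # overlap at expectation is never "significant"
    resE <- overRepresentation(paste0("u", 1:10),
                               data.frame(gene_id = paste0("u", c(1, 11)),
                                          term = "t"), universe)
    expect_gte(resE$p_value, 0.5)
    expect_error(overRepresentation("zz", ann, universe), "zz")
})
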