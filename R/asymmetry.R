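## The core statistic: is the focal (FIT-dependent) set disproportionately
## above the y = x line of clf-vs-wildtype log2 fold inductions?

.namedDeltas <- function(deltas) {
    if (is.data.frame(deltas)) {
        if (!all(c("gene_id", "delta") %in% colnames(deltas)))
            stop("a fold-change table needs 'gene_id' and 'delta' columns")
        deltas <- stats::setNames(deltas$delta, deltas$gene_id)
    }
    if (is.null(names(deltas))) stop("'deltas' must be named by gene")
    deltas
}

.setDeltas <- function(deltas, geneSet) {
    missing <- setdiff(geneSet, names(deltas))
    if (length(missing))
        stop("gene(s) missing from the delta table: ",
             paste(missing, collapse = ", "))
    deltas[geneSet]
}

#' Proportion of a gene set above the diagonal
#'
#' Fraction of set genes whose induction difference
#' `delta = lfc_clf - lfc_wt` is strictly positive, i.e. lying above the
#' y = x line of the clf-vs-wildtype log2 fold-change scatter. Ties
#' (`delta == 0`) count as not above.
#'
#' @param deltas named numeric vector of per-gene deltas, or a
#'   [foldChanges()] table.
#' @param geneSet character vector of gene identifiers; every member must
#'   be present in `deltas`.
#' @return A proportion in \[0, 1\].
#' @examples
#' proportionAboveDiagonal(c(a = 1, b = -1, c = 0, d = 2), c("a", "b", "c", "d"))
#' @export
proportionAboveDiagonal <- function(deltas, geneSet) {
    deltas <- .namedDeltas(deltas)
    if (length(geneSet) == 0L) stop("'geneSet' is empty")
    mean(.setDeltas(deltas, geneSet) > 0)
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs with a focal value exceeding a comparator value,
#' with ties contributing 1/2. When `n1 * n2 <= 400` and there are no ties,
#' the p-value is exact (null permutation distribution of U via
#' [stats::pwilcox()]); otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used. Degenerate samples (all
#' values tied) return p = 1.
#'
#' @param x,y numeric samples (focal, comparator); both non-empty.
#' @param alternative `"greater"` (x stochastically larger) or
#'   `"two.sided"`.
#' @return A list with elements `U`, `p` and `method`
#'   (`"exact"`/`"normal"`).
#' @examples
#' mannWhitney(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
#' @export
mannWhitney <- function(x, y, alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be non-empty")
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tieTab <- table(pooled)
    hasTies <- any(tieTab > 1)
    if (n1 * n2 <= 400 && !hasTies) {
        pg <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        pl <- stats::pwilcox(U, n1, n2)
        p <- if (alternative == "greater") pg else min(1, 2 * min(pg, pl))
        method <- "exact"
    } else {
        N <- n1 + n2
        tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
        if (sigma2 <= 0) {
            p <- 1
        } else {
            mu <- n1 * n2 / 2
            s <- sqrt(sigma2)
            p <- if (alternative == "greater")
                stats::pnorm((U - mu - 0.5) / s, lower.tail = FALSE)
            else min(1, 2 * stats::pnorm((abs(U - mu) - 0.5) / s,
                                         lower.tail = FALSE))
        }
        method <- "normal"
    }
    list(U = U, p = p, method = method)
}

#' Label-randomization test on the above-diagonal proportion
#'
#' Pools the focal and comparator genes and, for each permutation,
#' reassigns `|focal|` labels uniformly at random without replacement; the
#' null statistic is the above-diagonal proportion of the permuted focal
#' set. The one-sided p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + nPerm)` and so never returns 0;
#' `"two.sided"` doubles the smaller tail. Deterministic given `seed`.
#'
#' @inheritParams proportionAboveDiagonal
#' @param focalSet,comparatorSet disjoint, non-empty gene-identifier
#'   vectors present in `deltas`.
#' @param nPerm number of permutations (default 10000, resolving p-values
#'   down to about 1e-4).
#' @param seed integer seed.
#' @param alternative `"greater"` (focal proportion larger) or
#'   `"two.sided"`.
#' @param mw also run [mannWhitney()] on the two delta samples and store
#'   `U`/`p` in the result? (default `TRUE`).
#' @return An [AsymmetryResult-class].
#' @examples
#' d <- c(f1 = 2, f2 = 1, f3 = 0.5, c1 = -1, c2 = 0.2, c3 = -0.3)
#' randomizationTest(d, c("f1", "f2", "f3"), c("c1", "c2", "c3"),
#'                   nPerm = 1000, seed = 1)
#' @export
randomizationTest <- function(deltas, focalSet, comparatorSet,
                              nPerm = 10000, seed = 1L,
                              alternative = c("greater", "two.sided"),
                              mw = TRUE) {
    alternative <- match.arg(alternative)
    deltas <- .namedDeltas(deltas)
    if (length(focalSet) == 0L || length(comparatorSet) == 0L)
        stop("focal and comparator sets must be non-empty")
    if (length(intersect(focalSet, comparatorSet)))
        stop("focal and comparator sets must be disjoint")
    nPerm <- as.integer(nPerm)
    if (nPerm < 1) stop("'nPerm' must be >= 1")
    dFoc <- .setDeltas(deltas, focalSet)
    dCom <- .setDeltas(deltas, comparatorSet)
    nf <- length(dFoc); nc <- length(dCom)
    above <- c(dFoc, dCom) > 0
    pObsF <- mean(above[seq_len(nf)])
    pObsC <- mean(above[nf + seq_len(nc)])
    set.seed(as.integer(seed))
    nullP <- vapply(seq_len(nPerm), function(i)
        mean(above[sample.int(nf + nc, nf)]), numeric(1))
    pG <- (1 + sum(nullP >= pObsF)) / (1 + nPerm)
    pL <- (1 + sum(nullP <= pObsF)) / (1 + nPerm)
    pRand <- if (alternative == "greater") pG else min(1, 2 * min(pG, pL))
    if (mw) {
        mwRes <- mannWhitney(dFoc, dCom, alternative = alternative)
        mwU <- as.numeric(mwRes$U); mwP <- mwRes$p
    } else {
        mwU <- NA_real_; mwP <- NA_real_
    }
    new("AsymmetryResult",
        pObsFocal = pObsF, pObsComparator = pObsC, diffObs = pObsF - pObsC,
        pRandomization = pRand, nPerm = nPerm, nullProportions = nullP,
        mwU = mwU, mwP = mwP, alternative = alternative,
        seed = as.integer(seed), nFocal = nf, nComparator = nc)
}

#' Full induction-asymmetry test
#'
#' Convenience wrapper running both the label-randomization test on the
#' above-diagonal proportion and the Mann-Whitney comparison of the delta
#' distributions; equivalent to [randomizationTest()] with `mw = TRUE`.
#'
#' @inheritParams randomizationTest
#' @return An [AsymmetryResult-class].
#' @examples
#' sc <- defaultScenario(10, 10, 20, seed = 1)
#' fc <- foldChanges(simulateCounts(sc$specs, sc$design))
#' asymmetryTest(fc, sc$sets[["FIT"]], sc$sets[["PYE"]],
#'               nPerm = 1000, seed = 1)
#' @export
asymmetryTest <- function(deltas, focalSet, comparatorSet, nPerm = 10000,
                          seed = 1L,
                          alternative = c("greater", "two.sided")) {
    randomizationTest(deltas, focalSet, comparatorSet, nPerm = nPerm,
                      seed = seed, alternative = alternative, mw = TRUE)
}

#' Tidy scatter and density tables for the induction asymmetry figure
#'
#' Produces the two tidy tables behind the clf-vs-wildtype induction
#' scatter and the per-set delta density histogram: one row per set gene
#' with its log2 fold changes, and per-set histogram bins of `delta` using
#' the Freedman-Diaconis rule.
#'
#' @param fc a [foldChanges()] table.
#' @param sets a [GeneSets-class]; sets absent from `fc` contribute no rows.
#' @return A list of `data.frame`s: `scatter` with columns `gene_id`,
#'   `set`, `lfc_wt`, `lfc_clf`, `delta`; `density` with columns `set`,
#'   `bin_lower`, `bin_upper`, `count`.
#' @examples
#' sc <- defaultScenario(5, 5, 5, seed = 1)
#' fc <- foldChanges(simulateCounts(sc$specs, sc$design))
#' str(asymmetryTables(fc, sc$sets))
#' @export
asymmetryTables <- function(fc, sets) {
    stopifnot(is(sets, "GeneSets"))
    scatter <- data.frame(gene_id = character(), set = character(),
                          lfc_wt = numeric(), lfc_clf = numeric(),
                          delta = numeric(), stringsAsFactors = FALSE)
    density <- data.frame(set = character(), bin_lower = numeric(),
                          bin_upper = numeric(), count = integer(),
                          stringsAsFactors = FALSE)
    for (nm in names(sets)) {
        members <- intersect(sets[[nm]], fc$gene_id)
        if (length(members) == 0L) next
        sub <- fc[match(members, fc$gene_id), , drop = FALSE]
        scatter <- rbind(scatter, data.frame(
            gene_id = sub$gene_id, set = nm, lfc_wt = sub$lfc_wt,
            lfc_clf = sub$lfc_clf, delta = sub$delta,
            stringsAsFactors = FALSE))
        h <- graphics::hist(sub$delta, breaks = "FD", plot = FALSE)
        density <- rbind(density, data.frame(
            set = nm, bin_lower = utils::head(h$breaks, -1),
            bin_upper = utils::tail(h$breaks, -1), count = h$counts,
            stringsAsFactors = FALSE))
    }
    rownames(scatter) <- rownames(density) <- NULL
    list(scatter = scatter, density = density)
}
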