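## Condition-level z-scoring, hierarchical clustering of iron-regulated
## genes, and a generic over-representation test for cluster annotation.

#' Mean expression per genotype x condition cell
#'
#' Averages size-factor-normalized counts over the replicates of each of
#' the four design cells, yielding the gene x group matrix that
#' condition-level heat maps are built from.
#'
#' @param x an [IronCountExperiment-class].
#' @return Numeric matrix with columns `wildtype_plusFe`,
#'   `wildtype_minusFe`, `clf_plusFe`, `clf_minusFe`.
#' @export
conditionMeans <- function(x) {
    norm <- normalizedCounts(x)
    cd <- colData(x)
    grid <- expand.grid(condition = .CONDITIONS, genotype = .GENOTYPES,
                        stringsAsFactors = FALSE)[, 2:1]
    out <- vapply(seq_len(nrow(grid)), function(i)
        .conditionMean(norm, cd, grid$genotype[i], grid$condition[i]),
        numeric(nrow(x)))
    colnames(out) <- paste(grid$genotype, grid$condition, sep = "_")
    rownames(out) <- rownames(x)
    out
}

#' Row-wise z-scores
#'
#' Centers and scales each row to mean 0, standard deviation 1 (n - 1
#' denominator), so heat-map values read as standard deviations from the
#' gene's mean. Constant rows cannot be scaled and are dropped with a
#' message; their identifiers are recorded in the `"dropped"` attribute.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return The z-scored matrix (possibly fewer rows), with attribute
#'   `"dropped"`.
#' @examples
#' zscoreRows(rbind(a = c(1, 3), b = c(2, 8)))
#' @export
zscoreRows <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 2) stop("need >= 2 columns to z-score rows")
    sds <- apply(m, 1, stats::sd)
    dropped <- rownames(m)[sds == 0]
    if (length(dropped))
        message("dropping ", length(dropped), " constant row(s): ",
                paste(utils::head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ...")
    keep <- sds > 0
    z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
        sds[keep]
    attr(z, "dropped") <- dropped
    z
}

# canonical leaf order: at every merge the subtree containing the
# lexicographically smallest gene identifier goes left, so the order does
# not depend on input row order
.canonicalOrder <- function(merge, labels) {
    n <- nrow(merge) + 1L
    orderOf <- vector("list", nrow(merge))
    minOf <- character(nrow(merge))
    sub <- function(j) if (j < 0) labels[-j] else orderOf[[j]]
    for (i in seq_len(nrow(merge))) {
        L <- sub(merge[i, 1]); R <- sub(merge[i, 2])
        if (min(L) <= min(R)) orderOf[[i]] <- c(L, R)
        else orderOf[[i]] <- c(R, L)
        minOf[i] <- min(orderOf[[i]][1])
    }
    if (nrow(merge) == 0L) labels else orderOf[[nrow(merge)]]
}

#' Hierarchical clustering of z-scored expression rows
#'
#' Agglomerative clustering with Euclidean distance and average linkage
#' (via [stats::hclust()]); average linkage is monotone, so merge heights
#' are non-decreasing. The dendrogram leaf order is canonicalized so that
#' at every merge the subtree containing the lexicographically smallest
#' gene identifier comes first, making the reported order invariant to the
#' input row order.
#'
#' @param z numeric matrix of z-scored rows (finite values, >= 2 rows) with
#'   gene identifiers as rownames.
#' @param k optional number of clusters to cut the tree into.
#' @return A [ClusterResult-class].
#' @examples
#' z <- zscoreRows(matrix(rnorm(40), 10, 4,
#'                        dimnames = list(paste0("g", 1:10), NULL)))
#' hierarchicalCluster(z, k = 2)
#' @export
hierarchicalCluster <- function(z, k = NULL) {
    z <- as.matrix(z)
    if (nrow(z) < 2) stop("need >= 2 genes to cluster")
    if (any(!is.finite(z))) stop("z matrix must be finite")
    if (is.null(rownames(z))) rownames(z) <- as.character(seq_len(nrow(z)))
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "average")
    ord <- .canonicalOrder(hc$merge, hc$labels)
    cl <- if (is.null(k)) stats::setNames(integer(), character())
          else stats::cutree(hc, k = k)
    new("ClusterResult", geneOrder = ord, zMatrix = z,
        merge = hc$merge, height = hc$height,
        clusters = as.integer(cl) |> stats::setNames(names(cl)))
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the cluster contains more term genes than
#' expected under hypergeometric sampling from the universe (one-tailed
#' upper p-value, inclusive of the observed overlap), with BH adjustment
#' across terms. A generic stand-in for GO-term enrichment of expression
#' clusters.
#'
#' @param clusterGenes gene identifiers of the cluster; must all lie in
#'   `universe`.
#' @param annotation `data.frame` with columns `gene_id`, `term`; rows
#'   outside the universe are ignored.
#' @param universe gene identifiers of the background.
#' @return `data.frame` with columns `term`, `count`, `size`, `expected`,
#'   `p_value`, `padj`, sorted by `p_value`.
#' @examples
#' ann <- data.frame(gene_id = paste0("g", 1:6),
#'                   term = rep(c("iron", "other"), each = 3))
#' overRepresentation(paste0("g", 1:3), ann, paste0("g", 1:20))
#' @export
overRepresentation <- function(clusterGenes, annotation, universe) {
    .checkCols(annotation, c("gene_id", "term"), "'annotation'")
    out <- setdiff(clusterGenes, universe)
    if (length(out))
        stop("cluster gene(s) outside the universe: ",
             paste(out, collapse = ", "))
    annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
    N <- length(unique(universe))
    n <- length(unique(clusterGenes))
    terms <- unique(annotation$term)
    res <- do.call(rbind, lapply(terms, function(tm) {
        termGenes <- unique(annotation$gene_id[annotation$term == tm])
        K <- length(termGenes)
        k <- length(intersect(termGenes, clusterGenes))
        data.frame(term = tm, count = k, size = K,
                   expected = n * K / N,
                   p_value = stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(res))
        return(data.frame(term = character(), count = integer(),
                          size = integer(), expected = numeric(),
                          p_value = numeric(), padj = numeric()))
    res$padj <- bhAdjust(res$p_value)
    res[order(res$p_value), ]
}
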