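## Simplified per-genotype negative-binomial Wald test for iron regulation,
## with Benjamini-Hochberg FDR at padj < 0.05. Deliberately NOT a DESeq
## re-implementation: no dispersion shrinkage across genes, no outlier
## filtering, no independent filtering.

#' Benjamini-Hochberg adjusted p-values
#'
#' Validates the inputs and applies the standard step-up procedure via
#' [stats::p.adjust()]; input order is preserved and values are capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must be finite and in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-genotype negative-binomial Wald test for iron regulation
#'
#' For one genotype, tests each gene's minusFe vs plusFe contrast. The
#' gene-wise dispersion is estimated by method of moments,
#' `alpha = (var - mean) / mean^2`, pooled across the two conditions and
#' floored at 1e-8; the variance of each condition mean is floored at the
#' Poisson bound `mean / n`. The Wald statistic is the log2 fold change over
#' its delta-method standard error, referred to the standard normal
#' (two-sided). BH-adjusted p-values and the up-regulation call at
#' `padj < alpha` are appended.
#'
#' @param x an [IronCountExperiment-class].
#' @param genotype `"wildtype"` or `"clf"`; both conditions must have at
#'   least 2 replicates.
#' @param pseudocount pseudocount used for the log2 fold change.
#' @param alpha adjusted-p threshold for `significant_up` (default 0.05).
#' @return `data.frame` with columns `gene_id`, `genotype`, `base_mean`,
#'   `lfc`, `p_value`, `padj`, `significant_up`.
#' @examples
#' sc <- defaultScenario(3, 3, 10, seed = 1)
#' head(nbWaldTest(simulateCounts(sc$specs, sc$design), "wildtype"))
#' @export
nbWaldTest <- function(x, genotype = c("wildtype", "clf"),
                       pseudocount = 0.5, alpha = 0.05) {
    genotype <- match.arg(genotype)
    norm <- normalizedCounts(x)
    cd <- colData(x)
    sel1 <- cd$genotype == genotype & cd$condition == "minusFe"
    sel0 <- cd$genotype == genotype & cd$condition == "plusFe"
    if (sum(sel1) < 2 || sum(sel0) < 2)
        stop("need >= 2 replicates per condition for genotype ", genotype)
    y1 <- norm[, sel1, drop = FALSE]; n1 <- ncol(y1)
    y0 <- norm[, sel0, drop = FALSE]; n0 <- ncol(y0)
    m1 <- rowMeans(y1); m0 <- rowMeans(y0)
    v1 <- apply(y1, 1, stats::var); v0 <- apply(y0, 1, stats::var)
    # pooled method-of-moments dispersion, floored
    a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
    a0 <- ifelse(m0 > 0, (v0 - m0) / m0^2, NA_real_)
    disp <- pmax(rowMeans(cbind(a1, a0), na.rm = TRUE), 1e-8)
    disp[is.nan(disp)] <- 1e-8
    lfc <- log2((m1 + pseudocount) / (m0 + pseudocount))
    vm1 <- pmax(m1 + disp * m1^2, m1) / n1
    vm0 <- pmax(m0 + disp * m0^2, m0) / n0
    se2 <- (vm1 / (m1 + pseudocount)^2 + vm0 / (m0 + pseudocount)^2) / log(2)^2
    z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
    p <- 2 * stats::pnorm(-abs(z))
    padj <- bhAdjust(p)
    data.frame(gene_id = rownames(x), genotype = genotype,
               base_mean = rowMeans(norm[, sel1 | sel0, drop = FALSE]),
               lfc = lfc, p_value = p, padj = padj,
               significant_up = padj < alpha & lfc > 0,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Call iron-regulated genes from test records
#'
#' @param records output of [nbWaldTest()] for one genotype.
#' @param threshold adjusted-p threshold (default 0.05).
#' @param direction `"up"` (induced under iron deficiency) or `"down"`.
#' @return Character vector of gene identifiers, sorted.
#' @examples
#' rec <- data.frame(gene_id = c("a", "b", "c"), genotype = "wildtype",
#'                   base_mean = 10, lfc = c(2, 1, -2),
#'                   p_value = c(0.001, 0.2, 0.002),
#'                   padj = c(0.01, 0.2, 0.04), significant_up = NA)
#' callIronRegulated(rec, direction = "up")
#' @export
callIronRegulated <- function(records, threshold = 0.05,
                              direction = c("up", "down")) {
    direction <- match.arg(direction)
    if (nrow(records) == 0L) return(character())
    keep <- records$padj < threshold &
        (if (direction == "up") records$lfc > 0 else records$lfc < 0)
    sort(records$gene_id[keep])
}
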