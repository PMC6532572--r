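## Normalization, FPKM and per-genotype minusFe/plusFe fold changes
## (the x and y coordinates of the clf-vs-wildtype induction scatter).

#' Median-of-ratios size factors for a count matrix
#'
#' The classical median-of-ratios estimator: per-gene geometric means form a
#' pseudo-reference sample; a sample's factor is the median of its ratios to
#' that reference over genes expressed in every sample (positive geometric
#' mean). Factors are rescaled to geometric mean 1 so a matrix of identical
#' samples yields factors of exactly 1.
#'
#' @param counts non-negative gene x sample matrix.
#' @return Positive per-sample size factors (geometric mean 1).
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' medianOfRatios(m)  # ratio 1 : 2
#' @export
medianOfRatios <- function(counts) {
    counts <- as.matrix(counts)
    keep <- apply(counts > 0, 1, all)
    if (!any(keep))
        stop("no gene has positive counts in every sample; cannot estimate size factors")
    logc <- log(counts[keep, , drop = FALSE])
    ref <- rowMeans(logc)
    sf <- exp(apply(logc - ref, 2, stats::median))
    sf / exp(mean(log(sf)))
}

#' @rdname medianOfRatios
#' @param object an [IronCountExperiment-class].
#' @export
setMethod("sizeFactors", "IronCountExperiment", function(object) {
    medianOfRatios(counts(object))
})

#' Size-factor-normalized counts
#'
#' @param x an [IronCountExperiment-class].
#' @param sf optional precomputed size factors; defaults to
#'   [medianOfRatios()] of the count matrix.
#' @return Numeric gene x sample matrix of `counts / size_factor`.
#' @export
normalizedCounts <- function(x, sf = NULL) {
    if (is.null(sf)) sf <- sizeFactors(x)
    sweep(counts(x), 2, sf, "/")
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm(g, s) = count(g, s) * 1e9 / (length_bp(g) * total_counts(s))`,
#' using raw per-sample totals as the per-million denominator.
#'
#' @param x an [IronCountExperiment-class].
#' @return Numeric gene x sample matrix.
#' @examples
#' sc <- defaultScenario(3, 3, 2, seed = 1)
#' fpkm(simulateCounts(sc$specs, sc$design))[1:3, 1:2]
#' @export
fpkm <- function(x) {
    cts <- counts(x)
    totals <- colSums(cts)
    if (any(totals == 0)) stop("zero library total in sample(s): ",
                               paste(colnames(cts)[totals == 0], collapse = ", "))
    sweep(sweep(cts * 1e9, 1, as.numeric(geneLengths(x)), "/"),
          2, totals, "/")
}

.conditionMean <- function(norm, cd, genotype, condition) {
    sel <- cd$genotype == genotype & cd$condition == condition
    if (!any(sel))
        stop("design cell missing: ", genotype, "/", condition)
    rowMeans(norm[, sel, drop = FALSE])
}

#' Per-genotype iron-deficiency fold changes
#'
#' For each gene and genotype, the fold change is the ratio of mean
#' expression under iron deficiency to iron sufficiency,
#' `fc = (mean(minusFe) + pseudocount) / (mean(plusFe) + pseudocount)`,
#' where means are taken over replicates of size-factor-normalized counts
#' (or of FPKM with `method = "fpkm"`). The symmetric pseudocount keeps fold
#' changes finite on zero counts while leaving well-expressed genes
#' essentially unchanged. `delta = lfc_clf - lfc_wt` is the per-gene
#' genotype contrast on the log2 scale; genes with `delta > 0` lie above the
#' y = x diagonal of the clf-vs-wildtype induction scatter.
#'
#' Median-of-ratios factors need several genes to be meaningful: a
#' single-gene matrix self-normalizes and every fold change collapses to 1.
#' For such degenerate inputs (e.g. single-gene simulations at known unit
#' sequencing depth) supply `sf` explicitly.
#'
#' @param x an [IronCountExperiment-class] with all four design cells.
#' @param pseudocount added to both condition means (default 0.5).
#' @param method `"normalized"` (default) or `"fpkm"`.
#' @param sf optional per-sample size factors overriding the
#'   median-of-ratios estimate; ignored for `method = "fpkm"`.
#' @return `data.frame` with columns `gene_id`, `fc_wt`, `fc_clf`,
#'   `lfc_wt`, `lfc_clf`, `delta`, one row per gene in input order.
#' @examples
#' sc <- defaultScenario(3, 3, 2, seed = 1)
#' head(foldChanges(simulateCounts(sc$specs, sc$design)))
#' @export
foldChanges <- function(x, pseudocount = 0.5,
                        method = c("normalized", "fpkm"), sf = NULL) {
    method <- match.arg(method)
    if (pseudocount < 0) stop("'pseudocount' must be >= 0")
    norm <- if (method == "fpkm") fpkm(x) else normalizedCounts(x, sf = sf)
    cd <- colData(x)
    fc <- vapply(.GENOTYPES, function(g) {
        m1 <- .conditionMean(norm, cd, g, "minusFe")
        m0 <- .conditionMean(norm, cd, g, "plusFe")
        (m1 + pseudocount) / (m0 + pseudocount)
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) fc <- matrix(fc, nrow = 1L,
                                    dimnames = list(rownames(x), .GENOTYPES))
    lfc <- log2(fc)
    data.frame(gene_id = rownames(x),
               fc_wt = fc[, "wildtype"], fc_clf = fc[, "clf"],
               lfc_wt = lfc[, "wildtype"], lfc_clf = lfc[, "clf"],
               delta = lfc[, "clf"] - lfc[, "wildtype"],
               row.names = NULL, stringsAsFactors = FALSE)
}
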