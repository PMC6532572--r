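#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## factor levels used throughout: genotype and iron condition of a sample
.GENOTYPES  <- c("wildtype", "clf")
.CONDITIONS <- c("plusFe", "minusFe")

#' Genotype and iron-condition levels
#'
#' The two genotypes (wild type and the PRC2 mutant \emph{clf}) and the two
#' iron conditions (iron-sufficient \code{plusFe}, iron-deficient
#' \code{minusFe}) that every [IronCountExperiment] sample is annotated with.
#'
#' @return A character vector of levels.
#' @examples
#' genotypeLevels()
#' conditionLevels()
#' @export
genotypeLevels <- function() .GENOTYPES

#' @rdname genotypeLevels
#' @export
conditionLevels <- function() .CONDITIONS

# ---------------------------------------------------------------------------
# IronCountExperiment
# ---------------------------------------------------------------------------

#' Container for genotype x iron-condition RNA-seq counts
#'
#' An `IronCountExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding an integer gene x sample count matrix in the `"counts"` assay,
#' per-gene transcript lengths in `rowData(x)$length_bp`, and per-sample
#' `genotype` (`"wildtype"`/`"clf"`), `condition` (`"plusFe"`/`"minusFe"`)
#' and `replicate` columns in `colData(x)`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [simulateCounts()], [readCountMatrix()], [foldChanges()]
#' @export
setClass("IronCountExperiment", contains = "SummarizedExperiment")

setValidity("IronCountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(!is.finite(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    if (!"length_bp" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'length_bp'")
    else if (any(rowData(object)$length_bp < 1))
        msg <- c(msg, "gene lengths must be >= 1 bp")
    cd <- colData(object)
    need <- c("genotype", "condition", "replicate")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, sprintf("colData must contain %s",
                              paste(need, collapse = ", ")))
    else {
        if (!all(cd$genotype %in% .GENOTYPES))
            msg <- c(msg, sprintf("genotype must be one of %s",
                                  paste(.GENOTYPES, collapse = "/")))
        if (!all(cd$condition %in% .CONDITIONS))
            msg <- c(msg, sprintf("condition must be one of %s",
                                  paste(.CONDITIONS, collapse = "/")))
        key <- paste(cd$genotype, cd$condition, cd$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "each (genotype, condition, replicate) triple must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an IronCountExperiment
#'
#' @param counts integer gene x sample matrix with row and column names.
#' @param lengthsBp per-gene transcript lengths in base pairs (>= 1).
#' @param sampleInfo `data.frame` with one row per column of `counts` and
#'   columns `sample_id` (matching `colnames(counts)`), `genotype`,
#'   `condition`, `replicate`.
#' @return An [IronCountExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(8, 20), nrow = 2,
#'               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' info <- data.frame(sample_id = paste0("s", 1:4),
#'                    genotype = rep(c("wildtype", "clf"), each = 2),
#'                    condition = rep(c("plusFe", "minusFe"), 2),
#'                    replicate = 1L)
#' IronCountExperiment(cts, c(1000L, 1500L), info)
#' @export
IronCountExperiment <- function(counts, lengthsBp, sampleInfo) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        stop("'counts' must have gene identifiers as rownames")
    if (!identical(colnames(counts), as.character(sampleInfo$sample_id)))
        stop("colnames(counts) must equal sampleInfo$sample_id, in order")
    cd <- DataFrame(genotype = as.character(sampleInfo$genotype),
                    condition = as.character(sampleInfo$condition),
                    replicate = as.integer(sampleInfo$replicate),
                    row.names = as.character(sampleInfo$sample_id))
    rd <- DataFrame(length_bp = as.integer(lengthsBp),
                    row.names = rownames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rd, colData = cd)
    new("IronCountExperiment", se)
}

#' Accessors for IronCountExperiment
#'
#' `counts()` returns the integer count matrix, `geneLengths()` the per-gene
#' transcript lengths, `sampleGenotype()` / `sampleCondition()` the per-sample
#' design annotations.
#'
#' @param object,x an [IronCountExperiment-class].
#' @return `counts()`: integer matrix; the others: vectors along samples/genes.
#' @name ice-accessors
NULL

#' @rdname ice-accessors
#' @export
setMethod("counts", "IronCountExperiment",
          function(object) assay(object, "counts"))

#' @rdname ice-accessors
#' @export
geneLengths <- function(x) {
    stopifnot(is(x, "IronCountExperiment"))
    stats::setNames(rowData(x)$length_bp, rownames(x))
}

#' @rdname ice-accessors
#' @export
sampleGenotype <- function(x) {
    stopifnot(is(x, "IronCountExperiment"))
    stats::setNames(colData(x)$genotype, colnames(x))
}

#' @rdname ice-accessors
#' @export
sampleCondition <- function(x) {
    stopifnot(is(x, "IronCountExperiment"))
    stats::setNames(colData(x)$condition, colnames(x))
}

setMethod("show", "IronCountExperiment", function(object) {
    cd <- colData(object)
    cat("IronCountExperiment:", nrow(object), "genes x",
        ncol(object), "samples\n")
    cat("  design:", paste(sprintf("%s/%s n=%d",
        rep(.GENOTYPES, each = 2), rep(.CONDITIONS, 2),
        vapply(seq_len(4), function(i) {
            g <- rep(.GENOTYPES, each = 2)[i]; cc <- rep(.CONDITIONS, 2)[i]
            sum(cd$genotype == g & cd$condition == cc)
        }, integer(1))), collapse = ", "), "\n")
    invisible(NULL)
})

# ---------------------------------------------------------------------------
# GeneSets
# ---------------------------------------------------------------------------

#' Named collection of gene sets
#'
#' Holds named character vectors of gene identifiers; the set names act as
#' regulator labels (e.g. `"FIT"`, `"PYE"`, `"background"`).
#'
#' @slot sets named list of character vectors.
#' @seealso [readGeneSets()], [asymmetryTest()]
#' @export
setClass("GeneSets", representation(sets = "list"))

setValidity("GeneSets", function(object) {
    s <- object@sets
    if (length(s) && (is.null(names(s)) || any(names(s) == "")))
        return("all gene sets must be named")
    if (anyDuplicated(names(s)))
        return("gene set names must be unique")
    if (!all(vapply(s, is.character, logical(1))))
        return("gene sets must be character vectors")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0))
        return("gene identifiers must be unique within a set")
    TRUE
})

#' @param ... named character vectors of gene identifiers.
#' @return A [GeneSets-class] object.
#' @examples
#' gs <- GeneSets(FIT = c("FIT", "FRO2", "IRT1"),
#'                PYE = c("PYE", "BTS", "FRO3"))
#' names(gs)
#' gs[["FIT"]]
#' @rdname GeneSets-class
#' @export
GeneSets <- function(...) {
    new("GeneSets", sets = lapply(list(...), as.character))
}

#' @rdname GeneSets-class
#' @export
setMethod("names", "GeneSets", function(x) names(x@sets))

#' @rdname GeneSets-class
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSets", function(x, i) x@sets[[i]])

#' @rdname GeneSets-class
#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

setMethod("show", "GeneSets", function(object) {
    cat("GeneSets with", length(object@sets), "sets:\n")
    for (nm in names(object@sets))
        cat(sprintf("  %s: %d genes\n", nm, length(object@sets[[nm]])))
    invisible(NULL)
})

# ---------------------------------------------------------------------------
# AsymmetryResult
# ---------------------------------------------------------------------------

#' Result of the induction-asymmetry test
#'
#' Bundles the observed above-diagonal proportions of the focal and
#' comparator sets, their difference, the label-randomization p-value with
#' its null sample, and the Mann-Whitney U comparison of the per-gene
#' induction differences (delta = clf log2 fold change minus wild-type log2
#' fold change).
#'
#' @slot pObsFocal observed proportion of focal-set genes with delta > 0.
#' @slot pObsComparator same for the comparator set.
#' @slot diffObs focal minus comparator proportion.
#' @slot pRandomization add-one-corrected randomization p-value.
#' @slot nPerm number of label permutations.
#' @slot nullProportions permuted-focal proportions (the null sample).
#' @slot mwU Mann-Whitney U statistic (focal vs comparator deltas).
#' @slot mwP Mann-Whitney p-value.
#' @slot alternative `"greater"` or `"two.sided"`.
#' @slot seed integer seed used for the permutations.
#' @slot nFocal,nComparator set sizes.
#' @seealso [asymmetryTest()], [randomizationTest()], [mannWhitney()]
#' @export
setClass("AsymmetryResult",
         representation(pObsFocal = "numeric", pObsComparator = "numeric",
                        diffObs = "numeric", pRandomization = "numeric",
                        nPerm = "integer", nullProportions = "numeric",
                        mwU = "numeric", mwP = "numeric",
                        alternative = "character", seed = "integer",
                        nFocal = "integer", nComparator = "integer"))

setValidity("AsymmetryResult", function(object) {
    msg <- character()
    if (length(object@pRandomization) &&
        object@pRandomization < 1 / (object@nPerm + 1) - 1e-12)
        msg <- c(msg, "p must respect the add-one lower bound 1/(nPerm+1)")
    if (length(object@mwU) && !is.na(object@mwU) &&
        (object@mwU < 0 ||
         object@mwU > as.numeric(object@nFocal) * object@nComparator))
        msg <- c(msg, "U must lie in [0, nFocal * nComparator]")
    if (length(msg)) msg else TRUE
})

#' @rdname AsymmetryResult-class
#' @param x an `AsymmetryResult`.
#' @export
randomizationP <- function(x) x@pRandomization

#' @rdname AsymmetryResult-class
#' @export
mannWhitneyU <- function(x) x@mwU

#' @rdname AsymmetryResult-class
#' @export
mannWhitneyP <- function(x) x@mwP

#' @rdname AsymmetryResult-class
#' @export
observedProportions <- function(x)
    c(focal = x@pObsFocal, comparator = x@pObsComparator, diff = x@diffObs)

#' Flatten an AsymmetryResult to a plain list
#'
#' @param x an [AsymmetryResult-class].
#' @param ... ignored.
#' @return A named list of scalar fields (the null sample is omitted),
#'   suitable for JSON serialization.
#' @export
setMethod("as.list", "AsymmetryResult", function(x, ...) {
    list(p_obs_focal = x@pObsFocal, p_obs_comparator = x@pObsComparator,
         diff_obs = x@diffObs, p_randomization = x@pRandomization,
         n_perm = x@nPerm, mw_u = x@mwU, mw_p = x@mwP,
         alternative = x@alternative, seed = x@seed,
         n_focal = x@nFocal, n_comparator = x@nComparator)
})

setMethod("show", "AsymmetryResult", function(object) {
    cat("Induction asymmetry test (", object@alternative, ")\n", sep = "")
    cat(sprintf("  above-diagonal proportion: focal %.3f (n=%d), comparator %.3f (n=%d), diff %.3f\n",
                object@pObsFocal, object@nFocal, object@pObsComparator,
                object@nComparator, object@diffObs))
    cat(sprintf("  randomization p = %.3g  (%d permutations, seed %d)\n",
                object@pRandomization, object@nPerm, object@seed))
    if (!is.na(object@mwU))
        cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n",
                    object@mwU, object@mwP))
    invisible(NULL)
})

# ---------------------------------------------------------------------------
# ClusterResult
# ---------------------------------------------------------------------------

#' Result of hierarchical clustering of z-scored expression rows
#'
#' @slot geneOrder dendrogram leaf order after canonical tie-breaking.
#' @slot zMatrix the clustered z-score matrix (rows in input order).
#' @slot merge,height the agglomeration sequence as in [stats::hclust()].
#' @slot clusters named integer cluster assignments (empty if no cut
#'   was requested).
#' @seealso [hierarchicalCluster()], [zscoreRows()]
#' @export
setClass("ClusterResult",
         representation(geneOrder = "character", zMatrix = "matrix",
                        merge = "matrix", height = "numeric",
                        clusters = "integer"))

setValidity("ClusterResult", function(object) {
    if (length(object@height) > 1 &&
        any(diff(object@height) < -1e-8 * max(abs(object@height))))
        return("linkage heights must be non-decreasing")
    if (!setequal(object@geneOrder, rownames(object@zMatrix)))
        return("geneOrder must be a permutation of the z-matrix rows")
    TRUE
})

#' @rdname ClusterResult-class
#' @param x a `ClusterResult`.
#' @export
geneOrder <- function(x) x@geneOrder

#' @rdname ClusterResult-class
#' @export
clusterAssignments <- function(x) x@clusters

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult:", nrow(object@zMatrix), "genes,",
        ncol(object@zMatrix), "groups")
    if (length(object@clusters))
        cat(",", max(object@clusters), "clusters")
    cat("\n")
    invisible(NULL)
})
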