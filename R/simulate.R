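## Seeded negative-binomial simulator for the 2 genotype x 2 iron-condition
## x n replicate root RNA-seq design.

# derive a per-gene seed by counter offset so adding genes to a scenario
# never perturbs the draws of earlier genes; kept inside 32-bit range
.geneSeed <- function(seed, i) {
    as.integer((as.numeric(seed) + i) %% 2147483647)
}

#' Reported induction magnitudes used as simulation ground truth
#'
#' Fold inductions (mean expression under iron deficiency over iron
#' sufficiency) of hallmark iron-deficiency response genes in wild-type and
#' \emph{clf} roots, as quantified by RNA-seq of the two genotypes. The
#' FIT-dependent Strategy I genes (\emph{FIT}, \emph{FRO2}, \emph{IRT1})
#' carry a genotype x treatment interaction (stronger induction in
#' \emph{clf}); the PYE-dependent genes (\emph{PYE}, \emph{BTS},
#' \emph{FRO3}) are comparably induced in both genotypes. These pairs are
#' the effect-size pool of [defaultScenario()].
#'
#' @return A list with elements `FIT` and `PYE`, each a `data.frame` with
#'   columns `gene`, `induction_wt`, `induction_clf`.
#' @examples
#' inductionEffectPairs()$FIT
#' @export
inductionEffectPairs <- function() {
    list(FIT = data.frame(gene = c("FIT", "FRO2", "IRT1"),
                          induction_wt = c(3.9, 13.7, 11.3),
                          induction_clf = c(5.0, 40.8, 22.4)),
         PYE = data.frame(gene = c("PYE", "BTS", "FRO3"),
                          induction_wt = c(4.9, 5.9, 17.5),
                          induction_clf = c(4.6, 5.7, 16.4)))
}

#' Specify one simulated gene
#'
#' Builds a one-row gene specification for [simulateCounts()]. Expected
#' counts in a sample are `base_mean * size_factor`, multiplied by the
#' genotype's induction ratio when the sample is iron-deficient. Counts are
#' negative binomial with `var = mu + dispersion * mu^2`; `dispersion = 0`
#' degenerates to Poisson.
#'
#' @param geneId gene identifier.
#' @param baseMean expected iron-sufficient wild-type count at size factor 1
#'   (> 0).
#' @param inductionWt,inductionClf minusFe/plusFe mean ratio per genotype
#'   (> 0; 1 = not iron-regulated).
#' @param dispersion negative-binomial dispersion alpha (>= 0).
#' @param lengthBp transcript length in bp (>= 1); 1000 by default so FPKM
#'   values are easy to reason about.
#' @param setLabel `"FIT"`, `"PYE"` or `"background"`.
#' @return A one-row `data.frame`; rbind such rows to form a spec table.
#' @examples
#' simGeneSpec("FRO2", baseMean = 200, inductionWt = 13.7,
#'             inductionClf = 40.8, setLabel = "FIT")
#' @export
simGeneSpec <- function(geneId, baseMean, inductionWt = 1, inductionClf = 1,
                        dispersion = 0.05, lengthBp = 1000L,
                        setLabel = "background") {
    if (baseMean <= 0) stop("'baseMean' must be > 0")
    if (inductionWt <= 0 || inductionClf <= 0)
        stop("induction ratios must be > 0")
    if (dispersion < 0) stop("'dispersion' must be >= 0")
    if (lengthBp < 1) stop("'lengthBp' must be >= 1")
    setLabel <- match.arg(setLabel, c("FIT", "PYE", "background"))
    data.frame(gene_id = as.character(geneId), length_bp = as.integer(lengthBp),
               base_mean = baseMean, induction_wt = inductionWt,
               induction_clf = inductionClf, dispersion = dispersion,
               set_label = setLabel, stringsAsFactors = FALSE)
}

#' Specify the simulated experimental design
#'
#' Two genotypes (wildtype, clf) x two iron conditions (plusFe, minusFe)
#' with `nReps` biological replicates per cell (3 by default, the standard
#' design of root RNA-seq experiments of this kind). Size factors default
#' to 1; `perturbSizeFactors = TRUE` draws them log-normally (sdlog 0.1,
#' seeded) to exercise normalization.
#'
#' @param nReps replicates per design cell (>= 1).
#' @param sizeFactors optional vector of `4 * nReps` positive per-sample
#'   size factors (sample order: genotype, then condition, then replicate).
#' @param perturbSizeFactors draw size factors from lognormal(0, 0.1)?
#'   Ignored when `sizeFactors` is given.
#' @param seed integer seed governing all randomness of the design and of
#'   [simulateCounts()] runs using it.
#' @return A list with elements `genotypes`, `conditions`, `n_reps`,
#'   `size_factors`, `seed`.
#' @examples
#' simDesign(nReps = 3, seed = 1)
#' @export
simDesign <- function(nReps = 3, sizeFactors = NULL,
                      perturbSizeFactors = FALSE, seed = 1L) {
    nReps <- as.integer(nReps)
    if (nReps < 1) stop("'nReps' must be >= 1")
    n <- 4L * nReps
    if (is.null(sizeFactors)) {
        if (perturbSizeFactors) {
            set.seed(.geneSeed(seed, 0L))
            sizeFactors <- stats::rlnorm(n, meanlog = 0, sdlog = 0.1)
        } else sizeFactors <- rep(1, n)
    }
    if (length(sizeFactors) != n || any(sizeFactors <= 0))
        stop("'sizeFactors' must be ", n, " positive values")
    list(genotypes = .GENOTYPES, conditions = .CONDITIONS,
         n_reps = nReps, size_factors = as.numeric(sizeFactors),
         seed = as.integer(seed))
}

.designSamples <- function(design) {
    g <- rep(design$genotypes, each = 2L * design$n_reps)
    cc <- rep(rep(design$conditions, each = design$n_reps), 2L)
    r <- rep(seq_len(design$n_reps), 4L)
    data.frame(sample_id = paste(g, cc, r, sep = "_"),
               genotype = g, condition = cc, replicate = r,
               stringsAsFactors = FALSE)
}

#' Simulate a genotype x iron-condition count matrix
#'
#' Draws negative-binomial counts for each gene specification under the
#' given design: `mu = size_factor * base_mean * induction^[minusFe]`, with
#' the genotype-specific induction ratio applied only to iron-deficient
#' samples, and `var = mu + dispersion * mu^2`. Each gene uses its own
#' random stream derived from the design seed by counter offset, so the same
#' seed reproduces the matrix bit-identically and appending genes leaves
#' earlier genes' counts untouched.
#'
#' @param specs `data.frame` of gene specifications (rbind of
#'   [simGeneSpec()] rows).
#' @param design design list from [simDesign()].
#' @return An [IronCountExperiment-class].
#' @examples
#' sp <- rbind(simGeneSpec("FRO2", 200, 13.7, 40.8, setLabel = "FIT"),
#'             simGeneSpec("bg1", 100))
#' simulateCounts(sp, simDesign(nReps = 3, seed = 1))
#' @export
simulateCounts <- function(specs, design) {
    need <- c("gene_id", "length_bp", "base_mean", "induction_wt",
              "induction_clf", "dispersion", "set_label")
    if (!all(need %in% colnames(specs)))
        stop("'specs' must contain columns ", paste(need, collapse = ", "))
    if (any(specs$base_mean <= 0)) stop("base_mean must be > 0")
    if (any(specs$dispersion < 0)) stop("dispersion must be >= 0")
    if (any(specs$induction_wt <= 0) || any(specs$induction_clf <= 0))
        stop("induction ratios must be > 0")
    if (anyDuplicated(specs$gene_id)) stop("gene_id values must be unique")
    samples <- .designSamples(design)
    sf <- design$size_factors
    deficient <- samples$condition == "minusFe"
    isClf <- samples$genotype == "clf"
    nG <- nrow(specs); nS <- nrow(samples)
    cts <- matrix(0L, nrow = nG, ncol = nS,
                  dimnames = list(specs$gene_id, samples$sample_id))
    for (i in seq_len(nG)) {
        ind <- ifelse(isClf, specs$induction_clf[i], specs$induction_wt[i])
        mu <- sf * specs$base_mean[i] * ifelse(deficient, ind, 1)
        set.seed(.geneSeed(design$seed, i))
        a <- specs$dispersion[i]
        cts[i, ] <- if (a == 0) stats::rpois(nS, mu)
                    else stats::rnbinom(nS, mu = mu, size = 1 / a)
    }
    ice <- IronCountExperiment(cts, specs$length_bp, samples)
    S4Vectors::metadata(ice)$specs <- specs
    S4Vectors::metadata(ice)$design <- design
    ice
}

#' Default simulation scenario for the asymmetry analysis
#'
#' Builds the standard synthetic study: `nFit` focal genes cycling through
#' the three FIT-dependent induction pairs of [inductionEffectPairs()]
#' (stronger induction in \emph{clf}), `nPye` comparator genes cycling
#' through the three PYE-dependent pairs (no genotype effect), and
#' `nBackground` genes with no iron regulation. Baseline expression is drawn
#' log-normally around 100 counts (sdlog 1, seeded), a realistic spread for
#' moderately expressed root transcripts.
#'
#' @param nFit,nPye number of focal / comparator genes (>= 1).
#' @param nBackground number of unregulated genes (>= 0).
#' @param nReps replicates per design cell.
#' @param dispersion shared negative-binomial dispersion (0.05 by default,
#'   typical biological-replicate variability for bulk RNA-seq).
#' @param seed integer seed; the scenario is deterministic given it.
#' @return A list with `specs` (gene specification `data.frame`), `design`
#'   (from [simDesign()]) and `sets` (a [GeneSets-class] with the FIT,
#'   PYE and background memberships).
#' @examples
#' sc <- defaultScenario(nFit = 3, nPye = 3, nBackground = 2, seed = 1)
#' sc$specs[, c("gene_id", "induction_wt", "induction_clf", "set_label")]
#' @export
defaultScenario <- function(nFit = 45, nPye = 45, nBackground = 150,
                            nReps = 3, dispersion = 0.05, seed = 1L) {
    if (nFit < 1 || nPye < 1) stop("'nFit' and 'nPye' must be >= 1")
    if (nBackground < 0) stop("'nBackground' must be >= 0")
    pairs <- inductionEffectPairs()
    fitIdx <- ((seq_len(nFit) - 1L) %% 3L) + 1L
    pyeIdx <- ((seq_len(nPye) - 1L) %% 3L) + 1L
    ids <- c(sprintf("FIT_%03d", seq_len(nFit)),
             sprintf("PYE_%03d", seq_len(nPye)),
             if (nBackground > 0) sprintf("BG_%03d", seq_len(nBackground)))
    nTot <- nFit + nPye + nBackground
    set.seed(.geneSeed(seed, 0L))
    baseMean <- stats::rlnorm(nTot, meanlog = log(100), sdlog = 1)
    specs <- data.frame(
        gene_id = ids, length_bp = 1000L, base_mean = baseMean,
        induction_wt = c(pairs$FIT$induction_wt[fitIdx],
                         pairs$PYE$induction_wt[pyeIdx],
                         rep(1, nBackground)),
        induction_clf = c(pairs$FIT$induction_clf[fitIdx],
                          pairs$PYE$induction_clf[pyeIdx],
                          rep(1, nBackground)),
        dispersion = dispersion,
        set_label = rep(c("FIT", "PYE", "background"),
                        c(nFit, nPye, nBackground)),
        stringsAsFactors = FALSE)
    sets <- GeneSets(FIT = ids[seq_len(nFit)],
                     PYE = ids[nFit + seq_len(nPye)],
                     background = if (nBackground > 0)
                         ids[nFit + nPye + seq_len(nBackground)]
                     else character())
    list(specs = specs, design = simDesign(nReps = nReps, seed = seed),
         sets = sets)
}
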