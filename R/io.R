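## Plain-text readers/writers: counts + metadata TSV, gene sets (two-column
## TSV or GMT), qPCR plate CSV, ChIP-qPCR CSV.

#' Write counts and sample metadata as TSV
#'
#' The counts file has columns `gene_id`, `length_bp`, then one column per
#' sample; the metadata file has `sample_id`, `genotype`, `condition`,
#' `replicate`.
#'
#' @param x an [IronCountExperiment-class].
#' @param countsPath,metaPath output file paths.
#' @return Invisibly, `x`.
#' @export
writeCountMatrix <- function(x, countsPath, metaPath) {
    cts <- counts(x)
    df <- data.frame(gene_id = rownames(cts),
                     length_bp = as.integer(geneLengths(x)),
                     cts, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- colData(x)
    meta <- data.frame(sample_id = rownames(cd), genotype = cd$genotype,
                       condition = cd$condition, replicate = cd$replicate,
                       stringsAsFactors = FALSE)
    utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(x)
}

#' Read counts and sample metadata from TSV
#'
#' @param countsPath TSV with columns `gene_id`, `length_bp`, then sample
#'   columns.
#' @param metaPath TSV with columns `sample_id`, `genotype`, `condition`,
#'   `replicate`.
#' @return An [IronCountExperiment-class].
#' @export
readCountMatrix <- function(countsPath, metaPath) {
    df <- utils::read.delim(countsPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    .checkCols(df, c("gene_id", "length_bp"), "counts file")
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
    .checkCols(meta, c("sample_id", "genotype", "condition", "replicate"),
               "metadata file")
    sampleCols <- setdiff(colnames(df), c("gene_id", "length_bp"))
    if (!setequal(sampleCols, meta$sample_id))
        stop("sample columns of the counts file must match the metadata")
    cts <- as.matrix(df[, as.character(meta$sample_id), drop = FALSE])
    rownames(cts) <- df$gene_id
    IronCountExperiment(cts, df$length_bp, meta)
}

#' Read gene sets from two-column TSV or GMT
#'
#' TSV files need columns `gene_id` and `set`; GMT lines are
#' `set <tab> description <tab> gene...`. The format is inferred from the
#' file extension unless given.
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"` or `"gmt"`.
#' @return A [GeneSets-class].
#' @export
readGeneSets <- function(path, format = c("auto", "tsv", "gmt")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt"
                  else "tsv"
    if (format == "gmt") {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        sets <- lapply(parts, function(p) unique(p[-(1:2)]))
        names(sets) <- vapply(parts, `[[`, character(1), 1L)
    } else {
        df <- utils::read.delim(path, stringsAsFactors = FALSE)
        .checkCols(df, c("gene_id", "set"), "gene-set file")
        sets <- lapply(split(df$gene_id, df$set), unique)
    }
    do.call(GeneSets, sets)
}

#' Read a qPCR plate CSV
#'
#' Expects columns `sample_id`, `target`, `ct`, `is_reference`.
#'
#' @param path input CSV.
#' @return A validated `data.frame` for [relativeExpression()].
#' @export
readQpcrPlate <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    .checkCols(df, c("sample_id", "target", "ct", "is_reference"),
               "qPCR plate file")
    df$is_reference <- as.logical(df$is_reference)
    if (any(is.na(df$is_reference)))
        stop("'is_reference' must be TRUE/FALSE")
    df
}

#' Read a ChIP-qPCR table CSV
#'
#' Expects columns `sample_id`, `region`, `antibody`, `ct_ip`, `ct_input`
#' and optionally `input_fraction` (default 0.10).
#'
#' @param path input CSV.
#' @return A validated `data.frame` for [relativeEnrichment()].
#' @export
readChipTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    .checkCols(df, c("sample_id", "region", "antibody", "ct_ip", "ct_input"),
               "ChIP table file")
    if (!"input_fraction" %in% colnames(df)) df$input_fraction <- 0.10
    if (any(df$input_fraction <= 0 | df$input_fraction > 1))
        stop("'input_fraction' must be in (0, 1]")
    df
}
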