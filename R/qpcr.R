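## qRT-PCR delta-Ct relative expression and ChIP-qPCR percent-of-input /
## relative-enrichment calculators. Amplification efficiency is fixed at 2
## (100%): one PCR cycle doubles the template.

.checkCols <- function(df, cols, what) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop(what, " must contain column(s): ", paste(miss, collapse = ", "))
}

#' Relative expression by the delta-Ct method
#'
#' Per sample, the mean Ct of the reference target (e.g. \emph{ACT2}) is
#' subtracted from each target's mean Ct (technical replicates averaged
#' arithmetically); expression is `2^(-deltaCt)` and is reported as the
#' ratio to the calibrator sample (e.g. wild type under iron sufficiency),
#' whose ratio is 1 by construction. Plate-wide Ct offsets cancel within a
#' sample.
#'
#' @param wells `data.frame` with columns `sample_id`, `target`, `ct`,
#'   `is_reference` (logical; the internal-control wells). Every sample
#'   needs at least one reference well.
#' @param calibrator sample identifier the ratios are relative to; must
#'   carry every target.
#' @return `data.frame` with columns `sample_id`, `target`, `delta_ct`,
#'   `expression`, `relative_expression`.
#' @examples
#' plate <- data.frame(
#'   sample_id = rep(c("WT_plusFe", "WT_minusFe"), each = 2),
#'   target = rep(c("ACT2", "FRO2"), 2),
#'   ct = c(20, 30, 20, 25),
#'   is_reference = rep(c(TRUE, FALSE), 2))
#' relativeExpression(plate, "WT_plusFe")  # FRO2 induced 32-fold
#' @export
relativeExpression <- function(wells, calibrator) {
    .checkCols(wells, c("sample_id", "target", "ct", "is_reference"),
               "'wells'")
    if (any(!is.finite(wells$ct))) stop("all Ct values must be finite")
    samples <- unique(wells$sample_id)
    if (!calibrator %in% samples)
        stop("calibrator sample not found: ", calibrator)
    refBy <- tapply(wells$ct[wells$is_reference],
                    wells$sample_id[wells$is_reference], mean)
    noRef <- setdiff(samples, names(refBy))
    if (length(noRef))
        stop("sample(s) missing a reference well: ",
             paste(noRef, collapse = ", "))
    agg <- stats::aggregate(ct ~ sample_id + target, data = wells, FUN = mean)
    agg$delta_ct <- agg$ct - as.numeric(refBy[agg$sample_id])
    agg$expression <- 2^(-agg$delta_ct)
    calExpr <- agg$expression[agg$sample_id == calibrator]
    names(calExpr) <- agg$target[agg$sample_id == calibrator]
    missTarget <- setdiff(unique(agg$target), names(calExpr))
    if (length(missTarget))
        stop("calibrator lacks target(s): ", paste(missTarget, collapse = ", "))
    agg$relative_expression <- agg$expression / as.numeric(calExpr[agg$target])
    agg[order(agg$sample_id, agg$target),
        c("sample_id", "target", "delta_ct", "expression",
          "relative_expression")]
}

#' ChIP signal as percent of input
#'
#' The input Ct is first adjusted for the input dilution:
#' `adjusted = ct_input - log2(1 / input_fraction)` (a 10% input aliquot is
#' log2(10) cycles "ahead" of the full input). Percent input is then
#' `100 * 2^(adjusted - ct_ip)`.
#'
#' @param ctIp IP-sample Ct value(s).
#' @param ctInput input-sample Ct value(s).
#' @param inputFraction fraction of chromatin reserved as input, in (0, 1\];
#'   default 0.10.
#' @return Percent-of-input value(s), on the percent scale.
#' @examples
#' percentInput(26, 25, 0.10)  # 5%
#' @export
percentInput <- function(ctIp, ctInput, inputFraction = 0.10) {
    if (any(inputFraction <= 0) || any(inputFraction > 1))
        stop("'inputFraction' must be in (0, 1]")
    adjusted <- ctInput - log2(1 / inputFraction)
    100 * 2^(adjusted - ctIp)
}

#' Relative ChIP enrichment across samples
#'
#' Computes percent-of-input per record, averages technical replicates per
#' (sample, region, antibody), and reports the target antibody's
#' percent-input relative to a calibrator sample (e.g. H3K27me3 enrichment
#' relative to \emph{clf} under iron sufficiency). Optionally the IgG
#' percent-input is subtracted first (floored at 0, with a warning when the
#' floor binds) and/or the result divided by the H3 percent-input; both are
#' off by default as the standard normalization is to input only.
#'
#' @param records `data.frame` with columns `sample_id`, `region`,
#'   `antibody`, `ct_ip`, `ct_input` and optionally `input_fraction`
#'   (default 0.10).
#' @param calibrator sample identifier; must carry every region for the
#'   target antibody.
#' @param antibody the antibody quantified (default `"H3K27me3"`).
#' @param subtractIgG subtract matched IgG percent-input?
#' @param normalizeH3 divide by matched H3 percent-input?
#' @return `data.frame` with columns `sample_id`, `region`,
#'   `percent_input`, `relative_enrichment`.
#' @examples
#' chip <- data.frame(
#'   sample_id = rep(c("clf_plusFe", "WT_plusFe"), each = 1),
#'   region = "FIT-a", antibody = "H3K27me3",
#'   ct_ip = c(28, 26), ct_input = c(25, 25))
#' relativeEnrichment(chip, "clf_plusFe")
#' @export
relativeEnrichment <- function(records, calibrator, antibody = "H3K27me3",
                               subtractIgG = FALSE, normalizeH3 = FALSE) {
    .checkCols(records, c("sample_id", "region", "antibody", "ct_ip",
                          "ct_input"), "'records'")
    if (!"input_fraction" %in% colnames(records))
        records$input_fraction <- 0.10
    records$pi <- percentInput(records$ct_ip, records$ct_input,
                               records$input_fraction)
    agg <- stats::aggregate(pi ~ sample_id + region + antibody,
                            data = records, FUN = mean)
    pick <- function(ab) {
        sub <- agg[agg$antibody == ab, c("sample_id", "region", "pi")]
        stats::setNames(sub$pi, paste(sub$sample_id, sub$region, sep = "\r"))
    }
    main <- agg[agg$antibody == antibody, , drop = FALSE]
    if (nrow(main) == 0L) stop("no records for antibody ", antibody)
    value <- main$pi
    if (subtractIgG) {
        igg <- pick("IgG")
        key <- paste(main$sample_id, main$region, sep = "\r")
        if (any(!key %in% names(igg)))
            stop("IgG record missing for some (sample, region)")
        value <- value - as.numeric(igg[key])
        if (any(value < 0)) {
            warning("IgG-subtracted percent input floored at 0 for ",
                    sum(value < 0), " record(s)")
            value <- pmax(value, 0)
        }
    }
    if (normalizeH3) {
        h3 <- pick("H3")
        key <- paste(main$sample_id, main$region, sep = "\r")
        if (any(!key %in% names(h3)))
            stop("H3 record missing for some (sample, region)")
        value <- value / as.numeric(h3[key])
    }
    cal <- value[main$sample_id == calibrator]
    names(cal) <- main$region[main$sample_id == calibrator]
    missRegion <- setdiff(unique(main$region), names(cal))
    if (length(missRegion))
        stop("calibrator lacks region(s): ", paste(missRegion, collapse = ", "))
    out <- data.frame(sample_id = main$sample_id, region = main$region,
                      percent_input = main$pi,
                      relative_enrichment = value / as.numeric(cal[main$region]),
                      stringsAsFactors = FALSE)
    out[order(out$sample_id, out$region), ]
}
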