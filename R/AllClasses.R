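#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
NULL

.SAMPLE_KINDS <- c("library", "DNA", "RNA")
.AMPLICON_GROUPS <- c("GWAS", "LD", "FBDHS", "PutEnh", "other")

#' MpraExperiment: container for amplicon MPRA count data
#'
#' An S4 class extending \linkS4class{RangedSummarizedExperiment} that holds a
#' raw amplicon-by-sample count matrix (assay \code{"counts"}), the amplicon
#' catalog as row ranges (with metadata columns \code{amplicon_id},
#' \code{group}, \code{gc}, \code{ascertained_enhancer}), and the sample sheet
#' as column data (\code{kind} in \code{library}/\code{DNA}/\code{RNA},
#' \code{replicate}, and optional \code{technical_of} naming the biological
#' sample a technical replicate duplicates).
#'
#' @seealso [MpraExperiment()] for the constructor,
#'   [computeProportions()], [filterAmplicons()], [callActivity()].
#' @exportClass MpraExperiment
setClass("MpraExperiment", contains = "RangedSummarizedExperiment")

setValidity("MpraExperiment", function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    }
    cd <- colData(object)
    if (!all(c("kind", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'kind' and 'replicate'")
    else if (!all(cd$kind %in% .SAMPLE_KINDS))
        msg <- c(msg, sprintf("sample kind must be one of %s",
                              paste(.SAMPLE_KINDS, collapse = ", ")))
    if ("technical_of" %in% colnames(cd)) {
        tech <- cd$technical_of[!is.na(cd$technical_of)]
        if (!all(tech %in% rownames(cd)))
            msg <- c(msg, "technical_of must name an existing sample")
    }
    rr <- rowRanges(object)
    m <- mcols(rr)
    if (!all(c("amplicon_id", "group", "gc") %in% colnames(m)))
        msg <- c(msg, "rowRanges must carry 'amplicon_id', 'group' and 'gc'")
    else {
        if (anyDuplicated(m$amplicon_id))
            msg <- c(msg, "amplicon_id must be unique")
        if (any(m$gc < 0 | m$gc > 1, na.rm = TRUE))
            msg <- c(msg, "gc must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' BackgroundModelFit: fitted MPRA background regression
#'
#' Holds the ordinary least-squares fit of log2 mean RNA proportion on
#' log2 mean DNA proportion and amplicon GC fraction over a trimmed training
#' set, together with residual scale and a Kolmogorov-Smirnov normality
#' diagnostic of the training residuals.
#'
#' @slot coefficients Named numeric: \code{intercept}, \code{slope_dna}
#'   (per unit log2 DNA proportion), \code{coeff_gc} (per unit GC fraction).
#' @slot residualSd Residual standard deviation of the training fit.
#' @slot trainingIds Character vector of amplicon ids used for training.
#' @slot ksStatistic,ksP Kolmogorov-Smirnov statistic and p-value for
#'   normality of standardized training residuals.
#' @slot model The underlying \code{lm} object.
#' @exportClass BackgroundModelFit
setClass("BackgroundModelFit",
    representation(coefficients = "numeric", residualSd = "numeric",
                   trainingIds = "character", ksStatistic = "numeric",
                   ksP = "numeric", model = "ANY"))

setMethod("show", "BackgroundModelFit", function(object) {
    cat("BackgroundModelFit\n")
    cat(sprintf("  log2(RNA) = %.4f %+.4f * log2(DNA) %+.4f * GC\n",
                object@coefficients[["intercept"]],
                object@coefficients[["slope_dna"]],
                object@coefficients[["coeff_gc"]]))
    cat(sprintf("  residual sd: %.4f  (training n = %d)\n",
                object@residualSd, length(object@trainingIds)))
    cat(sprintf("  KS normality of residuals: D = %.4f, p = %.3g\n",
                object@ksStatistic, object@ksP))
    invisible(NULL)
})
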