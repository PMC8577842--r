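#' Convert raw amplicon counts to pseudocounted proportions
#'
#' Per amplicon \eqn{i} and sample \eqn{s}, the proportion is
#' \eqn{(c_{is} + 1) / (\sum_j c_{js} + 1)}: one pseudocount is added to the
#' numerator and to the sample total so zero counts never divide by zero.
#' Proportions therefore need not sum exactly to 1 within a sample, but rank
#' order within a sample is preserved.
#'
#' @param x An [MpraExperiment-class] or a numeric count matrix.
#' @param ... Unused.
#' @return For a matrix, the proportion matrix; for an
#'   \code{MpraExperiment}, the object with a \code{"proportions"} assay
#'   added.
#' @examples
#' computeProportions(matrix(c(1, 3), 2, 1,
#'     dimnames = list(c("a", "b"), "s1")))
#' @export
setGeneric("computeProportions",
           function(x, ...) standardGeneric("computeProportions"))

#' @rdname computeProportions
#' @export
setMethod("computeProportions", "matrix", function(x, ...) {
    if (!length(x)) stop("empty count matrix")
    sweep(x + 1, 2, colSums(x) + 1, "/")
})

#' @rdname computeProportions
#' @export
setMethod("computeProportions", "MpraExperiment", function(x, ...) {
    SummarizedExperiment::assay(x, "proportions") <-
        computeProportions(counts(x))
    x
})

#' Apply the amplicon inclusion filters
#'
#' An amplicon is removed if its minimum raw count across DNA samples falls
#' below \code{min_dna_count}, or if its mean proportion across DNA samples
#' falls below \code{min_lib_proportion}. The two rules are applied
#' independently and the exclusion log records which fired for each removed
#' amplicon, so the alternative readings of the thresholds remain auditable.
#' Technical replicates are never used for filtering; the previral library
#' sample participates only in QC correlations, not in filtering.
#'
#' @param x An [MpraExperiment-class].
#' @param min_dna_count Minimum raw count required in every DNA sample
#'   (default 200).
#' @param min_lib_proportion Minimum mean DNA proportion (default
#'   \code{2^-15}).
#' @return The filtered \code{MpraExperiment}; the exclusion log (a
#'   \code{DataFrame} with \code{amplicon_id}, \code{min_dna_count},
#'   \code{mean_dna_proportion}, \code{rule}) is stored in
#'   \code{metadata(x)$exclusionLog}.
#' @examples
#' sim <- simulateMpra(simConfig(n_amplicons = 50, depth_dna = 5e4, seed = 1))
#' filt <- filterAmplicons(sim$mpra)
#' S4Vectors::metadata(filt)$exclusionLog
#' @export
filterAmplicons <- function(x, min_dna_count = 200,
                            min_lib_proportion = 2^-15) {
    dna <- dnaSamples(x)
    if (!length(dna)) stop("no DNA samples present")
    cnt <- counts(x)
    prop <- computeProportions(cnt)
    min_cnt <- apply(cnt[, dna, drop = FALSE], 1, min)
    mean_prop <- rowMeans(prop[, dna, drop = FALSE])
    low_count <- min_cnt < min_dna_count
    low_prop <- mean_prop < min_lib_proportion
    drop <- low_count | low_prop
    rule <- ifelse(low_count & low_prop, "low_count;low_proportion",
                   ifelse(low_count, "low_count", "low_proportion"))
    log <- DataFrame(amplicon_id = ampliconIds(x)[drop],
                     min_dna_count = unname(min_cnt[drop]),
                     mean_dna_proportion = unname(mean_prop[drop]),
                     rule = unname(rule[drop]))
    out <- x[!drop, ]
    metadata(out)$exclusionLog <- log
    metadata(out)$filterThresholds <-
        list(min_dna_count = min_dna_count,
             min_lib_proportion = min_lib_proportion)
    out
}

#' Pearson correlation between two sample vectors
#'
#' Thin wrapper around \code{\link[stats]{cor.test}} used for
#' replicate-replicate, GC-representation and ortholog QC comparisons;
#' returns the coefficient with its two-sided p-value from the t transform.
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return List with elements \code{r} and \code{p}.
#' @examples
#' pairwiseCorrelation(1:4, c(1, 3, 2, 4))
#' @importFrom stats cor.test sd
#' @export
pairwiseCorrelation <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("x and y must have equal length >= 3")
    if (sd(x) == 0 || sd(y) == 0)
        stop("correlation undefined for constant input")
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Replicate and GC-bias QC correlations
#'
#' Computes all pairwise Pearson correlations between sample proportion
#' vectors (log2 scale) and the correlation of each sample's log2 proportion
#' with amplicon GC content.
#'
#' @param x An [MpraExperiment-class].
#' @return List with \code{samples} (data.frame of pairwise sample
#'   correlations with kinds) and \code{gc} (per-sample correlation of log2
#'   proportion with GC).
#' @export
qcCorrelations <- function(x) {
    lp <- log2(computeProportions(counts(x)))
    sids <- colnames(lp)
    kind <- sampleKind(x)
    pairs <- utils::combn(sids, 2)
    samples <- data.frame(
        sample1 = pairs[1, ], sample2 = pairs[2, ],
        kind1 = kind[pairs[1, ]], kind2 = kind[pairs[2, ]],
        r = apply(pairs, 2, function(p) {
            pairwiseCorrelation(lp[, p[1]], lp[, p[2]])$r
        }),
        p = apply(pairs, 2, function(p) {
            pairwiseCorrelation(lp[, p[1]], lp[, p[2]])$p
        }),
        row.names = NULL)
    gc <- mcols(rowRanges(x))$gc
    gc_cor <- vapply(sids, function(s) pairwiseCorrelation(lp[, s], gc)$r,
                     numeric(1))
    list(samples = samples,
         gc = data.frame(sample_id = sids, kind = unname(kind[sids]),
                         r = unname(gc_cor), row.names = NULL))
}
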