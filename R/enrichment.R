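#' Merge annotation intervals
#'
#' Reduces an interval set to sorted, non-overlapping ranges per chromosome,
#' merging overlapping and book-ended intervals; total covered bases are
#' preserved. Idempotent.
#'
#' @param x A \code{GRanges}, or a \code{data.frame} with \code{chrom},
#'   \code{start}, \code{end} in 0-based half-open coordinates.
#' @return A reduced \code{GRanges}.
#' @examples
#' mergeIntervals(data.frame(chrom = "chr1", start = c(1, 4), end = c(5, 8)))
#' @export
mergeIntervals <- function(x) {
    if (is.data.frame(x)) {
        if (any(x$end <= x$start)) stop("intervals require end > start")
        x <- GRanges(x$chrom, IRanges(x$start + 1L, x$end))
    }
    GenomicRanges::reduce(x)
}

#' Amplicon overlap flags against a merged mark
#'
#' TRUE for each amplicon sharing at least one base with any interval of the
#' mark on the same chromosome (half-open semantics are handled by the
#' GRanges coordinate conversion in [mergeIntervals()]).
#'
#' @param amplicons A catalog \code{GRanges}.
#' @param mark A mark \code{GRanges} (merged or not; it is merged first).
#' @return Named logical vector over amplicons.
#' @importFrom IRanges overlapsAny
#' @export
markOverlap <- function(amplicons, mark) {
    flags <- suppressWarnings(overlapsAny(amplicons, mergeIntervals(mark)))
    names(flags) <- mcols(amplicons)$amplicon_id
    flags
}

#' Background-aware permutation test for annotation enrichment
#'
#' Tests whether significant amplicons overlap an annotation mark more often
#' than random draws from the assay's own library background: the null
#' resamples \code{length(significant_ids)} amplicons without replacement
#' from \code{background_ids} and counts their overlaps. The one-tailed
#' Monte-Carlo p-value uses the add-one estimator
#' \eqn{(\#\{null \ge obs\} + 1) / (n_{perm} + 1)}, so it is never zero.
#' Sampling amplicon identities (rather than genomic positions) conditions
#' the test on the library's composition, absorbing selection bias.
#'
#' @param significant_ids Ids of significant amplicons (subset of
#'   background).
#' @param background_ids Ids of all retained amplicons.
#' @param overlap_flags Named logical vector over the background, as from
#'   [markOverlap()].
#' @param n_perm Number of random samplings (default 20000).
#' @param seed Integer seed for reproducibility.
#' @return List with \code{observed_overlap}, \code{n_significant},
#'   \code{n_background}, \code{perm_p}, \code{n_permutations}, \code{seed}.
#' @export
permutationEnrichment <- function(significant_ids, background_ids,
                                  overlap_flags, n_perm = 20000, seed = 1L) {
    if (!all(significant_ids %in% background_ids))
        stop("significant_ids must be a subset of background_ids")
    k <- length(significant_ids)
    if (k > length(background_ids))
        stop("more significant than background amplicons")
    flags <- overlap_flags[background_ids]
    obs <- sum(flags[significant_ids])
    set.seed(seed)
    null <- vapply(seq_len(n_perm),
                   function(i) sum(flags[sample.int(length(flags), k)]),
                   numeric(1))
    list(observed_overlap = obs, n_significant = k,
         n_background = length(background_ids),
         perm_p = (sum(null >= obs) + 1) / (n_perm + 1),
         n_permutations = n_perm, seed = seed)
}

#' Evaluate an annotation mark as a GLM covariate
#'
#' Compares Gaussian linear models of log2 RNA proportion on log2 DNA
#' proportion and GC, with and without a dichotomous mark-overlap flag.
#' Reports the flag's coefficient and t-test p-value and the BIC of both
#' models; a BIC reduction when adding the flag indicates the mark improves
#' prediction of reporter RNA beyond background.
#'
#' @param log2_rna,log2_dna,gc Numeric vectors over amplicons.
#' @param mark_flag Logical vector of mark overlap (non-constant).
#' @return List with \code{coef}, \code{t_p}, \code{bic_without},
#'   \code{bic_with}.
#' @importFrom stats lm BIC
#' @export
glmCovariateBic <- function(log2_rna, log2_dna, gc, mark_flag) {
    if (length(unique(mark_flag)) < 2)
        stop("degenerate covariate: mark_flag is constant")
    df <- data.frame(y = log2_rna, dna = log2_dna, gc = gc,
                     flag = as.numeric(mark_flag))
    m0 <- lm(y ~ dna + gc, data = df)
    m1 <- lm(y ~ dna + gc + flag, data = df)
    ct <- summary(m1)$coefficients
    list(coef = unname(ct["flag", "Estimate"]),
         t_p = unname(ct["flag", "Pr(>|t|)"]),
         bic_without = BIC(m0), bic_with = BIC(m1))
}

#' Point-biserial correlation of Z-scores with a mark flag
#'
#' Pearson correlation between a continuous score and the 0/1 encoding of a
#' dichotomous annotation flag.
#'
#' @param z Numeric vector.
#' @param flag Logical vector with both classes present.
#' @return The correlation coefficient.
#' @examples
#' pointBiserial(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' @importFrom stats cor
#' @export
pointBiserial <- function(z, flag) {
    if (length(unique(flag)) < 2)
        stop("flag must contain both classes")
    cor(z, as.numeric(flag))
}

#' Enrichment analysis of active amplicons across annotation marks
#'
#' For each mark: merges its intervals, intersects the amplicon catalog,
#' runs the background-aware permutation test comparing significant
#' amplicons to the library background, evaluates the mark as a GLM
#' covariate and computes the point-biserial correlation with the model
#' Z-scores.
#'
#' @param activity An activity \code{DataFrame} from [callActivity()].
#' @param catalog The catalog \code{GRanges} of the retained amplicons.
#' @param marks Named list or \code{GRangesList} of annotation interval
#'   sets.
#' @param significant Logical vector (or amplicon ids) defining the
#'   significant set; default \code{p_model < 0.05}.
#' @param n_perm,seed Permutation settings (default 20000 samplings).
#' @return \code{data.frame} with one row per mark: observed overlap counts,
#'   permutation p, GLM covariate coefficient, t p-value, BIC with/without,
#'   and point-biserial correlation.
#' @export
enrichmentAnalysis <- function(activity, catalog, marks,
                               significant = NULL, n_perm = 20000,
                               seed = 1L) {
    ids <- activity$amplicon_id
    catalog <- catalog[match(ids, mcols(catalog)$amplicon_id)]
    if (is.null(significant)) significant <- activity$p_model < 0.05
    sig_ids <- if (is.logical(significant)) ids[significant]
               else as.character(significant)
    rows <- lapply(names(marks), function(mk) {
        flags <- markOverlap(catalog, marks[[mk]])
        pe <- permutationEnrichment(sig_ids, ids, flags,
                                    n_perm = n_perm, seed = seed)
        glm_row <- if (length(unique(flags)) < 2)
            list(coef = NA_real_, t_p = NA_real_,
                 bic_without = NA_real_, bic_with = NA_real_)
        else glmCovariateBic(log2(activity$mean_rna_prop),
                             log2(activity$mean_dna_prop),
                             activity$gc, flags[ids])
        pb <- if (length(unique(flags)) < 2) NA_real_
              else pointBiserial(activity$z, flags[ids])
        data.frame(mark = mk, n_overlap_background = sum(flags),
                   observed_overlap = pe$observed_overlap,
                   n_significant = pe$n_significant,
                   n_background = pe$n_background, perm_p = pe$perm_p,
                   n_permutations = pe$n_permutations,
                   glm_coef = glm_row$coef, glm_t_p = glm_row$t_p,
                   bic_without = glm_row$bic_without,
                   bic_with = glm_row$bic_with, point_biserial = pb)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
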