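#' Read an allele count table
#'
#' Long-format TSV mirroring common readcount-extractor output, with one row
#' per (SNP, sample, allele): columns \code{snp_id}, \code{amplicon_id},
#' \code{chrom}, \code{pos}, \code{sample_id}, \code{base}, \code{is_ref},
#' \code{count}, \code{mean_base_quality}.
#'
#' @param path File path.
#' @return \code{data.frame}.
#' @export
readAlleleCounts <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("snp_id", "sample_id", "base", "is_ref", "count",
              "mean_base_quality")
    if (!all(need %in% colnames(tab)))
        stop("allele table must have columns: ", paste(need, collapse = ", "))
    tab$is_ref <- as.logical(tab$is_ref)
    tab
}

#' Filter allele counts to well-supported biallelic SNPs
#'
#' Drops allele observations with mean base quality below
#' \code{min_base_quality} and alleles whose within-sample frequency falls
#' below \code{min_af}, then retains only SNPs left with exactly two
#' surviving alleles across the table. (Per-read mapping/base-quality
#' filters are the upstream extractor's job; only the tabular filters are
#' applied here.)
#'
#' @param table Allele count \code{data.frame} as from
#'   [readAlleleCounts()] or [simulateAlleles()].
#' @param min_base_quality Minimum mean base quality (default 25).
#' @param min_af Minimum within-sample allele frequency (default 0.01).
#' @return The filtered biallelic table.
#' @export
filterAlleleCounts <- function(table, min_base_quality = 25, min_af = 0.01) {
    tab <- table[table$mean_base_quality >= min_base_quality, , drop = FALSE]
    if (nrow(tab)) {
        key <- paste(tab$snp_id, tab$sample_id)
        tot <- tapply(tab$count, key, sum)
        af <- tab$count / as.numeric(tot[key])
        tab <- tab[af >= min_af, , drop = FALSE]
    }
    n_alleles <- vapply(split(tab$base, tab$snp_id),
                        function(b) length(unique(b)), integer(1))
    biallelic <- names(n_alleles)[n_alleles == 2]
    out <- tab[tab$snp_id %in% biallelic, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-SNP allele-frequency summary for DNA versus RNA
#'
#' Pools ref/alt counts within each sample kind, reports the reference
#' allele frequency per SNP in DNA and RNA, flags SNPs whose pooled-DNA
#' minor allele frequency exceeds \code{maf_threshold} as eligible for
#' allelic comparison, and computes the Pearson correlation of ref AF
#' between DNA and RNA across eligible SNPs. SNPs with zero total counts in
#' a kind are reported as missing (NA), not zero.
#'
#' @param table A filtered biallelic table from [filterAlleleCounts()].
#' @param sample_kinds Named character vector mapping sample ids to kinds
#'   (as from [sampleKind()]).
#' @param maf_threshold Pooled-DNA MAF eligibility threshold (default 0.1).
#' @return List with \code{snps} (data.frame: \code{snp_id},
#'   \code{amplicon_id}, \code{ref_af_dna}, \code{ref_af_rna}, \code{maf_dna},
#'   \code{eligible}) and \code{dna_rna_correlation} over eligible SNPs (NA
#'   when fewer than 3 are eligible).
#' @export
alleleSummary <- function(table, sample_kinds, maf_threshold = 0.1) {
    kinds <- sample_kinds[table$sample_id]
    if (anyNA(kinds)) stop("sample ids missing from sample_kinds")
    if (!any(kinds == "DNA") || !any(kinds == "RNA"))
        stop("need >= 1 DNA and >= 1 RNA sample")
    pool_af <- function(kind) {
        sub <- table[kinds == kind, , drop = FALSE]
        ref <- tapply(sub$count[sub$is_ref], sub$snp_id[sub$is_ref], sum)
        tot <- tapply(sub$count, sub$snp_id, sum)
        r <- as.numeric(ref[names(tot)])
        r[is.na(r)] <- 0  # SNP observed but no ref-allele rows
        af <- ifelse(tot == 0, NA_real_, r / as.numeric(tot))
        setNames(af, names(tot))
    }
    af_dna <- pool_af("DNA")
    af_rna <- pool_af("RNA")
    snp_ids <- sort(unique(table$snp_id))
    amp <- table$amplicon_id[match(snp_ids, table$snp_id)]
    ref_dna <- unname(af_dna[snp_ids])
    ref_rna <- unname(af_rna[snp_ids])
    maf <- pmin(ref_dna, 1 - ref_dna)
    eligible <- !is.na(maf) & maf > maf_threshold
    snps <- data.frame(snp_id = snp_ids, amplicon_id = amp,
                       ref_af_dna = ref_dna, ref_af_rna = ref_rna,
                       maf_dna = maf, eligible = eligible)
    ok <- eligible & !is.na(ref_rna)
    corr <- if (sum(ok) >= 3 && sd(ref_dna[ok]) > 0 && sd(ref_rna[ok]) > 0)
        cor(ref_dna[ok], ref_rna[ok]) else NA_real_
    list(snps = snps, dna_rna_correlation = corr)
}
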