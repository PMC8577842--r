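#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T), case-insensitive. IUPAC ambiguity
#' codes (N, R, Y, ...) are excluded from both numerator and denominator, so
#' the estimate is unbiased on masked sequence.
#'
#' @param x Character vector of nucleotide sequences, or a
#'   \code{\link[Biostrings]{DNAStringSet}}.
#' @return Numeric vector of GC fractions in \code{[0, 1]}.
#' @examples
#' gcContent(c("ACGT", "GGCC", "ATGCN"))
#' @importFrom Biostrings DNAStringSet letterFrequency
#' @export
gcContent <- function(x) {
    if (is.character(x)) x <- DNAStringSet(toupper(x))
    freq <- letterFrequency(x, letters = c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    if (any(denom == 0))
        stop("sequence with zero unambiguous A/C/G/T characters")
    unname((freq[, "G"] + freq[, "C"]) / denom)
}

#' In-silico PCR against a reference sequence
#'
#' Predicts PCR products for a primer pair on a reference: a product requires
#' a forward-primer match at its 5' end and a reverse-complemented
#' reverse-primer match at its 3' end (each allowing up to
#' \code{max_mismatches} mismatches) with total length within
#' \code{[min_product, max_product]}. Both orientations are scanned, so
#' products primed off the bottom strand are reported with strand \code{"-"}.
#' Primer sequences are the genomic-priming portions only; cloning homology
#' tails must be stripped before calling.
#'
#' @param reference Character or \code{DNAString} reference sequence.
#' @param forward,reverse Primer sequences (character).
#' @param min_product,max_product Allowed product length range in bp.
#' @param max_mismatches Maximum mismatches tolerated per primer site.
#' @return \code{data.frame} with columns \code{start}, \code{end} (0-based,
#'   half-open on the reference), \code{length} and \code{strand}, sorted by
#'   ascending start. Zero rows when no product is predicted.
#' @examples
#' inSilicoPcr("AAACCCTTTTTTGGGAGA", "AAACCC", "TCTCCC", 10, 30)
#' @importFrom Biostrings DNAString reverseComplement matchPattern
#' @export
inSilicoPcr <- function(reference, forward, reverse,
                        min_product, max_product, max_mismatches = 0) {
    if (!nzchar(forward) || !nzchar(reverse))
        stop("primers must be non-empty")
    if (min_product > max_product)
        stop("min_product must be <= max_product")
    ref <- if (is.character(reference)) DNAString(toupper(reference)) else reference
    hits <- function(primer) {
        m <- matchPattern(DNAString(toupper(primer)), ref,
                          max.mismatch = max_mismatches)
        data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
    }
    pair_up <- function(p5, p3, strand) {
        out <- list()
        for (i in seq_len(nrow(p5))) for (j in seq_len(nrow(p3))) {
            len <- p3$end[j] - p5$start[i] + 1L
            if (p3$start[j] > p5$end[i] &&
                len >= min_product && len <= max_product)
                out[[length(out) + 1L]] <- data.frame(
                    start = p5$start[i] - 1L, end = p3$end[j],
                    length = len, strand = strand)
        }
        out
    }
    rc <- function(p) as.character(reverseComplement(DNAString(toupper(p))))
    prods <- c(pair_up(hits(forward), hits(rc(reverse)), "+"),
               pair_up(hits(reverse), hits(rc(forward)), "-"))
    if (!length(prods))
        return(data.frame(start = integer(), end = integer(),
                          length = integer(), strand = character()))
    out <- do.call(rbind, prods)
    out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read / write an amplicon catalog TSV
#'
#' Tab-separated catalog with columns \code{amplicon_id}, \code{chrom},
#' \code{start}, \code{end} (0-based half-open), \code{group}, \code{gc},
#' \code{ascertained_enhancer}. Coordinates are converted to the 1-based
#' closed convention of \code{GRanges} on read and back on write.
#'
#' @param path File path.
#' @param catalog A catalog \code{GRanges}.
#' @return \code{readAmpliconCatalog} returns a \code{GRanges};
#'   \code{writeAmpliconCatalog} invisibly returns \code{path}.
#' @importFrom utils read.delim write.table
#' @export
readAmpliconCatalog <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("amplicon_id", "chrom", "start", "end", "group", "gc")
    if (!all(need %in% colnames(tab)))
        stop("catalog must have columns: ", paste(need, collapse = ", "))
    if (any(tab$end <= tab$start)) stop("catalog requires end > start")
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
    mcols(gr)$amplicon_id <- tab$amplicon_id
    mcols(gr)$group <- tab$group
    mcols(gr)$gc <- tab$gc
    mcols(gr)$ascertained_enhancer <-
        if ("ascertained_enhancer" %in% colnames(tab))
            as.logical(tab$ascertained_enhancer) else NA
    names(gr) <- tab$amplicon_id
    gr
}

#' @rdname readAmpliconCatalog
#' @export
writeAmpliconCatalog <- function(catalog, path) {
    m <- mcols(catalog)
    tab <- data.frame(amplicon_id = m$amplicon_id,
                      chrom = as.character(GenomicRanges::seqnames(catalog)),
                      start = BiocGenerics::start(catalog) - 1L,
                      end = BiocGenerics::end(catalog),
                      group = m$group, gc = m$gc,
                      ascertained_enhancer = m$ascertained_enhancer)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
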