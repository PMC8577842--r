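# Independent oracles used to freeze expected values. Deliberately written
# with different algorithms than the package implementations.

# Brute-force in-silico PCR: scan every (forward site, reverse site) pair by
# direct character comparison.
bruteForcePcr <- function(reference, forward, reverse,
                          min_product, max_product, max_mismatches = 0) {
    ref <- strsplit(toupper(reference), "")[[1]]
    revcomp <- function(s) {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
    }
    sites <- function(primer) {
        p <- strsplit(toupper(primer), "")[[1]]
        found <- integer()
        for (i in seq_len(length(ref) - length(p) + 1))
            if (sum(ref[i:(i + length(p) - 1)] != p) <= max_mismatches)
                found <- c(found, i)
        found
    }
    rows <- list()
    scan <- function(p5, p3, strand) {
        for (i in sites(p5)) for (j in sites(p3)) {
            s <- i; e <- j + nchar(p3) - 1
            len <- e - s + 1
            if (j > i + nchar(p5) - 1 && len >= min_product &&
                len <= max_product)
                rows[[length(rows) + 1L]] <<- data.frame(
                    start = s - 1L, end = e, length = len, strand = strand)
        }
    }
    scan(forward, revcomp(reverse), "+")
    scan(reverse, revcomp(forward), "-")
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          length = integer(), strand = character()))
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Exact one-tailed rank-sum p by bitmask enumeration of all group
# assignments (midranks for ties).
enumWilcoxonP <- function(dna, rna) {
    n1 <- length(dna); n2 <- length(rna); n <- n1 + n2
    rk <- rank(c(dna, rna))
    w_obs <- sum(rk[(n1 + 1):n])
    hits <- 0L; total <- 0L
    for (mask in 0:(2^n - 1)) {
        bits <- as.integer(intToBits(mask))[1:n]
        if (sum(bits) != n2) next
        total <- total + 1L
        if (sum(rk[bits == 1]) >= w_obs - 1e-9) hits <- hits + 1L
    }
    hits / total
}

# Small MpraExperiment built directly from a count matrix, a uniform-GC
# catalog and an inferred sample sheet (column names DNA<i>/RNA<i>/library).
makeToyMpra <- function(counts, gc = NULL, group = "GWAS") {
    n <- nrow(counts)
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1000, by = 2000, length.out = n), width = 900))
    S4Vectors::mcols(gr)$amplicon_id <- rownames(counts)
    S4Vectors::mcols(gr)$group <- rep_len(group, n)
    S4Vectors::mcols(gr)$gc <- if (is.null(gc)) rep(0.5, n) else gc
    S4Vectors::mcols(gr)$ascertained_enhancer <- rep(FALSE, n)
    names(gr) <- rownames(counts)
    sid <- colnames(counts)
    kind <- ifelse(grepl("^DNA", sid), "DNA",
                   ifelse(grepl("^RNA", sid), "RNA", "library"))
    rep_id <- as.integer(gsub("[^0-9]", "", sid))
    rep_id[is.na(rep_id)] <- 1L
    MpraExperiment(counts, gr,
                   data.frame(sample_id = sid, kind = kind,
                              replicate = rep_id))
}
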