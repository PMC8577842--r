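#' Simulation configuration for synthetic MPRA data
#'
#' Collects the generative parameters of the synthetic amplicon MPRA used for
#' benchmarking the activity models. Defaults emulate the design of an
#' AAV-delivered amplicon library screened in brain: ~308 amplicons of
#' ~900 bp with varying GC, one previral library sample, four DNA and four
#' RNA biological replicates plus one high-cycle technical RNA replicate,
#' GC-correlated library representation, basal transcription proportional to
#' DNA representation, a multiplicative enhancer effect for a spiked-active
#' subset, and replicate-specific dropout of low-abundance amplicons in RNA.
#'
#' @param n_amplicons Number of amplicons.
#' @param n_dna_reps,n_rna_reps Number of DNA / RNA biological replicates.
#' @param depth_dna,depth_rna Expected total reads per DNA / RNA sample.
#' @param frac_active Fraction of amplicons spiked with a true enhancer
#'   effect; exactly \code{round(frac_active * n_amplicons)} are active.
#' @param effect_meanlog,effect_sdlog Log-normal law of the multiplicative
#'   enhancer effect for active amplicons (defaults give a fixed 4x effect).
#' @param gc_shape1,gc_shape2 Beta law for amplicon GC fraction.
#' @param gc_bias_coeff Log2 change in library/DNA representation per unit
#'   GC fraction (cloning/PCR GC bias).
#' @param basal_slope Expected log2 RNA proportion per log2 DNA proportion
#'   (basal transcription from the minimal promoter; near 1).
#' @param dispersion Negative-binomial overdispersion of counts
#'   (\code{variance = mu + dispersion * mu^2}); 0 gives Poisson counts.
#' @param dropout_rate Per-replicate probability that an amplicon in the
#'   lowest DNA-abundance decile yields zero RNA counts.
#' @param abundance_sd SD of amplicon-specific log2 abundance (library
#'   representation spread beyond GC bias).
#' @param include_technical Add one technical RNA replicate duplicating the
#'   last RNA replicate's expectation with independent noise.
#' @param seed Integer seed; all generators are reproducible given the seed.
#' @return A validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simConfig(n_amplicons = 100, seed = 1)
#' @export
simConfig <- function(n_amplicons = 308, n_dna_reps = 4, n_rna_reps = 4,
                      depth_dna = 2e6, depth_rna = 2e6,
                      frac_active = 0.1,
                      effect_meanlog = log(4), effect_sdlog = 0,
                      gc_shape1 = 10, gc_shape2 = 10,
                      gc_bias_coeff = 3, basal_slope = 1,
                      dispersion = 0.1, dropout_rate = 0.1,
                      abundance_sd = 0.8, include_technical = TRUE,
                      seed = 1L) {
    cfg <- list(n_amplicons = as.integer(n_amplicons),
                n_dna_reps = as.integer(n_dna_reps),
                n_rna_reps = as.integer(n_rna_reps),
                depth_dna = depth_dna, depth_rna = depth_rna,
                frac_active = frac_active,
                effect_meanlog = effect_meanlog, effect_sdlog = effect_sdlog,
                gc_shape1 = gc_shape1, gc_shape2 = gc_shape2,
                gc_bias_coeff = gc_bias_coeff, basal_slope = basal_slope,
                dispersion = dispersion, dropout_rate = dropout_rate,
                abundance_sd = abundance_sd,
                include_technical = isTRUE(include_technical),
                seed = as.integer(seed))
    stopifnot(cfg$n_amplicons > 0, cfg$n_dna_reps >= 1, cfg$n_rna_reps >= 1,
              cfg$depth_dna > 0, cfg$depth_rna > 0,
              cfg$frac_active >= 0, cfg$frac_active <= 1,
              cfg$dropout_rate >= 0, cfg$dropout_rate <= 1,
              cfg$dispersion >= 0)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate an amplicon catalog and activity ground truth
#'
#' Draws amplicon coordinates (~900 bp), group labels, GC fractions and an
#' open-chromatin ascertainment flag, and assigns a multiplicative enhancer
#' effect to exactly \code{round(frac_active * n)} amplicons (all others have
#' effect 1). Group proportions and the group-wise ascertainment rates mirror
#' a GWAS/LD/open-chromatin candidate library in which most SNP-bearing
#' amplicons are expected negatives.
#'
#' @param config A [simConfig()] object.
#' @return List with \code{catalog} (a \code{GRanges}) and \code{truth}
#'   (a \code{DataFrame} with \code{amplicon_id}, \code{true_effect}).
#' @examples
#' tr <- simulateTruth(simConfig(n_amplicons = 50, seed = 3))
#' table(tr$truth$true_effect > 1)
#' @importFrom stats rbeta rlnorm rnorm runif rbinom
#' @export
simulateTruth <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    n <- config$n_amplicons
    ids <- sprintf("amp%04d", seq_len(n))
    gc <- rbeta(n, config$gc_shape1, config$gc_shape2)
    width <- pmin(940L, pmax(880L, as.integer(round(rnorm(n, 905, 12)))))
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    start <- as.integer(round(runif(n, 1e5, 1e8)))
    group <- sample(.AMPLICON_GROUPS[1:4], n, replace = TRUE,
                    prob = c(0.42, 0.22, 0.32, 0.04))
    asc_p <- c(GWAS = 0.15, LD = 0.15, FBDHS = 0.9, PutEnh = 0.5)
    ascertained <- rbinom(n, 1, asc_p[group]) == 1
    n_active <- round(config$frac_active * n)
    effect <- rep(1, n)
    if (n_active > 0) {
        active <- sample(n, n_active)
        effect[active] <- rlnorm(n_active, config$effect_meanlog,
                                 config$effect_sdlog)
    }
    catalog <- GRanges(chrom, IRanges(start, width = width))
    mcols(catalog)$amplicon_id <- ids
    mcols(catalog)$group <- group
    mcols(catalog)$gc <- gc
    mcols(catalog)$ascertained_enhancer <- ascertained
    names(catalog) <- ids
    list(catalog = catalog,
         truth = DataFrame(amplicon_id = ids, true_effect = effect))
}

.rcounts <- function(n, mu, dispersion) {
    if (dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate an MPRA count matrix with sample sheet
#'
#' Library and DNA samples draw counts around expected proportions
#' proportional to \code{2^(gc_bias_coeff * gc + a)} with amplicon-specific
#' log2 abundance \code{a}; RNA expected proportions are proportional to the
#' DNA proportion raised to \code{basal_slope} times the amplicon's true
#' enhancer effect. Counts are negative-binomial at the configured
#' dispersion (Poisson at dispersion 0). Amplicons in the lowest
#' DNA-abundance decile drop to zero RNA counts with probability
#' \code{dropout_rate} independently per RNA replicate, emulating
#' replicate-specific cDNA dropout of weakly represented amplicons.
#'
#' @param catalog,truth As produced by [simulateTruth()], aligned on
#'   \code{amplicon_id}.
#' @param config The same [simConfig()] used for the truth.
#' @return An [MpraExperiment-class] with one library sample, the DNA and RNA
#'   biological replicates, and (optionally) one technical RNA replicate
#'   flagged via \code{technical_of}.
#' @examples
#' cfg <- simConfig(n_amplicons = 60, seed = 2)
#' tr <- simulateTruth(cfg)
#' mp <- simulateCounts(tr$catalog, tr$truth, cfg)
#' @export
simulateCounts <- function(catalog, truth, config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (!identical(mcols(catalog)$amplicon_id, truth$amplicon_id))
        stop("catalog and truth must be aligned on amplicon_id")
    set.seed(config$seed + 1L)
    n <- length(catalog)
    gc <- mcols(catalog)$gc
    abund <- rnorm(n, 0, config$abundance_sd)
    log2_rep <- config$gc_bias_coeff * gc + abund
    p_dna <- 2^log2_rep / sum(2^log2_rep)
    w_rna <- p_dna^config$basal_slope * truth$true_effect
    p_rna <- w_rna / sum(w_rna)

    ids <- mcols(catalog)$amplicon_id
    low_decile <- p_dna <= stats::quantile(p_dna, 0.1)
    samples <- data.frame(sample_id = "library", kind = "library",
                          replicate = 1L, technical_of = NA_character_)
    counts <- matrix(.rcounts(n, config$depth_dna * p_dna, config$dispersion),
                     ncol = 1, dimnames = list(ids, "library"))
    for (r in seq_len(config$n_dna_reps)) {
        sid <- paste0("DNA", r)
        counts <- cbind(counts, .rcounts(n, config$depth_dna * p_dna,
                                         config$dispersion))
        colnames(counts)[ncol(counts)] <- sid
        samples <- rbind(samples, data.frame(sample_id = sid, kind = "DNA",
                                             replicate = r,
                                             technical_of = NA_character_))
    }
    rna_draw <- function() {
        cc <- .rcounts(n, config$depth_rna * p_rna, config$dispersion)
        drop <- low_decile & stats::runif(n) < config$dropout_rate
        cc[drop] <- 0L
        cc
    }
    for (r in seq_len(config$n_rna_reps)) {
        sid <- paste0("RNA", r)
        counts <- cbind(counts, rna_draw())
        colnames(counts)[ncol(counts)] <- sid
        samples <- rbind(samples, data.frame(sample_id = sid, kind = "RNA",
                                             replicate = r,
                                             technical_of = NA_character_))
    }
    if (config$include_technical) {
        r <- config$n_rna_reps
        sid <- paste0("RNA", r, "_tech")
        counts <- cbind(counts, rna_draw())
        colnames(counts)[ncol(counts)] <- sid
        samples <- rbind(samples, data.frame(sample_id = sid, kind = "RNA",
                                             replicate = r,
                                             technical_of = paste0("RNA", r)))
    }
    MpraExperiment(counts, catalog, samples)
}

#' One-call synthetic MPRA dataset
#'
#' Convenience wrapper running [simulateTruth()] then [simulateCounts()].
#'
#' @param config A [simConfig()].
#' @return List with \code{mpra} (an [MpraExperiment-class]) and \code{truth}.
#' @export
simulateMpra <- function(config) {
    tr <- simulateTruth(config)
    list(mpra = simulateCounts(tr$catalog, tr$truth, config),
         truth = tr$truth)
}

#' Simulate epigenomic annotation interval sets
#'
#' For each mark, an amplicon overlaps the mark with probability
#' \code{p_active} if its true effect exceeds 1 and \code{p_inactive}
#' otherwise; the annotation interval is placed inside the amplicon's span
#' (central 50%), so interval intersection recovers exactly the simulated
#' overlap flags.
#'
#' @param catalog,truth As produced by [simulateTruth()].
#' @param p_active,p_inactive Overlap probabilities for active / inactive
#'   amplicons (\code{p_active >= p_inactive}).
#' @param marks Character vector of mark names.
#' @param seed Integer seed.
#' @return Named \code{GRangesList}, one element per mark.
#' @export
simulateAnnotations <- function(catalog, truth, p_active = 0.8,
                                p_inactive = 0.2,
                                marks = c("DNase", "H3K4me1"), seed = 1L) {
    stopifnot(p_active >= p_inactive)
    set.seed(seed)
    active <- truth$true_effect > 1
    out <- lapply(marks, function(mk) {
        p <- ifelse(active, p_active, p_inactive)
        hit <- stats::runif(length(catalog)) < p
        gr <- catalog[hit]
        if (!length(gr)) return(GRanges())
        w <- BiocGenerics::width(gr)
        GRanges(GenomicRanges::seqnames(gr),
                IRanges(BiocGenerics::start(gr) + as.integer(w * 0.25),
                        BiocGenerics::end(gr) - as.integer(w * 0.25)))
    })
    names(out) <- marks
    GRangesList(out)
}

#' Simulate biallelic SNP allele counts
#'
#' Places \code{n_snps} biallelic SNPs on random amplicons, draws each SNP's
#' reference-allele frequency from a Beta law, and generates binomial
#' ref/alt counts per sample at the given expected depth. Allele frequencies
#' are shared between DNA and RNA samples (the null of no allelic activity
#' difference).
#'
#' @param catalog A catalog \code{GRanges}.
#' @param sample_ids Character vector of sample ids to generate counts for.
#' @param n_snps Number of SNPs.
#' @param af_shape1,af_shape2 Beta law for the reference allele frequency.
#' @param depth Expected read depth per SNP per sample.
#' @param base_quality Mean base quality reported for every allele
#'   observation.
#' @param seed Integer seed.
#' @return Long-format \code{data.frame} with columns \code{snp_id},
#'   \code{amplicon_id}, \code{chrom}, \code{pos}, \code{sample_id},
#'   \code{base}, \code{is_ref}, \code{count}, \code{mean_base_quality}.
#' @export
simulateAlleles <- function(catalog, sample_ids, n_snps = 50,
                            af_shape1 = 0.5, af_shape2 = 0.5,
                            depth = 500, base_quality = 32, seed = 1L) {
    stopifnot(n_snps >= 0)
    set.seed(seed)
    if (n_snps == 0)
        return(data.frame(snp_id = character(), amplicon_id = character(),
                          chrom = character(), pos = integer(),
                          sample_id = character(), base = character(),
                          is_ref = logical(), count = integer(),
                          mean_base_quality = numeric()))
    idx <- sample(length(catalog), n_snps, replace = TRUE)
    snp_id <- sprintf("snp%04d", seq_len(n_snps))
    pos <- BiocGenerics::start(catalog)[idx] +
        as.integer(BiocGenerics::width(catalog)[idx] * stats::runif(n_snps))
    af <- rbeta(n_snps, af_shape1, af_shape2)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    rows <- list()
    for (i in seq_len(n_snps)) for (s in sample_ids) {
        tot <- stats::rpois(1, depth)
        r <- stats::rbinom(1, tot, af[i])
        rows[[length(rows) + 1L]] <- data.frame(
            snp_id = snp_id[i],
            amplicon_id = mcols(catalog)$amplicon_id[idx[i]],
            chrom = as.character(GenomicRanges::seqnames(catalog))[idx[i]],
            pos = pos[i], sample_id = s,
            base = c(ref[i], alt[i]), is_ref = c(TRUE, FALSE),
            count = c(r, tot - r),
            mean_base_quality = base_quality + round(stats::rnorm(2, 0, 1), 1))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
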