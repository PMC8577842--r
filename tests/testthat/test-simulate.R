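test_that("simulateTruth spikes exactly round(frac_active * n) amplicons", {
    cfg <- simConfig(n_amplicons = 308, frac_active = 0.1, seed = 2)
    tr <- simulateTruth(cfg)
    expect_equal(sum(tr$truth$true_effect > 1), 31L)
    cfg0 <- simConfig(n_amplicons = 100, frac_active = 0, seed = 2)
    expect_true(all(simulateTruth(cfg0)$truth$true_effect == 1))
})

test_that("generators are bit-reproducible under a fixed seed", {
    cfg <- simConfig(n_amplicons = 60, seed = 123)
    a <- simulateMpra(cfg)
    b <- simulateMpra(cfg)
    expect_identical(counts(a$mpra), counts(b$mpra))
    expect_identical(a$truth$true_effect, b$truth$true_effect)
    tr <- simulateTruth(cfg)
    expect_identical(
        simulateAnnotations(tr$catalog, tr$truth, seed = 9),
        simulateAnnotations(tr$catalog, tr$truth, seed = 9))
})

test_that("Poisson no-dropout null gives mean RNA/DNA ratio near 1", {
    cfg <- simConfig(n_amplicons = 400, frac_active = 0, dispersion = 0,
                     dropout_rate = 0, include_technical = FALSE, seed = 5)
    sim <- simulateMpra(cfg)
    prop <- computeProportions(counts(sim$mpra))
    ratio <- rowMeans(prop[, rnaSamples(sim$mpra)]) /
        rowMeans(prop[, dnaSamples(sim$mpra)])
    expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("a 4x spiked amplicon has ~4x the inactive median raw ratio", {
    cfg <- simConfig(n_amplicons = 300, frac_active = 1 / 300,
                     effect_meanlog = log(4), effect_sdlog = 0,
                     dispersion = 0, dropout_rate = 0,
                     depth_dna = 5e6, depth_rna = 5e6,
                     include_technical = FALSE, seed = 8)
    sim <- simulateMpra(cfg)
    prop <- computeProportions(counts(sim$mpra))
    ratio <- rowMeans(prop[, rnaSamples(sim$mpra)]) /
        rowMeans(prop[, dnaSamples(sim$mpra)])
    active <- sim$truth$true_effect > 1
    expect_equal(ratio[active] / median(ratio[!active]), 4,
                 tolerance = 0.15, ignore_attr = TRUE)
})

test_that("annotation overlap rates match their generating probabilities", {
    cfg <- simConfig(n_amplicons = 1000, frac_active = 0.3, seed = 21)
    tr <- simulateTruth(cfg)
    active <- tr$truth$true_effect > 1

    both <- simulateAnnotations(tr$catalog, tr$truth, p_active = 1,
                                p_inactive = 1, marks = "m", seed = 1)
    expect_equal(sum(markOverlap(tr$catalog, both$m)), 1000L)
    none <- simulateAnnotations(tr$catalog, tr$truth, p_active = 0,
                                p_inactive = 0, marks = "m", seed = 1)
    expect_equal(length(none$m), 0L)

    ann <- simulateAnnotations(tr$catalog, tr$truth, p_active = 0.8,
                               p_inactive = 0.2, marks = "m", seed = 3)
    flags <- markOverlap(tr$catalog, ann$m)
    ci_a <- binom.test(sum(flags[active]), sum(active))$conf.int
    ci_i <- binom.test(sum(flags[!active]), sum(!active))$conf.int
    expect_true(ci_a[1] <= 0.8 && 0.8 <= ci_a[2])
    expect_true(ci_i[1] <= 0.2 && 0.2 <= ci_i[2])
    expect_error(
        simulateAnnotations(tr$catalog, tr$truth, p_active = 0.1,
                            p_inactive = 0.5, seed = 1),
        "p_active")
})

test_that("allele counts preserve frequencies between DNA and RNA", {
    cfg <- simConfig(n_amplicons = 50, seed = 6)
    tr <- simulateTruth(cfg)
    sids <- c("DNA1", "DNA2", "RNA1", "RNA2")
    tab <- simulateAlleles(tr$catalog, sids, n_snps = 120, depth = 4000,
                           seed = 13)
    kinds <- setNames(c("DNA", "DNA", "RNA", "RNA"), sids)
    summ <- alleleSummary(filterAlleleCounts(tab), kinds)
    ok <- summ$snps$eligible
    expect_gt(summ$dna_rna_correlation, 0.98)
    expect_equal(summ$snps$ref_af_dna[ok], summ$snps$ref_af_rna[ok],
                 tolerance = 0.1)
    # af extremes behave as constructed
    expect_true(all(tab$count >= 0))
    expect_equal(nrow(simulateAlleles(tr$catalog, sids, n_snps = 0)), 0L)
})

test_that("simulateCounts rejects misaligned catalog and truth", {
    cfg <- simConfig(n_amplicons = 20, seed = 1)
    tr <- simulateTruth(cfg)
    shuffled <- tr$truth[rev(seq_len(nrow(tr$truth))), ]
    expect_error(simulateCounts(tr$catalog, shuffled, cfg), "aligned")
})
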