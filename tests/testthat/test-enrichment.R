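test_that("mergeIntervals unions overlapping and book-ended intervals", {
    m <- mergeIntervals(data.frame(chrom = "chr1", start = c(1, 4),
                                   end = c(5, 8)))
    expect_equal(BiocGenerics::start(m) - 1L, 1L)
    expect_equal(BiocGenerics::end(m), 8L)
    b <- mergeIntervals(data.frame(chrom = "chr1", start = c(1, 5),
                                   end = c(5, 8)))
    expect_equal(length(b), 1L)        # book-ended merge
    expect_equal(BiocGenerics::end(b), 8L)
    d <- mergeIntervals(data.frame(chrom = "chr1", start = c(1, 10),
                                   end = c(5, 15)))
    expect_equal(length(d), 2L)        # disjoint unchanged
    expect_identical(mergeIntervals(d), d)  # idempotent
    expect_error(mergeIntervals(data.frame(chrom = "chr1", start = 5,
                                           end = 5)), "end > start")
})

test_that("markOverlap uses >=1 shared base with half-open inputs", {
    amp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
    S4Vectors::mcols(amp)$amplicon_id <- "a1"   # [100, 200) 0-based
    inside <- mergeIntervals(data.frame(chrom = "chr1", start = 150,
                                        end = 160))
    expect_true(unname(markOverlap(amp, inside)))
    adjacent <- mergeIntervals(data.frame(chrom = "chr1", start = 0,
                                          end = 100))
    expect_false(unname(markOverlap(amp, adjacent)))
    expect_false(unname(markOverlap(amp, GenomicRanges::GRanges())))
    other_chrom <- mergeIntervals(data.frame(chrom = "chr2", start = 150,
                                             end = 160))
    expect_false(unname(markOverlap(amp, other_chrom)))
})

test_that("permutation enrichment agrees with the hypergeometric tail", {
    # all small backgrounds: sizes 4..12, all overlap counts and set sizes
    set.seed(1)
    n_perm <- 4000
    for (nb in c(4, 8, 12)) {
        ids <- sprintf("b%02d", seq_len(nb))
        for (n_ov in c(1, nb %/% 2, nb - 1)) {
            flags <- setNames(seq_len(nb) <= n_ov, ids)
            for (k in c(2, nb %/% 2)) {
                sig <- ids[seq_len(k)]
                res <- permutationEnrichment(sig, ids, flags,
                                             n_perm = n_perm, seed = 7)
                obs <- sum(flags[sig])
                exact <- phyper(obs - 1, n_ov, nb - n_ov, k,
                                lower.tail = FALSE)
                mc_se <- sqrt(exact * (1 - exact) / n_perm)
                expect_lt(abs(res$perm_p - exact), 3 * mc_se + 2 / n_perm)
            }
        }
    }
})

test_that("permutation p is deterministic, never zero, and 1 when trivial", {
    ids <- sprintf("b%02d", 1:4)
    all_flags <- setNames(rep(TRUE, 4), ids)
    res <- permutationEnrichment(ids[1:2], ids, all_flags, n_perm = 500,
                                 seed = 3)
    expect_equal(res$perm_p, 1)
    half <- setNames(c(TRUE, TRUE, FALSE, FALSE), ids)
    a <- permutationEnrichment(ids[1:2], ids, half, n_perm = 2000, seed = 5)
    b <- permutationEnrichment(ids[1:2], ids, half, n_perm = 2000, seed = 5)
    expect_identical(a$perm_p, b$perm_p)
    expect_gt(a$perm_p, 0)
    # hypergeometric oracle: P(X = 2) drawing 2 of 4 with 2 overlapping = 1/6
    expect_equal(a$perm_p, 1 / 6, tolerance = 3 * sqrt(1/6 * 5/6 / 2000))
    expect_error(permutationEnrichment(c("z9"), ids, half), "subset")
})

test_that("GLM covariate comparison penalizes null marks, rewards real ones", {
    set.seed(12)
    wins <- 0L
    for (i in 1:100) {
        n <- 120
        dna <- rnorm(n, -8); gc <- runif(n)
        rna <- 0.9 * dna + 0.5 * gc + rnorm(n, 0, 0.3)
        flag <- runif(n) < 0.4   # independent of residuals
        res <- glmCovariateBic(rna, dna, gc, flag)
        wins <- wins + (res$bic_with > res$bic_without)
    }
    expect_gte(wins / 100, 0.9)   # BIC penalty dominates under the null

    n <- 200
    dna <- rnorm(n, -8); gc <- runif(n)
    noise <- rnorm(n, 0, 0.3)
    rna <- 0.9 * dna + 0.5 * gc + noise
    informative <- noise > 0      # flag carries real residual signal
    res <- glmCovariateBic(rna, dna, gc, informative)
    expect_lt(res$bic_with, res$bic_without)
    expect_lt(res$t_p, 1e-6)
    expect_error(glmCovariateBic(rna, dna, gc, rep(TRUE, n)), "constant")
})

test_that("point-biserial equals Pearson on the 0/1 encoding", {
    expect_equal(pointBiserial(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)),
                 2 / sqrt(5), tolerance = 1e-12)   # ~0.894
    z <- rnorm(50)
    flag <- rep(c(TRUE, FALSE), 25)
    expect_equal(pointBiserial(z, flag), -pointBiserial(z, !flag))
    expect_error(pointBiserial(z, rep(TRUE, 50)), "both classes")
})

test_that("enrichmentAnalysis detects simulated mark preference for actives", {
    sim <- simulateMpra(simConfig(seed = 23))
    tr_truth <- sim$truth
    catalog <- ampliconCatalog(sim$mpra)
    marks <- simulateAnnotations(catalog, tr_truth, p_active = 0.9,
                                 p_inactive = 0.15,
                                 marks = c("DNase", "ctrl"), seed = 2)
    # make the control mark independent of activity
    marks$ctrl <- simulateAnnotations(catalog,
        S4Vectors::DataFrame(amplicon_id = tr_truth$amplicon_id,
                             true_effect = rep(1, nrow(tr_truth))),
        p_active = 0.4, p_inactive = 0.4, marks = "ctrl", seed = 3)$ctrl
    act <- callActivity(filterAmplicons(sim$mpra))
    enr <- enrichmentAnalysis(act, catalog, marks, n_perm = 3000, seed = 11)
    expect_lt(enr$perm_p[enr$mark == "DNase"], 0.05)
    expect_gt(enr$perm_p[enr$mark == "ctrl"], 0.05)
    expect_lt(enr$bic_with[enr$mark == "DNase"],
              enr$bic_without[enr$mark == "DNase"])
    expect_gt(enr$point_biserial[enr$mark == "DNase"], 0)
})
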