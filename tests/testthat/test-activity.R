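test_that("ratiometric summary applies the mean/sd call rule", {
    # RNA identical to DNA in every replicate -> ratio 1, sd 0, no call
    cnt <- matrix(rep(c(100, 200, 300, 400), 8), nrow = 4,
                  dimnames = list(paste0("a", 1:4),
                                  c(paste0("DNA", 1:4), paste0("RNA", 1:4))))
    rs <- ratiometricSummary(makeToyMpra(cnt))
    expect_equal(rs$summary$ratio_mean, rep(1, 4))
    expect_equal(rs$summary$ratio_sd, rep(0, 4))
    expect_false(any(rs$summary$ratiometric_call))
    # call boundary: mean > 1.5 with sd < mean
    expect_true((1.6 > 1.5) && (0 < 1.6))      # ratios [1.6 x4] -> call
    expect_false(1.7 < 1.6)                    # sd >= mean -> no call
})

test_that("ratiometric call requires sd below mean", {
    set.seed(2)
    cnt <- matrix(rpois(80, 500), nrow = 10,
                  dimnames = list(sprintf("a%02d", 1:10),
                                  c(paste0("DNA", 1:4), paste0("RNA", 1:4))))
    rs <- ratiometricSummary(makeToyMpra(cnt))
    s <- rs$summary
    expect_identical(s$ratiometric_call,
                     s$ratio_mean > 1.5 & s$ratio_sd < s$ratio_mean)
})

test_that("training-set trimming uses the floor rule", {
    x10 <- setNames(rnorm(10), sprintf("a%02d", 1:10))
    expect_length(selectTrainingSet(x10), 8L)
    x308 <- setNames(rnorm(308), sprintf("a%03d", 1:308))
    expect_length(selectTrainingSet(x308), 248L)
    expect_setequal(selectTrainingSet(x10, trim_fraction = 0), names(x10))
    # deterministic tie-break by amplicon id
    ties <- setNames(rep(1, 20), sprintf("a%02d", 20:1))
    expect_identical(selectTrainingSet(ties), selectTrainingSet(ties))
    expect_error(selectTrainingSet(setNames(1:5, letters[1:5])), "10")
})

test_that("background model recovers noiseless coefficients exactly", {
    ids <- sprintf("a%02d", 1:40)
    set.seed(7)
    dna <- setNames(rnorm(40, -8, 1), ids)
    gc <- setNames(runif(40, 0.3, 0.7), ids)
    rna <- setNames(0.1 + 0.9 * dna + 0.5 * gc, ids)
    fit <- fitBackgroundModel(rna, dna, gc)
    expect_equal(fit@coefficients[["intercept"]], 0.1, tolerance = 1e-10)
    expect_equal(fit@coefficients[["slope_dna"]], 0.9, tolerance = 1e-10)
    expect_equal(fit@coefficients[["coeff_gc"]], 0.5, tolerance = 1e-10)
    expect_error(fitBackgroundModel(rna, dna, setNames(rep(0.5, 40), ids)),
                 "degenerate")
})

test_that("background model slope matches the generating basal slope", {
    cfg <- simConfig(n_amplicons = 2000, frac_active = 0,
                     depth_dna = 4e6, depth_rna = 4e6, seed = 19)
    filt <- filterAmplicons(simulateMpra(cfg)$mpra)
    act <- callActivity(filt)
    fit <- S4Vectors::metadata(act)$backgroundFit
    expect_equal(fit@coefficients[["slope_dna"]], cfg$basal_slope,
                 tolerance = 0.05)
    # with RNA GC bias inherited only through DNA, the GC partial effect
    # in the background model is near zero
    expect_lt(abs(fit@coefficients[["coeff_gc"]]),
              0.2 * cfg$gc_bias_coeff)
})

test_that("scoreActivity maps Z-scores to upper-tail normal p-values", {
    ids <- sprintf("a%02d", 1:30)
    set.seed(1)
    dna <- setNames(rnorm(30, -8), ids)
    gc <- setNames(runif(30), ids)
    rna <- setNames(0.9 * dna + 0.5 * gc + rnorm(30, 0, 0.2), ids)
    fit <- fitBackgroundModel(rna, dna, gc)
    sc <- scoreActivity(fit, rna, dna, gc)
    expect_equal(mean(sc$z), 0, tolerance = 1e-12)
    expect_equal(sd(sc$z), 1, tolerance = 1e-12)
    expect_equal(sc$p_model, pnorm(sc$z, lower.tail = FALSE))
    # reference points of the z -> p mapping
    expect_equal(pnorm(0, lower.tail = FALSE), 0.5)
    expect_equal(pnorm(1.645, lower.tail = FALSE), 0.05, tolerance = 1e-3)
    expect_equal(pnorm(-1, lower.tail = FALSE), 0.8413, tolerance = 1e-4)
})

test_that("empirical FDR matches the tail-area estimator and is monotone", {
    v <- qnorm(stats::ppoints(100))
    v <- v / sqrt(mean(v[v <= 0]^2))  # placeholders with exact sigma-hat = 1
    z <- c(v, 3.0)
    q <- empiricalFdr(z)
    expect_equal(sqrt(mean(z[z <= 0]^2)), 1, tolerance = 1e-12)
    expect_equal(q[101], 101 * pnorm(3, lower.tail = FALSE),
                 tolerance = 1e-8)   # ~0.136
    expect_true(all(q >= 0 & q <= 1))
    ord <- order(z)
    expect_true(all(diff(q[ord]) <= 1e-12))
    expect_error(empiricalFdr(rnorm(10)), "20")
})

test_that("exact Wilcoxon equals the enumeration oracle up to n = 10", {
    expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4))$p, 1 / 6)
    expect_equal(wilcoxonRankSum(1:4, 5:8)$p, 1 / 70)
    set.seed(55)
    for (i in 1:30) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        dna <- round(rnorm(n1), 1)   # rounding induces occasional ties
        rna <- round(rnorm(n2), 1)
        expect_equal(wilcoxonRankSum(dna, rna)$p, enumWilcoxonP(dna, rna))
    }
    # no evidence for greater when RNA == DNA
    expect_gte(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 0.5)
})

test_that("BH adjustment follows the step-up formula, order-invariant", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(9)
    p <- runif(50)
    perm <- sample(50)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("one-way ANOVA matches its closed form and invariances", {
    res <- anovaGroups(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
    expect_equal(res$F, 8)
    expect_equal(res$p, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-10)
    flat <- anovaGroups(c(1, 2, 1, 2), c("g1", "g1", "g2", "g2"))
    expect_equal(flat$F, 0)
    expect_equal(flat$p, 1)
    shifted <- anovaGroups(c(1, 2, 3, 4) + 100, c("g1", "g1", "g2", "g2"))
    expect_equal(shifted$F, 8)
    expect_error(anovaGroups(1:3, c("a", "a", "b")), "2 members")
})

test_that("Fisher 2x2 reports the sample odds ratio and hypergeometric p", {
    res <- fisher2x2(1, 1, 1, 1)
    expect_equal(res$odds_ratio, 1)
    expect_equal(res$p, 5 / 6)
    expect_equal(fisher2x2(5, 0, 2, 7)$odds_ratio, Inf)
    expect_true(fisher2x2(5, 0, 2, 7)$p <= 1)
    expect_error(fisher2x2(0, 0, 0, 0), "margin")
})

test_that("amplicons with identical counts receive identical scores", {
    set.seed(40)
    cnt <- matrix(rpois(30 * 9, 800), nrow = 30,
                  dimnames = list(sprintf("a%02d", 1:30),
                                  c("library", paste0("DNA", 1:4),
                                    paste0("RNA", 1:4))))
    cnt["a10", ] <- cnt["a20", ]   # duplicate rows
    gc <- seq(0.3, 0.7, length.out = 30)
    gc[10] <- gc[20]
    mp <- makeToyMpra(cnt, gc = gc)
    act <- callActivity(mp)
    for (col in c("ratio_mean", "residual", "z", "p_model", "q_model",
                  "p_wilcoxon"))
        expect_equal(act["a10", col], act["a20", col], ignore_attr = TRUE)
})

test_that("model and ratiometric rankings agree in the top decile on spikes", {
    sim <- simulateMpra(simConfig(seed = 77))
    act <- callActivity(filterAmplicons(sim$mpra))
    k <- floor(nrow(act) / 10)
    top_z <- act$amplicon_id[order(-act$z)][1:k]
    top_ratio <- act$amplicon_id[order(-log2(act$ratio_mean))][1:k]
    expect_gte(length(intersect(top_z, top_ratio)) / k, 0.9)
})
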