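#' Ratiometric RNA/DNA activity summary
#'
#' Computes per-replicate RNA/DNA proportion ratios after adding a count
#' stabilizer to raw counts (default 1000) to damp ratio noise where counts
#' are low, then summarizes each amplicon by the mean and sample standard
#' deviation of its replicate ratios. An amplicon is called ratiometrically
#' active when its mean ratio exceeds \code{ratio_threshold} and the
#' standard deviation is smaller than the mean. DNA and RNA replicates are
#' paired by replicate id; technical replicates are excluded.
#'
#' @param x An [MpraExperiment-class].
#' @param stabilizer Counts added to RNA and DNA counts before proportion
#'   conversion (default 1000).
#' @param ratio_threshold Mean-ratio call threshold (default 1.5).
#' @return List with \code{ratios} (amplicon x replicate matrix) and
#'   \code{summary} (\code{DataFrame} with \code{amplicon_id},
#'   \code{ratio_mean}, \code{ratio_sd}, \code{ratiometric_call}).
#' @examples
#' sim <- simulateMpra(simConfig(n_amplicons = 50, seed = 1))
#' rs <- ratiometricSummary(sim$mpra)
#' head(rs$summary)
#' @export
ratiometricSummary <- function(x, stabilizer = 1000, ratio_threshold = 1.5) {
    dna <- dnaSamples(x)
    rna <- rnaSamples(x)
    cd <- colData(x)
    reps <- intersect(cd[dna, "replicate"], cd[rna, "replicate"])
    if (!length(reps)) stop("no paired DNA/RNA replicates")
    prop <- computeProportions(counts(x) + stabilizer)
    ratios <- vapply(reps, function(r) {
        d <- dna[cd[dna, "replicate"] == r][1]
        s <- rna[cd[rna, "replicate"] == r][1]
        prop[, s] / prop[, d]
    }, numeric(nrow(x)))
    if (is.null(dim(ratios)))
        ratios <- matrix(ratios, nrow = nrow(x))
    dimnames(ratios) <- list(ampliconIds(x), paste0("rep", reps))
    m <- rowMeans(ratios)
    s <- apply(ratios, 1, sd)
    list(ratios = ratios,
         summary = DataFrame(amplicon_id = ampliconIds(x),
                             ratio_mean = unname(m), ratio_sd = unname(s),
                             ratiometric_call = unname(m > ratio_threshold &
                                                       s < m)))
}

#' Select the trimmed background-model training set
#'
#' Ranks amplicons by mean ratiometric activity and removes
#' \code{floor(trim_fraction * n)} amplicons from each extreme, so the
#' middle of the activity distribution trains the background model (with the
#' default 10% trim, 308 amplicons leave 248). Ties are broken by amplicon
#' id for determinism.
#'
#' @param ratio_mean Named numeric vector of mean ratiometric activity,
#'   names being amplicon ids.
#' @param trim_fraction Fraction trimmed from each extreme (default 0.10).
#' @return Character vector of retained amplicon ids.
#' @examples
#' length(selectTrainingSet(setNames(rnorm(308), sprintf("a%03d", 1:308))))
#' @export
selectTrainingSet <- function(ratio_mean, trim_fraction = 0.10) {
    n <- length(ratio_mean)
    if (n < 10) stop("need at least 10 amplicons")
    ids <- names(ratio_mean)
    ord <- order(ratio_mean, ids)
    k <- floor(trim_fraction * n)
    keep <- if (k > 0) ord[(k + 1):(n - k)] else ord
    sort(ids[keep])
}

#' Fit the GC-aware background regression model
#'
#' Ordinary least squares of log2 mean RNA proportion on log2 mean DNA
#' proportion with amplicon GC fraction as a covariate, fitted over the
#' trimmed training set. The model absorbs basal transcription from the
#' minimal promoter (DNA representation term) and residual GC bias, so its
#' residuals measure enhancer activity above background. Residual normality
#' is checked with a Kolmogorov-Smirnov test on standardized residuals.
#'
#' @param log2_rna,log2_dna,gc Numeric vectors over all amplicons, named by
#'   amplicon id.
#' @param training_ids Amplicon ids used for fitting (default: all).
#' @return A [BackgroundModelFit-class].
#' @examples
#' ids <- sprintf("a%02d", 1:30)
#' dna <- setNames(rnorm(30, -8), ids); gc <- setNames(runif(30), ids)
#' rna <- setNames(0.1 + 0.9 * dna + 0.5 * gc, ids)
#' fitBackgroundModel(rna, dna, gc)
#' @importFrom stats lm coef residuals ks.test
#' @export
fitBackgroundModel <- function(log2_rna, log2_dna, gc,
                               training_ids = names(log2_rna)) {
    stopifnot(!is.null(names(log2_rna)),
              length(log2_rna) == length(log2_dna),
              length(log2_rna) == length(gc))
    tr <- match(training_ids, names(log2_rna))
    if (anyNA(tr)) stop("training_ids must be a subset of the scored ids")
    df <- data.frame(y = log2_rna[tr], dna = log2_dna[tr], gc = gc[tr])
    if (sd(df$dna) == 0 || sd(df$gc) == 0)
        stop("degenerate design: constant DNA proportion or GC in training set")
    fit <- lm(y ~ dna + gc, data = df)
    if (anyNA(coef(fit)))
        stop("degenerate design: collinear predictors")
    res <- residuals(fit)
    ks <- suppressWarnings(ks.test(res / sd(res), "pnorm"))
    new("BackgroundModelFit",
        coefficients = c(intercept = unname(coef(fit)[1]),
                         slope_dna = unname(coef(fit)["dna"]),
                         coeff_gc = unname(coef(fit)["gc"])),
        residualSd = suppressWarnings(summary(fit)$sigma),
        trainingIds = as.character(training_ids),
        ksStatistic = unname(ks$statistic), ksP = ks$p.value,
        model = fit)
}

#' Score activity of all amplicons against the background model
#'
#' Applies the background model to every retained amplicon: the residual is
#' observed minus predicted log2 RNA proportion; residuals are Z-scaled
#' using the mean and standard deviation over all scored amplicons; the
#' one-tailed p-value is the upper-tail standard-normal probability of the
#' Z-score (increased RNA only; amplicons with lower-than-expected RNA are
#' reported but never called active).
#'
#' @param fit A [BackgroundModelFit-class].
#' @param log2_rna,log2_dna,gc Numeric vectors over the amplicons to score,
#'   named by amplicon id.
#' @return \code{DataFrame} with \code{amplicon_id}, \code{residual},
#'   \code{z}, \code{p_model}.
#' @importFrom stats pnorm predict
#' @export
scoreActivity <- function(fit, log2_rna, log2_dna, gc) {
    pred <- predict(fit@model,
                    newdata = data.frame(dna = log2_dna, gc = gc))
    res <- log2_rna - pred
    z <- (res - mean(res)) / sd(res)
    DataFrame(amplicon_id = names(log2_rna), residual = unname(res),
              z = unname(z), p_model = unname(pnorm(z, lower.tail = FALSE)))
}

#' Empirical tail-area FDR q-values from Z-scores
#'
#' Estimates one-tailed tail-area FDR q-values from the observed Z-score
#' distribution against an empirical null fitted to the non-positive
#' Z-scores by mirroring: the null is a centered normal with half-normal
#' scale estimate \eqn{\hat\sigma = \sqrt{\mathrm{mean}(z_{\le 0}^2)}}. The
#' raw estimate at threshold \eqn{z_i} is
#' \eqn{\hat\pi_0 \, n \, S_0(z_i) / \#\{z_j \ge z_i\}} capped at 1, with
#' monotonicity enforced so q never increases with z (each amplicon receives
#' the minimum raw estimate over all looser thresholds).
#'
#' @param z Numeric vector of Z-scores (length >= 20).
#' @param pi0 Null proportion estimate (default 1, conservative).
#' @return Numeric vector of q-values in the input order.
#' @importFrom stats pnorm
#' @export
empiricalFdr <- function(z, pi0 = 1) {
    n <- length(z)
    if (n < 20) stop("need at least 20 z-scores")
    znp <- z[z <= 0]
    sigma <- if (length(znp) >= 5) sqrt(mean(znp^2)) else sd(z)
    s_null <- pnorm(z / sigma, lower.tail = FALSE)
    n_ge <- vapply(z, function(zi) sum(z >= zi), numeric(1))
    raw <- pmin(1, pi0 * n * s_null / n_ge)
    ord <- order(z)
    q <- numeric(n)
    q[ord] <- cummin(raw[ord])
    q
}

#' One-tailed Wilcoxon rank-sum test for increased RNA
#'
#' Rank-sum test of RNA proportion values against DNA proportion values
#' across replicates, one-tailed for increased RNA. For combined sample size
#' up to \code{exact_max} the null is enumerated exactly over all rank
#' assignments (midranks for ties); otherwise the normal approximation with
#' continuity and tie correction is used. Also reports whether the one-sided
#' location-shift confidence bound exceeds zero.
#'
#' @param dna_props,rna_props Numeric vectors (each length >= 2).
#' @param exact_max Largest combined n for exact enumeration (default 12).
#' @return List with \code{p}, \code{statistic} (RNA rank sum) and
#'   \code{shift_gt_zero}.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3, 4), c(5, 6, 7, 8))  # p = 1/70
#' @importFrom stats wilcox.test
#' @importFrom utils combn
#' @export
wilcoxonRankSum <- function(dna_props, rna_props, exact_max = 12) {
    n1 <- length(dna_props); n2 <- length(rna_props)
    if (n1 < 2 || n2 < 2) stop("need >= 2 values per group")
    pooled <- c(dna_props, rna_props)
    rk <- rank(pooled)  # midranks for ties
    w_obs <- sum(rk[(n1 + 1):(n1 + n2)])
    n <- n1 + n2
    if (n <= exact_max) {
        sets <- combn(n, n2)
        w_null <- colSums(matrix(rk[sets], nrow = n2))
        p <- mean(w_null >= w_obs - 1e-9)
    } else {
        mu <- n2 * (n + 1) / 2
        ties <- table(rk)
        sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        p <- pnorm((w_obs - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
    }
    ci <- suppressWarnings(
        wilcox.test(rna_props, dna_props, alternative = "greater",
                    conf.int = TRUE, exact = FALSE)$conf.int)
    list(p = p, statistic = w_obs, shift_gt_zero = unname(ci[1] > 0))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, capped at 1; invariant to input order.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted q-values.
#' @importFrom stats p.adjust
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' One-way ANOVA of activity across amplicon groups
#'
#' @param values Numeric vector of per-amplicon activity summaries.
#' @param groups Group labels (>= 2 groups with >= 2 members each).
#' @return List with \code{F} and \code{p}.
#' @examples
#' anovaGroups(c(1, 2, 3, 4), c("a", "a", "b", "b"))
#' @importFrom stats aov
#' @export
anovaGroups <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2 || any(table(groups) < 2))
        stop("need >= 2 groups with >= 2 members each")
    tab <- summary(aov(values ~ groups))[[1]]
    f <- tab["groups", "F value"]
    p <- tab["groups", "Pr(>F)"]
    if (f == 0) p <- 1
    list(F = f, p = p)
}

#' One-tailed Fisher's exact test for a 2x2 table
#'
#' Reports the sample odds ratio \eqn{ad/bc} (infinite when \eqn{bc = 0})
#' and the one-tailed hypergeometric enrichment p-value for the table
#' \code{rbind(c(a, b), c(c, d))}.
#'
#' @param a,b,c,d Non-negative integer cell counts: \code{a}/\code{b}
#'   successes/failures in the first class, \code{c}/\code{d} in the second.
#' @return List with \code{odds_ratio} and \code{p}.
#' @examples
#' fisher2x2(20, 106, 21, 161)  # OR ~ 1.45, p ~ 0.176
#' @importFrom stats fisher.test
#' @export
fisher2x2 <- function(a, b, c, d) {
    if (a + b + c + d == 0) stop("at least one margin must be non-zero")
    or <- if (b * c == 0) {
        if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c)
    p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    list(odds_ratio = or, p = p)
}

#' Call enhancer activity with both models
#'
#' Runs the full activity workflow on a filtered [MpraExperiment-class]:
#' mean DNA/RNA proportions across biological replicates (technical
#' replicates excluded), the stabilized ratiometric summary and call, the
#' trimmed training set, the GC-aware background regression, Z-residual
#' one-tailed p-values with empirical tail-area FDR q-values, and the
#' per-amplicon Wilcoxon rank-sum test of RNA versus DNA proportions with
#' Benjamini-Hochberg correction.
#'
#' @param x A filtered [MpraExperiment-class] with >= 1 DNA and >= 1 RNA
#'   biological replicate.
#' @param stabilizer Ratio stabilizer added to counts (default 1000).
#' @param trim_fraction Training-set trim per extreme (default 0.10).
#' @param ratio_threshold Ratiometric call threshold (default 1.5).
#' @return \code{DataFrame} (one row per amplicon) with columns
#'   \code{amplicon_id}, \code{group}, \code{gc}, \code{mean_dna_prop},
#'   \code{mean_rna_prop}, \code{ratio_mean}, \code{ratio_sd},
#'   \code{ratiometric_call}, \code{in_training}, \code{residual}, \code{z},
#'   \code{p_model}, \code{q_model}, \code{p_wilcoxon}, \code{q_bh}. The
#'   [BackgroundModelFit-class] is attached as
#'   \code{metadata(result)$backgroundFit}.
#' @examples
#' sim <- simulateMpra(simConfig(n_amplicons = 120, seed = 5))
#' act <- callActivity(filterAmplicons(sim$mpra))
#' head(act)
#' @export
callActivity <- function(x, stabilizer = 1000, trim_fraction = 0.10,
                         ratio_threshold = 1.5) {
    dna <- dnaSamples(x); rna <- rnaSamples(x)
    if (!length(dna) || !length(rna))
        stop("need at least one DNA and one RNA biological replicate")
    prop <- computeProportions(counts(x))
    mean_dna <- rowMeans(prop[, dna, drop = FALSE])
    mean_rna <- rowMeans(prop[, rna, drop = FALSE])
    rs <- ratiometricSummary(x, stabilizer = stabilizer,
                             ratio_threshold = ratio_threshold)
    ratio_mean <- setNames(rs$summary$ratio_mean, rs$summary$amplicon_id)
    training <- selectTrainingSet(ratio_mean, trim_fraction = trim_fraction)
    gc <- setNames(mcols(rowRanges(x))$gc, ampliconIds(x))
    log2_rna <- setNames(log2(mean_rna), ampliconIds(x))
    log2_dna <- setNames(log2(mean_dna), ampliconIds(x))
    fit <- fitBackgroundModel(log2_rna, log2_dna, gc, training_ids = training)
    sc <- scoreActivity(fit, log2_rna, log2_dna, gc)
    q_model <- empiricalFdr(sc$z)
    wil <- lapply(seq_len(nrow(x)), function(i)
        wilcoxonRankSum(prop[i, dna], prop[i, rna]))
    p_w <- vapply(wil, `[[`, numeric(1), "p")
    out <- DataFrame(amplicon_id = ampliconIds(x),
                     group = mcols(rowRanges(x))$group,
                     gc = unname(gc),
                     mean_dna_prop = unname(mean_dna),
                     mean_rna_prop = unname(mean_rna),
                     ratio_mean = unname(ratio_mean),
                     ratio_sd = rs$summary$ratio_sd,
                     ratiometric_call = rs$summary$ratiometric_call,
                     in_training = ampliconIds(x) %in% training,
                     residual = sc$residual, z = sc$z,
                     p_model = sc$p_model, q_model = q_model,
                     p_wilcoxon = p_w, q_bh = bhAdjust(p_w))
    rownames(out) <- out$amplicon_id
    metadata(out)$backgroundFit <- fit
    metadata(out)$parameters <- list(stabilizer = stabilizer,
                                     trim_fraction = trim_fraction,
                                     ratio_threshold = ratio_threshold)
    out
}
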