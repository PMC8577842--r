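---
title: "Calling enhancer activity in AAV STARR-seq amplicon MPRAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling enhancer activity in AAV STARR-seq amplicon MPRAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starrcall)
```

## The assay and the statistical problem

In a STARR-seq-oriented MPRA the candidate sequence is cloned into the
3'-UTR of a reporter driven by a minimal promoter, so any sequence with
enhancer activity increases transcription of the transcript that contains
it. Delivered to tissue by AAV, the experiment yields, per amplicon
(~900 bp candidate), raw de-duplicated read counts in three kinds of
samples: the previral plasmid **library**, the recovered viral **DNA** from
each injected animal (delivery control), and the reporter **RNA** (cDNA)
from the same tissue. Activity is RNA output in excess of what the
amplicon's DNA representation predicts.

Three nuisance effects dominate such data and drive the package's design:

* **Representation spread.** Batch cloning and PCR leave amplicons
  represented over orders of magnitude, correlated with GC content.
* **Basal transcription.** The minimal promoter transcribes every
  construct at a low level proportional to its DNA abundance, so raw RNA
  counts alone do not indicate enhancer activity.
* **Replicate-specific dropout.** Weakly represented amplicons can fail to
  be recovered in the cDNA of individual animals.

`starrcall` stores the data in an `MpraExperiment`
(a `RangedSummarizedExperiment`: counts assay, catalog `GRanges` as row
ranges, sample sheet as column data) and implements two complementary
activity models plus their downstream statistics.

## Normalization and inclusion filters

Counts become proportions with a single pseudocount added to both the
numerator and the per-sample total,
\(p_{is} = (c_{is} + 1) / (\sum_j c_{js} + 1)\). The pseudocount is applied
exactly once, to the sample total in the denominator; proportions then need
not sum exactly to 1, but zero counts never divide by zero and within-sample
rank order is preserved.

`filterAmplicons()` removes an amplicon when **either** its minimum raw
count across DNA samples is below 200 **or** its mean proportion across DNA
samples is below \(2^{-15}\). The two thresholds are deliberately applied
as independent removal rules, and the exclusion log records which rule
fired, so the alternative reading (a single conjunctive filter) can be
audited on any dataset. The mean-proportion rule is evaluated on the DNA
replicate samples; the previral library sample participates only in QC
correlations (`qcCorrelations()`), never in filtering or activity
estimation. Technical replicates (flagged by `technical_of` in the sample
sheet, e.g. a high-PCR-cycle re-preparation of one RNA sample) are excluded
from every summary.

## The ratiometric model

Per replicate pair (DNA and RNA from the same animal), the activity ratio
is \(p^{RNA}/p^{DNA}\) computed after adding a stabilizer of 1000 counts to
every raw count. The stabilizer is added *before* proportion conversion:
this shrinks low-count ratios toward the library-average ratio while
leaving well-covered amplicons essentially unchanged. An amplicon is called
ratiometrically active when its mean replicate ratio exceeds 1.5 and the
sample standard deviation of the ratios is smaller than the mean — a
consistency requirement that rejects amplicons whose apparent activity is
driven by a single replicate.

## The background regression model

The training set is the middle 80% of amplicons ranked by mean stabilized
ratiometric activity: `selectTrainingSet()` removes
\(\lfloor 0.10\,n \rfloor\) amplicons from each extreme (ties broken by
amplicon id), so 308 amplicons leave 248. Trimming both tails keeps
presumed enhancers and dropout-affected amplicons out of the background
fit. We use the floor rule on each extreme; with 308 inputs this retains
248, which we adopt as the canonical behavior of the trimming step.

`fitBackgroundModel()` fits, by ordinary least squares over the training
set,
\[
\log_2 \bar p^{RNA} = \beta_0 + \beta_1 \log_2 \bar p^{DNA} + \beta_2\,GC
+ \varepsilon ,
\]
where \(\bar p\) are mean proportions over biological replicates and GC is
the amplicon's GC fraction. \(\beta_1\) captures basal transcription
(near 1 when RNA tracks DNA proportionally); \(\beta_2\) absorbs residual
GC bias not already expressed through DNA representation. Residual
normality is checked with a Kolmogorov-Smirnov test on standardized
residuals (`@ksStatistic`, `@ksP` on the returned `BackgroundModelFit`).

`scoreActivity()` applies the model to **all** retained amplicons.
Residuals are Z-scaled using the mean and SD of the full scored set — not
the training set — because p-values are defined on the distribution of
residuals after applying the model to everything; one-tailed p-values are
upper normal tail probabilities of Z. Only the high tail is interpreted:
amplicons with lower-than-expected RNA may reflect 3'-UTR-mediated
transcript degradation rather than silencing, so they are reported but
never called.

### Empirical tail-area FDR

`empiricalFdr()` converts Z-scores to q-values with a tail-area estimator:
\[
q(z_i) = \min\!\Big(1,\; \hat\pi_0\, n\, S_0(z_i)\,/\,\#\{j : z_j \ge z_i\}\Big),
\]
where the null upper tail \(S_0\) is a centered normal whose scale is the
half-normal estimate from the non-positive Z-scores
(\(\hat\sigma = \sqrt{\mathrm{mean}(z_{\le 0}^2)}\), i.e. the empirical
null fitted by mirroring the left half of the distribution), and
\(\hat\pi_0 = 1\) by default (conservative). Monotonicity is enforced
BH-style: each amplicon receives the minimum raw estimate over all looser
thresholds, so q never increases with z. This estimator is a deliberate,
documented simplification of general empirical-null tail-area FDR
machinery; it does not claim numerical equality with any particular
implementation of that idea, and its FDR control is verified on simulated
nulls and spike-ins in the test suite. Fewer than five non-positive
Z-scores trigger a fallback to the overall SD.

### Rank-sum testing and group structure

`wilcoxonRankSum()` compares DNA vs RNA proportion values across
replicates, one-tailed for increased RNA. We use the *rank-sum* (pooled)
form rather than a paired signed-rank test: with four replicates a paired
test has almost no resolution, and pooling matches the way proportions are
summarized elsewhere in the workflow. For combined \(n \le 12\) the null is
enumerated exactly over all \(\binom{n}{n_2}\) assignments using midranks,
so ties are handled without approximation; larger inputs use the normal
approximation with continuity and tie corrections. BH correction is applied
across amplicons (`bhAdjust()`). `anovaGroups()` (one-way ANOVA) tests
whether amplicon group labels predict mean activity, and `fisher2x2()`
reports the sample odds ratio \(ad/bc\) with the one-tailed hypergeometric
p for ascertainment enrichment (active-by-ascertained tables).

## Annotation enrichment

Annotation interval sets (open chromatin, histone marks, TF footprints,
conservation — one BED per mark) are merged with `mergeIntervals()`
(overlapping *and* book-ended intervals union, matching `reduce`
semantics) before intersection; `markOverlap()` flags an amplicon on one or
more shared bases. `permutationEnrichment()` draws
\(|\mathrm{significant}|\) amplicons without replacement from the retained
library background 20,000 times and counts mark overlaps; the one-tailed
Monte-Carlo p uses the add-one estimator \((\#\{X_{null} \ge obs\}+1)/(n_{perm}+1)\),
which is valid and never zero. Resampling amplicon *identities* rather
than genomic positions conditions the null on the library's composition,
absorbing the selection bias of a candidate-based design; we do not
additionally condition on amplicon group composition, sampling from the
full library background as stated. Complementing the permutation test,
`glmCovariateBic()` asks whether the mark flag improves the background
regression (coefficient t-test and BIC with/without the flag; `stats::BIC`
conventions), and `pointBiserial()` reports the correlation between the
Z-scores and the 0/1 flag.

## Allele-level summaries

`filterAlleleCounts()` applies the tabular filters — mean base quality
\(\ge 25\), within-sample allele frequency \(\ge 0.01\), then biallelic
SNPs only; per-read extraction filters (mapping quality, raw base quality)
belong to the upstream read-count extractor whose output this module
consumes. `alleleSummary()` pools ref/alt counts within sample kind,
reports per-SNP reference allele frequencies in DNA and RNA, flags SNPs
with pooled-DNA minor allele frequency above 0.1 as eligible for allelic
comparison, and computes the DNA-RNA reference-AF correlation over eligible
SNPs. No allelic significance test is offered: amplicon MPRAs of this
design are underpowered for moderate allelic effects, and pretending
otherwise would invite overinterpretation.

## The synthetic-data generator

`simConfig()` fixes the benchmark conditions; `simulateTruth()`,
`simulateCounts()`, `simulateAnnotations()` and `simulateAlleles()` are
bit-reproducible given the seed. The generative model:

* Amplicon GC ~ Beta(10, 10) (mean 0.5, SD ~0.11, the realistic range for
  ~900 bp amplicons designed with 30-70% primer GC).
* Library/DNA expected proportions \(\propto 2^{\gamma\,GC + a}\) with
  GC-bias coefficient \(\gamma = 3\) log2 units per unit GC and
  amplicon-specific log2 abundance \(a \sim N(0, 0.8)\) — a moderate
  GC-representation correlation on top of a ~5-fold representation
  interquartile spread.
* RNA expected proportions \(\propto (p^{DNA})^{s} \cdot e\) with basal
  slope \(s = 1\) and multiplicative enhancer effect \(e\) (log-normal;
  default a fixed 4x for the spiked 10% of amplicons, 1 otherwise). The
  effect acts multiplicatively on expected RNA, matching the ratiometric
  definition of activity.
* Counts are negative-binomial with dispersion 0.1
  (variance \(\mu + 0.1\mu^2\); Poisson recovered at dispersion 0) —
  a standard overdispersion model for amplicon sequencing counts.
* RNA dropout: amplicons in the lowest DNA-abundance decile drop to zero
  with probability 0.1 independently per RNA replicate, emulating
  replicate-specific cDNA dropout of weakly represented amplicons. Dropout
  is modeled only in RNA and only for low-abundance amplicons.
* Design: 308 amplicons, 1 library sample, 4 DNA + 4 RNA replicates at
  2M expected reads each, plus one technical RNA replicate duplicating the
  last RNA replicate's expectation with independent noise.
* Annotations overlap active amplicons with probability 0.8 and inactive
  ones with 0.2; intervals are placed inside the amplicon span so interval
  intersection recovers the simulated flags exactly.
* SNP reference-allele frequencies ~ Beta(0.5, 0.5) (U-shaped: most SNPs
  have unbalanced alleles, a minority clear the MAF > 0.1 eligibility bar,
  as is typical for amplicons cloned from pooled population DNA), shared
  between DNA and RNA under the null.

Effect sizes of real in vivo enhancers are not well quantified; the 4x
default is a benchmarking choice giving the models a realistic but
non-trivial detection task, not an estimate from any dataset. The
generator does not emulate read-level artifacts (alignment, PCR duplicate
structure), cross-contamination, transduction mosaicism beyond the scalar
dropout, or spatial/cell-type structure — so passing benchmarks demonstrate
statistical correctness of the pipeline under its own assumptions, not
robustness to every failure mode of real sequencing data.

## Benchmark problem sizes and what the suite verifies

The test suite and acceptance script use: a 2000-amplicon all-null library
(4M reads/sample) for p-value calibration (fraction below 0.05 within
[0.03, 0.07]) and GC-coefficient recovery (within 20%); the 308-amplicon
default design with 10% spiked 4x actives for recovery (>= 80% sensitivity
at q < 0.1, empirical FDR <= 0.15); exhaustive enumeration oracles for the
in-silico PCR scan and the exact Wilcoxon p (all combined n <= 10);
hypergeometric tails for the permutation test on all backgrounds of size
<= 12; and byte-identical repeated pipeline runs for determinism. These
sizes keep the full suite under a minute of simulation-heavy work while
leaving Monte-Carlo error well inside the asserted tolerances.

## Numerical and edge-case conventions

* Coordinates are 0-based half-open in all TSV/BED interfaces and
  converted at the `GRanges` boundary; 1-based coordinates appear only
  inside R containers.
* GC content excludes IUPAC ambiguity codes from numerator and
  denominator; sequences with no unambiguous base are an error.
* In-silico PCR reports both orientations (forward primer priming either
  strand), requires primer sites in the proper relative orientation, and
  sorts products by start; cloning homology tails are not part of primer
  matching.
* Degenerate designs (constant GC or DNA proportion in the training set,
  constant mark flag, single-class point-biserial input) raise errors
  rather than returning NaN.
* All stochastic steps take explicit seeds; pipeline outputs embed the
  seed, package version and config hash, and repeated runs are
  byte-identical.

## Known limitations

Repressor/silencer calling is out of scope (the low tail is uninterpreted
by design). The empirical-FDR estimator is intentionally simple; datasets
with a heavy-tailed or asymmetric null would warrant a richer empirical
null. The Wilcoxon location-shift confidence bound uses the normal
approximation from `stats::wilcox.test` even when the p-value is exact.
Allele summaries assume one amplicon per SNP and biallelic sites. The
pipeline expects counts already produced by an external
trim/align/de-duplicate/count workflow; no read processing is performed.
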