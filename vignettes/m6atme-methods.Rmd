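---
title: "Methods: m6A-regulator subtyping and the m6A score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A-regulator subtyping and the m6A score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of **m6aTME**: the
models each stage fits, the tunable parameters and their defaults, the
numerical conventions that make runs reproducible, what the synthetic
cohort generator does and does not emulate, and the design choices made
where the workflow was genuinely open. It states no empirical claims
beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## The scientific setting

N6-methyladenosine (m6A) is the most abundant internal mRNA
modification. It is deposited by writer complexes (METTL3, METTL14,
METTL16, WTAP, VIRMA, ZC3H13, RBM15, RBM15B), removed by erasers (FTO,
ALKBH5), and interpreted by readers (YTHDC1/2, YTHDF1/2/3, HNRNPC, FMR1,
LRPPRC, HNRNPA2B1, IGFBP1/2/3, RBMX). The working hypothesis of this
workflow is that the joint expression of these 23 regulators defines a
small number of discrete "modification patterns" in a tumor cohort, and
that a continuous per-patient summary of the genes tracking those
patterns — the m6A score — stratifies survival, tumor-microenvironment
(TME) composition and immunotherapy response.

The shipped regulator list preserves the spellings of its source,
including two variants ("L RPPRC", "ALKBH"); `m6a_regulator_aliases()`
records the canonical symbols (LRPPRC, ALKBH5) and
`m6a_regulators(resolve_aliases = TRUE)` applies them. Gene matching is
exact-string throughout — no silent alias resolution.

## Preprocessing

*Units.* Expression matrices carry a unit tag (FPKM, TPM, LOG2). TPM is
the per-column normalization `tpm_ij = fpkm_ij / Σ_i fpkm_ij × 10⁶`;
clustering, differential expression and scoring all operate on
`log2(x + 1)` values. Missing values are an error, not imputed: the
workflow's inputs are complete quantification matrices, and silent
imputation would leak into every downstream stage.

*Merging cohorts.* `merge_cohorts()` intersects gene sets, concatenates
samples and removes per-gene batch effects in location and scale. The
default method standardizes each batch's per-gene mean and SD to the
pooled targets **exactly**. We chose this over empirical-Bayes shrinkage
of the batch parameters (available as `method = "combat"`, via sva)
because exact equalization is idempotent — re-correcting corrected data
is a no-op to floating-point precision — and leaves no residual per-gene
batch mean difference, which downstream per-gene survival screens would
otherwise see as signal. EB shrinkage is preferable only when batches
are very small (tens of samples), where per-gene scale estimates are
noisy.

## Consensus clustering

`consensus_cluster()` repeats, `reps = 1000` times: draw
`⌈p_item · n⌉` samples without replacement (`p_item = 0.8`), cluster
them at every K in `k_range` (default 2–6) with the base clusterer —
hierarchical clustering on `1 − Pearson` distance with average linkage
(k-means and PAM are alternatives). The consensus matrix entry for a
pair is the fraction of co-sampled runs in which the pair co-clustered
(pairs never co-sampled score 0). Final labels at each K come from
hierarchical clustering of `1 − M_K`. The 1000-replicate default is the
one setting the source workflow states; subsampling fraction and base
clusterer follow the conventions of the standard consensus-clustering
package.

*Choosing K.* For each K we compute the empirical CDF of off-diagonal
consensus values and its area (AUC). The relative delta-area series
`(A_K − A_{K−1}) / A_{K−1}` measures how much consensus improves when a
cluster is added. `select_k()` returns the largest K whose increment
still clears a threshold (default 0.1) — i.e. the smallest K after
which improvement stalls. Two safeguards: with fewer than three
candidate K no selection is attempted, and when the consensus matrix at
the chosen K is mostly ambiguous (more than 40% of off-diagonal entries
in (0.1, 0.9) — a PAC-style criterion) the run is flagged "no
structure" and falls back to the smallest K, because delta-area gains on
structureless data only reflect fragmentation of noise.

*Reproducibility.* One integer seed is expanded through a documented
linear-congruential fan-out (`derive_seed()`); the subsample draws are
positional, so runs are bit-stable given the seed and the sample order.
With `p_item = 1` and the (deterministic) hierarchical base, consensus
entries are exactly 0/1.

## Differential expression and the phenotype gene set

Between-cluster differential expression uses the empirical-Bayes
moderated t: per-gene residual variances `s²_g` (from a single
group-means linear fit shared by all pairwise contrasts) are shrunk to
`s̃²_g = (d₀ s₀² + d_g s²_g) / (d₀ + d_g)`, with the prior degrees of
freedom `d₀` and prior variance `s₀²` estimated by method of moments on
`log s²_g`. This is limma's model and our implementation delegates the
fit to limma; the test suite verifies it against an independent literal
transcription of the formulas (including the trigamma-inverse moment
estimator) to 1e-8, and checks that the `d₀ = 0` limit reproduces the
ordinary pooled t.

The **phenotype gene set** is the intersection of genes with BH-adjusted
p < 0.05 in *every* pairwise cluster contrast (a Venn-diagram core).
Intersection is the default because the workflow treats these genes as
markers of the modification patterns as a whole, not of one boundary;
`rule = "union"` is available. No fold-change filter is applied — the
screening criterion is the adjusted p-value alone. In the orchestrated
pipeline the regulators themselves are excluded from the phenotype set:
they define the clusters, so keeping them would be circular.

## Survival statistics

Kaplan-Meier estimation (product-limit with Greenwood variance), the
log-rank test (hypergeometric O−E/V accumulation over pooled event
times, generalized-inverse chi-square for ≥3 groups) and univariate Cox
regression (Newton-Raphson on the Breslow partial likelihood, Efron
available; step-halving; monotone-likelihood detection with a |β| ≤ 15
cap and non-convergence flag) are implemented directly in the package.
The reason is the cutpoint search below, which needs the standardized
two-group log-rank statistic at every candidate split; having one
internal O−E/V engine serve all three keeps them consistent. The
survival package is used in the test suite as an independent oracle —
coefficients, variances and chi-squares agree to at least 1e-7 — and
the classical identity "Cox score test at β = 0 equals the log-rank
chi-square" is verified numerically to 1e-8.

*Prognostic gene filter.* Per gene: univariate Cox on expression, plus
a log-rank test after a median split (the cutpoint split is available
behind a flag). A gene is kept when either test clears `alpha = 0.05`
("Cox OR KM"); the AND rule is a flag. The OR default mirrors a screen
meant to be inclusive before unsupervised re-clustering and scoring.

*Maximally selected cutpoint.* `optimal_cutpoint()` evaluates the
standardized log-rank statistic `z = (O − E)/√V` at every split leaving
at least `⌈minprop · n⌉` samples per side (`minprop = 0.1`, the
convention of the standard cutpoint tool), and returns the split
maximizing `|z|`. Ties break toward the median score; the cutpoint is
reported as the midpoint of the adjacent order statistics so group
assignment is stable under floating-point noise. The implementation is
verified against brute-force enumeration via `survdiff` on every tested
instance. Note that the *selected* statistic is the maximum of many
correlated tests; its nominal chi-square p-value is anti-conservative
and should be read as descriptive, not inferential.

## Single-sample enrichment

*ssGSEA* (`ssgsea_score()`): per sample, genes are ranked by expression
(average ranks on ties); walking the genes in decreasing order, the
enrichment score of a set is the summed difference between the
rank-weighted in-set ECDF (weights `rank^α`, `α = 0.25`) and the
unweighted out-of-set ECDF — the running-sum integral. Scores are
min-max normalized over the whole matrix to [0, 1] by default. Because
only ranks enter, scores are invariant to any strictly monotone
per-sample transform.

*GSVA-style scores* (`gsva_score()`): per gene, a Gaussian-kernel CDF
across samples (bandwidth SD/4; an ECDF kernel is available) turns
expression into a relative level; genes are re-ranked per sample, ranks
are folded into the symmetric statistic `|n/2 − rank|`, and each set is
scored by a weighted Kolmogorov walk, reporting the signed sum of the
maximum positive and maximum negative deviations ("difference of
extremes"). Zero-variance genes get the midrank with a warning; a fully
constant matrix scores 0 everywhere, since no relative variation exists
to rank. Both scorers are deterministic and are tested against
independent loop-level transcriptions of their recipes (1e-10 / 1e-8).

The packaged 28-cell-type immune signature file is **synthetic** — real
published immune gene lists are not redistributed here; the file
carries placeholder gene symbols, exists so the machinery can be
exercised end-to-end, and must be replaced (any GMT via `read_gmt()`)
for biological use.

## SVR deconvolution

`svr_deconvolve()` estimates immune-cell fractions per mixture sample by
linear ν-support-vector regression (e1071's `nu-regression`) of the
z-scored mixture profile on the z-scored signature matrix, over the
signature genes shared with the mixture (at least 50% overlap required).
For each sample the ν in {0.25, 0.5, 0.75} minimizing reconstruction
RMSE is kept; negative coefficients are clipped to zero and the rest
renormalized onto the simplex. Significance per sample comes from a
permutation null: profiles assembled from randomly drawn mixture values
are deconvolved and their reconstruction correlation forms the null
distribution (default 100 permutations, seeded). These conventions —
joint z-scoring, ν grid, clip-and-renormalize, gene-permutation null —
follow the canonical SVR deconvolution tool. No published signature
matrix ships with the package; the synthetic generator provides
signature/mixture pairs for validation.

## The m6A score

`compute_score()` z-scores each prognostic phenotype gene across
samples (correlation PCA — the genes are on a common scale by
construction), takes the SVD of the samples × genes matrix, and defines

    score_j = PC1_j + PC2_j = Σ_i (v1_i + v2_i) · z_ij ,

the sum of each sample's projections on the first two components. Among
the readings the compact published formula admits, this one keeps the
score an exactly linear functional of standardized expression (the
stored loadings reproduce it to 1e-10 in the tests) and uses both
dominant variance directions without weighting them by eigenvalue.

*Sign convention.* An SVD determines components only up to sign, which
would make "high score" irreproducible. Each component is oriented so
its largest-magnitude gene loading is positive — a rule independent of
sample order. The gene sets A (positively correlated with oriented PC1)
and B (negatively correlated) are then derived and reported;
whether the high-score group has better or worse survival is an
empirical property of the data, not of the convention.

*Dichotomization.* The score is split at the maximally selected
survival cutpoint (`minprop = 0.1`). On the default synthetic cohort,
where the latent score carries a protective log-hazard of −1 per SD,
the high-score group has visibly higher Kaplan-Meier curves and the
log-rank p is far below 0.01 (recomputed by the acceptance script).

Whether the PCA should run on all phenotype DEGs or only the
Cox/KM-prognostic subset is ambiguous in workflows of this kind; the
gene list is therefore an explicit argument, the pipeline defaults to
the prognostic subset (`score_genes = "prognostic"`), and `"deg"`
switches to the full set.

## Clinical associations

TMB is the per-sample count of nonsynonymous variants (missense,
nonsense, frameshift, in-frame indel, splice-site, translation-start,
nonstop); a per-megabase mode divides by the capture size (default 38
Mb). The variant-class filter is configurable because "mutation rate"
conventions differ; counts are the default since no capture size is
implied by a count-based workflow. TMB is dichotomized by the same
cutpoint search and crossed with the score groups into four strata for
an overall log-rank test. Response tables (CR/PR/SD/PD; responders =
CR|PR) are summarized by the sample odds ratio `(a·d)/(b·c)` (Haldane-
Anscombe 0.5 correction when a cell is zero, flagged) with a two-sided
Fisher exact p — exact rather than chi-square because checkpoint
cohorts are small (tens of patients).

## The synthetic cohort generator

`generate_cohort()` plants exactly the structure the pipeline is meant
to recover, at the scale of the motivating study: 180 patients, 23
regulators, 3 clusters, 2000 additional genes of which 121 are
phenotype genes. Regulator expression is Gaussian around
cluster-specific means separated by 3 within-cluster SDs; a latent
score (cluster center + N(0, 0.5²), standardized) loads positively on
the phenotype genes with mean effect 2 SD; remaining genes are noise.
The genes of the packaged synthetic immune signatures are appended so
enrichment stages have targets — odd-numbered cell types are linked to
the score (coefficient 0.6), the rest are noise. Overall survival is
Weibull with shape 1.2 and median ≈ 30 months at baseline (a
non-trivial but realistic event-time shape for sarcoma-scale cohorts),
with log-hazard −1 per score SD and −0.5 per SD of log mutation burden,
so that the TMB × score strata have a planted ordering; censoring is
independent exponential with its rate solved numerically to hit the
target fraction (default 0.4). PFS uses half the effect and half the
time scale. Mutation counts are negative binomial (mean 30, dispersion
5); with that mean essentially every sample carries a nonsynonymous
variant, so per-group "overall mutation rates" on synthetic data sit
near 100% — a property of the chosen count distribution, not of the
counting code. The first three phenotype genes are named PDCD1, CD274,
CTLA4 so checkpoint analyses have targets. `generate_icb_cohort()`
draws responder status from `plogis(−1 + 1.5 · score)` with CR/PR/SD/PD
grades and halved hazard for responders.

What the generator does **not** emulate: library-size and GC biases,
probe effects, heavy-tailed expression noise, correlated gene modules
beyond the planted ones, informative censoring, or competing risks.
Passing recovery tests on these cohorts demonstrates that the
implementations do what their formulas say under their own modeling
assumptions — not that the workflow's biological conclusions transfer
to any real cohort.

## Problem sizes and determinism

The test suite and acceptance script run the generator at its default
sizes (consensus clustering at 1000 replicates on 180 samples; Cox
consistency at n = 1000; calibration nulls at 500–1000 replicates),
which keeps a complete run in the minutes range on a single core while
leaving all planted-effect margins wide. Every stochastic stage takes
an explicit seed; the pipeline fans one master seed out to stages via
`derive_seed()`, writes all outputs as plain TSV, and records MD5
checksums in a manifest — reruns with the same configuration are
byte-identical.

## Known limitations

- The maximally-selected cutpoint's p-value is not adjusted for the
  selection; treat dichotomized-group log-rank p-values as descriptive.
- Consensus K selection is a heuristic (threshold 0.1 on relative
  delta-area plus an ambiguity fallback); the full delta-area series is
  always reported for manual override.
- The SVR deconvolution is the relative ("fractions sum to one") mode
  only; absolute scoring and batch-corrected signature variants are out
  of scope.
- Univariate Cox only — no multivariable adjustment or
  proportional-hazards diagnostics.
- GO/KEGG annotation enrichment is out of scope: the pipeline exports
  ranked gene lists for external annotation tools.
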