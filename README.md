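# m6aTME

Molecular subtyping of tumor cohorts by N6-methyladenosine (m6A) regulator
expression, and a per-patient **m6A score** that links those modification
patterns to survival, tumor-microenvironment composition, mutation burden
and immunotherapy response.

m6A, the most common internal mRNA modification, is controlled by a small
set of regulator genes — methyltransferase "writers" (METTL3, METTL14,
WTAP, ...), demethylase "erasers" (FTO, ALKBH5) and m6A-binding "readers"
(YTHDF1/2/3, HNRNPC, ...). In sarcoma and other tumors, the joint
expression of these regulators defines discrete modification patterns with
distinct prognosis and immune infiltration. This package implements that
full analysis workflow for anyone with a gene-by-sample expression matrix
and a clinical table:

1. **Preprocessing** — FPKM→TPM conversion
   (`tpm_ij = fpkm_ij / Σ_i fpkm_ij × 10^6`), log2(x+1) transform, sample
   alignment, multi-cohort merging with per-gene batch correction.
2. **Regulator landscape** — tumor-vs-normal Wilcoxon tests, CNV gain/loss
   frequencies, mutation frequency, and a prognostic Spearman coexpression
   network over the 23 regulators.
3. **Consensus clustering** — resampling-based clustering (default: 1000
   subsamples of 80% of patients, hierarchical clustering on 1−Pearson
   distance), consensus CDF/delta-area diagnostics, and automatic selection
   of the number of clusters K.
4. **Differential expression** — empirical-Bayes moderated t (per-gene
   variances shrunk by `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`) between all
   cluster pairs, BH correction, and a phenotype gene set from the
   intersection of significant contrasts.
5. **Survival statistics** — Kaplan-Meier product-limit curves with
   Greenwood variance, the log-rank test, Newton-Raphson univariate Cox
   regression (Breslow/Efron ties), a Cox+KM prognostic gene filter, and a
   maximally-selected-rank-statistic cutpoint search.
6. **Microenvironment** — rank-based ssGSEA immune-infiltration scores,
   GSVA-style pathway scores, and CIBERSORT-style cell-fraction estimation
   by linear ν-support-vector regression with permutation significance.
7. **m6A score** — z-score the prognostic phenotype genes, take the first
   two principal components, and set
   `score_j = PC1_j + PC2_j = Σ_i (v1_i + v2_i) z_ij`; patients are split
   into high/low score groups at the survival-optimal cutpoint.
8. **Clinical associations** — tumor mutational burden (TMB), TMB×score
   survival strata, age/sex subgroup survival, checkpoint-gene (PDCD1,
   CD274, CTLA4) expression differences, and CR/PR/SD/PD response-rate
   analysis with odds ratio and Fisher exact test.

A synthetic-cohort generator with fully known ground truth (planted
expression clusters, a latent score driving survival, immune mixtures,
mutation counts, checkpoint response) backs the entire test suite.

## Worked example

```r
library(m6aTME)
res <- run_pipeline(config = list(seed = 1), out_dir = "m6atme_out")
```

On the default synthetic cohort (180 patients, 23 regulators, 3 planted
modification patterns, 121 score-linked phenotype genes) this prints:

```
[m6aTME] generating synthetic cohort (seed 1)
[m6aTME] regulator mutation frequency: 47.22%
[m6aTME] consensus clustering 180 samples on 23 regulators (reps = 1000)
[m6aTME] selected K = 3 for the regulator clusters
[m6aTME] 229 phenotype DEGs at adj. p < 0.05 (intersection rule)
[m6aTME] 228 prognostic phenotype genes
[m6aTME] m6A score cutpoint -15.13: 158 high / 22 low
[m6aTME] OS log-rank high vs low score: p = 3.67e-17
[m6aTME] TMB x score 4-group log-rank: p = 8.39e-19
[m6aTME] checkpoint response rate: high 44%, low 14% (OR 4.67, p 0.118)
```

Reading the output: consensus clustering found exactly the three planted
modification patterns (`selected K = 3`); the phenotype gene set contains
the planted score-linked genes; the PCA score splits the cohort into a
high-score group with far better overall survival (log-rank p ≈ 4e-17,
matching the planted protective log-hazard of −1 per score SD); and in the
synthetic checkpoint-therapy cohort the high-score group responds at 44%
versus 14%. Every table behind these lines (cluster labels, delta-area
series, DEG statistics, score loadings, KM inputs, strata, response
composition) is written to `m6atme_out/` as TSV, with a JSON manifest of
file checksums; reruns with the same config are byte-identical.

Individual stages are plain functions returning classed objects:

```r
g  <- generate_cohort(seed = 1)                       # synthetic cohort + truth
cc <- consensus_cluster(g$cohort$expression[m6a_regulators(TRUE), ],
                        k_range = 2:6, seed = 1)
#> <consensus_result> n = 180 samples, K in {2,3,4,5,6}, reps = 1000
#>   selected K = 3
#>   delta-area: K2=0.452 K3=0.489 K4=0.008 K5=0.012 K6=0.014
sc <- compute_score(g$cohort$expression, g$truth$deg_genes)
sc <- dichotomize_score(sc, g$cohort$clinical)
#> <m6a_score> 180 samples; PC1+PC2 capture 56.6% of variance
#>   cutpoint -15.13: 158 high / 22 low
```

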