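# momics — multi-omics prognostic subtyping by signed NMF consensus clustering

`momics` is an R package for discovering prognostic molecular subtypes of
tumors (the motivating application is resected brain metastases) from
overlapping multi-omics cohorts: bulk RNA-seq expression, LC-MS/MS protein
intensities, and targeted (p180-style) metabolite concentrations, joined to a
clinical table with overall-survival (OS) and distant-brain-failure (DBF)
endpoints. It is aimed at computational biologists who want the full analysis
— subtype discovery, model selection against a negative control, survival
comparison, cross-layer differential analysis, and pathway scoring — as one
tested, reproducible pipeline, plus a synthetic-cohort generator so every
stage can be exercised and validated without patient data.

## The method

**Preprocessing.** Features undetected in more than half the samples are
discarded (strictly `> n/2`; exactly half survives). Each remaining feature
`x` is log-transformed, centered, and scaled by its root mean square
(population convention):

    z = (log2(x + c) - mean) / rms,   rms = sqrt(mean((log2(x+c) - mean)^2))

**Signed NMF bi-clustering.** Centered data are signed, so the matrix
`X (m x n)` is stacked as `Y = [max(X,0); max(-X,0)] (2m x n)` — non-negative
and exactly invertible — and factorized as `Y ≈ WH` by Lee–Seung
multiplicative updates minimizing `||Y - WH||²_F` from seeded uniform random
starts (objective monotone non-increasing). Samples are labeled by the argmax
of their `H` column after scale normalization; a gene's signed loading on
cluster `c` is `W[g,c] - W[g+m,c]`, and a gene is *associated* with the
cluster of its largest absolute loading when that loading carries at least a
fraction τ of the total.

**Rank selection.** For `k = 2..6`, a consensus matrix `C` over restarts is
scored with seven metrics — cophenetic correlation, dispersion
`mean(4(C-½)²)`, explained variance, final residual, RSS, silhouette on
`1 - C`, and Hoyer sparseness `(√n - ‖·‖₁/‖·‖₂)/(√n - 1)` — on both the real
matrix and a row-permuted randomization (negative control). The selected `k`
maximizes the real-data cophenetic coefficient among candidates that beat
their randomized control.

**Survival.** Kaplan–Meier product-limit curves with Greenwood variance and
log(−log) 95% CIs; two-group Mantel–Haenszel log-rank (`chi² = U²/V`, 1 df)
between the two largest subtypes, for OS and DBF endpoints; labels transfer
to the other omics layers by sample-id intersection.

**Differential analysis.** Empirical-Bayes moderated t-test built from first
principles: per-feature pooled variances are shrunk toward a prior fit by
moment-matching `log s²` to a scaled-F model (Newton solve of the trigamma
equation), `t̃ = Δ / (s̃ √(1/n₁+1/n₂))` with `d0 + d_g` degrees of freedom,
Benjamini–Hochberg FDR at 0.05. Metabolite ratio indicators (`Orn / Arg`,
`Total SM-OH / Total SM-non OH`, …) are computed on raw concentrations and
appended to the panel before testing.

**Pathway scoring.** One-sided hypergeometric enrichment of the
subtype-associated genes (RNA) and the differential proteins (protein)
against user-supplied GMT gene sets; each layer contributes `-log10(p)` and
the overall pathway score is their sum.

## Worked example

```r
library(momics)

cohort <- generate_cohort(synthetic_config(seed = 1))
cohort
#> <synthetic_cohort> 78 patients, layers: rna(46), protein(64), metabolite(41)
overlap_summary(cohort$truth$membership)
#> <overlap_summary> sizes: 46/64/41 | union 78 | >=2 layers 56 | all three 17

X <- normalize_omics(filter_low_detected(cohort$layers$rna))
sel <- select_k(X, k_range = 2:6, n_restarts = 20, seed = 1,
                max_iter = 500, tol = 1e-5)
sel$k_best
#> [1] 4
subset(sel$metrics, condition == "real")[, c("k", "cophenetic", "dispersion",
                                             "evar", "silhouette")]
#>  k cophenetic dispersion  evar silhouette
#>  2      0.992      0.317 0.356      0.543
#>  3      0.995      0.678 0.386      0.846
#>  4      1.000      1.000 0.415      1.000
#>  5      0.998      0.902 0.431      0.759
#>  6      0.995      0.850 0.446      0.568

model <- fit_subtypes(X, k = sel$k_best, n_restarts = 20, base_seed = 1,
                      max_iter = 800)
model
#> <subtype_model> k=4  cluster sizes: 12/14/10/10  associated genes: 482

compare_subtypes(model, cohort$clinical, endpoint = "os", pairwise = TRUE)
#> <subtype_survival> endpoint=os n=46
#>   medians (months): 1=13.3 2=13.63 3=10.94 4=18.91
#>   two largest subtypes (2 vs 1): <logrank_result> chi2=1.201 df=1 p=0.2732
```

The rank screen is unambiguous: at `k = 4` (the planted number) the
consensus matrix is binary across restarts (cophenetic = dispersion =
silhouette = 1), while the row-permuted control stays far below. The sample
labels recover the planted subtypes essentially perfectly. The survival
contrast on the 46-patient transcriptomics cohort is, however, weak at this
seed (good-vs-poor pairwise p ≈ 0.08): with ~10 patients per subtype and 25%
censoring, single-cohort log-rank tests are underpowered — which mirrors the
scale of the real studies this pipeline is built for. The survival machinery
itself separates the planted 7.89- vs 42.27-month subtypes decisively at
n = 100 per arm:

```r
a <- simulate_survival_times(100, 7.89,  censor_rate = 0.25, seed = 11)
b <- simulate_survival_times(100, 42.27, censor_rate = 0.25, seed = 12)
log_rank(a$time, a$event, b$time, b$event)
#> <logrank_result> chi2=96.900 df=1 p=7.291e-23
```

The full eight-stage pipeline (data → preprocess → select_k → subtype →
survival → transfer → differential → enrich) runs from one config:

```r
cfg <- pipeline_config(out_dir = "run1", simulate = TRUE, seed = 1,
                       k_range = 2:6, n_restarts = 20)
res <- run_pipeline(cfg)   # writes TSV/CSV/JSON outputs + manifest.json
```

or from the command line via `exec/momics`:

```sh
momics simulate --out cohort_dir --seed 1
momics run --config config.json --out run1
```

## Layout

- `R/` — implementation; `src/` — Rcpp multiplicative-update kernel
- `tests/testthat/` — unit, property and acceptance suites (the oracles in
  `helper-oracles.R` are coded independently of the implementation)
- `vignettes/momics-methods.Rmd` — the methods vignette: model, assumptions,
  parameter choices, what the synthetic world does and does not establish
- `inst/extdata/table2_pathway_scores.csv` — printed two-layer pathway score
  table used as acceptance input
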