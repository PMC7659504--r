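# ckindex — the Clinical Kinase Index

`ckindex` prioritizes candidate drug-target genes (typically kinases)
within a cancer cohort by integrating four lines of clinical evidence into
one normalized score, the **Clinical Kinase Index (CKI)**. It is aimed at
target-discovery and translational groups who have bulk tumor expression,
clinical annotation and somatic mutation calls for a cohort and want a
transparent, reproducible ranking of genes worth pursuing — including
understudied ones that annotation-driven prioritization overlooks.

## The score

For gene *g* in a cohort, four evidence components are computed:

- **E** ∈ {0, 1} — differential overexpression: 1 iff log2FC > 1 with
  Benjamini-Hochberg FDR < 0.01 (Welch test on log2-CPM, tumor vs normal);
- **S** ∈ {0, 1} — adverse survival: 1 iff the log-rank test between the
  upper- and lower-quartile expression arms has p < 0.05 *and* the
  high-expression arm has worse restricted mean survival;
- **M** ∈ {0, 1} — mutational hotspot: 1 iff the gene's positional
  clustering score is significant against the cross-gene background and
  the gene carries ≥ 5 qualifying mutations;
- **C_p** ∈ [0, 1] for each staging parameter *p* (T, N, M stage, grade,
  pathologic/clinical stage): the fraction of level pairs at which
  expression is significantly *higher at the higher level*.

```
raw(g)  = E + S + M + Σ_p C_p
CKI(g)  = 100 · raw(g) / (n_binary_components + n_available_parameters)
```

The denominator adapts to what a cohort actually provides (a cohort with
full staging scores out of 9; one with only T/N/M out of 6), so CKI
percentages are comparable across cohorts. Only the progression-consistent
direction ever scores: under-expression, protective survival and falling
stage trends contribute nothing.

The package also ships a synthetic cohort generator with planted effects
(`simulate_cohort()`), readers/writers for counts, clinical, MAF,
annotation and dependency-matrix files, and a benchmarking module that
compares CKI against loss-of-function dependency screens
(`benchmark_cohort()`: Kruskal-Wallis, Spearman, ROC with the strict
score < −1 dependency cutoff).

## Worked example

```r
library(ckindex)

sim <- simulate_cohort(sim_config(n_genes = 40, n_tumor = 60, n_normal = 20,
                                  planting = "composite", seed = 7))
fit <- cki(sim$bundle)
fit
#> Clinical Kinase Index fit: cohort SIM
#>   40 genes scored; maximum score 9 (3 evidence components + 6 clinical parameters)
#>   top genes:
#>      1. KIN0038    CKI  31.48 (raw 2.83 / 9)
#>      2. KIN0013    CKI  29.63 (raw 2.67 / 9)
#>      2. KIN0014    CKI  29.63 (raw 2.67 / 9)
#>      4. KIN0024    CKI  27.78 (raw 2.50 / 9)
#>      4. KIN0030    CKI  27.78 (raw 2.50 / 9)

head(as.data.frame(fit)[, c("gene", "dge", "hotspot", "clinical_T",
                            "raw_score", "cki_percent", "rank")], 3)
#>       gene dge hotspot clinical_T raw_score cki_percent rank
#> 38 KIN0038   1       1  0.6666667  2.833333    31.48148    1
#> 13 KIN0013   1       1  0.6666667  2.666667    29.62963    2
#> 14 KIN0014   1       1  0.3333333  2.666667    29.62963    2

benchmark_cohort(fit$scorecards, sim$bundle$dependency)
#> <cki_benchmark> cohort SIM: 40 shared genes, 5 cell line(s)
#>   tissue-mean: AUC 1.000, KW p 9.84e-07, dependent mean CKI 28.0 vs 1.4
```

Reading this: the cohort's eight planted composite-relevance genes top
the ranking — each is flagged overexpressed (`dge = 1`), carries a
mutational hotspot (`hotspot = 1`) and shows a rising T-stage expression
trend (`clinical_T` = fraction of significant increasing stage pairs).
Genes that are "dependent" in the simulated knockout screen (score < −1)
have a mean CKI of 28 versus 1.4 for the rest, and CKI separates the two
classes with AUC 1.0. On a cohort scored out of 6 (T/N/M only), a gene
with all three binary components plus clinical sub-scores of 1, 0.25 and 0
has raw score 4.25 and CKI 70.83%.

`run_score()` / `run_benchmark()` orchestrate multi-cohort runs from
bundles or exported directories and write deterministic TSV/JSON outputs;
`read_run_config()` loads a YAML run configuration.

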