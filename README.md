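# radsig

Gene signatures of ionizing radiation exposure, derived and externally
validated with biochemically-inspired machine learning.

## What it does, and for whom

Radiation biodosimetry needs fast screening tests that tell exposed from
unexposed individuals — and estimate how much dose (in cGy) was absorbed
— from a blood sample's transcriptome. `radsig` implements a complete
discovery-and-validation pipeline for such gene signatures, for
bioinformaticians working with expression matrices (microarray or
otherwise) and a curated panel of candidate radiation-response genes:

1. **Preprocessing** — completeness filtering (≥ 95% observed),
   nearest-neighbor imputation, per-probe z-scoring, probe→gene
   collapsing, and restriction of all datasets to their common panel
   genes.
2. **mRMR ranking** — incremental selection under the
   mutual-information-difference criterion
   `max_i [ I(i, h) − (1/|S|) Σ_{j∈S} I(i, j) ]`, with `I` the plug-in
   mutual information (nats) between 3-level discretized expression and
   dose class `h`, and `S` the already-selected genes.
3. **Wrapper feature selection** — complete (CSFS), forward (FSFS) and
   backward (BSFS) sequential selection over the top-ranked genes,
   scored by stratified k-fold cross-validation of a Gaussian-kernel
   SVM (`K(u, v) = exp(−‖u−v‖²/2σ²)`) under misclassification or
   multi-class log loss, followed by a `(C, σ)` grid search over the
   21-pair lattice `{10⁰…10⁵}², C ≥ σ`.
4. **External validation** — signature-centric repeated stratified
   k-fold on an independent dataset, and traditional train/test
   validation with quantile normalization restricted to the signature
   genes. Metrics: misclassification, multi-class log loss
   `−(1/N) Σᵢ Σⱼ y_ij ln p_ij`, and goodness of fit (mean |predicted −
   true| dose, cGy), each as mean ± standard error over repeats, plus
   confusion matrices.
5. **Cross-signature analyses** — top-signature tables, scaled
   gene-frequency heat maps, frequency–mutual-information correlation,
   and per-gene removal weights (ΔMC, ΔLL, ΔGoF).
6. **A synthetic-data generator** — planted dose-responsive genes
   (induced and repressed), redundant co-expressed blocks, missing
   values, and monotone cubic cross-cohort batch distortion — so the
   whole pipeline runs and is tested without any download.

All user-facing functions take a data frame first and return tibbles,
so stages chain with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## A worked example

Simulate a 4-class cohort ({0, 50, 200, 1000} cGy, 30 samples per
class, 500 panel genes with 5 planted responders), run discovery, and
validate the selected signature:

```r
library(radsig)

sim <- simulate_dataset(sim_config(seed = 11))
pre <- preprocess_expression(sim$expression)

ranking <- mid_rank(pre, sim$labels, n_select = 50)
head(ranking, 3)
#> # A tibble: 3 × 5
#>    rank gene   relevance_nats redundancy_nats mid_score
#>   <int> <chr>           <dbl>           <dbl>     <dbl>
#> 1     1 RG0002          0.878           0         0.878
#> 2     2 RG0005          0.784           0.602     0.182
#> 3     3 RG0003          0.720           0.560     0.160

sig <- fsfs(ranking, pre, sim$labels, C = 10, sigma = 1,
            criterion = "log_loss", seed = 11)
sig$genes
#> [1] "RG0002" "RG0004" "RG0005" "RG0010" "RG0003" "RG0001"
intersect(sig$genes, sim$truth$planted)   # all 5 planted genes
#> [1] "RG0002" "RG0004" "RG0005" "RG0003" "RG0001"

report <- kfold_validate(pre, sim$labels, sig, k = 5, C = 10, sigma = 1,
                         repeats = 5, seed = 12)
report
#> Validation report (kfold), 120 samples, 5 repeats
#>   misclassification: 0.03 ± 0.0057
#>   log loss (nats):   0.1972 ± 0.0048
#>   goodness of fit:   18.58 ± 2.99 cGy
```

The ranking puts the planted responders on top (their mutual
information with dose, 0.7–0.9 nats, towers over the ~0.05-nat noise
floor); forward selection keeps six genes — the five planted responders
plus one co-expressed satellite (`RG0010`); and repeated stratified
5-fold validation classifies 97% of samples correctly, with the
remaining errors landing in dose classes adjacent to the truth (see
`autoplot(report)` for the confusion matrix).
`traditional_validate()` runs the train-on-one-cohort,
predict-the-other protocol with signature-restricted quantile
normalization, and `gene_frequency()` / `gene_removal_weight()` analyze
ensembles of signatures.

A thin command-line wrapper is installed at
`system.file("exec", "radsig", package = "radsig")` with `simulate`,
`discover` and `validate` subcommands driven by YAML configs (see
`?load_run_config`).

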