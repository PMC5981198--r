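---
title: "Deriving and validating radiation exposure gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating radiation exposure gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
library(dplyr)
```

## The problem

Radiation biodosimetry asks how much ionizing radiation a person has
absorbed, using only biological measurements — here, gene expression in
peripheral blood. The package derives small *gene signatures* that
classify samples into dose classes (cGy), and validates them strictly on
data independent of the data that produced them. Its pipeline is:

1. **Preprocess** expression matrices: drop probes/samples less than 95%
   complete, impute the rest by nearest-neighbor rows, z-score each
   probe, average probes of the same gene, and restrict all datasets to
   the genes they share with a curated radiation-response panel.
2. **Rank** panel genes by minimum-redundancy-maximum-relevance (mRMR)
   under the mutual-information-difference (MID) criterion: at each step
   select the gene maximizing
   $I(i, h) - \frac{1}{|S|}\sum_{j \in S} I(i, j)$,
   where $h$ is the dose class and $S$ the genes already selected.
3. **Select** a signature by a wrapper algorithm — complete (CSFS,
   best prefix of the ranking), forward (FSFS, greedy addition from the
   top-50 pool) or backward (BSFS, greedy removal from the top-30 pool) —
   scored by stratified k-fold cross-validation of an RBF-kernel SVM
   under misclassification or multi-class log loss.
4. **Tune** the SVM box constraint $C$ and kernel scale $\sigma$ for the
   selected signature over the 21-pair lattice
   $\{10^0,\dots,10^5\}^2,\ C \ge \sigma$.
5. **Validate** externally: *signature-centric* repeated stratified
   k-fold on an independent dataset, or *traditional* train-on-one,
   predict-the-other after quantile normalization restricted to the
   signature genes. Metrics: misclassification, multi-class log loss
   (nats), and goodness of fit (mean |predicted − true| dose in cGy),
   each reported with a standard error over repeats.

## Model components and their assumptions

### Mutual information and discretization

Mutual information is estimated by the plug-in formula on discrete
states. Expression is continuous, so each gene is first mapped to three
levels at mean ± $\alpha$·sd (default $\alpha = 0.5$, the convention of
the mRMR literature for standardized expression). All information is in
nats, matching the natural logarithm of the log-loss formula. The
plug-in estimator is biased upward for small samples; since mRMR only
compares MI values computed on the same samples with the same
discretization, this bias is immaterial for ranking.

When the selected set is empty the redundancy term $1/|S|$ is undefined;
we define it as 0, so the first selected gene simply maximizes
relevance. Ties (common on discrete data) break by higher relevance and
then lexicographic symbol; scores within $10^{-9}$ are treated as tied
so that floating-point summation order cannot flip a selection.

### SVM and its probability contract

The classifier is a one-vs-one multi-class SVM with the Gaussian kernel
$K(u, v) = \exp(-\lVert u - v\rVert^2 / 2\sigma^2)$, fitted by libsvm
(e1071) with box constraint $C$ on the z-scored signature genes. Class
probabilities are produced by the package itself: each pairwise
classifier's training decision values get a Platt sigmoid (fitted on
training data only, with Platt's smoothed targets so separable data do
not produce degenerate calibration), and pairwise probabilities are
coupled into a class distribution by the Wu–Lin second method. This
construction is deliberately deterministic: refitting on the same data
reproduces identical probabilities bit for bit, which the wrapper
algorithms and the gene-removal analyses rely on. Probabilities are
clipped to $[10^{-15}, 1 - 10^{-15}]$ and renormalized before log loss.
Predictions are the row-wise argmax; exact ties resolve to the lower
dose, the conservative choice for triage.

A consequence of training-set Platt calibration is mild overconfidence
on overfit machines: on pure-noise features with a hard margin
($C = 10$, $\sigma = 1$) cross-validated log loss sits noticeably above
the uninformative limit $\ln M$. The limit is recovered with a smooth
machine ($C = 1$, $\sigma = 2$), which is how the package's tests probe
it.

### Wrapper feature selection

"Performance plateaus" is implemented as *no candidate step strictly
improves the criterion* (tolerance zero) — any positive tolerance would
be an extra free parameter. FSFS always accepts its first gene so
signatures are non-empty; BSFS never removes the last gene. Internal
scoring uses stratified 5-fold partitions, dealt round-robin within each
class from a rotated starting fold, so balanced classes produce equal
fold sizes. The feature-selection run uses a fixed $(C, \sigma)$; the
grid search is applied afterwards to the selected signature, and ties on
the grid prefer smaller $C$, then larger $\sigma$ (the least complex
machine).

### Quantile normalization

Traditional validation quantile normalizes each sample's
signature-restricted expression vector against the per-rank means of the
pooled train + test samples (ties averaged over the tied span), after
which every sample carries an identical sorted vector and only
within-sample rank patterns remain. A train-only reference is available
as an option (`reference = "train"`) for settings where the test cohort
must not influence the transform. The operation is idempotent and, being
rank-based, invariant to any monotone distortion of a sample's values —
which is exactly why it can undo cross-platform batch effects.

This also defines its limitation: a signature whose genes all respond to
dose *in the same direction with the same shape* carries its information
in cross-sample location, which per-sample normalization removes. After
per-gene z-scoring, same-direction responders have nearly identical
standardized profiles regardless of their raw effect sizes, so
informative rank patterns require signatures mixing up- and
down-regulated (or responsive and unresponsive) genes. Radiation-response
panels do contain both induced and repressed genes, and the synthetic
generator plants both accordingly.

## The synthetic data generator

No public cohort ships with the package; every property is exercised on
synthetic data whose structure mirrors what the pipeline assumes:

* background genes are standard normal;
* each of the `n_planted` responders shifts its mean by
  $\pm\beta \log_{10}(1 + d)$ at dose $d$ cGy, signs alternating
  (induced and repressed genes), with within-class standard deviation
  `planted_sd`;
* redundant blocks are co-expressed satellites of a planted driver:
  correlated with it at exactly `rho_block` within class, with the
  attenuated response $\rho\beta$ and unit variance;
* entries are masked completely at random at `missing_fraction`;
* a paired cohort can be drawn from identical ground truth and passed
  through a monotone cubic batch distortion $y = a_1 x + a_3 x^3$
  (non-affine, so it survives z-scoring; rank-preserving, so quantile
  normalization can remove it).

Defaults emulate a murine-style 4-class design ({0, 50, 200, 1000} cGy,
30 samples/class, 500 panel genes, 5 planted responders, 3 blocks of 4,
1% missing). The paired-cohort benchmark uses the 2-class (0 vs 200 cGy)
human-style design, the setting in which one cohort trains a model that
must predict another platform's samples.

Two generator constants deserve justification, both fixed from design
analysis rather than data:

* **`planted_sd = 0.4`.** The hardest boundary in the 4-class design is
  50 vs 200 cGy: the planted mean gap is
  $\log_{10}(201) - \log_{10}(51) \approx 0.60$. With unit residual
  noise the Bayes error of the 5-gene planted signature is ~25%
  ($\Phi(-0.60\sqrt{5}/2) \approx 0.25$ for that pair alone) — far from
  the few-percent error regime of real total-body irradiation cohorts
  that the generator emulates. Residual sd 0.4 puts the Bayes error
  near 3–5%, matching that regime.
* **`distortion = c(1, 1)`.** Strong enough that unnormalized
  cross-cohort transfer measurably degrades, while the quantile-
  normalized arm is unaffected (monotone invariance).

What passing on this generator does **not** show: robustness to
platform-specific probe effects, non-monotone or saturating
dose–response kinetics, time-course structure, partial-body exposure, or
informative missingness. Real cohorts have all of these.

## Problem sizes used by the test-suite benchmarks

The recovery benchmark runs the full pipeline (preprocess → mRMR →
FSFS under log loss → 5-fold validation) on the 4-class defaults for 10
generator seeds and checks that the signature recovers most planted
genes at low validated error, and that errors land almost exclusively in
adjacent dose classes. The normalization benchmark compares traditional
validation with and without quantile normalization on 10 paired 2-class
cohorts. Oracle-equivalence checks (mRMR against exhaustive per-step MID
evaluation; the three wrappers against brute-force greedy/prefix
oracles) run on hundreds of small random instances (≤ 12 genes, ≤ 40
samples) where exhaustive evaluation is cheap.

## A worked discovery run

```{r discovery, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 11))
pre <- preprocess_expression(sim$expression)
ranking <- mid_rank(pre, sim$labels, n_select = 50)
head(ranking, 5)

sig <- fsfs(ranking, pre, sim$labels, C = 10, sigma = 1,
            criterion = "log_loss", seed = 11)
sig$genes
intersect(sig$genes, sim$truth$planted)

report <- kfold_validate(pre, sim$labels, sig, k = 5, C = 10, sigma = 1,
                         repeats = 5, seed = 12)
tidy(report)
autoplot(report)
```

The chunk is not evaluated at build time (a full run takes ~20 s); the
README shows the same example with its actual printed output.

## Numerical and design choices, collected

* Completeness filtering is rows (probes) first, then samples, both at
  the same threshold; the order is a documented argument.
* Nearest-neighbor imputation: k = 10 unweighted row neighbors by
  Euclidean distance over mutually observed columns; neighbor order on
  tied distances is alphabetical, so imputation is deterministic.
* Constant rows cannot be z-scored and are dropped with a warning
  rather than emitting non-finite values.
* Gene symbols match case-insensitively (human/murine conventions);
  the first annotated spelling is kept for display.
* Dose classes are unordered for classification; their numeric cGy
  values are used by goodness of fit and the adjacency statistic.
* The `±` uncertainties in reports are standard errors over repeated
  repartitions (k-fold) or re-runs (traditional), default 20, seeded;
  traditional validation is deterministic end-to-end, so its standard
  errors are 0 by construction.
* The frequency–MI correlation defaults to Pearson (Spearman behind a
  flag); gene frequencies pool over dataset columns by their mean.
* When a signature group holds fewer than `n` signatures, frequencies
  scale by that group's own maximum, never by `n`.
* The null predictor (empty signature) has uniform class probabilities
  and predicts the lowest dose class, making all three metrics defined
  and deterministic.

## Known limitations

* The plug-in MI estimator with 3-level discretization cannot be
  expected to reproduce MI values computed with other estimators, bin
  counts, or logarithm bases.
* Platt calibration on training decision values is slightly
  overconfident for hard-margin machines (see above); downstream
  comparisons are unaffected because every candidate is scored by the
  same construction.
* Per-sample quantile normalization erases cross-sample location;
  signatures of uniformly same-direction responders lose most of their
  signal under traditional validation. This is a property of the
  method, faithfully reproduced.
* The pipeline treats dose as a finite class set; it does not regress
  continuous dose or produce interval estimates.
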