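#' Built-in end-to-end benchmarks on synthetic data
#'
#' `benchmark_recovery()` runs the full discovery pipeline — raw
#' simulated 4-class data ({0, 50, 200, 1000} cGy, 30 samples per
#' class, 500 panel genes, 5 planted responders), preprocessing, mRMR
#' ranking, forward sequential feature selection under the log-loss
#' criterion, and stratified k-fold validation of the selected
#' signature — and reports how much of the planted truth was
#' recovered.
#'
#' `benchmark_normalization()` runs the paired-cohort experiment the
#' generator is built for: two cohorts drawn from identical truth in
#' the two-class (0 vs 200 cGy) design, with the second cohort passed
#' through a monotone cubic batch distortion; the planted signature is
#' then validated traditionally (train on cohort 1, predict cohort 2)
#' with and without signature-restricted quantile normalization.
#'
#' @param seed Integer seed for the generator and all downstream
#'   stochastic steps.
#' @param config Optional [sim_config()] override (its `seed` is
#'   replaced by `seed`).
#' @param C,sigma SVM hyper-parameters for feature selection and
#'   validation models.
#' @param k Folds for feature selection and k-fold validation.
#' @param repeats Repeats of the k-fold repartitioning.
#' @return `benchmark_recovery()`: one-row tibble with `seed`,
#'   `n_planted`, `n_recovered`, `n_genes` (signature size),
#'   `misclassification`, `log_loss`, `goodness_of_fit`,
#'   `adjacent_errors`, `total_errors` (per-repeat averages from the
#'   pooled confusion matrix). `benchmark_normalization()`: one-row
#'   tibble with `seed`, `mc_normalized`, `mc_unnormalized`.
#' @export
benchmark_recovery <- function(seed, config = NULL, C = 10, sigma = 1,
                               k = 5, repeats = 2) {
  cfg <- config %||% sim_config()
  cfg$seed <- seed
  sim <- simulate_dataset(cfg)
  pre <- preprocess_expression(sim$expression)
  ranking <- mid_rank(pre, sim$labels, n_select = min(50, nrow(pre)))
  sig <- fsfs(ranking, pre, sim$labels, C = C, sigma = sigma,
              criterion = "log_loss", k = k, seed = seed)
  report <- kfold_validate(pre, sim$labels, sig, k = k, C = C, sigma = sigma,
                           repeats = repeats, seed = seed)
  conf <- report$confusion
  off <- conf
  diag(off) <- 0
  tibble(
    seed = seed,
    n_planted = length(sim$truth$planted),
    n_recovered = length(intersect(sig$genes, sim$truth$planted)),
    n_genes = length(sig$genes),
    misclassification = report$misclassification[["mean"]],
    log_loss = report$log_loss[["mean"]],
    goodness_of_fit = report$goodness_of_fit[["mean"]],
    adjacent_errors = sum(off[abs(row(off) - col(off)) == 1]),
    total_errors = sum(off)
  )
}

#' @rdname benchmark_recovery
#' @export
benchmark_normalization <- function(seed, config = NULL, C = 10, sigma = 1) {
  cfg <- config %||% sim_config(doses = c(0, 200))
  cfg$seed <- seed
  pair <- simulate_paired_datasets(cfg)
  pre1 <- preprocess_expression(pair$dataset1$expression)
  pre2 <- preprocess_expression(pair$dataset2$expression)
  sig <- pair$truth$planted
  with_qn <- traditional_validate(pre1, pair$dataset1$labels, pre2,
                                  pair$dataset2$labels, sig, C = C,
                                  sigma = sigma, normalize = TRUE)
  without_qn <- traditional_validate(pre1, pair$dataset1$labels, pre2,
                                     pair$dataset2$labels, sig, C = C,
                                     sigma = sigma, normalize = FALSE)
  tibble(
    seed = seed,
    mc_normalized = with_qn$misclassification[["mean"]],
    mc_unnormalized = without_qn$misclassification[["mean"]]
  )
}
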