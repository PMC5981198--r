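#' Build a signature collection table
#'
#' Assembles signatures and their external validation reports into the
#' flat tibble consumed by the cross-signature analyses: one row per
#' signature with its provenance, gene list (list-column) and the mean
#' validation log loss / misclassification over its reports.
#'
#' @param signatures List of `radsig_signature` objects.
#' @param reports List (parallel to `signatures`) of lists of
#'   `validation_report`s (>= 1 each).
#' @return Tibble with columns `id`, `dataset`, `algorithm`,
#'   `criterion`, `C`, `sigma`, `n_genes`, `genes` (list), `log_loss`,
#'   `misclassification`.
#' @export
signature_collection <- function(signatures, reports) {
  stopifnot(length(signatures) == length(reports),
            length(signatures) >= 1)
  ids <- names(signatures) %||% seq_along(signatures)
  rows <- purrr::map(seq_along(signatures), function(i) {
    sig <- signatures[[i]]
    reps <- reports[[i]]
    if (inherits(reps, "validation_report")) reps <- list(reps)
    if (length(reps) < 1) abort("every signature needs >= 1 validation report")
    tibble(
      id = ids[i], dataset = sig$dataset, algorithm = sig$algorithm,
      criterion = sig$criterion, C = sig$C, sigma = sig$sigma,
      n_genes = length(sig$genes), genes = list(sig$genes),
      log_loss = mean(vapply(reps, function(r) r$log_loss[["mean"]], numeric(1))),
      misclassification = mean(vapply(reps, function(r) r$misclassification[["mean"]],
                                      numeric(1)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Top signatures per source dataset
#'
#' Within each source dataset, keeps the `n` signatures with the
#' lowest mean validation log loss; ties break by lower mean
#' misclassification, then fewer genes.
#'
#' @param collection Tibble from [signature_collection()] (columns
#'   `dataset`, `log_loss`, `misclassification`, `n_genes` required).
#' @param n Signatures kept per dataset (default 20).
#' @return Filtered collection tibble, ranked within dataset.
#' @export
top_signatures <- function(collection, n = 20) {
  stopifnot(nrow(collection) >= 1)
  collection |>
    dplyr::group_by(.data$dataset) |>
    dplyr::arrange(.data$log_loss, .data$misclassification, .data$n_genes,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
}

#' Scaled gene-frequency table across signature groups
#'
#' Counts, per source dataset, how many signatures contain each gene;
#' scales counts within each dataset by that dataset's maximum and
#' then across datasets by the global maximum of the scaled values, so
#' all entries lie in \[0, 1\] and at least one entry is 1. Genes
#' absent from every signature are excluded.
#'
#' @param collection Tibble with `dataset` and a `genes` list-column
#'   (e.g. the output of [top_signatures()]).
#' @return Tibble `gene` x dataset of scaled frequencies (0 = absent).
#' @export
gene_frequency <- function(collection) {
  long <- collection |>
    dplyr::select("dataset", "genes") |>
    tidyr::unnest("genes") |>
    dplyr::rename(gene = "genes") |>
    dplyr::count(.data$dataset, .data$gene, name = "freq") |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(scaled = .data$freq / max(.data$freq)) |>
    dplyr::ungroup()
  long$scaled <- long$scaled / max(long$scaled)
  long |>
    dplyr::select("gene", "dataset", "scaled") |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "scaled",
                       values_fill = 0) |>
    dplyr::arrange(.data$gene)
}

#' Correlation between signature frequency and mutual information
#'
#' Correlates per-gene signature frequency (pooled over the dataset
#' columns of a [gene_frequency()] table by their mean) with per-gene
#' mean relevance (mutual information with dose, nats).
#'
#' @param freqs [gene_frequency()] table, or a tibble with columns
#'   `gene` and `frequency`.
#' @param mi Tibble with columns `gene` and `mi` (nats), or a named
#'   numeric vector.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
frequency_mi_correlation <- function(freqs, mi,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!"frequency" %in% names(freqs)) {
    vals <- as.matrix(freqs[, setdiff(names(freqs), "gene"), drop = FALSE])
    freqs <- tibble(gene = freqs$gene, frequency = rowMeans(vals))
  }
  if (!is.data.frame(mi)) mi <- tibble(gene = names(mi), mi = as.numeric(mi))
  joined <- dplyr::inner_join(freqs, mi, by = "gene")
  if (nrow(joined) < 3) abort("need at least 3 genes shared by freqs and mi")
  cor(joined$frequency, joined$mi, method = method)
}

null_predictor_metrics <- function(labels, classes = sort(unique(labels$dose_cGy))) {
  n <- nrow(labels)
  lowest <- min(classes)
  proba <- matrix(1 / length(classes), n, length(classes),
                  dimnames = list(labels$sample_id, as.character(classes)))
  pred <- tibble(sample_id = labels$sample_id, dose_cGy = lowest)
  list(mc = misclassification(labels, pred),
       ll = multiclass_log_loss(labels, proba),
       gof = goodness_of_fit(labels, pred))
}

#' Weight of a gene within a signature by leave-one-out validation
#'
#' Validates the signature with and without `gene` on each evaluation
#' dataset under identical seeds; the deltas (metric without the gene
#' minus metric with it) measure the gene's contribution — positive
#' deltas mean removal hurts. Removing the only gene of a single-gene
#' signature falls back to the null predictor (uniform class
#' probabilities, lowest-dose prediction). For the dataset that
#' derived the signature, the goodness-of-fit delta is reported as
#' `NA` when goodness of fit was not the optimized criterion (it never
#' is).
#'
#' @param signature `radsig_signature` or character vector.
#' @param gene Gene to remove (must be in the signature).
#' @param datasets Named list; each element a list with `expression`
#'   and `labels`.
#' @inheritParams kfold_validate
#' @param derive_dataset Name of the dataset used to derive the
#'   signature (its `delta_gof` is suppressed), or `NA`.
#' @return Tibble with one row per dataset plus an `"Average"` row:
#'   `delta_misclassification`, `delta_log_loss`, `delta_gof_cGy`.
#' @export
gene_removal_weight <- function(signature, gene, datasets, k = 5, C = 10,
                                sigma = 1, repeats = 5, seed = 1,
                                derive_dataset = NA_character_) {
  genes <- signature_genes(signature)
  if (!gene %in% genes) abort(paste0(gene, " is not in the signature"))
  reduced <- setdiff(genes, gene)
  rows <- purrr::imap(datasets, function(d, name) {
    with_rep <- kfold_validate(d$expression, d$labels, genes, k = k, C = C,
                               sigma = sigma, repeats = repeats, seed = seed)
    if (length(reduced) == 0) {
      base <- null_predictor_metrics(d$labels)
      wo <- list(mc = base$mc, ll = base$ll, gof = base$gof)
    } else {
      r <- kfold_validate(d$expression, d$labels, reduced, k = k, C = C,
                          sigma = sigma, repeats = repeats, seed = seed)
      wo <- list(mc = r$misclassification[["mean"]], ll = r$log_loss[["mean"]],
                 gof = r$goodness_of_fit[["mean"]])
    }
    tibble(
      dataset = name,
      delta_misclassification = wo$mc - with_rep$misclassification[["mean"]],
      delta_log_loss = wo$ll - with_rep$log_loss[["mean"]],
      delta_gof_cGy = if (!is.na(derive_dataset) && name == derive_dataset) {
        NA_real_
      } else {
        wo$gof - with_rep$goodness_of_fit[["mean"]]
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  avg <- tibble(
    dataset = "Average",
    delta_misclassification = mean(out$delta_misclassification),
    delta_log_loss = mean(out$delta_log_loss),
    delta_gof_cGy = mean(out$delta_gof_cGy, na.rm = TRUE)
  )
  dplyr::bind_rows(out, avg)
}

#' Heat map of the scaled gene-frequency table
#'
#' @param freqs [gene_frequency()] output.
#' @return A ggplot object.
#' @export
plot_gene_frequency <- function(freqs) {
  long <- tidyr::pivot_longer(freqs, -"gene", names_to = "dataset",
                              values_to = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dataset, y = .data$gene,
                                     fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nfrequency",
                  title = "Gene frequency in top signatures") +
    ggplot2::theme_minimal()
}

#' Scatter plot of mutual information versus signature frequency
#'
#' @param freqs,mi As in [frequency_mi_correlation()].
#' @return A ggplot object.
#' @export
plot_frequency_mi <- function(freqs, mi) {
  if (!"frequency" %in% names(freqs)) {
    vals <- as.matrix(freqs[, setdiff(names(freqs), "gene"), drop = FALSE])
    freqs <- tibble(gene = freqs$gene, frequency = rowMeans(vals))
  }
  if (!is.data.frame(mi)) mi <- tibble(gene = names(mi), mi = as.numeric(mi))
  joined <- dplyr::inner_join(freqs, mi, by = "gene")
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$mi, y = .data$gene,
                                       size = .data$frequency)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::labs(x = "mutual information with dose (nats)", y = NULL,
                  size = "signature\nfrequency") +
    ggplot2::theme_minimal()
}
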