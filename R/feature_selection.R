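#' Internal cross-validated score of a gene set
#'
#' The wrapper criterion driving feature selection: stratified k-fold
#' cross-validation of an RBF SVM on the data restricted to `genes`,
#' returning pooled misclassification or multi-class log loss (lower
#' is better for both).
#'
#' @inheritParams kfold_validate
#' @param genes Character vector of genes to evaluate (subset of the
#'   data rows).
#' @param criterion `"misclassification"` or `"log_loss"`.
#' @return A single non-negative score.
#' @export
internal_score <- function(x, labels, genes, C = 10, sigma = 1,
                           criterion = c("misclassification", "log_loss"),
                           k = 5, seed = 1) {
  criterion <- match.arg(criterion)
  m <- check_signature_eligible(as_expr_matrix(x), genes)
  labels <- labels[labels$sample_id %in% colnames(m), ]
  folds <- stratified_kfold(labels, k = k, seed = seed)
  res <- run_kfold_round(m, folds, C = C, sigma = sigma)
  if (criterion == "misclassification") {
    misclassification(labels, res$pred)
  } else {
    multiclass_log_loss(labels, res$proba)
  }
}

new_signature <- function(genes, algorithm, dataset, C, sigma, criterion,
                          score, trajectory) {
  structure(
    list(genes = genes, algorithm = algorithm, dataset = dataset,
         C = C, sigma = sigma, criterion = criterion, score = score),
    trajectory = trajectory,
    class = "radsig_signature"
  )
}

#' @export
print.radsig_signature <- function(x, ...) {
  cat("Gene signature (", x$algorithm, ", ", x$criterion, " = ",
      signif(x$score, 4), ")\n", sep = "")
  if (!is.na(x$dataset)) cat("  derived from:", x$dataset, "\n")
  cat("  C =", x$C, " sigma =", x$sigma, "\n")
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.radsig_signature <- function(x, ...) {
  attr(x, "trajectory")
}

#' @export
glance.radsig_signature <- function(x, ...) {
  tibble(algorithm = x$algorithm, dataset = x$dataset, C = x$C,
         sigma = x$sigma, criterion = x$criterion, score = x$score,
         n_genes = length(x$genes))
}

ranking_genes <- function(ranking) {
  if (inherits(ranking, "mrmr_ranking") || is.data.frame(ranking)) {
    as.character(ranking$gene)
  } else {
    as.character(ranking)
  }
}

#' Complete sequential feature selection
#'
#' Evaluates every prefix of the mRMR ranking (gene 1, genes 1-2, ...)
#' with [internal_score()] and returns the best-scoring prefix as the
#' signature (ties break toward the shorter prefix). The trajectory
#' records one row per evaluated prefix.
#'
#' @param ranking An `mrmr_ranking` (or character vector already in
#'   rank order).
#' @inheritParams internal_score
#' @param dataset Identifier stored in the signature's provenance.
#' @return A `radsig_signature`; the per-step trajectory is available
#'   via `tidy()`.
#' @export
csfs <- function(ranking, x, labels, C = 10, sigma = 1,
                 criterion = c("misclassification", "log_loss"), k = 5,
                 seed = 1, dataset = NA_character_) {
  criterion <- match.arg(criterion)
  genes <- ranking_genes(ranking)
  stopifnot(length(genes) >= 1)
  m <- as_expr_matrix(x)
  scores <- vapply(seq_along(genes), function(p) {
    internal_score(m, labels, genes[seq_len(p)], C = C, sigma = sigma,
                   criterion = criterion, k = k, seed = seed)
  }, numeric(1))
  best <- which.min(scores) # first minimum = shortest prefix on ties
  trajectory <- tibble(step = seq_along(genes), action = "add",
                       gene = genes, size = seq_along(genes),
                       score = scores)
  new_signature(genes[seq_len(best)], "CSFS", dataset, C, sigma, criterion,
                scores[best], trajectory)
}

#' Forward sequential feature selection
#'
#' Greedy addition from the pool of the top `pool` mRMR-ranked genes:
#' each step adds the candidate whose addition most improves the
#' internal criterion, stopping when no addition strictly improves it.
#' The first gene (the best-scoring singleton) is always accepted so
#' the signature is non-empty. Score ties break toward the better
#' mRMR rank.
#'
#' @inheritParams csfs
#' @param pool Pool size taken from the top of the ranking (default
#'   50).
#' @return A `radsig_signature` with its accepted-step trajectory.
#' @export
fsfs <- function(ranking, x, labels, C = 10, sigma = 1,
                 criterion = c("misclassification", "log_loss"), k = 5,
                 seed = 1, pool = 50, dataset = NA_character_) {
  criterion <- match.arg(criterion)
  genes <- head(ranking_genes(ranking), pool)
  m <- as_expr_matrix(x)
  score_of <- function(gs) internal_score(m, labels, gs, C = C, sigma = sigma,
                                          criterion = criterion, k = k,
                                          seed = seed)
  current <- character(0)
  current_score <- Inf
  steps <- list()
  repeat {
    cand <- setdiff(genes, current)
    if (length(cand) == 0) break
    cand_scores <- vapply(cand, function(g) score_of(c(current, g)), numeric(1))
    # ties toward better mRMR rank: candidates are in rank order already
    best <- which.min(cand_scores)
    if (length(current) > 0 && cand_scores[best] >= current_score) break
    current <- c(current, cand[best])
    current_score <- unname(cand_scores[best])
    steps[[length(steps) + 1]] <- tibble(
      step = length(steps) + 1L, action = "add", gene = cand[best],
      size = length(current), score = current_score
    )
  }
  new_signature(current, "FSFS", dataset, C, sigma, criterion,
                current_score, dplyr::bind_rows(steps))
}

#' Backward sequential feature selection
#'
#' Greedy removal starting from the full pool of the top `pool`
#' mRMR-ranked genes: each step removes the gene whose removal most
#' improves the internal criterion, stopping when no removal strictly
#' improves it. The signature never shrinks below one gene. Score
#' ties break toward removing the worse-ranked gene.
#'
#' @inheritParams fsfs
#' @return A `radsig_signature`; the trajectory's first row records
#'   the starting pool score (`action = "start"`).
#' @export
bsfs <- function(ranking, x, labels, C = 10, sigma = 1,
                 criterion = c("misclassification", "log_loss"), k = 5,
                 seed = 1, pool = 30, dataset = NA_character_) {
  criterion <- match.arg(criterion)
  genes <- head(ranking_genes(ranking), pool)
  m <- as_expr_matrix(x)
  score_of <- function(gs) internal_score(m, labels, gs, C = C, sigma = sigma,
                                          criterion = criterion, k = k,
                                          seed = seed)
  current <- genes
  current_score <- score_of(current)
  steps <- list(tibble(step = 0L, action = "start", gene = NA_character_,
                       size = length(current), score = current_score))
  while (length(current) > 1) {
    cand_scores <- vapply(seq_along(current), function(i) {
      score_of(current[-i])
    }, numeric(1))
    # ties toward removing the worse-ranked (later) gene
    best <- length(current) + 1 - which.min(rev(cand_scores))
    if (cand_scores[best] >= current_score) break
    removed <- current[best]
    current <- current[-best]
    current_score <- unname(cand_scores[best])
    steps[[length(steps) + 1]] <- tibble(
      step = length(steps) - 0L, action = "remove", gene = removed,
      size = length(current), score = current_score
    )
  }
  new_signature(current, "BSFS", dataset, C, sigma, criterion,
                current_score, dplyr::bind_rows(steps))
}
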