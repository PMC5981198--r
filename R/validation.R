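#' Performance metrics for dose classification
#'
#' `misclassification()` is the fraction of samples whose predicted
#' class differs from the true class. `goodness_of_fit()` is the mean
#' absolute difference between predicted and true dose in cGy.
#' `multiclass_log_loss()` is `-(1/N) sum_i sum_j y_ij log(p_ij)` in
#' nats, where `y_ij` indicates the true class of sample `i` and
#' `p_ij` is its predicted probability for class `j`.
#'
#' @param truth,pred Dose-label tibbles (`sample_id`, `dose_cGy`) over
#'   the same samples.
#' @param proba Sample-by-class probability matrix as returned by
#'   `predict(model, type = "prob")`; column names are dose classes and
#'   row names sample ids.
#' @return A single number: fraction in \[0, 1\], nats, or cGy.
#' @examples
#' t <- tibble::tibble(sample_id = c("a", "b"), dose_cGy = c(0, 1000))
#' p <- tibble::tibble(sample_id = c("a", "b"), dose_cGy = c(50, 1000))
#' misclassification(t, p) # 0.5
#' goodness_of_fit(t, p)   # 25
#' @export
misclassification <- function(truth, pred) {
  al <- align_label_pair(truth, pred)
  mean(al$truth != al$pred)
}

#' @rdname misclassification
#' @export
goodness_of_fit <- function(truth, pred) {
  al <- align_label_pair(truth, pred)
  mean(abs(al$truth - al$pred))
}

align_label_pair <- function(truth, pred) {
  validate_labels(truth)
  validate_labels(pred)
  if (!setequal(truth$sample_id, pred$sample_id)) {
    abort("truth and prediction cover different sample sets")
  }
  idx <- match(truth$sample_id, pred$sample_id)
  list(truth = truth$dose_cGy, pred = pred$dose_cGy[idx])
}

#' @rdname misclassification
#' @export
multiclass_log_loss <- function(truth, proba) {
  validate_labels(truth)
  stopifnot(is.matrix(proba))
  if (is.null(rownames(proba)) || !setequal(rownames(proba), truth$sample_id)) {
    abort("probability matrix rows must match the truth sample set")
  }
  if (any(abs(rowSums(proba) - 1) > 1e-6)) {
    abort("probability rows must sum to 1")
  }
  p <- pmax(proba, 1e-15)
  doses <- truth$dose_cGy[match(rownames(proba), truth$sample_id)]
  j <- match(as.character(doses), colnames(proba))
  if (anyNA(j)) abort("true class missing from probability matrix columns")
  -mean(log(p[cbind(seq_len(nrow(p)), j)]))
}

#' Confusion matrix over dose classes
#'
#' Rows are true classes, columns predicted classes, over the union of
#' both class sets ordered by dose; row sums equal the per-class sample
#' counts.
#'
#' @inheritParams misclassification
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred) {
  al <- align_label_pair(truth, pred)
  classes <- sort(union(al$truth, al$pred))
  tab <- table(factor(al$truth, levels = classes),
               factor(al$pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = as.character(classes),
                              predicted = as.character(classes)))
  m
}

#' Fraction of errors falling in an adjacent dose class
#'
#' From a confusion matrix over dose-ordered classes, the fraction of
#' misclassified samples whose predicted class is exactly one ordered
#' step from the true class. Returns `NaN` when there are no errors.
#'
#' @param confusion Matrix from [confusion_matrix()].
#' @return Fraction in \[0, 1\] (or `NaN` with no errors).
#' @export
dose_adjacency <- function(confusion) {
  k <- nrow(confusion)
  off <- confusion
  diag(off) <- 0
  adj <- sum(off[abs(row(off) - col(off)) == 1])
  adj / sum(off)
}

#' Stratified k-fold assignment
#'
#' Shuffles samples within each dose class (seeded) and deals them
#' round-robin into `k` folds, starting each class at a rotated fold so
#' balanced classes give equally sized folds. Every class must have at
#' least `k` samples.
#'
#' @param labels Dose-label tibble.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble (`sample_id`, `dose_cGy`, `fold`) with fold indices
#'   in `1..k`.
#' @export
stratified_kfold <- function(labels, k, seed = 1) {
  validate_labels(labels)
  stopifnot(k >= 2)
  counts <- table(labels$dose_cGy)
  if (any(counts < k)) {
    abort(paste0("classes with fewer than k = ", k, " samples: ",
                 paste(names(counts)[counts < k], collapse = ", "),
                 "; use a smaller k"))
  }
  classes <- sort(unique(labels$dose_cGy))
  out <- labels[order(labels$dose_cGy, labels$sample_id), c("sample_id", "dose_cGy")]
  out$fold <- NA_integer_
  local_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(out$dose_cGy == classes[ci])
      idx <- idx[sample.int(length(idx))]
      start <- (ci - 1) %% k
      out$fold[idx] <- ((start + seq_along(idx) - 1) %% k) + 1L
    }
  })
  as_tibble(out)
}

new_validation_report <- function(protocol, per_repeat, confusion, n_samples,
                                  k, seed) {
  summarise_metric <- function(v) {
    c(mean = mean(v), se = sd(v) / sqrt(length(v)))
  }
  structure(
    list(protocol = protocol,
         misclassification = summarise_metric(per_repeat$mc),
         log_loss = summarise_metric(per_repeat$ll),
         goodness_of_fit = summarise_metric(per_repeat$gof),
         confusion = confusion,
         n_samples = n_samples,
         n_repeats = length(per_repeat$mc),
         k = k, seed = seed,
         per_repeat = as_tibble(per_repeat)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v, d = 4) paste0(round(v["mean"], d), " ± ", round(v["se"], d))
  cat("Validation report (", x$protocol, "), ", x$n_samples, " samples, ",
      x$n_repeats, " repeats\n", sep = "")
  cat("  misclassification:", fmt(x$misclassification), "\n")
  cat("  log loss (nats):  ", fmt(x$log_loss), "\n")
  cat("  goodness of fit:  ", fmt(x$goodness_of_fit, 2), "cGy\n")
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) {
  tibble(
    metric = c("misclassification", "log_loss", "goodness_of_fit"),
    mean = c(x$misclassification["mean"], x$log_loss["mean"],
             x$goodness_of_fit["mean"]),
    se = c(x$misclassification["se"], x$log_loss["se"],
           x$goodness_of_fit["se"]),
    unit = c("fraction", "nats", "cGy")
  )
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble(
    protocol = x$protocol,
    misclassification = unname(x$misclassification["mean"]),
    misclassification_se = unname(x$misclassification["se"]),
    log_loss = unname(x$log_loss["mean"]),
    log_loss_se = unname(x$log_loss["se"]),
    goodness_of_fit = unname(x$goodness_of_fit["mean"]),
    goodness_of_fit_se = unname(x$goodness_of_fit["se"]),
    n_samples = x$n_samples, n_repeats = x$n_repeats
  )
}

#' @export
autoplot.validation_report <- function(object, ...) {
  conf <- as_tibble(as.data.frame(object$confusion))
  names(conf) <- c("true", "predicted", "count")
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$predicted, y = .data$true,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$count, 1))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted dose (cGy)", y = "true dose (cGy)",
                  title = paste0("Confusion (", object$protocol, " validation)")) +
    ggplot2::theme_minimal()
}

signature_genes <- function(signature) {
  if (inherits(signature, "radsig_signature")) signature$genes
  else as.character(signature)
}

check_signature_eligible <- function(m, signature) {
  genes <- signature_genes(signature)
  missing <- setdiff(canonical_symbol(genes), canonical_symbol(rownames(m)))
  if (length(missing) > 0) {
    abort(paste0("signature not contained in dataset; absent genes: ",
                 paste(missing, collapse = ", ")))
  }
  m[match(canonical_symbol(genes), canonical_symbol(rownames(m))), , drop = FALSE]
}

#' Signature-centric stratified k-fold validation
#'
#' Validates a signature on one dataset by repeated stratified k-fold
#' partitioning: in each repeat every fold is predicted by a model
#' trained on the remaining folds, metrics are computed on the pooled
#' predictions, and the report gives each metric's mean and standard
#' error over repeats. Every signature gene must be present in the
#' dataset (the eligibility rule that also gates cross-platform use).
#'
#' @param x Gene-level expression tibble/matrix of the validation
#'   dataset.
#' @param labels Dose labels for its samples.
#' @param signature Character vector of genes or a `radsig_signature`.
#' @param k Number of folds.
#' @param C,sigma SVM hyper-parameters used for the fold models.
#' @param repeats Number of independent repartitions (>= 2).
#' @param seed Integer seed; repeat `r` uses `seed + r - 1`.
#' @return A `validation_report` (confusion matrix averaged over
#'   repeats).
#' @export
kfold_validate <- function(x, labels, signature, k = 5, C = 10, sigma = 1,
                           repeats = 20, seed = 1) {
  stopifnot(repeats >= 2)
  m <- check_signature_eligible(as_expr_matrix(x), signature)
  labels <- labels[labels$sample_id %in% colnames(m), ]
  mc <- ll <- gof <- numeric(repeats)
  conf <- NULL
  for (r in seq_len(repeats)) {
    folds <- stratified_kfold(labels, k = k, seed = seed + r - 1)
    res <- run_kfold_round(m, folds, C = C, sigma = sigma)
    mc[r] <- misclassification(labels, res$pred)
    ll[r] <- multiclass_log_loss(labels, res$proba)
    gof[r] <- goodness_of_fit(labels, res$pred)
    cm <- confusion_matrix(labels, res$pred)
    conf <- if (is.null(conf)) cm else conf + cm
  }
  new_validation_report("kfold", list(mc = mc, ll = ll, gof = gof),
                        conf / repeats, n_samples = nrow(labels),
                        k = k, seed = seed)
}

# One pass over all folds: returns pooled predictions and probabilities.
run_kfold_round <- function(m, folds, C, sigma) {
  k <- max(folds$fold)
  preds <- vector("list", k)
  probas <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds$sample_id[folds$fold == f]
    train_ids <- folds$sample_id[folds$fold != f]
    train_labels <- folds[folds$fold != f, c("sample_id", "dose_cGy")]
    model <- fit_dose_svm(m[, train_ids, drop = FALSE], train_labels,
                          C = C, sigma = sigma)
    test_m <- m[, test_ids, drop = FALSE]
    pr <- predict(model, test_m, type = "prob")
    preds[[f]] <- proba_to_pred(pr, as.numeric(colnames(pr)))
    probas[[f]] <- pr
  }
  proba <- do.call(rbind, probas)
  list(pred = dplyr::bind_rows(preds), proba = proba)
}

proba_to_pred <- function(proba, classes) {
  pick <- apply(proba, 1, function(p) which(p >= max(p) - 1e-12)[1])
  tibble(sample_id = rownames(proba), dose_cGy = classes[pick])
}

#' Signature-restricted quantile normalization
#'
#' Restricts both matrices to the signature genes and quantile
#' normalizes all samples (columns) together: each sample's values are
#' replaced by the per-rank means of the pooled sorted sample vectors
#' (ties receive the average of the tied span), so afterwards every
#' sample has an identical sorted value vector. With
#' `reference = "train"` the reference distribution is built from the
#' training samples only and test samples are mapped onto it.
#'
#' @param train,test Gene-level expression tibbles/matrices.
#' @param signature Genes to normalize over.
#' @param reference `"pooled"` (default) or `"train"`.
#' @return List with normalized `train` and `test` expression tibbles
#'   restricted to the signature genes.
#' @export
quantile_normalize <- function(train, test, signature,
                               reference = c("pooled", "train")) {
  reference <- match.arg(reference)
  genes <- signature_genes(signature)
  mtr <- check_signature_eligible(as_expr_matrix(train), genes)
  mte <- check_signature_eligible(as_expr_matrix(test), genes)
  if (reference == "pooled") {
    pooled <- cbind(mtr, mte)
    norm <- limma::normalizeQuantiles(pooled, ties = TRUE)
    dimnames(norm) <- dimnames(pooled)
    out_tr <- norm[, seq_len(ncol(mtr)), drop = FALSE]
    out_te <- norm[, ncol(mtr) + seq_len(ncol(mte)), drop = FALSE]
  } else {
    out_tr <- limma::normalizeQuantiles(mtr, ties = TRUE)
    dimnames(out_tr) <- dimnames(mtr)
    ref <- rowMeans(apply(mtr, 2, sort))
    out_te <- apply(mte, 2, function(v) {
      out <- numeric(length(v))
      out[order(v)] <- ref
      # average reference values over tied spans
      stats::ave(out, v, FUN = mean)
    })
    dimnames(out_te) <- dimnames(mte)
  }
  list(train = as_expr_tbl(out_tr), test = as_expr_tbl(out_te))
}

#' Traditional (model-centric) external validation
#'
#' Quantile normalizes train and test over the signature genes, fits
#' one SVM on the training dataset and predicts the test dataset.
#' Train and test must carry the same dose class set. The fit is
#' deterministic, so repeats exist only to populate the report's
#' standard-error fields (they are 0).
#'
#' @param train,test Gene-level expression tibbles/matrices.
#' @param train_labels,test_labels Dose labels for each dataset.
#' @inheritParams kfold_validate
#' @param normalize Apply signature-restricted quantile normalization
#'   (default) or validate on the raw values.
#' @param reference Passed to [quantile_normalize()].
#' @return A `validation_report`.
#' @export
traditional_validate <- function(train, train_labels, test, test_labels,
                                 signature, C = 10, sigma = 1, repeats = 2,
                                 seed = 1, normalize = TRUE,
                                 reference = "pooled") {
  stopifnot(repeats >= 2)
  if (!setequal(train_labels$dose_cGy, test_labels$dose_cGy)) {
    abort("train and test must share the same dose class set")
  }
  genes <- signature_genes(signature)
  if (normalize) {
    qn <- quantile_normalize(train, test, genes, reference = reference)
    mtr <- as_expr_matrix(qn$train)
    mte <- as_expr_matrix(qn$test)
  } else {
    mtr <- check_signature_eligible(as_expr_matrix(train), genes)
    mte <- check_signature_eligible(as_expr_matrix(test), genes)
  }
  mc <- ll <- gof <- numeric(repeats)
  conf <- NULL
  for (r in seq_len(repeats)) {
    model <- fit_dose_svm(mtr, train_labels, C = C, sigma = sigma)
    proba <- predict(model, mte, type = "prob")
    pred <- proba_to_pred(proba, model$classes)
    mc[r] <- misclassification(test_labels, pred)
    ll[r] <- multiclass_log_loss(test_labels, proba)
    gof[r] <- goodness_of_fit(test_labels, pred)
    cm <- confusion_matrix(test_labels, pred)
    conf <- if (is.null(conf)) cm else conf + cm
  }
  new_validation_report("traditional", list(mc = mc, ll = ll, gof = gof),
                        conf / repeats, n_samples = nrow(test_labels),
                        k = NA_integer_, seed = seed)
}

#' Serialize a validation report
#'
#' `write_validation_report()` writes the full report (protocol,
#' metric means and standard errors, confusion matrix, seeds) as JSON;
#' the flat one-row form for tabulation across signatures is
#' `glance()`.
#'
#' @param report A `validation_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  payload <- list(
    protocol = report$protocol,
    misclassification = as.list(report$misclassification),
    log_loss = as.list(report$log_loss),
    goodness_of_fit = as.list(report$goodness_of_fit),
    confusion = list(classes = rownames(report$confusion),
                     counts = unname(apply(report$confusion, 1, as.list))),
    n_samples = report$n_samples, n_repeats = report$n_repeats,
    k = report$k, seed = report$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
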