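# Platt sigmoid fit: P(y=1 | f) = 1/(1 + exp(A*f + B)), fitted by
# minimizing cross-entropy against Platt's smoothed targets
# t+ = (n+ + 1)/(n+ + 2), t- = 1/(n- + 2). Deterministic (BFGS from
# Platt's standard initialization).
platt_fit <- function(f, y) {
  np <- sum(y)
  nn <- length(y) - np
  t_i <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # stable log(1+exp(z)) and cross-entropy
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t_i * lse + (1 - t_i) * (lse - z))
  }
  init <- c(0, log((nn + 1) / (np + 1)))
  fit <- optim(init, nll, method = "BFGS", control = list(maxit = 200))
  c(A = fit$par[1], B = fit$par[2])
}

platt_prob <- function(f, par) {
  stats::plogis(-(par[1] * f + par[2]))
}

# Wu & Lin (2004) second method: couple pairwise probabilities r[i, j]
# (probability of class i in the i-vs-j problem) into a class
# distribution. Deterministic fixed-point iteration as in libsvm.
couple_pairwise <- function(r, eps = 1e-12, max_iter = 200) {
  k <- nrow(r)
  if (k == 2) {
    p <- c(r[1, 2], r[2, 1])
    return(p / sum(p))
  }
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
  }
  p <- rep(1 / k, k)
  for (iter in seq_len(max_iter)) {
    Qp <- drop(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p
}

#' Fit a multi-class RBF support vector machine for dose classes
#'
#' Trains a one-vs-one SVM with the Gaussian radial basis kernel
#' `K(u, v) = exp(-||u - v||^2 / (2 sigma^2))` on samples (columns) of
#' a z-scored expression table, using box constraint `C`. Class
#' probabilities come from Platt sigmoid calibration of each pairwise
#' classifier's training decision values, coupled by the Wu-Lin
#' pairwise method; the whole fit is deterministic.
#'
#' @param x Expression tibble/matrix restricted to the signature genes
#'   under evaluation.
#' @param labels Dose labels (`sample_id`, `dose_cGy`).
#' @param C Box constraint (> 0): how severely training
#'   misclassifications are penalized.
#' @param sigma Kernel scale (> 0): width of the Gaussian basis
#'   function.
#' @return An object of class `radsig_svm` holding the fitted machine,
#'   the dose class set, `(C, sigma)` and the ordered training gene
#'   list.
#' @export
fit_dose_svm <- function(x, labels, C = 10, sigma = 1) {
  stopifnot(C > 0, sigma > 0)
  m <- as_expr_matrix(x)
  doses <- aligned_doses(m, labels)
  classes <- sort(unique(doses))
  if (length(classes) < 2) abort("training data contain a single dose class")
  counts <- table(doses)
  if (any(counts < 2)) abort("every dose class needs at least 2 training samples")
  y <- dose_factor(doses, classes)
  X <- t(m)
  fit <- e1071::svm(X, y, scale = FALSE, type = "C-classification",
                    kernel = "radial", gamma = 1 / (2 * sigma^2), cost = C)
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  pairs <- colnames(dv)
  calib <- lapply(seq_along(pairs), function(p) {
    nm <- strsplit(pairs[p], "/", fixed = TRUE)[[1]]
    idx <- y %in% nm
    platt_fit(dv[idx, p], as.integer(as.character(y[idx]) == nm[1]))
  })
  names(calib) <- pairs
  structure(
    list(fit = fit, classes = classes, C = C, sigma = sigma,
         genes = rownames(m), calibration = calib, pair_names = pairs),
    class = "radsig_svm"
  )
}

#' @export
print.radsig_svm <- function(x, ...) {
  cat("Multi-class RBF SVM dose classifier\n")
  cat("  classes (cGy):", paste(x$classes, collapse = ", "), "\n")
  cat("  C =", x$C, " sigma =", x$sigma, "\n")
  cat("  genes:", length(x$genes), "\n")
  invisible(x)
}

#' @export
glance.radsig_svm <- function(x, ...) {
  tibble(C = x$C, sigma = x$sigma, n_classes = length(x$classes),
         n_genes = length(x$genes),
         n_support_vectors = nrow(x$fit$SV))
}

check_model_genes <- function(object, m) {
  missing <- setdiff(object$genes, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("test data lack model genes: ", paste(missing, collapse = ", ")))
  }
  m[object$genes, , drop = FALSE]
}

#' Predict dose classes or class probabilities
#'
#' `type = "prob"` returns the sample-by-class probability matrix
#' (rows sum to 1, entries clipped to at least 1e-15); `type = "class"`
#' returns the per-sample argmax of those probabilities as a dose-label
#' tibble, breaking exact ties toward the lower dose.
#'
#' @param object Fitted [fit_dose_svm()] model.
#' @param newdata Expression tibble/matrix containing all training
#'   genes.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return A tibble (`sample_id`, `dose_cGy`) or a numeric matrix with
#'   one column per dose class.
#' @export
predict.radsig_svm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- check_model_genes(object, as_expr_matrix(newdata))
  X <- t(m)
  dv <- attr(predict(object$fit, X, decision.values = TRUE), "decision.values")
  k <- length(object$classes)
  cls <- as.character(object$classes)
  n <- nrow(X)
  proba <- matrix(0, n, k, dimnames = list(rownames(X), cls))
  r <- matrix(0, k, k)
  pair_idx <- lapply(object$pair_names, function(p) {
    match(strsplit(p, "/", fixed = TRUE)[[1]], cls)
  })
  for (s in seq_len(n)) {
    for (p in seq_along(object$pair_names)) {
      ij <- pair_idx[[p]]
      pr <- platt_prob(dv[s, p], object$calibration[[p]])
      pr <- min(max(pr, 1e-7), 1 - 1e-7)
      r[ij[1], ij[2]] <- pr
      r[ij[2], ij[1]] <- 1 - pr
    }
    proba[s, ] <- couple_pairwise(r)
  }
  proba <- pmin(pmax(proba, 1e-15), 1 - 1e-15)
  proba <- proba / rowSums(proba)
  if (type == "prob") return(proba)
  # argmax with ties toward the lower dose (classes are dose-sorted)
  pick <- apply(proba, 1, function(p) which(p >= max(p) - 1e-12)[1])
  tibble(sample_id = rownames(X), dose_cGy = object$classes[pick])
}

#' The C/sigma grid of candidate SVM hyper-parameters
#'
#' All pairs with `C` and `sigma` in `{10^0, ..., 10^5}` such that
#' `C >= sigma`: 21 candidates.
#'
#' @return Tibble with columns `C` and `sigma`.
#' @export
svm_grid <- function() {
  powers <- 10^(0:5)
  grid <- expand.grid(sigma = powers, C = powers)[, 2:1]
  out <- as_tibble(grid[grid$C >= grid$sigma, ])
  out[order(out$C, -out$sigma), ]
}

#' Grid search over (C, sigma)
#'
#' Scores every [svm_grid()] candidate by stratified k-fold
#' cross-validation on the training data under the chosen criterion
#' and returns the best pair. Ties break toward smaller `C`, then
#' larger `sigma` (the least complex machine).
#'
#' @inheritParams fit_dose_svm
#' @param criterion `"misclassification"` or `"log_loss"` (both: lower
#'   is better).
#' @param k Folds for the internal cross-validation.
#' @param seed Integer seed for the fold assignment.
#' @param grid Candidate tibble; defaults to the full 21-pair lattice.
#' @return One-row tibble: `C`, `sigma`, `score`.
#' @export
grid_search <- function(x, labels, criterion = c("misclassification", "log_loss"),
                        k = 5, seed = 1, grid = svm_grid()) {
  criterion <- match.arg(criterion)
  m <- as_expr_matrix(x)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    internal_score(m, labels, genes = rownames(m), C = grid$C[i],
                   sigma = grid$sigma[i], criterion = criterion,
                   k = k, seed = seed)
  }, numeric(1))
  ord <- order(scores, grid$C, -grid$sigma)
  tibble(C = grid$C[ord[1]], sigma = grid$sigma[ord[1]], score = scores[ord[1]])
}

#' Save and restore a fitted dose classifier
#'
#' The archive stores a format version, the class set, hyper-parameters,
#' gene list, calibration coefficients and the fitted machine.
#'
#' @param model A `radsig_svm`.
#' @param path File path for the archive.
#' @return `save_dose_svm()` the path, invisibly; `load_dose_svm()` the
#'   restored `radsig_svm`.
#' @export
save_dose_svm <- function(model, path) {
  stopifnot(inherits(model, "radsig_svm"))
  saveRDS(list(format = "radsig_svm/1", model = model), path)
  invisible(path)
}

#' @rdname save_dose_svm
#' @export
load_dose_svm <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "radsig_svm/1")) {
    abort("not a radsig_svm archive (or an unsupported version)")
  }
  obj$model
}

#' Write predictions with class probabilities as TSV
#'
#' One row per sample: `sample_id`, `predicted_cGy`, then one
#' probability column per dose class (`p_<dose>`).
#'
#' @inheritParams predict.radsig_svm
#' @param path Output TSV path.
#' @return The prediction tibble, invisibly.
#' @export
write_predictions <- function(object, newdata, path) {
  proba <- predict(object, newdata, type = "prob")
  pred <- proba_to_pred(proba, object$classes)
  out <- dplyr::bind_cols(
    pred,
    as_tibble(proba, .name_repair = ~ paste0("p_", colnames(proba)))
  )
  names(out)[2] <- "predicted_cGy"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
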