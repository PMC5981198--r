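mklab <- function(doses) {
  tibble::tibble(sample_id = sprintf("s%02d", seq_along(doses)), dose_cGy = doses)
}

test_that("misclassification and goodness of fit follow their definitions", {
  truth <- mklab(c(0, 0, 50, 50, 200, 200, 1000, 1000))
  expect_equal(misclassification(truth, truth), 0)
  flip <- truth
  flip$dose_cGy <- rev(truth$dose_cGy)
  expect_equal(misclassification(truth, flip), 1)
  two_wrong <- truth
  two_wrong$dose_cGy[c(1, 5)] <- c(50, 50)
  expect_equal(misclassification(truth, two_wrong), 0.25)

  t2 <- mklab(c(0, 1000))
  p2 <- mklab(c(50, 1000))
  expect_equal(goodness_of_fit(t2, t2), 0)
  expect_equal(goodness_of_fit(t2, p2), 25)
  expect_equal(goodness_of_fit(p2, t2), 25) # symmetric
  expect_error(misclassification(truth, mklab(c(0, 0))), "different sample sets")
})

test_that("multi-class log loss equals the formula and its closed forms", {
  truth <- mklab(c(0, 50))
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                    dimnames = list(truth$sample_id, c("0", "50")))
  expect_equal(multiclass_log_loss(truth, perfect), 0, tolerance = 1e-12)

  # uniform predictor = ln M for any M
  for (M in 2:4) {
    classes <- c(0, 50, 200, 1000)[1:M]
    tr <- mklab(rep(classes, 2))
    unif <- matrix(1 / M, nrow(tr), M,
                   dimnames = list(tr$sample_id, as.character(classes)))
    expect_equal(multiclass_log_loss(tr, unif), log(M), tolerance = 1e-12)
  }

  # N = 2 worked example: true-class probabilities 0.8 and 0.5
  proba <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, byrow = TRUE,
                  dimnames = list(truth$sample_id, c("0", "50")))
  expect_equal(multiclass_log_loss(truth, proba), -(log(0.8) + log(0.5)) / 2,
               tolerance = 1e-12)
  bad <- proba
  bad[1, ] <- c(0.7, 0.6)
  expect_error(multiclass_log_loss(truth, bad), "sum to 1")
})

test_that("confusion matrix conserves counts and supports the adjacency statistic", {
  truth <- mklab(c(0, 0, 50, 50, 200, 200, 1000, 1000))
  expect_true(all(confusion_matrix(truth, truth) ==
                    diag(2, 4) - diag(0, 4))) # diagonal of 2s
  pred <- truth
  pred$dose_cGy <- c(0, 50, 50, 50, 0, 200, 1000, 1000)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 8)
  expect_equal(unname(rowSums(cm)), c(2, 2, 2, 2))
  # errors: 0->50 (adjacent), 200->0 (two steps): 1 of 2 adjacent
  expect_equal(dose_adjacency(cm), 0.5)
})

test_that("stratified folds are disjoint, covering, and class-balanced for many (n, k, seed)", {
  for (k in 2:4) {
    for (seed in c(1, 99)) {
      labels <- mklab(rep(c(0, 50, 200), times = c(7, 9, 12)))
      folds <- stratified_kfold(labels, k = k, seed = seed)
      expect_setequal(folds$sample_id, labels$sample_id)
      expect_equal(nrow(folds), nrow(labels))
      counts <- table(folds$dose_cGy, folds$fold)
      expect_true(all(apply(counts, 1, function(r) diff(range(r)) <= 1)))
    }
  }
  # 12 samples, 3 balanced classes, k = 3: folds of exactly 4, >= 1 per class
  labels <- mklab(rep(c(0, 50, 200), each = 4))
  folds <- stratified_kfold(labels, k = 3, seed = 5)
  expect_equal(unname(table(folds$fold)), rep(4L, 3), ignore_attr = TRUE)
  expect_true(all(table(folds$dose_cGy, folds$fold) >= 1))
  expect_error(stratified_kfold(labels, k = 5), "smaller k")
})

test_that("k-fold validation is perfect for an informative signature and chance-level for noise", {
  toy <- toy_dataset(n_per_class = 12, n_genes = 3, n_inf = 2, sep = 5, seed = 1)
  rep1 <- kfold_validate(toy$expr, toy$labels, c("G01", "G02"), k = 4,
                         C = 100, sigma = 1, repeats = 2, seed = 1)
  expect_equal(unname(rep1$misclassification["mean"]), 0)
  expect_equal(unname(rep1$misclassification["se"]), 0)
  expect_equal(unname(rep1$goodness_of_fit["mean"]), 0)

  # uninformative limit: average over noise datasets (any single dataset
  # has spurious structure a k-fold estimate legitimately picks up)
  mets <- sapply(1:8, function(s) {
    noise <- toy_dataset(n_per_class = 15, n_genes = 3, n_inf = 0, seed = 200 + s)
    r <- kfold_validate(noise$expr, noise$labels, c("G01", "G02"), k = 5,
                        C = 1, sigma = 2, repeats = 3, seed = s)
    c(r$misclassification[["mean"]], r$log_loss[["mean"]])
  })
  expect_lt(abs(mean(mets[1, ]) - 0.5), 0.1)
  expect_lt(abs(mean(mets[2, ]) - log(2)), 0.1)

  expect_error(kfold_validate(toy$expr, toy$labels, c("G01", "NOPE")),
               "NOPE")
  expect_error(kfold_validate(toy$expr, toy$labels, "G01", repeats = 1),
               "repeats")
})

test_that("no fold prediction can depend on a model trained with that sample", {
  labels <- mklab(rep(c(0, 200), each = 8))
  folds <- stratified_kfold(labels, k = 4, seed = 3)
  for (f in 1:4) {
    test_ids <- folds$sample_id[folds$fold == f]
    train_ids <- folds$sample_id[folds$fold != f]
    expect_length(intersect(test_ids, train_ids), 0)
  }
})

test_that("quantile normalization matches the worked example, is idempotent, equalizes samples", {
  m_tr <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  m_te <- matrix(c(2, 4, 6), 3, 1, dimnames = list(c("A", "B", "C"), "t1"))
  qn <- quantile_normalize(as_expr_tbl(m_tr), as_expr_tbl(m_te), c("A", "B", "C"))
  expect_equal(as_expr_matrix(qn$train)[, 1], c(A = 1.5, B = 3, C = 4.5))
  expect_equal(as_expr_matrix(qn$test)[, 1], c(A = 1.5, B = 3, C = 4.5))

  set.seed(4)
  tr <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  te <- matrix(rnorm(24, 2, 3), 8, 3, dimnames = list(paste0("g", 1:8), paste0("t", 1:3)))
  qn1 <- quantile_normalize(as_expr_tbl(tr), as_expr_tbl(te), paste0("g", 1:8))
  all_cols <- cbind(as_expr_matrix(qn1$train), as_expr_matrix(qn1$test))
  sorted <- apply(all_cols, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1:7)], ignore_attr = TRUE) # identical sorted vectors
  qn2 <- quantile_normalize(qn1$train, qn1$test, paste0("g", 1:8))
  expect_equal(as_expr_matrix(qn2$train), as_expr_matrix(qn1$train))
  expect_equal(as_expr_matrix(qn2$test), as_expr_matrix(qn1$test))

  expect_error(quantile_normalize(as_expr_tbl(tr), as_expr_tbl(te), "missing_gene"),
               "absent genes")

  # train-only reference: test samples are mapped onto the training
  # distribution; every output sample shares the train reference vector
  qn3 <- quantile_normalize(as_expr_tbl(tr), as_expr_tbl(te), paste0("g", 1:8),
                            reference = "train")
  ref <- sort(rowMeans(apply(tr, 2, sort)))
  cols3 <- cbind(as_expr_matrix(qn3$train), as_expr_matrix(qn3$test))
  for (j in seq_len(ncol(cols3))) {
    expect_equal(unname(sort(cols3[, j])), unname(ref))
  }
})

test_that("traditional validation is consistent on identical data and enforces shared classes", {
  # opposite-direction responders: the class signal survives per-sample
  # quantile normalization through the within-sample rank pattern
  set.seed(5)
  n <- 20
  doses <- rep(c(0, 200), each = n / 2)
  hi <- ifelse(doses == 200, 5, 0)
  lo <- ifelse(doses == 0, 5, 0)
  m <- rbind(UP = hi + rnorm(n, sd = 0.5), DOWN = -hi + rnorm(n, sd = 0.5),
             UP0 = lo + rnorm(n, sd = 0.5), DOWN0 = -lo + rnorm(n, sd = 0.5))
  colnames(m) <- sprintf("s%02d", 1:n)
  labels <- tibble::tibble(sample_id = colnames(m), dose_cGy = doses)
  expr <- as_expr_tbl(m)
  rep1 <- traditional_validate(expr, labels, expr, labels,
                               c("UP", "DOWN", "UP0", "DOWN0"), C = 100, sigma = 1)
  expect_equal(unname(rep1$misclassification["mean"]), 0)

  other <- labels
  other$dose_cGy[other$dose_cGy == 200] <- 1000
  expect_error(
    traditional_validate(expr, labels, expr, other, c("UP", "DOWN")),
    "same dose class set"
  )
})

test_that("validation reports tidy and glance into the tabular formats", {
  toy <- toy_dataset(n_per_class = 8, n_genes = 2, n_inf = 1, sep = 3, seed = 6)
  rep1 <- kfold_validate(toy$expr, toy$labels, c("G01", "G02"), k = 4,
                         C = 10, sigma = 1, repeats = 3, seed = 6)
  td <- tidy(rep1)
  expect_equal(td$metric, c("misclassification", "log_loss", "goodness_of_fit"))
  expect_true(all(is.finite(td$mean)))
  g <- glance(rep1)
  expect_equal(g$n_repeats, 3)
  expect_equal(g$n_samples, 16)
  # confusion row sums equal per-class counts (averaged over repeats)
  expect_equal(unname(rowSums(rep1$confusion)), c(8, 8))
})

test_that("validation reports serialize to JSON with metrics and confusion", {
  dir <- withr::local_tempdir()
  toy <- toy_dataset(n_per_class = 8, n_genes = 2, n_inf = 1, sep = 4, seed = 13)
  rep1 <- kfold_validate(toy$expr, toy$labels, c("G01", "G02"), k = 4,
                         repeats = 2, seed = 13)
  path <- file.path(dir, "report.json")
  write_validation_report(rep1, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$protocol, "kfold")
  expect_equal(back$misclassification$mean,
               unname(rep1$misclassification["mean"]))
  expect_length(back$confusion$counts, 2)
})
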