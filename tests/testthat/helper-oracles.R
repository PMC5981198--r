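# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's code paths: mutual information
# goes through entropies, mRMR/greedy selection re-evaluates every
# candidate from scratch with plain loops.

# --- fixtures ---------------------------------------------------------

# Tiny labelled expression matrix: `sep` controls class separation of the
# first `n_inf` genes; remaining genes are pure noise.
toy_dataset <- function(n_per_class = 9, classes = c(0, 200), n_genes = 4,
                        n_inf = 1, sep = 3, seed = 1, sd = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  doses <- rep(classes, each = n_per_class)
  m <- matrix(rnorm(n_genes * n, sd = sd), n_genes, n,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  for (g in seq_len(n_inf)) {
    m[g, ] <- m[g, ] + sep * (match(doses, classes) - 1)
  }
  list(expr = radsig::as_expr_tbl(m),
       m = m,
       labels = tibble::tibble(sample_id = colnames(m), dose_cGy = doses))
}

# Random discrete instance for mRMR oracle checks.
random_discrete_instance <- function(seed, max_genes = 12, max_samples = 40) {
  set.seed(seed)
  ng <- sample(3:max_genes, 1)
  ns <- sample(10:max_samples, 1)
  nc <- sample(2:4, 1)
  m <- matrix(sample(c(-1L, 0L, 1L), ng * ns, replace = TRUE), ng, ns,
              dimnames = list(sprintf("g%02d", seq_len(ng)),
                              sprintf("s%02d", seq_len(ns))))
  doses <- sample(c(0, 50, 200, 1000)[seq_len(nc)], ns, replace = TRUE)
  # guarantee >= 2 classes realized
  doses[1:2] <- c(0, 50)
  list(m = m, labels = tibble::tibble(sample_id = colnames(m), dose_cGy = doses))
}

# --- oracles ----------------------------------------------------------

# MI via entropies H(X) + H(Y) - H(X, Y), in nats.
oracle_mi <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  ent(x) + ent(y) - ent(paste(x, y, sep = "\r"))
}

# Exhaustive per-step MID evaluation (brute force, no caching).
oracle_mid_rank <- function(m, doses, n_select = nrow(m)) {
  genes <- rownames(m)
  selected <- character(0)
  for (step in seq_len(n_select)) {
    remaining <- setdiff(genes, selected)
    rel <- vapply(remaining, function(g) oracle_mi(m[g, ], doses), numeric(1))
    red <- vapply(remaining, function(g) {
      if (length(selected) == 0) return(0)
      mean(vapply(selected, function(j) oracle_mi(m[g, ], m[j, ]), numeric(1)))
    }, numeric(1))
    score <- rel - red
    tol <- 1e-9
    cand <- remaining[score >= max(score) - tol]
    relc <- rel[match(cand, remaining)]
    cand <- cand[relc >= max(relc) - tol]
    selected <- c(selected, sort(cand)[1])
  }
  selected
}

# Fold-pooled criterion evaluated with plain loops (fits the package's
# SVM but re-derives the cross-validation bookkeeping independently).
oracle_cv_score <- function(m, labels, genes, C, sigma, criterion, k, seed) {
  folds <- radsig::stratified_kfold(labels, k = k, seed = seed)
  sub <- m[genes, , drop = FALSE]
  pred <- numeric(0)
  truth <- numeric(0)
  ll_terms <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds[folds$fold != f, ]
    te <- folds[folds$fold == f, ]
    fit <- radsig::fit_dose_svm(sub[, tr$sample_id, drop = FALSE],
                                tr[, c("sample_id", "dose_cGy")],
                                C = C, sigma = sigma)
    pr <- predict(fit, sub[, te$sample_id, drop = FALSE], type = "prob")
    cls <- as.numeric(colnames(pr))
    pick <- apply(pr, 1, function(p) which(p >= max(p) - 1e-12)[1])
    pred <- c(pred, cls[pick])
    truth <- c(truth, te$dose_cGy[match(rownames(pr), te$sample_id)])
    j <- match(as.character(te$dose_cGy[match(rownames(pr), te$sample_id)]),
               colnames(pr))
    ll_terms <- c(ll_terms, -log(pmax(pr[cbind(seq_len(nrow(pr)), j)], 1e-15)))
  }
  if (criterion == "misclassification") mean(pred != truth) else mean(ll_terms)
}

# Brute-force greedy forward selection.
oracle_fsfs <- function(pool, m, labels, C, sigma, criterion, k, seed) {
  current <- character(0)
  score <- Inf
  path <- list()
  repeat {
    cand <- setdiff(pool, current)
    if (length(cand) == 0) break
    sc <- vapply(cand, function(g) {
      oracle_cv_score(m, labels, c(current, g), C, sigma, criterion, k, seed)
    }, numeric(1))
    b <- which.min(sc)
    if (length(current) > 0 && sc[b] >= score) break
    current <- c(current, cand[b])
    score <- unname(sc[b])
    path[[length(path) + 1]] <- list(gene = cand[b], score = score)
  }
  list(genes = current, score = score, path = path)
}

# Brute-force greedy backward elimination.
oracle_bsfs <- function(pool, m, labels, C, sigma, criterion, k, seed) {
  current <- pool
  score <- oracle_cv_score(m, labels, current, C, sigma, criterion, k, seed)
  path <- list()
  while (length(current) > 1) {
    sc <- vapply(seq_along(current), function(i) {
      oracle_cv_score(m, labels, current[-i], C, sigma, criterion, k, seed)
    }, numeric(1))
    b <- length(current) + 1 - which.min(rev(sc))
    if (sc[b] >= score) break
    path[[length(path) + 1]] <- list(gene = current[b], score = unname(sc[b]))
    current <- current[-b]
    score <- unname(sc[b])
  }
  list(genes = current, score = score, path = path)
}

# Exhaustive prefix evaluation for CSFS.
oracle_csfs <- function(ranked, m, labels, C, sigma, criterion, k, seed) {
  scores <- vapply(seq_along(ranked), function(p) {
    oracle_cv_score(m, labels, ranked[seq_len(p)], C, sigma, criterion, k, seed)
  }, numeric(1))
  best <- which.min(scores)
  list(genes = ranked[seq_len(best)], score = scores[best], scores = scores)
}
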