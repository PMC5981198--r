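test_that("internal score is 0 for a perfectly informative gene and near chance for noise", {
  # class-determined gene
  toy <- toy_dataset(n_per_class = 10, n_genes = 3, n_inf = 1, sep = 6, seed = 1)
  expect_equal(internal_score(toy$expr, toy$labels, "G01", C = 100, sigma = 1,
                              criterion = "misclassification", k = 5, seed = 1), 0)

  # pure noise, 2 balanced classes: misclassification ~ 0.5, log loss ~ ln 2
  mcs <- lls <- numeric(20)
  for (s in 1:20) {
    noise <- toy_dataset(n_per_class = 15, n_genes = 2, n_inf = 0, seed = 100 + s)
    mcs[s] <- internal_score(noise$expr, noise$labels, c("G01", "G02"),
                             C = 1, sigma = 2,
                             criterion = "misclassification", k = 5, seed = s)
    lls[s] <- internal_score(noise$expr, noise$labels, c("G01", "G02"),
                             C = 1, sigma = 2,
                             criterion = "log_loss", k = 5, seed = s)
  }
  expect_lt(abs(mean(mcs) - 0.5), 0.15)
  expect_lt(abs(mean(lls) - log(2)), 0.1)
})

test_that("internal score demands enough samples per class for the fold count", {
  toy <- toy_dataset(n_per_class = 4, seed = 2)
  expect_error(internal_score(toy$expr, toy$labels, "G01", k = 5),
               "smaller k")
})

test_that("CSFS evaluates every prefix and returns the best (shortest on ties)", {
  # genes ranked 1-2 jointly sufficient, later genes noise
  set.seed(3)
  n <- 40
  doses <- rep(c(0, 200), each = n / 2)
  m <- rbind(
    A = ifelse(doses == 0, -1, 1) * 0.6 + rnorm(n, sd = 0.8),
    B = ifelse(doses == 0, 1, -1) * 0.6 + rnorm(n, sd = 0.8),
    C = rnorm(n), D = rnorm(n), E = rnorm(n)
  )
  colnames(m) <- sprintf("s%02d", 1:n)
  labels <- tibble::tibble(sample_id = colnames(m), dose_cGy = doses)
  ranked <- c("A", "B", "C", "D", "E")
  sig <- csfs(ranked, as_expr_tbl(m), labels, C = 10, sigma = 1,
              criterion = "misclassification", k = 5, seed = 4)
  traj <- tidy(sig)
  expect_equal(nrow(traj), 5)
  oracle <- oracle_csfs(ranked, m, labels, C = 10, sigma = 1,
                        criterion = "misclassification", k = 5, seed = 4)
  expect_identical(sig$genes, oracle$genes)
  expect_equal(traj$score, oracle$scores)
  expect_equal(sig$score, oracle$score)

  single <- csfs("A", as_expr_tbl(m), labels, k = 5, seed = 4)
  expect_identical(single$genes, "A")
  expect_equal(nrow(tidy(single)), 1)
})

test_that("FSFS first accepts the best singleton and keeps a non-empty signature on pure noise", {
  toy <- toy_dataset(n_per_class = 10, n_genes = 5, n_inf = 1, sep = 4, seed = 5)
  sig <- fsfs(paste0("G0", 1:5), toy$expr, toy$labels, C = 10, sigma = 1,
              k = 5, seed = 5)
  singletons <- sapply(paste0("G0", 1:5), function(g) {
    internal_score(toy$expr, toy$labels, g, C = 10, sigma = 1, k = 5, seed = 5)
  })
  expect_identical(tidy(sig)$gene[1], names(which.min(singletons)))

  noise <- toy_dataset(n_per_class = 10, n_genes = 4, n_inf = 0, seed = 6)
  nsig <- fsfs(paste0("G0", 1:4), noise$expr, noise$labels, k = 5, seed = 6)
  expect_gte(length(nsig$genes), 1)
})

test_that("FSFS and BSFS trajectories match brute-force greedy oracles", {
  for (s in 1:4) {
    toy <- toy_dataset(n_per_class = 9, n_genes = 7, n_inf = 2, sep = 1.5,
                       seed = 20 + s, sd = 1)
    pool <- sprintf("G%02d", 1:7)
    crit <- if (s %% 2 == 0) "log_loss" else "misclassification"
    fs <- fsfs(pool, toy$expr, toy$labels, C = 10, sigma = 1, criterion = crit,
               k = 3, seed = s)
    ofs <- oracle_fsfs(pool, toy$m, toy$labels, C = 10, sigma = 1,
                       criterion = crit, k = 3, seed = s)
    expect_identical(fs$genes, ofs$genes)
    expect_equal(fs$score, ofs$score)

    bs <- bsfs(pool, toy$expr, toy$labels, C = 10, sigma = 1, criterion = crit,
               k = 3, seed = s)
    obs <- oracle_bsfs(pool, toy$m, toy$labels, C = 10, sigma = 1,
                       criterion = crit, k = 3, seed = s)
    expect_identical(bs$genes, obs$genes)
    expect_equal(bs$score, obs$score)
  }
})

test_that("BSFS removes an adversarial gene first and keeps an all-informative pool", {
  set.seed(30)
  n <- 36
  doses <- rep(c(0, 200), each = n / 2)
  inf <- ifelse(doses == 0, -1, 1) + rnorm(n, sd = 0.4)
  m <- rbind(INF = inf,
             FLIP = -inf + rnorm(n, sd = 0.1), # label-flipped near-duplicate
             OK = ifelse(doses == 0, -1, 1) + rnorm(n, sd = 0.5))
  colnames(m) <- sprintf("s%02d", 1:n)
  labels <- tibble::tibble(sample_id = colnames(m), dose_cGy = doses)
  removal_scores <- sapply(1:3, function(i) {
    oracle_cv_score(m, labels, rownames(m)[-i], 10, 1, "log_loss", 3, 7)
  })
  sig <- bsfs(rownames(m), as_expr_tbl(m), labels, C = 10, sigma = 1,
              criterion = "log_loss", k = 3, seed = 7)
  traj <- tidy(sig)
  if (nrow(traj) > 1) {
    expect_identical(traj$gene[2], rownames(m)[which.min(removal_scores)])
  }

  # strongly informative pool with an immediate plateau returns everything
  toy <- toy_dataset(n_per_class = 10, n_genes = 2, n_inf = 2, sep = 5, seed = 8)
  full <- bsfs(c("G01", "G02"), toy$expr, toy$labels, C = 100, sigma = 1,
               k = 5, seed = 8)
  expect_lte(2 - length(full$genes), 1) # at most one removal from a 2-gene pool
})

test_that("accepted FSFS/BSFS steps strictly improve the criterion", {
  for (s in 1:3) {
    toy <- toy_dataset(n_per_class = 8, n_genes = 6, n_inf = 2, sep = 1.2,
                       seed = 40 + s)
    fs <- fsfs(sprintf("G%02d", 1:6), toy$expr, toy$labels, criterion = "log_loss",
               k = 4, seed = s)
    expect_true(all(diff(tidy(fs)$score) < 0))
    bs <- bsfs(sprintf("G%02d", 1:6), toy$expr, toy$labels, criterion = "log_loss",
               k = 4, seed = s)
    expect_true(all(diff(tidy(bs)$score) < 0))
  }
})

test_that("signature provenance is recorded", {
  toy <- toy_dataset(seed = 9)
  sig <- fsfs(c("G01", "G02"), toy$expr, toy$labels, C = 100, sigma = 10,
              criterion = "log_loss", k = 3, seed = 9, dataset = "cohortA")
  g <- glance(sig)
  expect_equal(g$algorithm, "FSFS")
  expect_equal(g$dataset, "cohortA")
  expect_equal(g$C, 100)
  expect_equal(g$sigma, 10)
  expect_equal(g$criterion, "log_loss")
})
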