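#' Discretize expression into three levels
#'
#' Maps each gene's values to -1/0/+1 using thresholds at the gene's
#' mean plus/minus `alpha` standard deviations, the conventional
#' preparation for mutual-information estimation on continuous
#' expression. On z-scored rows the thresholds sit at `-alpha` and
#' `+alpha`.
#'
#' @inheritParams filter_incomplete
#' @param alpha Threshold in standard-deviation multiples (> 0).
#' @return Expression-shaped tibble of integers in {-1, 0, 1} with
#'   attribute `alpha`.
#' @export
discretize_expression <- function(x, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("alpha must be a single positive number")
  }
  m <- as_expr_matrix(x)
  if (anyNA(m)) abort("discretization requires a complete matrix")
  mu <- rowMeans(m)
  sds <- apply(m, 1, sd)
  lo <- mu - alpha * sds
  hi <- mu + alpha * sds
  d <- (m > hi) - (m < lo)
  storage.mode(d) <- "integer"
  out <- as_expr_tbl(d, id_col = id_col_name(x))
  attr(out, "alpha") <- alpha
  class(out) <- c("radsig_discretized", class(out))
  out
}

# Plug-in MI in nats from integer state codes (no input checks).
mi_codes <- function(xc, yc, nx, ny) {
  n <- length(xc)
  joint <- tabulate((xc - 1L) * ny + yc, nbins = nx * ny)
  p <- joint / n
  px <- tabulate(xc, nbins = nx) / n
  py <- tabulate(yc, nbins = ny) / n
  pij <- outer(px, py)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / t(matrix(pij, nx, ny, byrow = FALSE))[pos]))
}

#' Mutual information of two discrete vectors
#'
#' Plug-in (maximum-likelihood) estimate from the joint empirical
#' frequencies, in nats: `sum p(x,y) * log(p(x,y) / (p(x) p(y)))`.
#'
#' @param x,y Vectors of equal length (any discrete coding: integers,
#'   characters, factors).
#' @return Non-negative mutual information in nats.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c("a", "a", "b", "b")) # = log(2)
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least two observations")
  xf <- factor(x)
  yf <- factor(y)
  mi <- mi_codes(as.integer(xf), as.integer(yf), nlevels(xf), nlevels(yf))
  max(mi, 0)
}

#' Rank genes by minimum redundancy, maximum relevance
#'
#' Incremental mRMR selection under the mutual-information-difference
#' (MID) criterion. At each step the gene maximizing
#' `I(gene, dose) - mean(I(gene, selected))` is appended; the first
#' gene maximizes relevance alone (the redundancy term is defined as 0
#' for an empty selected set). Ties break toward higher relevance,
#' then lexicographically by symbol. All mutual information is the
#' plug-in estimate on 3-level discretized expression, in nats.
#'
#' @param x Expression tibble/matrix (discretized with
#'   [discretize_expression()] if not already).
#' @param labels Dose-label tibble (`sample_id`, `dose_cGy`).
#' @param n_select Number of genes to rank (defaults to all).
#' @param alpha Discretization threshold, used when `x` is continuous.
#' @param discretize Set `FALSE` when `x` already holds 3-level
#'   discrete states in `{-1, 0, 1}` that should be used as-is.
#' @return A tibble of class `mrmr_ranking` with columns `rank`,
#'   `gene`, `relevance_nats`, `redundancy_nats`, `mid_score`.
#' @export
mid_rank <- function(x, labels, n_select = NULL, alpha = 0.5,
                     discretize = !inherits(x, "radsig_discretized")) {
  if (discretize) x <- discretize_expression(x, alpha = alpha)
  m <- as_expr_matrix(as_tibble(unclass(x)))
  if (!all(m %in% c(-1, 0, 1))) abort("discrete states must be in {-1, 0, 1}")
  doses <- aligned_doses(x, labels)
  genes <- rownames(m)
  n_select <- n_select %||% length(genes)
  stopifnot(n_select >= 1, n_select <= length(genes))

  states <- m + 2L # codes 1..3
  h <- as.integer(dose_factor(doses))
  nh <- length(unique(h))
  relevance <- vapply(seq_along(genes), function(i) {
    mi_codes(states[i, ], h, 3L, nh)
  }, numeric(1))
  names(relevance) <- genes

  selected <- integer(0)
  remaining <- seq_along(genes)
  red_sum <- numeric(length(genes)) # sum of MI with selected genes
  rows <- vector("list", n_select)
  for (step in seq_len(n_select)) {
    s <- length(selected)
    red <- if (s == 0) numeric(length(remaining)) else red_sum[remaining] / s
    score <- relevance[remaining] - red
    # scores equal up to fp noise are ties; break by relevance, then symbol
    tol <- 1e-9
    cand <- remaining[score >= max(score) - tol]
    relc <- relevance[cand]
    cand <- cand[relc >= max(relc) - tol]
    pick <- cand[order(genes[cand])][1]
    rows[[step]] <- tibble(
      rank = step, gene = genes[pick],
      relevance_nats = unname(relevance[pick]),
      redundancy_nats = if (s == 0) 0 else unname(red_sum[pick] / s),
      mid_score = unname(relevance[pick]) - (if (s == 0) 0 else unname(red_sum[pick] / s))
    )
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0) {
      xi <- states[pick, ]
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) mi_codes(states[j, ], xi, 3L, 3L), numeric(1))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mrmr_ranking", class(out))
  out
}

#' @export
autoplot.mrmr_ranking <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(unclass(object)),
    cols = c("relevance_nats", "redundancy_nats", "mid_score"),
    names_to = "component", values_to = "nats"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$nats,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mRMR rank", y = "nats",
                  title = "mRMR selection trace (MID criterion)") +
    ggplot2::theme_minimal()
}
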