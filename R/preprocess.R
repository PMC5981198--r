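#' Remove incomplete probes and samples
#'
#' Drops rows (probes) and then columns (samples) whose observed
#' fraction falls below `completeness`. The default keeps rows and
#' columns that are at least 95% complete; a row that is exactly 95%
#' observed is retained.
#'
#' @param x Expression tibble or matrix (see [as_expr_matrix()]).
#' @param completeness Minimum observed fraction in (0, 1].
#' @param rows_first Filter rows before columns (default) or the
#'   reverse.
#' @return Expression tibble with incomplete rows/columns removed;
#'   surviving values are untouched.
#' @export
filter_incomplete <- function(x, completeness = 0.95, rows_first = TRUE) {
  stopifnot(completeness > 0, completeness <= 1)
  m <- as_expr_matrix(x)
  filt_rows <- function(m) m[rowMeans(!is.na(m)) >= completeness, , drop = FALSE]
  filt_cols <- function(m) m[, colMeans(!is.na(m)) >= completeness, drop = FALSE]
  m <- if (rows_first) filt_cols(filt_rows(m)) else filt_rows(filt_cols(m))
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort("no rows/columns meet the completeness threshold; dataset unusable")
  }
  as_expr_tbl(m, id_col = id_col_name(x))
}

id_col_name <- function(x) if (is.data.frame(x)) names(x)[1] else "gene"

# Squared Euclidean distances between rows over mutually observed
# columns (no rescaling by the number of shared columns). Pairs with no
# shared observed column get Inf.
row_distances_sq <- function(m) {
  w <- !is.na(m)
  a <- m
  a[!w] <- 0
  wn <- w * 1
  s1 <- (a * a) %*% t(wn)
  cross <- a %*% t(a)
  d2 <- s1 + t(s1) - 2 * cross
  d2[d2 < 0] <- 0
  shared <- wn %*% t(wn)
  d2[shared == 0] <- Inf
  d2
}

#' Impute missing values by nearest-neighbor rows
#'
#' Each missing entry is replaced by the unweighted mean of the `k`
#' nearest rows (Euclidean distance over mutually observed columns)
#' that have an observed value in that column. Observed entries are
#' never changed.
#'
#' @inheritParams filter_incomplete
#' @param k Number of neighbor rows to average (>= 1).
#' @return Expression tibble with no missing values.
#' @export
impute_knn <- function(x, k = 10) {
  stopifnot(k >= 1)
  m <- as_expr_matrix(x)
  if (!anyNA(m)) return(as_expr_tbl(m, id_col = id_col_name(x)))
  if (any(rowSums(!is.na(m)) == 0)) abort("rows with no observed values cannot be imputed")
  d2 <- row_distances_sq(m)
  diag(d2) <- Inf
  out <- m
  need <- which(rowSums(is.na(m)) > 0)
  for (i in need) {
    if (all(is.infinite(d2[i, ]))) {
      abort(paste0("row ", rownames(m)[i],
                   " shares no observed columns with any other row"))
    }
    # deterministic neighbor order: distance, then row name
    ord <- order(d2[i, ], rownames(m))
    for (s in which(is.na(m[i, ]))) {
      cand <- ord[!is.na(m[ord, s]) & is.finite(d2[i, ord])]
      if (length(cand) == 0) {
        abort(paste0("no neighbor with an observed value for row ",
                     rownames(m)[i], ", sample ", colnames(m)[s]))
      }
      out[i, s] <- mean(m[cand[seq_len(min(k, length(cand)))], s])
    }
  }
  as_expr_tbl(out, id_col = id_col_name(x))
}

#' Standardize each row to z-scores
#'
#' Centers and scales every row to mean 0 and unit sample (n-1)
#' standard deviation. Constant rows cannot be standardized and are
#' dropped with a warning.
#'
#' @inheritParams filter_incomplete
#' @return Expression tibble of z-scores.
#' @export
zscore_rows <- function(x) {
  m <- as_expr_matrix(x)
  if (anyNA(m)) abort("z-scoring requires a complete matrix; impute first")
  sds <- apply(m, 1, sd)
  const <- sds == 0
  if (any(const)) {
    warn(paste0("dropping ", sum(const), " constant row(s): ",
                paste(head(rownames(m)[const], 5), collapse = ", ")))
    m <- m[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  if (nrow(m) == 0) abort("all rows constant; nothing to standardize")
  z <- (m - rowMeans(m)) / sds
  as_expr_tbl(z, id_col = id_col_name(x))
}

# Uppercase canonical form used whenever gene symbols are matched.
canonical_symbol <- function(x) toupper(trimws(x))

#' Collapse probe rows to gene rows
#'
#' Maps probes to gene symbols through an annotation table and assigns
#' each gene the arithmetic mean of its probes' rows. Probes without a
#' mapping are dropped. Symbols are matched case-insensitively; the
#' first annotated spelling is kept for display.
#'
#' @inheritParams filter_incomplete
#' @param annotation Tibble with columns `probe_id` and `gene_symbol`
#'   (see [read_probe_annotation()]).
#' @return Expression tibble with one row per gene symbol.
#' @export
collapse_probes <- function(x, annotation) {
  m <- as_expr_matrix(x)
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(annotation)))
  map <- annotation[!is.na(annotation$gene_symbol) & nzchar(annotation$gene_symbol), ]
  sym <- map$gene_symbol[match(rownames(m), map$probe_id)]
  keep <- !is.na(sym)
  if (!any(keep)) abort("no probe maps to a gene symbol")
  m <- m[keep, , drop = FALSE]
  canon <- canonical_symbol(sym[keep])
  display <- sym[keep][!duplicated(canon)]
  groups <- split(seq_len(nrow(m)), canon)
  display <- display[match(names(groups), canonical_symbol(display))]
  collapsed <- do.call(rbind, lapply(groups, function(idx) {
    colMeans(m[idx, , drop = FALSE])
  }))
  rownames(collapsed) <- display
  as_expr_tbl(collapsed, id_col = "gene")
}

#' Restrict datasets to their common panel genes
#'
#' Intersects the gene sets of all datasets with each other and with a
#' curated gene panel, and returns every dataset restricted to that
#' shared, alphabetically sorted gene set. Symbol matching is
#' case-insensitive.
#'
#' @param datasets List of gene-level expression tibbles/matrices.
#' @param panel Character vector of panel gene symbols.
#' @return List of expression tibbles sharing an identical row set and
#'   order.
#' @export
harmonize_datasets <- function(datasets, panel) {
  stopifnot(length(datasets) >= 1, length(panel) >= 1)
  mats <- lapply(datasets, as_expr_matrix)
  canon_sets <- lapply(mats, function(m) canonical_symbol(rownames(m)))
  common <- Reduce(intersect, canon_sets)
  common <- intersect(common, canonical_symbol(panel))
  if (length(common) == 0) abort("no genes shared by all datasets and the panel")
  common <- sort(common)
  out <- lapply(mats, function(m) {
    idx <- match(common, canonical_symbol(rownames(m)))
    as_expr_tbl(m[idx, , drop = FALSE])
  })
  names(out) <- names(datasets)
  out
}

#' Full preprocessing for one dataset
#'
#' Convenience chain: completeness filter, nearest-neighbor imputation,
#' per-row z-scoring and, when an annotation is supplied, probe-to-gene
#' collapsing. Panel restriction across datasets is done separately
#' with [harmonize_datasets()].
#'
#' @inheritParams filter_incomplete
#' @inheritParams impute_knn
#' @param annotation Optional probe annotation; `NULL` when rows are
#'   already gene symbols.
#' @return Gene-level z-scored expression tibble.
#' @export
preprocess_expression <- function(x, annotation = NULL, completeness = 0.95,
                                  k = 10) {
  out <- filter_incomplete(x, completeness = completeness)
  out <- impute_knn(out, k = k)
  out <- zscore_rows(out)
  if (!is.null(annotation)) out <- collapse_probes(out, annotation)
  out
}
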