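#' Expression tables
#'
#' Expression data travel through the package as a tibble whose first
#' column holds the probe or gene identifier and whose remaining columns
#' are numeric, one per sample. Missing measurements are `NA`.
#' `as_expr_matrix()` and `as_expr_tbl()` convert between this tibble
#' form and a plain numeric matrix (rows = genes/probes, columns =
#' samples); most numerical work happens on the matrix form internally.
#'
#' @param x For `as_expr_matrix()`, an expression tibble (or a matrix,
#'   returned as-is after validation). For `as_expr_tbl()`, a numeric
#'   matrix with row and column names.
#' @param id_col Name of the identifier column for `as_expr_tbl()`.
#' @return `as_expr_matrix()` a numeric matrix with unique row and
#'   column names; `as_expr_tbl()` an expression tibble.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' as_expr_tbl(m)
#' @export
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (!is.data.frame(x) || ncol(x) < 2) {
      abort("expression data must be a data frame with an id column plus >=1 sample column")
    }
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(m)) abort("sample columns must all be numeric")
    rownames(m) <- ids
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("expression matrix needs row (gene) and column (sample) names")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate row identifiers in expression data")
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers in expression data")
  m
}

#' @rdname as_expr_matrix
#' @export
as_expr_tbl <- function(x, id_col = "gene") {
  stopifnot(is.matrix(x))
  out <- as_tibble(x, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(x)), out)
  out
}

expr_ids <- function(x) {
  if (is.matrix(x)) rownames(x) else as.character(x[[1]])
}

expr_samples <- function(x) {
  if (is.matrix(x)) colnames(x) else names(x)[-1]
}

#' Read and write the package's tab-delimited file formats
#'
#' * Expression: first column probe/gene id, header row of sample ids;
#'   empty cells, `NA` or `NaN` are treated as missing.
#' * Dose labels: two columns, `sample_id` and `dose_cGy`.
#' * Probe annotation: two columns, `probe_id` and `gene_symbol`; a
#'   blank symbol marks an unmapped probe.
#' * Gene panel: one symbol per line, `#` comments and blank lines
#'   ignored.
#'
#' @param path File path.
#' @return A tibble (`read_expression()`, `read_dose_labels()`,
#'   `read_probe_annotation()`) or character vector (`read_gene_panel()`).
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, na = c("", "NA", "NaN"), show_col_types = FALSE,
                         progress = FALSE)
  names(tbl)[1] <- "gene"
  as_expr_matrix(tbl) # validate
  tbl
}

#' @rdname read_expression
#' @param x Object to write (expression tibble/matrix, labels tibble, or
#'   character vector of panel symbols).
#' @export
write_expression <- function(x, path) {
  if (is.matrix(x)) x <- as_expr_tbl(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_dose_labels <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("sample_id", "dose_cGy")
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$dose_cGy <- as.numeric(tbl$dose_cGy)
  validate_labels(tbl)
  tbl
}

#' @rdname read_expression
#' @export
write_dose_labels <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_probe_annotation <- function(path) {
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("probe_id", "gene_symbol")
  tbl$probe_id <- as.character(tbl$probe_id)
  tbl$gene_symbol <- as.character(tbl$gene_symbol)
  tbl$gene_symbol[!is.na(tbl$gene_symbol) & tbl$gene_symbol == ""] <- NA_character_
  if (anyDuplicated(tbl$probe_id)) abort("probe annotation maps a probe more than once")
  tbl
}

#' @rdname read_expression
#' @export
read_gene_panel <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  panel <- lines[nzchar(lines)]
  if (length(panel) == 0) abort("gene panel file contains no symbols")
  if (anyDuplicated(toupper(panel))) {
    panel <- panel[!duplicated(toupper(panel))]
  }
  panel
}

validate_labels <- function(labels) {
  if (!is.data.frame(labels) || !all(c("sample_id", "dose_cGy") %in% names(labels))) {
    abort("dose labels must be a data frame with columns sample_id and dose_cGy")
  }
  if (anyDuplicated(labels$sample_id)) abort("duplicate sample_id in dose labels")
  if (any(is.na(labels$dose_cGy)) || any(labels$dose_cGy < 0)) {
    abort("dose_cGy must be non-negative and non-missing")
  }
  invisible(labels)
}

# Dose classes as an ordered-by-dose factor over the label set.
dose_factor <- function(doses, classes = sort(unique(doses))) {
  factor(doses, levels = classes)
}

# Align labels to the sample columns of an expression object; errors on
# unlabeled samples.
aligned_doses <- function(x, labels) {
  validate_labels(labels)
  samples <- expr_samples(x)
  idx <- match(samples, labels$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples without a dose label: ",
                 paste(samples[is.na(idx)], collapse = ", ")))
  }
  setNames(labels$dose_cGy[idx], samples)
}
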