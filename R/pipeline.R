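#' Run configuration for discovery and validation
#'
#' A run configuration is a plain list (writable as YAML) with fields:
#'
#' * `datasets`: named list; each element has `expression` (path or
#'   tibble), `labels` (path or tibble), optional `annotation` (path or
#'   tibble) and `role` (`"derive"` or `"validate"`; a dataset may be
#'   both: `c("derive", "validate")`).
#' * `panel`: path or character vector of panel gene symbols.
#' * `algorithms`: subset of `c("CSFS", "FSFS", "BSFS")`.
#' * `criterion`: `"misclassification"` or `"log_loss"`.
#' * `params`: data frame / list of `(C, sigma)` rows used during
#'   feature selection, or `"lattice"` for the full 21-pair grid.
#' * `k`, `repeats`, `seed`, `n_rank` (genes to rank), `pool_fsfs`,
#'   `pool_bsfs`, `out_dir` (optional).
#'
#' `load_run_config()` reads such a list from a YAML file and applies
#' defaults; `run_discovery()` executes preprocessing through feature
#' selection plus the post-selection grid search; `run_validate()`
#' produces k-fold validation reports for each signature on each
#' validation dataset, skipping (with a message) signatures not fully
#' contained in a dataset.
#'
#' @param path YAML file path.
#' @return `load_run_config()`: the config list with defaults filled.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fill_config_defaults(cfg)
}

fill_config_defaults <- function(cfg) {
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0) {
    abort("config needs at least one dataset")
  }
  cfg$algorithms <- cfg$algorithms %||% "FSFS"
  stopifnot(all(cfg$algorithms %in% c("CSFS", "FSFS", "BSFS")))
  cfg$criterion <- cfg$criterion %||% "misclassification"
  stopifnot(cfg$criterion %in% c("misclassification", "log_loss"))
  cfg$k <- cfg$k %||% 5
  cfg$repeats <- cfg$repeats %||% 20
  cfg$seed <- cfg$seed %||% 1
  cfg$pool_fsfs <- cfg$pool_fsfs %||% 50
  cfg$pool_bsfs <- cfg$pool_bsfs %||% 30
  cfg$n_rank <- cfg$n_rank %||% max(cfg$pool_fsfs, cfg$pool_bsfs)
  if (is.null(cfg$params) || identical(cfg$params, "lattice")) {
    cfg$params <- if (is.null(cfg$params)) tibble(C = 10, sigma = 1) else svm_grid()
  } else {
    cfg$params <- as_tibble(as.data.frame(cfg$params))
    stopifnot(all(c("C", "sigma") %in% names(cfg$params)))
  }
  roles <- lapply(cfg$datasets, function(d) d$role %||% c("derive", "validate"))
  if (!any(vapply(roles, function(r) "derive" %in% r, logical(1)))) {
    abort("config needs at least one derivation dataset")
  }
  cfg
}

load_dataset_inputs <- function(d) {
  expr <- if (is.character(d$expression)) read_expression(d$expression) else d$expression
  labels <- if (is.character(d$labels)) read_dose_labels(d$labels) else d$labels
  annot <- if (is.null(d$annotation)) {
    NULL
  } else if (is.character(d$annotation)) {
    read_probe_annotation(d$annotation)
  } else {
    d$annotation
  }
  list(expression = expr, labels = labels, annotation = annot,
       role = d$role %||% c("derive", "validate"))
}

preprocess_config_datasets <- function(cfg) {
  panel <- if (is.character(cfg$panel) && length(cfg$panel) == 1 &&
               file.exists(cfg$panel)) {
    read_gene_panel(cfg$panel)
  } else {
    cfg$panel
  }
  inputs <- lapply(cfg$datasets, load_dataset_inputs)
  pre <- lapply(inputs, function(d) {
    preprocess_expression(d$expression, annotation = d$annotation)
  })
  harmonized <- harmonize_datasets(pre, panel)
  purrr::imap(inputs, function(d, name) {
    list(expression = harmonized[[name]], labels = d$labels, role = d$role)
  })
}

#' @rdname load_run_config
#' @param config Config list (see above) or a YAML path.
#' @return `run_discovery()`: a list with `signatures`
#'   (`radsig_signature` objects, one per derivation dataset x
#'   algorithm x parameter row), `manifest` (tibble of provenance:
#'   tuned post-selection hyper-parameters, scores, seeds) and the
#'   preprocessed `datasets`.
#' @export
run_discovery <- function(config) {
  cfg <- if (is.character(config)) load_run_config(config) else fill_config_defaults(config)
  datasets <- preprocess_config_datasets(cfg)
  derive <- names(datasets)[vapply(datasets, function(d) "derive" %in% d$role,
                                   logical(1))]
  signatures <- list()
  manifest <- list()
  for (name in derive) {
    d <- datasets[[name]]
    n_rank <- min(cfg$n_rank, nrow(d$expression))
    ranking <- mid_rank(d$expression, d$labels, n_select = n_rank)
    for (alg in cfg$algorithms) {
      for (i in seq_len(nrow(cfg$params))) {
        C <- cfg$params$C[i]
        sigma <- cfg$params$sigma[i]
        sig <- switch(
          alg,
          CSFS = csfs(ranking, d$expression, d$labels, C = C, sigma = sigma,
                      criterion = cfg$criterion, k = cfg$k, seed = cfg$seed,
                      dataset = name),
          FSFS = fsfs(ranking, d$expression, d$labels, C = C, sigma = sigma,
                      criterion = cfg$criterion, k = cfg$k, seed = cfg$seed,
                      pool = cfg$pool_fsfs, dataset = name),
          BSFS = bsfs(ranking, d$expression, d$labels, C = C, sigma = sigma,
                      criterion = cfg$criterion, k = cfg$k, seed = cfg$seed,
                      pool = cfg$pool_bsfs, dataset = name)
        )
        tuned <- grid_search(
          check_signature_eligible(as_expr_matrix(d$expression), sig),
          d$labels, criterion = cfg$criterion, k = cfg$k, seed = cfg$seed
        )
        sig$C_tuned <- tuned$C
        sig$sigma_tuned <- tuned$sigma
        id <- paste(name, alg, paste0("C", C), paste0("s", sigma), sep = "_")
        signatures[[id]] <- sig
        manifest[[id]] <- tibble(
          id = id, dataset = name, algorithm = alg, criterion = cfg$criterion,
          C_fs = C, sigma_fs = sigma, C_tuned = tuned$C,
          sigma_tuned = tuned$sigma, fs_score = sig$score,
          n_genes = length(sig$genes), k = cfg$k, seed = cfg$seed
        )
      }
    }
  }
  out <- list(signatures = signatures, manifest = dplyr::bind_rows(manifest),
              datasets = datasets)
  if (!is.null(cfg$out_dir)) write_discovery(out, cfg$out_dir)
  out
}

write_discovery <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  for (id in names(run$signatures)) {
    sig <- run$signatures[[id]]
    header <- c(
      paste0("# algorithm=", sig$algorithm), paste0("# dataset=", sig$dataset),
      paste0("# C=", sig$C), paste0("# sigma=", sig$sigma),
      paste0("# criterion=", sig$criterion),
      paste0("# internal_score=", sig$score)
    )
    writeLines(c(header, sig$genes), file.path(out_dir, paste0(id, ".signature.tsv")))
    readr::write_tsv(attr(sig, "trajectory"),
                     file.path(out_dir, paste0(id, ".trajectory.tsv")),
                     progress = FALSE)
  }
  invisible(out_dir)
}

#' @rdname load_run_config
#' @param discovery Output of [run_discovery()] (or a compatible list
#'   with `signatures` and preprocessed `datasets`).
#' @param use_tuned Use each signature's post-selection tuned
#'   hyper-parameters for validation models (default) rather than its
#'   feature-selection pair.
#' @return `run_validate()`: a list with `reports` (nested:
#'   signature id -> dataset -> `validation_report`) and `summary`, a
#'   flat tibble with one row per (signature, dataset) mirroring the
#'   package's tabular report format (FS score plus validation
#'   misclassification / log loss / goodness of fit with standard
#'   errors).
#' @export
run_validate <- function(discovery, config = NULL, use_tuned = TRUE) {
  cfg <- if (is.null(config)) {
    list(k = 5, repeats = 20, seed = 1)
  } else if (is.character(config)) {
    load_run_config(config)
  } else {
    config
  }
  k <- cfg$k %||% 5
  repeats <- cfg$repeats %||% 20
  seed <- cfg$seed %||% 1
  datasets <- discovery$datasets
  val_names <- names(datasets)[vapply(datasets, function(d) "validate" %in% d$role,
                                      logical(1))]
  reports <- list()
  rows <- list()
  for (id in names(discovery$signatures)) {
    sig <- discovery$signatures[[id]]
    C <- if (use_tuned && !is.null(sig$C_tuned)) sig$C_tuned else sig$C
    sigma <- if (use_tuned && !is.null(sig$sigma_tuned)) sig$sigma_tuned else sig$sigma
    for (name in setdiff(val_names, sig$dataset)) {
      d <- datasets[[name]]
      present <- all(canonical_symbol(sig$genes) %in%
                       canonical_symbol(expr_ids(d$expression)))
      if (!present) {
        message("skipping ", id, " on ", name, ": signature not fully contained")
        next
      }
      rep <- kfold_validate(d$expression, d$labels, sig, k = k, C = C,
                            sigma = sigma, repeats = repeats, seed = seed)
      reports[[id]][[name]] <- rep
      rows[[paste(id, name)]] <- dplyr::bind_cols(
        tibble(id = id, signature_dataset = sig$dataset,
               validation_dataset = name, algorithm = sig$algorithm,
               criterion = sig$criterion, fs_score = sig$score,
               n_genes = length(sig$genes), C = C, sigma = sigma),
        glance(rep)[, c("misclassification", "misclassification_se",
                        "log_loss", "log_loss_se", "goodness_of_fit",
                        "goodness_of_fit_se")]
      )
    }
  }
  list(reports = reports, summary = dplyr::bind_rows(rows))
}
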