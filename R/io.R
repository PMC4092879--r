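# TSV/JSON interchange and the file-level pipeline commands.

#' @name countbench-io
#' @title Read and write the package's TSV interchange formats
#' @description
#' Counts: `gene_id` column then one integer column per sample.
#' Truth: `gene_id`, `d`, `fc`. Panel: `gene_id`, `mu`, `phi`.
#' Results: `gene_id`, `p`, `p_adj`, `fc`, `direction`.
#' @param x object to write.
#' @param path file path.
NULL

#' @rdname countbench-io
#' @export
write_counts_tsv <- function(x, path) {
  m <- as_count_matrix(x, require_integer = TRUE)
  df <- dplyr::bind_cols(tibble(gene_id = rownames(m)),
                         as_tibble(as.data.frame(m)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname countbench-io
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_count_matrix(as.data.frame(df))
}

#' @rdname countbench-io
#' @export
write_truth_tsv <- function(x, path) {
  if (inherits(x, "sim_experiment")) x <- x$truth
  readr::write_tsv(dplyr::select(x, "gene_id", "d", "fc"), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname countbench-io
#' @export
read_truth_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(df, class = c("truth_table", class(tibble())))
}

#' @rdname countbench-io
#' @export
write_panel_tsv <- function(x, path) {
  x <- validate_nb_panel(x)
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname countbench-io
#' @export
read_panel_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_nb_panel(df)
}

#' @rdname countbench-io
#' @export
write_method_result_tsv <- function(x, path) {
  df <- as_tibble(x)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname countbench-io
#' @param method method label to attach when reading a result file
#'   (default: inferred from the file name).
#' @export
read_method_result_tsv <- function(path, method = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  method <- method %||% sub("_results?\\.tsv$", "", basename(path))
  structure(
    df,
    class = c("method_result", class(tibble())),
    method = method,
    has_direction = "direction" %in% names(df) && !all(is.na(df$direction))
  )
}

# JSON sidecar recording the configuration and seeds of a run.
write_run_sidecar <- function(config, path, extra = list()) {
  payload <- c(unclass(config), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a scenario to files on disk
#'
#' Writes one counts TSV and one truth TSV per replicate dataset, named
#' `<scenario>_rep<k>_counts.tsv` / `<scenario>_rep<k>_truth.tsv`, plus
#' the shared panel and a JSON sidecar recording the configuration and
#' the per-dataset seeds. Re-running with the same seeded config
#' reproduces the files byte for byte.
#'
#' @param config a [scenario_config()].
#' @param out_dir writable output directory (created if missing).
#' @param panel,panel_args see [simulate_scenario()].
#' @return invisible character vector of the files written.
#' @export
cmd_simulate <- function(config, out_dir, panel = NULL, panel_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  sims <- simulate_scenario(config, panel = panel, panel_args = panel_args)
  files <- character(0)
  for (k in seq_along(sims)) {
    stem <- file.path(out_dir, sprintf("%s_rep%d", config$name, k))
    files <- c(files,
               write_counts_tsv(sims[[k]], paste0(stem, "_counts.tsv")),
               write_truth_tsv(sims[[k]], paste0(stem, "_truth.tsv")))
  }
  panel_path <- file.path(out_dir, sprintf("%s_panel.tsv", config$name))
  write_panel_tsv(attr(sims, "panel"), panel_path)
  sidecar <- file.path(out_dir, sprintf("%s_sidecar.json", config$name))
  write_run_sidecar(config, sidecar,
                    extra = list(dataset_seeds = attr(sims, "seeds")))
  invisible(c(files, panel_path, sidecar))
}

#' Run a full benchmark and write its tables
#'
#' Runs [run_benchmark()] and writes a scenario-level performance TSV
#' (columns `scenario`, `method`, `fdr_cutoff`, `ns`, `fp`, `tp`, `fpr`,
#' `tpr`), the per-dataset metrics, an AUC TSV, per-method timings and a
#' JSON sidecar.
#'
#' @inheritParams run_benchmark
#' @param out_dir writable output directory.
#' @return the `de_benchmark` object, invisibly.
#' @export
cmd_benchmark <- function(config, out_dir,
                          methods = de_methods_available(),
                          cutoffs = c(0.1, 0.05, 0.01),
                          panel = NULL, method_args = list(),
                          panel_args = list(), verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bm <- run_benchmark(config, methods = methods, panel = panel,
                      cutoffs = cutoffs, method_args = method_args,
                      panel_args = panel_args, verbose = verbose)
  perf <- glance(bm) |>
    dplyr::select("scenario", "method", fdr_cutoff = "cutoff",
                  "ns", "fp", "tp", "fpr", "tpr")
  readr::write_tsv(perf, file.path(out_dir, "performance.tsv"),
                   progress = FALSE)
  readr::write_tsv(bm$metrics,
                   file.path(out_dir, "performance_by_dataset.tsv"),
                   progress = FALSE)
  readr::write_tsv(bm$auc, file.path(out_dir, "auc_by_dataset.tsv"),
                   progress = FALSE)
  readr::write_tsv(bm$auc_means, file.path(out_dir, "auc.tsv"),
                   progress = FALSE)
  readr::write_tsv(bm$timings, file.path(out_dir, "timings.tsv"),
                   progress = FALSE)
  write_run_sidecar(config, file.path(out_dir, "benchmark_sidecar.json"),
                    extra = list(methods = methods, cutoffs = cutoffs))
  invisible(bm)
}

#' Concordance report from result files
#'
#' Reads per-method result TSVs (either a directory containing
#' `*_results.tsv` files or an explicit character vector of paths),
#' verifies they share one gene universe (an error names the offending
#' files), and writes the Spearman matrices, ICC values, Venn cells,
#' singleton counts and identification-frequency table.
#'
#' @param input directory or character vector of result TSV paths.
#' @param alpha significance cutoff in (0, 1).
#' @param out_dir writable output directory.
#' @return the `concordance_report`, invisibly.
#' @export
cmd_concordance <- function(input, alpha = 0.05, out_dir) {
  files <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "_results?\\.tsv$", full.names = TRUE)
  } else {
    input
  }
  if (length(files) < 2) {
    abort("Need at least 2 result files for a concordance report.")
  }
  results <- lapply(files, read_method_result_tsv)
  names(results) <- vapply(results, function(r) attr(r, "method"),
                           character(1))
  universes <- lapply(results, function(r) sort(r$gene_id))
  for (i in seq_along(universes)[-1]) {
    if (!identical(universes[[i]], universes[[1]])) {
      abort(sprintf(
        "Gene universe of '%s' does not match '%s'.",
        files[i], files[1]
      ))
    }
  }
  rep <- concordance_report(results, alpha = alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix <- function(m, path) {
    df <- dplyr::bind_cols(tibble(method = rownames(m)),
                           as_tibble(as.data.frame(m)))
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_matrix(rep$spearman_fc, file.path(out_dir, "spearman_fc.tsv"))
  write_matrix(rep$spearman_p, file.path(out_dir, "spearman_p.tsv"))
  jsonlite::write_json(
    list(icc_fc = rep$icc_fc, icc_p = rep$icc_p, alpha = alpha),
    file.path(out_dir, "icc.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(rep$overlap$venn)) {
    readr::write_tsv(rep$overlap$venn, file.path(out_dir, "venn.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(rep$overlap$singletons,
                   file.path(out_dir, "singletons.tsv"), progress = FALSE)
  readr::write_tsv(rep$overlap$identification_frequency,
                   file.path(out_dir, "identification_frequency.tsv"),
                   progress = FALSE)
  readr::write_tsv(rep$overlap$by_frequency,
                   file.path(out_dir, "by_frequency.tsv"), progress = FALSE)
  invisible(rep)
}
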