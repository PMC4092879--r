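# End-to-end benchmark: simulate -> run methods -> evaluate.

#' Run a simulation benchmark of the test families
#'
#' Simulates the replicate datasets of a scenario, runs the requested
#' test families on each, and scores them with [confusion_at_cutoffs()]
#' and [roc_auc()]. A method failing on a dataset is recorded and skipped
#' for that dataset; the run continues. Wall-clock time per method and
#' dataset is logged (informational only — it depends on hardware).
#'
#' @param config a [scenario_config()] (set `config$seed` for a fully
#'   reproducible run).
#' @param methods subset of [de_methods_available()].
#' @param panel optional fixed [nb_panel()]; default draws a stand-in
#'   panel.
#' @param cutoffs BH-FDR cutoffs for the confusion summaries.
#' @param method_args named list of per-method argument lists, e.g.
#'   `list(eb_nb = list(n_hyper_samples = 20))`.
#' @param panel_args passed to [make_standin_panel()] when `panel` is
#'   `NULL`.
#' @param verbose print progress.
#' @return an object of class `de_benchmark`: list with `metrics` and
#'   `auc` (per dataset), `metric_means` and `auc_means` (scenario
#'   level), `timings`, `failures`, `config` and `panel`. Use [tidy()],
#'   [glance()] and [ggplot2::autoplot()] on it.
#' @examples
#' cfg <- scenario_preset("I", n_genes = 300, n_datasets = 2, seed = 1)
#' bm <- run_benchmark(cfg, methods = c("poisson_ma", "nb_exact"))
#' glance(bm)
#' @export
run_benchmark <- function(config, methods = de_methods_available(),
                          panel = NULL, cutoffs = c(0.1, 0.05, 0.01),
                          method_args = list(), panel_args = list(),
                          verbose = FALSE) {
  if (length(methods) == 0) {
    abort("At least one method must be requested.")
  }
  bad <- setdiff(methods, de_methods_available())
  if (length(bad) > 0) {
    abort(sprintf("Unknown method(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(cutoffs <= 0) || any(cutoffs >= 1)) {
    abort("FDR cutoffs must lie strictly between 0 and 1.")
  }
  sims <- simulate_scenario(config, panel = panel, panel_args = panel_args)

  metrics <- list()
  aucs <- list()
  timings <- list()
  failures <- list()
  for (k in seq_along(sims)) {
    sim <- sims[[k]]
    for (m in methods) {
      if (verbose) {
        inform(sprintf("dataset %d/%d: %s", k, length(sims), m))
      }
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        do.call(de_test, c(list(sim, method = m), method_args[[m]])),
        error = function(e) e
      )
      elapsed <- proc.time()[["elapsed"]] - t0
      timings[[length(timings) + 1]] <-
        tibble(dataset = k, method = m, seconds = elapsed,
               ok = !inherits(res, "error"))
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          tibble(dataset = k, method = m, message = conditionMessage(res))
        next
      }
      conf <- confusion_at_cutoffs(res, sim$truth, cutoffs)
      conf$dataset <- k
      metrics[[length(metrics) + 1]] <- conf
      aucs[[length(aucs) + 1]] <-
        tibble(dataset = k, method = m,
               auc = roc_auc(1 - res$p, sim$truth))
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  aucs <- dplyr::bind_rows(aucs)
  structure(
    list(
      config = config,
      panel = attr(sims, "panel"),
      metrics = metrics,
      auc = aucs,
      metric_means = if (nrow(metrics)) aggregate_scenario(metrics) else metrics,
      auc_means = if (nrow(aucs)) aggregate_scenario(aucs) else aucs,
      timings = dplyr::bind_rows(timings),
      failures = if (length(failures)) dplyr::bind_rows(failures) else NULL
    ),
    class = "de_benchmark"
  )
}

#' @export
print.de_benchmark <- function(x, ...) {
  cat(sprintf(
    "<de_benchmark '%s'>: %d datasets, %d method(s)%s\n",
    x$config$name, x$config$n_datasets,
    length(unique(x$metrics$method)),
    if (is.null(x$failures)) "" else sprintf(", %d failure(s)",
                                             nrow(x$failures))
  ))
  print(x$metric_means)
  invisible(x)
}

#' Tidy a benchmark into per-dataset rows
#'
#' @param x a `de_benchmark`.
#' @param type `"metrics"` (Ns/FPR/TPR per cutoff) or `"auc"`.
#' @param ... unused.
#' @return tibble of per-dataset values.
#' @export
tidy.de_benchmark <- function(x, type = c("metrics", "auc"), ...) {
  type <- match.arg(type)
  if (type == "metrics") x$metrics else x$auc
}

#' Scenario-level summary of a benchmark
#'
#' @param x a `de_benchmark`.
#' @param ... unused.
#' @return tibble with one row per method and cutoff: mean Ns, FP, TP,
#'   FPR, TPR across datasets, plus the method's mean AUC.
#' @export
glance.de_benchmark <- function(x, ...) {
  out <- x$metric_means
  if (nrow(x$auc_means)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$auc_means, "method", mean_auc = "auc"),
      by = "method"
    )
  }
  out$scenario <- x$config$name
  dplyr::relocate(out, "scenario")
}
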