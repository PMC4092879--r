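# Truth-aware evaluation: BH adjustment, confusion summaries at FDR
# cutoffs, ROC AUC, scenario-level aggregation.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: monotone, capped at 1, ties sharing one
#' adjusted value.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values of the same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

# Coerce a truth argument (truth_table tibble, sim_experiment, or bare d
# vector) into a tibble with gene_id (optional) and d.
as_truth <- function(truth) {
  if (inherits(truth, "sim_experiment")) {
    return(truth$truth)
  }
  if (is.data.frame(truth)) {
    if (!"d" %in% names(truth)) {
      abort("`truth` must contain a `d` column.")
    }
    return(truth)
  }
  tibble(d = as.integer(truth))
}

#' Confusion summary at FDR cutoffs
#'
#' A gene is called significant when its BH-adjusted p-value is at or
#' below the cutoff. True/false positives are split by the truth
#' direction indicator; rates use the truth denominators (`FPR = FP /`
#' number of truly non-DE genes, `TPR = TP /` number of truly DE genes).
#'
#' @param result a `method_result` (or tibble with `gene_id` and `p_adj`).
#' @param truth a `truth_table`, `sim_experiment`, or direction vector.
#' @param cutoffs FDR cutoffs (default `c(0.1, 0.05, 0.01)`).
#' @return a `confusion_summary` tibble with one row per cutoff: columns
#'   `method`, `cutoff`, `ns`, `fp`, `tp`, `fpr`, `tpr`.
#' @export
confusion_at_cutoffs <- function(result, truth,
                                 cutoffs = c(0.1, 0.05, 0.01)) {
  truth <- as_truth(truth)
  if (!is.null(result$gene_id) && !is.null(truth$gene_id)) {
    if (!setequal(result$gene_id, truth$gene_id)) {
      abort("`result` and `truth` cover different gene sets.")
    }
    truth <- truth[match(result$gene_id, truth$gene_id), ]
  } else if (nrow(truth) != nrow(result)) {
    abort("`result` and `truth` have different lengths.")
  }
  if (any(cutoffs <= 0) || any(cutoffs > 1)) {
    abort("FDR cutoffs must lie in (0, 1].")
  }
  d <- truth$d
  n_de <- sum(d != 0)
  n_null <- sum(d == 0)
  rows <- lapply(cutoffs, function(a) {
    sig <- result$p_adj <= a
    tp <- sum(sig & d != 0)
    fp <- sum(sig & d == 0)
    tibble(
      method = attr(result, "method") %||% NA_character_,
      cutoff = a, ns = tp + fp, fp = fp, tp = tp,
      fpr = if (n_null > 0) fp / n_null else NA_real_,
      tpr = if (n_de > 0) tp / n_de else NA_real_
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("confusion_summary", class(tibble())))
}

#' Area under the ROC curve by the rank-sum identity
#'
#' Computes the AUC for ranking truly DE genes above non-DE genes using
#' the Mann-Whitney identity with midrank tie handling. The conventional
#' ranking statistic is `1 - p` (equivalently the posterior probability
#' for the empirical-Bayes method).
#'
#' @param scores per-gene ranking statistic (larger = more significant).
#' @param truth a `truth_table`, `sim_experiment`, or direction vector.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L))
#' @export
roc_auc <- function(scores, truth) {
  truth <- as_truth(truth)
  de <- truth$d != 0
  if (length(scores) != length(de)) {
    abort("`scores` and `truth` have different lengths.")
  }
  n1 <- sum(de)
  n0 <- sum(!de)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined: need at least one DE and one non-DE gene.")
  }
  r <- rank(scores)
  (sum(r[de]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average per-dataset metrics to scenario level
#'
#' Arithmetic mean of every numeric metric across replicate datasets,
#' grouped by the remaining identifier columns (method, cutoff, ...).
#'
#' @param per_dataset tibble of per-dataset metrics including a `dataset`
#'   column.
#' @return tibble of means with one row per identifier combination.
#' @export
aggregate_scenario <- function(per_dataset) {
  if (nrow(per_dataset) == 0) {
    abort("No dataset summaries to aggregate.")
  }
  if (!"dataset" %in% names(per_dataset)) {
    abort("`per_dataset` needs a `dataset` column.")
  }
  keys <- setdiff(names(per_dataset)[!vapply(per_dataset, is.numeric,
                                             logical(1))], "dataset")
  metrics <- setdiff(names(per_dataset)[vapply(per_dataset, is.numeric,
                                               logical(1))], "dataset")
  if ("cutoff" %in% names(per_dataset)) {
    keys <- union(keys, "cutoff")
    metrics <- setdiff(metrics, "cutoff")
  }
  per_dataset |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics), ~ mean(.x)),
      .groups = "drop"
    )
}

#' Internal-consistency check of a published-style performance table
#'
#' For a table of per-method `ns`, `fpr`, `tpr` values at a known genome
#' size and DE proportion, the identity
#' \eqn{N_s \approx FPR \cdot G_0 + TPR \cdot G_1} (with \eqn{G_1} truly
#' DE genes and \eqn{G_0 = G - G_1}) must hold up to rounding. Returns
#' the per-row deviation so inconsistent cells can be spotted.
#'
#' @param table tibble with columns `scenario`, `method`, `cutoff`, `ns`,
#'   `fpr`, `tpr`.
#' @param n_genes genome size G.
#' @param prop_de named vector mapping scenario label to its DE
#'   proportion.
#' @return the table with added columns `ns_implied` and `deviation`.
#' @export
check_performance_identity <- function(table, n_genes = 10000,
                                       prop_de = NULL) {
  if (is.null(prop_de)) {
    p <- scenario_presets()
    prop_de <- stats::setNames(p$prop_de, p$name)
  }
  g1 <- round(prop_de[table$scenario] * n_genes)
  g0 <- n_genes - g1
  table$ns_implied <- table$fpr * g0 + table$tpr * g1
  table$deviation <- abs(table$ns - table$ns_implied)
  table
}

#' Reference performance table from a published six-method benchmark
#'
#' The per-scenario significant-gene counts, false positive rates and
#' true positive rates reported by a published comparison of six
#' count-based RNA-seq differential expression packages, transcribed as
#' printed (including its typographical inconsistencies; see
#' [check_performance_identity()]). Used as a fixture for
#' internal-consistency checks and as a qualitative yardstick.
#'
#' @return tibble with columns `scenario`, `method`, `cutoff`, `ns`,
#'   `fpr`, `tpr`.
#' @export
reference_performance <- function() {
  path <- system.file("extdata", "reference_performance.tsv",
                      package = "countbench")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
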