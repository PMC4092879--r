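# Truth-free concordance across methods: Spearman correlation matrices,
# intraclass correlation, overlap/singleton and identification-frequency
# analysis.

#' Pairwise Spearman correlation matrix
#'
#' Spearman correlations (midranks for ties) between the columns of a
#' gene-by-method value matrix. Constant columns yield `NA` entries with
#' a warning.
#'
#' @param values numeric matrix or data frame, genes in rows and methods
#'   in columns (>= 2 columns, >= 3 rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(values) {
  m <- as.matrix(values)
  if (ncol(m) < 2) abort("Need at least 2 methods (columns).")
  if (nrow(m) < 3) abort("Need at least 3 genes (rows).")
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    warn(sprintf(
      "Constant column(s) give undefined correlations: %s",
      paste(colnames(m)[constant] %||% which(constant), collapse = ", ")
    ))
  }
  suppressWarnings(cor(m, method = "spearman"))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the standard mean-squares decomposition, treating
#' methods as interchangeable raters of each gene.
#'
#' @param values numeric matrix or data frame, genes in rows (>= 2) and
#'   methods in columns (>= 2).
#' @return ICC scalar in `[-1, 1]`; `NA` with a warning when the total
#'   variance is zero.
#' @examples
#' x <- matrix(rnorm(20), ncol = 2)
#' icc(cbind(x[, 1], x[, 1]))
#' @export
icc <- function(values) {
  m <- as.matrix(values)
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("Need at least 2 methods (columns).")
  if (n < 2) abort("Need at least 2 genes (rows).")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  if (sst <= 0) {
    warn("Zero total variance; ICC is undefined.")
    return(NA_real_)
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Validate a named list of method_result objects over one gene universe;
# returns the list with names filled in from the method attribute.
check_result_list <- function(results) {
  if (length(results) < 2) {
    abort("Need at least 2 method results.")
  }
  nms <- names(results) %||% rep("", length(results))
  nms[nms == ""] <- vapply(results[nms == ""], function(r) {
    attr(r, "method") %||% "method"
  }, character(1))
  nms <- make.unique(nms)
  names(results) <- nms
  ref <- results[[1]]$gene_id
  for (i in seq_along(results)) {
    if (!identical(sort(results[[i]]$gene_id), sort(ref))) {
      abort(sprintf(
        "Result '%s' covers a different gene universe than '%s'.",
        nms[i], nms[1]
      ))
    }
    results[[i]] <- results[[i]][match(ref, results[[i]]$gene_id), ]
  }
  results
}

#' Overlap, singleton and identification-frequency report
#'
#' Calls a gene significant for a method when its BH-adjusted p-value is
#' at or below `alpha`. Reports the per-gene identification frequency
#' (number of methods calling it), per-method singleton counts (genes
#' called by exactly one method), per-direction Venn cell counts over all
#' method subsets (methods lacking a direction are excluded from the
#' directional cells with a notice), and fold-change / p-value summaries
#' by identification frequency.
#'
#' @param results named list of `method_result` objects over one gene
#'   universe.
#' @param alpha significance cutoff on the adjusted p-values, in (0, 1).
#' @return a list of class `concordance_overlap` with elements
#'   `identification_frequency`, `singletons`, `venn`, `by_frequency` and
#'   `alpha`.
#' @export
overlap_report <- function(results, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  results <- check_result_list(results)
  nms <- names(results)
  genes <- results[[1]]$gene_id
  sig <- vapply(results, function(r) r$p_adj <= alpha,
                logical(length(genes)))
  colnames(sig) <- nms
  freq <- rowSums(sig)

  singletons <- tibble(
    method = nms,
    n_significant = colSums(sig),
    n_singleton = vapply(nms, function(m) sum(sig[, m] & freq == 1),
                         numeric(1))
  )

  directional <- nms[vapply(results, function(r) {
    isTRUE(attr(r, "has_direction"))
  }, logical(1))]
  if (length(directional) < length(nms)) {
    inform(sprintf(
      "Excluding directionless method(s) from directional overlap: %s",
      paste(setdiff(nms, directional), collapse = ", ")
    ))
  }
  venn <- NULL
  if (length(directional) >= 1) {
    cells <- list()
    for (dir in c("up", "down")) {
      dsig <- vapply(directional, function(m) {
        r <- results[[m]]
        sig[, m] & if (dir == "up") r$direction > 0 else r$direction < 0
      }, logical(length(genes)))
      called <- rowSums(dsig) > 0
      if (!any(called)) next
      combo <- apply(dsig[called, , drop = FALSE], 1, function(z) {
        paste(directional[z], collapse = "+")
      })
      tab <- table(combo)
      cells[[dir]] <- tibble(direction = dir,
                             methods = names(tab),
                             n_genes = as.integer(tab))
    }
    venn <- dplyr::bind_rows(cells)
  }

  fc_mat <- vapply(results, function(r) r$fc, numeric(length(genes)))
  p_mat <- vapply(results, function(r) r$p, numeric(length(genes)))
  by_freq <- tibble(gene_id = genes, frequency = freq,
                    mean_abs_log2_fc = rowMeans(abs(log2(fc_mat))),
                    mean_p = rowMeans(p_mat)) |>
    dplyr::filter(.data$frequency > 0) |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      median_abs_log2_fc = median(.data$mean_abs_log2_fc),
      median_p = median(.data$mean_p),
      .groups = "drop"
    )

  structure(
    list(
      identification_frequency = tibble(gene_id = genes, frequency = freq),
      singletons = singletons,
      venn = venn,
      by_frequency = by_freq,
      alpha = alpha,
      methods = nms,
      directional_methods = directional
    ),
    class = "concordance_overlap"
  )
}

#' Cross-method concordance report
#'
#' Bundles the pairwise Spearman correlation matrices of per-gene fold
#' changes and p-values, the intraclass correlations ICC(2,1) of
#' log2 fold changes and of p-values, and the [overlap_report()].
#'
#' @inheritParams overlap_report
#' @return a list of class `concordance_report` with elements
#'   `spearman_fc`, `spearman_p`, `icc_fc`, `icc_p` and `overlap`.
#' @export
concordance_report <- function(results, alpha = 0.05) {
  results <- check_result_list(results)
  genes <- results[[1]]$gene_id
  fc_mat <- vapply(results, function(r) r$fc, numeric(length(genes)))
  p_mat <- vapply(results, function(r) r$p, numeric(length(genes)))
  structure(
    list(
      spearman_fc = spearman_matrix(fc_mat),
      spearman_p = spearman_matrix(p_mat),
      icc_fc = icc(log2(fc_mat)),
      icc_p = icc(p_mat),
      overlap = overlap_report(results, alpha),
      methods = names(results)
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report>: %d methods; ICC(fc) = %.3f, ICC(p) = %.3f\n",
    length(x$methods), x$icc_fc, x$icc_p
  ))
  invisible(x)
}

#' @export
tidy.concordance_report <- function(x, ...) {
  sp <- as_tibble(as.data.frame(as.table(x$spearman_fc)),
                  .name_repair = "minimal")
  names(sp) <- c("method_a", "method_b", "spearman_fc")
  sp$method_a <- as.character(sp$method_a)
  sp$method_b <- as.character(sp$method_b)
  sp$spearman_p <- as.vector(x$spearman_p)
  sp
}

#' @export
glance.concordance_report <- function(x, ...) {
  tibble(
    n_methods = length(x$methods),
    icc_fc = x$icc_fc,
    icc_p = x$icc_p,
    mean_spearman_fc = mean(x$spearman_fc[upper.tri(x$spearman_fc)]),
    mean_spearman_p = mean(x$spearman_p[upper.tri(x$spearman_p)])
  )
}
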