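# Shared scaffolding for the differential expression test families.

#' Available differential expression test families
#'
#' @return character vector of method identifiers accepted by [de_test()]:
#'   `"poisson_ma"` (Poisson MA-style conditional test),
#'   `"nb_exact"` (NB exact test with empirical-Bayes dispersion
#'   shrinkage), `"nb_pooled"` (NB exact test with a fitted
#'   mean-dispersion trend), `"nbp"` (NB exact test with a power-law
#'   dispersion model), `"tspm"` (two-stage Poisson) and `"eb_nb"`
#'   (empirical-Bayes NB posterior).
#' @export
de_methods_available <- function() {
  c("poisson_ma", "nb_exact", "nb_pooled", "nbp", "tspm", "eb_nb")
}

# Assemble the uniform per-gene result tibble. `direction` may be NULL
# (posterior method): it is stored as NA and the method is marked
# directionless.
method_result <- function(method_name, gene_id, p, fc, direction,
                          norm_factors, details = list()) {
  p <- pmin(pmax(p, 0), 1)
  has_direction <- !is.null(direction)
  out <- tibble(
    gene_id = as.character(gene_id),
    p = as.numeric(p),
    p_adj = bh_adjust(p),
    fc = as.numeric(fc),
    direction = if (has_direction) as.numeric(direction) else NA_real_
  )
  structure(
    out,
    class = c("method_result", class(tibble())),
    method = method_name,
    has_direction = has_direction,
    norm_factors = norm_factors,
    details = details
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf(
    "<method_result '%s'>: %d genes, %d significant at BH 0.05%s\n",
    attr(x, "method"), nrow(x), sum(x$p_adj <= 0.05),
    if (attr(x, "has_direction")) "" else " (no direction reported)"
  ))
  NextMethod()
}

# Resolve counts/group into the pieces every test needs.
prepare_test_input <- function(counts, group, norm_factors = NULL) {
  m <- as_count_matrix(counts, require_integer = TRUE)
  grp <- check_two_groups(group, ncol(m))
  f <- norm_factors %||% normalize_total_count(m)
  y <- sweep(m, 2, f, "/")
  list(
    counts = m, group = grp, f = f, y = y,
    k1 = round(rowSums(y[, grp$idx1, drop = FALSE])),
    k2 = round(rowSums(y[, grp$idx2, drop = FALSE])),
    n1 = length(grp$idx1), n2 = length(grp$idx2),
    zero = rowSums(m) == 0
  )
}

# Per-gene fitted means under the two-group model with library-size
# offsets: m_hat[g, j] = (group mean of gene g) * f_j.
fitted_group_means <- function(input) {
  sum_f1 <- sum(input$f[input$group$idx1])
  sum_f2 <- sum(input$f[input$group$idx2])
  m1 <- rowSums(input$counts[, input$group$idx1, drop = FALSE]) / sum_f1
  m2 <- rowSums(input$counts[, input$group$idx2, drop = FALSE]) / sum_f2
  mu <- matrix(0, nrow = nrow(input$counts), ncol = ncol(input$counts))
  mu[, input$group$idx1] <- outer(m1, input$f[input$group$idx1])
  mu[, input$group$idx2] <- outer(m2, input$f[input$group$idx2])
  list(m1 = m1, m2 = m2, mu = mu)
}

# Apply the all-zero-gene policy: p = 1, fc = 1, direction 0 where a gene
# has no reads in any sample (undefined tests must not break BH).
apply_zero_policy <- function(p, fc, direction, zero) {
  p[zero] <- 1
  fc[zero] <- 1
  if (!is.null(direction)) direction[zero] <- 0
  list(p = p, fc = fc, direction = direction)
}

#' Run one differential expression test family
#'
#' Uniform dispatcher over the six implemented test families; see
#' [de_methods_available()] for identifiers and the individual functions
#' ([poisson_ma_test()], [nb_exact_test()], [nb_pooled_test()],
#' [nbp_test()], [two_stage_poisson()], [eb_nb_posterior()]) for the
#' statistics.
#'
#' @param counts gene-by-sample integer count matrix (or data frame with a
#'   gene_id first column, or a `sim_experiment`).
#' @param group two-group label vector; defaults to the experiment's own
#'   groups when `counts` is a `sim_experiment`.
#' @param method one of [de_methods_available()].
#' @param ... passed to the selected test function.
#' @return a `method_result` tibble with columns `gene_id`, `p`, `p_adj`,
#'   `fc` and `direction`.
#' @examples
#' cfg <- scenario_preset("I", n_genes = 50, n_datasets = 1, seed = 1)
#' sim <- simulate_scenario(cfg)[[1]]
#' de_test(sim, method = "poisson_ma")
#' @export
de_test <- function(counts, group = NULL, method = "nb_exact", ...) {
  if (inherits(counts, "sim_experiment")) {
    group <- group %||% counts$group
    counts <- counts$counts
  }
  if (is.null(group)) {
    abort("`group` is required unless `counts` is a sim_experiment.")
  }
  method <- match.arg(method, de_methods_available())
  fn <- switch(method,
    poisson_ma = poisson_ma_test,
    nb_exact = nb_exact_test,
    nb_pooled = nb_pooled_test,
    nbp = nbp_test,
    tspm = two_stage_poisson,
    eb_nb = eb_nb_posterior
  )
  fn(counts, group, ...)
}
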