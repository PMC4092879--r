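# shared input coercion and seeding helpers

#' Coerce counts input to an integer gene-by-sample matrix
#'
#' Accepts a numeric matrix (genes in rows) or a data frame whose first
#' column holds gene identifiers and whose remaining columns are samples.
#'
#' @param counts matrix or data frame of non-negative integer counts.
#' @param require_integer error on non-integer cells (default `TRUE`).
#' @return numeric matrix with gene identifiers as row names.
#' @keywords internal
#' @noRd
as_count_matrix <- function(counts, require_integer = TRUE) {
  if (inherits(counts, "sim_experiment")) {
    return(counts$counts)
  }
  if (is.data.frame(counts)) {
    if (ncol(counts) < 2) {
      abort("A counts data frame needs a gene_id column plus sample columns.")
    }
    ids <- as.character(counts[[1]])
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- ids
  } else if (is.matrix(counts)) {
    m <- counts
  } else {
    abort("`counts` must be a matrix or a data frame with a gene_id column.")
  }
  if (!is.numeric(m)) {
    abort("Counts must be numeric.")
  }
  if (anyNA(m)) {
    abort("Counts must not contain missing values.")
  }
  if (any(m < 0)) {
    abort("Counts must be non-negative.")
  }
  if (require_integer && any(abs(m - round(m)) > 1e-8)) {
    abort("Counts must be integers (read counts).")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("gene_%05d", seq_len(nrow(m)))
  }
  m
}

# Evaluate `expr` under `seed` (restoring RNG state afterwards), or in the
# current RNG stream when seed is NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Draw n child seeds (< 2^31) from the current RNG stream.
spawn_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

# Validate and normalise a two-group label vector; returns a list with the
# sample indices of each group and the group labels.
check_two_groups <- function(group, n_samples) {
  if (length(group) != n_samples) {
    abort(sprintf(
      "`group` has length %d but the counts have %d samples.",
      length(group), n_samples
    ))
  }
  g <- factor(group)
  if (nlevels(g) != 2) {
    abort("Exactly two groups are required.")
  }
  list(
    idx1 = which(g == levels(g)[1]),
    idx2 = which(g == levels(g)[2]),
    labels = levels(g),
    factor = g
  )
}
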