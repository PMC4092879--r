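# Library-size normalization and shared expression summaries.

#' Total-count normalization factors
#'
#' Per-sample scaling factors from library totals:
#' `factor_j = total_j / geometric mean of totals`. Dividing a sample's
#' counts by its factor equalizes library sizes; the factors multiply to 1.
#'
#' @param counts gene-by-sample count matrix (or data frame with a gene_id
#'   first column).
#' @return named numeric vector of positive factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), nrow = 2)
#' normalize_total_count(m)
#' @export
normalize_total_count <- function(counts) {
  m <- as_count_matrix(counts, require_integer = FALSE)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0] %||% which(totals <= 0)
    abort(sprintf(
      "Sample(s) with zero total count cannot be normalized: %s",
      paste(bad, collapse = ", ")
    ))
  }
  f <- totals / exp(mean(log(totals)))
  stats::setNames(f, colnames(m))
}

#' Reads per kilobase per million mapped reads
#'
#' \eqn{RPKM = 10^9 \cdot C / (N \cdot L)} where `C` is the read count of
#' the gene, `N` the total mapped reads of the sample and `L` the gene
#' length in bases.
#'
#' @param C reads mapped to the gene (>= 0).
#' @param N total mapped reads (> 0).
#' @param L gene length in bases (> 0).
#' @return RPKM value(s); vectorized over the arguments.
#' @examples
#' compute_rpkm(10, 1e6, 1000)
#' @export
compute_rpkm <- function(C, N, L) {
  if (any(N <= 0)) abort("`N` (total mapped reads) must be > 0.")
  if (any(L <= 0)) abort("`L` (gene length) must be > 0.")
  if (any(C < 0)) abort("`C` (gene reads) must be >= 0.")
  1e9 * C / (N * L)
}

#' Shared fold-change estimator
#'
#' Fold change of group 2 over group 1 on normalized counts with a
#' stabilizing pseudocount:
#' `fc = (mean normalized group-2 count + pseudocount) /
#'       (mean normalized group-1 count + pseudocount)`.
#' All test families report this common estimator so that cross-method
#' fold-change concordance reflects normalization alone.
#'
#' @param counts gene-by-sample count matrix.
#' @param group two-group label vector.
#' @param norm_factors optional per-sample factors (default:
#'   [normalize_total_count()]).
#' @param pseudocount non-negative stabilizer, default 0.5.
#' @return numeric vector of positive per-gene fold changes.
#' @export
fold_change_estimate <- function(counts, group, norm_factors = NULL,
                                 pseudocount = 0.5) {
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  m <- as_count_matrix(counts, require_integer = FALSE)
  grp <- check_two_groups(group, ncol(m))
  f <- norm_factors %||% normalize_total_count(m)
  y <- sweep(m, 2, f, "/")
  m1 <- rowMeans(y[, grp$idx1, drop = FALSE])
  m2 <- rowMeans(y[, grp$idx2, drop = FALSE])
  (m2 + pseudocount) / (m1 + pseudocount)
}
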