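# Poisson MA-style test (conditional binomial on pooled counts).

#' Poisson MA-style differential expression test
#'
#' Pools the raw counts of each gene within groups. Under a Poisson null
#' with equal per-library rates, the group-1 pooled count \eqn{k_1} given
#' the total \eqn{n = k_1 + k_2} is binomial with success probability
#' \eqn{N_1 / (N_1 + N_2)}, where \eqn{N_1, N_2} are the summed library
#' sizes of the groups. The two-sided p-value comes from the normal
#' approximation \eqn{z = (k_1 - n p) / \sqrt{n p (1 - p)}}. Because the
#' Poisson null ignores biological overdispersion, this family is
#' over-sensitive on negative binomial data.
#'
#' @param counts gene-by-sample integer count matrix.
#' @param group two-group label vector.
#' @param norm_factors optional per-sample normalization factors used for
#'   the fold-change estimate.
#' @return a `method_result` tibble.
#' @examples
#' m <- matrix(rpois(200, 50), nrow = 20)
#' poisson_ma_test(m, rep(1:2, each = 5))
#' @export
poisson_ma_test <- function(counts, group, norm_factors = NULL) {
  input <- prepare_test_input(counts, group, norm_factors)
  m <- input$counts
  grp <- input$group
  k1 <- rowSums(m[, grp$idx1, drop = FALSE])
  k2 <- rowSums(m[, grp$idx2, drop = FALSE])
  N1 <- sum(m[, grp$idx1])
  N2 <- sum(m[, grp$idx2])
  pr <- N1 / (N1 + N2)
  n <- k1 + k2
  z <- ifelse(n > 0, (k1 - n * pr) / sqrt(n * pr * (1 - pr)), 0)
  p <- ifelse(n > 0, 2 * pnorm(-abs(z)), 1)
  fc <- fold_change_estimate(m, grp$factor, input$f)
  direction <- sign(log(fc))
  pol <- apply_zero_policy(p, fc, direction, input$zero)
  method_result("poisson_ma", rownames(m), pol$p, pol$fc, pol$direction,
                input$f, details = list(z = z))
}
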