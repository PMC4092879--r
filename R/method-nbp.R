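# NB exact test with a power-law dispersion model ("NBP"):
# phi(mu) = phi0 * mu^(alpha - 2), with global (phi0, alpha) fitted by
# maximum likelihood. alpha = 2 collapses to a constant dispersion.

# Cox-Reid adjusted negative log-likelihood of (log phi0, alpha) over all
# usable genes at fitted two-group means (the adjustment removes the
# downward bias of profiling out the group means).
nbp_negloglik <- function(par, counts, mu, m_gene, group_cols) {
  phi0 <- exp(par[1])
  alpha <- par[2]
  phi <- pmin(pmax(phi0 * m_gene^(alpha - 2), 1e-8), 100)
  mu <- pmax(mu, 1e-10)
  ll <- rowSums(dnbinom(counts, mu = mu, size = 1 / phi, log = TRUE))
  w <- mu / (1 + phi * mu)
  adj <- 0
  for (cols in group_cols) {
    adj <- adj + 0.5 * log(rowSums(w[, cols, drop = FALSE]))
  }
  -sum(ll - adj)
}

#' Exact NB test with power-law dispersion
#'
#' Models the dispersion as a smooth power function of expression,
#' \eqn{\phi(\mu) = \phi_0 \mu^{\alpha - 2}}, fits the two global
#' parameters by maximum likelihood over all genes (group means profiled
#' out), and applies the exact conditional NB test with the fitted
#' per-gene dispersions. \eqn{\alpha = 2} reproduces a constant
#' dispersion \eqn{\phi_0}; on non-convergence the fit falls back to that
#' case with a warning.
#'
#' @inheritParams nb_exact_test
#' @param phi0,alpha optional fixed power-law parameters overriding the
#'   ML fit (both must be supplied together).
#' @return a `method_result` tibble; `details` carries `phi0`, `alpha`
#'   and the per-gene dispersions.
#' @export
nbp_test <- function(counts, group, phi0 = NULL, alpha = NULL,
                     norm_factors = NULL) {
  input <- prepare_test_input(counts, group, norm_factors)
  fit <- fitted_group_means(input)
  keep <- !input$zero
  m_gene <- rowMeans(input$y)
  if (xor(is.null(phi0), is.null(alpha))) {
    abort("Supply both `phi0` and `alpha`, or neither.")
  }
  if (is.null(phi0)) {
    if (ncol(input$counts) - 2 < 1) {
      abort(paste(
        "No residual degrees of freedom to fit the dispersion model;",
        "supply `phi0` and `alpha`."
      ))
    }
    common <- estimate_common_dispersion(input$counts, input$group$factor,
                                         input$f)
    opt <- tryCatch(
      optim(
        c(log(max(common, 1e-4)), 2),
        nbp_negloglik,
        counts = input$counts[keep, , drop = FALSE],
        mu = fit$mu[keep, , drop = FALSE],
        m_gene = m_gene[keep],
        group_cols = list(input$group$idx1, input$group$idx2),
        method = "L-BFGS-B",
        lower = c(log(1e-6), 0.25),
        upper = c(log(1e3), 3.75)
      ),
      error = function(e) NULL
    )
    if (is.null(opt) || opt$convergence != 0) {
      warn("Power-law dispersion fit did not converge; using alpha = 2.")
      phi0 <- max(common, 1e-6)
      alpha <- 2
    } else {
      phi0 <- exp(opt$par[1])
      alpha <- opt$par[2]
    }
  }
  phi <- pmin(pmax(phi0 * ifelse(m_gene > 0, m_gene, 1)^(alpha - 2), 1e-8),
              100)
  p <- nb_exact_pvalue(input$k1, input$k2, input$n1, input$n2, phi)
  fc <- fold_change_estimate(input$counts, input$group$factor, input$f)
  direction <- sign(log(fc))
  pol <- apply_zero_policy(p, fc, direction, input$zero)
  method_result("nbp", rownames(input$counts), pol$p, pol$fc,
                pol$direction, input$f,
                details = list(phi0 = phi0, alpha = alpha, dispersion = phi))
}
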