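# Empirical-Bayes NB posterior method.
#
# Per-gene marginal likelihoods of "equivalent expression" (one shared
# mean) and "different expression" (the mean split between groups by a
# log-fold-change prior) are averaged over dispersion hyperparameters
# sampled from a random subset of genes — the method's deliberate
# randomization. Likelihoods are evaluated on library-size-equalized
# per-sample counts, so hyperparameter sets that fit a gene poorly are
# suppressed exponentially in the sample count. The prior DE proportion
# is estimated by iterative re-weighting.

# log-likelihood pieces for NB(mu, size r) at equalized counts:
# sum_j log f(y_j) = W - n*lgamma(r) + n*r*log(r/(r+mu)) + T*log(mu/(r+mu))
# up to a term free of (mu, r) that cancels in the posterior.
# W = sum_j lgamma(y_j + r) and T = sum_j y_j.

#' Empirical-Bayes NB posterior test
#'
#' For each gene the marginal likelihoods of "equivalent expression" and
#' "different expression" are computed on library-size-equalized counts,
#' averaging over `n_hyper_samples` dispersion values sampled from a
#' random subset of genes and, for the DE model, over a normal prior on
#' the log fold change evaluated on a quadrature grid. The prior DE
#' proportion is estimated by iterative re-weighting and the reported
#' `p` slot is 1 minus the posterior probability of differential
#' expression. No direction is reported. With `seed = NULL` repeated
#' runs differ slightly (the hyperparameter subset is re-sampled); with
#' a fixed seed the result is reproducible.
#'
#' @inheritParams nb_exact_test
#' @param n_hyper_samples number of sampled hyperparameter sets (>= 1).
#' @param seed optional seed for the hyperparameter sampling.
#' @param prior_lfc_sd standard deviation of the natural-log fold-change
#'   prior under the DE model (default 2).
#' @param n_lfc_nodes quadrature nodes for the fold-change prior.
#' @param max_iter,tol iteration control for the prior DE proportion.
#' @return a `method_result` tibble with `direction = NA` (the method is
#'   directionless); `details` carries the estimated prior DE proportion
#'   and the posterior probabilities.
#' @export
eb_nb_posterior <- function(counts, group, n_hyper_samples = 50,
                            seed = NULL, prior_lfc_sd = 2,
                            n_lfc_nodes = 13, max_iter = 50, tol = 1e-8,
                            norm_factors = NULL) {
  if (length(n_hyper_samples) != 1 || n_hyper_samples < 1) {
    abort("`n_hyper_samples` must be a single value >= 1.")
  }
  input <- prepare_test_input(counts, group, norm_factors)
  G <- nrow(input$counts)
  n1 <- input$n1
  n2 <- input$n2
  n <- n1 + n2
  # library-size-equalized pseudo-counts
  yt <- round(sweep(input$counts, 2, input$f, "/"))
  T1 <- rowSums(yt[, input$group$idx1, drop = FALSE])
  T2 <- rowSums(yt[, input$group$idx2, drop = FALSE])
  s <- T1 + T2

  mom <- moment_dispersions(input)
  phi_hat <- pmin(pmax(ifelse(is.finite(mom$phi), mom$phi, 1e-4), 1e-4), 10)
  eligible <- which(s > 0)
  if (length(eligible) == 0) {
    abort("All genes have zero counts; nothing to analyze.")
  }
  idx <- with_seed_if(seed, {
    sample(eligible, n_hyper_samples, replace = TRUE)
  })
  phi_hyper <- phi_hat[idx]

  lfc <- seq(-3, 3, length.out = n_lfc_nodes) * prior_lfc_sd
  w_lfc <- dnorm(lfc, 0, prior_lfc_sd)
  w_lfc <- w_lfc / sum(w_lfc)

  m0 <- pmax(s / n, 1e-10)
  ll0 <- matrix(-Inf, G, n_hyper_samples)
  ll1 <- matrix(-Inf, G, n_hyper_samples)
  for (i in seq_len(n_hyper_samples)) {
    r <- 1 / phi_hyper[i]
    W <- rowSums(lgamma(yt + r)) - n * lgamma(r)
    ll0[, i] <- W + n * r * log(r / (r + m0)) + s * log(m0 / (r + m0))
    acc <- rep(-Inf, G)
    for (t in seq_along(lfc)) {
      q <- exp(lfc[t])
      m1 <- pmax(m0 * n / (n1 + n2 * q), 1e-10)
      m2 <- pmax(q * m1, 1e-10)
      piece <- W +
        n1 * r * log(r / (r + m1)) + T1 * log(m1 / (r + m1)) +
        n2 * r * log(r / (r + m2)) + T2 * log(m2 / (r + m2))
      acc <- pmax(acc, piece + log(w_lfc[t])) +
        log1p(exp(-abs(acc - piece - log(w_lfc[t]))))
    }
    ll1[, i] <- acc
  }
  logmeanexp <- function(mat) {
    mx <- apply(mat, 1, max)
    mx + log(rowMeans(exp(mat - mx)))
  }
  l0 <- logmeanexp(ll0)
  l1 <- logmeanexp(ll1)

  # prior DE proportion by iterative re-weighting
  pde <- 0.1
  nonzero <- s > 0
  lr <- l1 - l0
  lr[!nonzero] <- 0
  for (it in seq_len(max_iter)) {
    odds <- pde / (1 - pde) * exp(pmin(lr, 700))
    post <- odds / (1 + odds)
    pde_new <- min(max(mean(post[nonzero]), 1e-4), 0.999)
    if (abs(pde_new - pde) < tol) {
      pde <- pde_new
      break
    }
    pde <- pde_new
  }
  odds <- pde / (1 - pde) * exp(pmin(lr, 700))
  post <- odds / (1 + odds)

  p <- 1 - post
  fc <- fold_change_estimate(input$counts, input$group$factor, input$f)
  pol <- apply_zero_policy(p, fc, NULL, input$zero)
  method_result("eb_nb", rownames(input$counts), pol$p, pol$fc, NULL,
                input$f,
                details = list(prior_de = pde, posterior = post,
                               phi_hyper = phi_hyper))
}
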