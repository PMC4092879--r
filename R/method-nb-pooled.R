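# NB exact test with a fitted mean-dispersion trend (pooled per-gene
# moment estimates, parametric trend phi(mu) = a1 + a0 / mu, working
# dispersion = max(gene-wise, trend)).

# Pooled within-group method-of-moments dispersion per gene on normalized
# counts. Returns mean, pooled variance and the moment dispersion.
moment_dispersions <- function(input) {
  y <- input$y
  i1 <- input$group$idx1
  i2 <- input$group$idx2
  m <- rowMeans(y)
  rowvar <- function(cols) {
    if (length(cols) < 2) {
      return(rep(NA_real_, nrow(y)))
    }
    sub <- y[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    rowSums((sub - mu)^2) / (length(cols) - 1)
  }
  v1 <- rowvar(i1)
  v2 <- rowvar(i2)
  df1 <- max(length(i1) - 1, 0)
  df2 <- max(length(i2) - 1, 0)
  w <- (df1 * ifelse(is.na(v1), 0, v1) + df2 * ifelse(is.na(v2), 0, v2)) /
    max(df1 + df2, 1)
  phi <- ifelse(m > 0, (w - m) / m^2, NA_real_)
  list(mean = m, var = w, phi = phi)
}

#' Fit a parametric mean-dispersion trend
#'
#' Regresses per-gene moment dispersions on the inverse mean,
#' \eqn{\phi(\mu) = a_1 + a_0 / \mu}, by a gamma-family GLM with identity
#' link (falling back to ordinary least squares, then to a flat trend at
#' the median dispersion, when the fit degenerates).
#'
#' @param mu per-gene mean normalized counts.
#' @param phi_hat per-gene moment dispersion estimates.
#' @return named numeric `c(a0, a1)` (slope on `1/mu`, asymptote).
#' @export
fit_dispersion_trend <- function(mu, phi_hat) {
  use <- is.finite(mu) & is.finite(phi_hat) & mu > 0 & phi_hat > 1e-8
  fallback <- function() {
    med <- if (any(use)) median(phi_hat[use]) else 0.1
    warn("Dispersion trend fit degenerated; using a flat trend.")
    c(a0 = 0, a1 = med)
  }
  if (sum(use) < 10) {
    return(fallback())
  }
  x <- 1 / mu[use]
  d <- phi_hat[use]
  co <- tryCatch({
    start <- coef(lm(d ~ x))
    fit <- suppressWarnings(glm(d ~ x, family = Gamma(link = "identity"),
                                start = pmax(start, c(1e-3, 1e-3))))
    coef(fit)
  }, error = function(e) tryCatch(coef(lm(d ~ x)),
                                  error = function(e2) NULL))
  if (is.null(co) || anyNA(co)) {
    return(fallback())
  }
  a1 <- max(co[[1]], 0)
  a0 <- max(co[[2]], 0)
  if (a0 == 0 && a1 == 0) {
    return(fallback())
  }
  c(a0 = a0, a1 = a1)
}

#' Exact NB test with a pooled mean-dispersion trend
#'
#' Per-gene dispersions are estimated by the method of moments on
#' normalized counts (pooled across groups), a smooth parametric trend
#' \eqn{\phi(\mu) = a_1 + a_0/\mu} is fitted over genes, and the working
#' dispersion of each gene is the maximum of its own estimate and the
#' trend value — a conservative choice that guards against
#' underestimated variability. The exact conditional NB test is then
#' applied with the working dispersions.
#'
#' @inheritParams nb_exact_test
#' @param trend_coef optional fixed trend coefficients `c(a0, a1)`
#'   overriding the fit.
#' @return a `method_result` tibble; `details` carries the gene-wise,
#'   trend and working dispersions.
#' @export
nb_pooled_test <- function(counts, group, dispersion = NULL,
                           trend_coef = NULL, norm_factors = NULL) {
  input <- prepare_test_input(counts, group, norm_factors)
  G <- nrow(input$counts)
  details <- list()
  if (!is.null(dispersion)) {
    if (any(dispersion < 0)) abort("`dispersion` must be >= 0.")
    phi <- rep_len(dispersion, G)
  } else {
    if (ncol(input$counts) - 2 < 1) {
      abort(paste(
        "No residual degrees of freedom to estimate dispersions;",
        "supply `dispersion` explicitly."
      ))
    }
    mom <- moment_dispersions(input)
    co <- trend_coef %||% fit_dispersion_trend(mom$mean, mom$phi)
    trend <- ifelse(mom$mean > 0, co[[2]] + co[[1]] / mom$mean, co[[2]])
    gene_wise <- ifelse(is.finite(mom$phi), pmax(mom$phi, 0), 0)
    phi <- pmin(pmax(pmax(gene_wise, trend), 1e-8), 100)
    details <- list(gene_dispersion = gene_wise, trend_coef = co,
                    trend_dispersion = trend, dispersion = phi)
  }
  p <- nb_exact_pvalue(input$k1, input$k2, input$n1, input$n2, phi)
  fc <- fold_change_estimate(input$counts, input$group$factor, input$f)
  direction <- sign(log(fc))
  pol <- apply_zero_policy(p, fc, direction, input$zero)
  method_result("nb_pooled", rownames(input$counts), pol$p, pol$fc,
                pol$direction, input$f, details = details)
}
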