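# Dispersion estimation on a log-phi grid.
#
# The per-gene log-likelihood profile over dispersion is evaluated on a
# fixed grid with group means profiled out (library-size offsets kept in
# the fitted means). Common dispersion maximizes the summed profile;
# per-gene (tagwise) dispersions maximize a weighted compromise between
# the gene's own profile and the genome-wide average, the weight acting as
# prior degrees of freedom.

dispersion_grid <- function(lower = 1e-4, upper = 20, n = 60) {
  exp(seq(log(lower), log(upper), length.out = n))
}

# Genes x grid matrix of Cox-Reid adjusted NB profile log-likelihoods at
# fitted two-group means. The adjustment subtracts half the log Fisher
# information of the profiled group means, removing the downward bias of
# the plug-in profile (without it, dispersions are underestimated by
# roughly a factor (n - 2)/n and the exact test becomes anticonservative).
nb_loglik_grid <- function(counts, mu, grid, group_cols = NULL) {
  ll <- matrix(0, nrow = nrow(counts), ncol = length(grid))
  mu <- pmax(mu, 1e-10)
  for (k in seq_along(grid)) {
    raw <- rowSums(dnbinom(counts, mu = mu, size = 1 / grid[k], log = TRUE))
    adj <- 0
    if (!is.null(group_cols)) {
      w <- mu / (1 + grid[k] * mu)
      for (cols in group_cols) {
        adj <- adj + 0.5 * log(rowSums(w[, cols, drop = FALSE]))
      }
    }
    ll[, k] <- raw - adj
  }
  ll
}

# Quadratic interpolation of the maximum around grid index i on log(phi).
refine_grid_max <- function(lx, y, i) {
  if (i <= 1 || i >= length(lx)) {
    return(exp(lx[i]))
  }
  x0 <- lx[i - 1]; x1 <- lx[i]; x2 <- lx[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- (y0 - 2 * y1 + y2)
  if (!is.finite(denom) || denom >= 0) {
    return(exp(x1))
  }
  xs <- x1 - 0.5 * ((x1 - x0)^2 * (y1 - y2) - (x1 - x2)^2 * (y1 - y0)) /
    ((x1 - x0) * (y1 - y2) - (x1 - x2) * (y1 - y0))
  exp(max(min(xs, x2), x0))
}

#' Common NB dispersion by profile likelihood
#'
#' Maximizes the summed per-gene NB log-likelihood over a shared
#' dispersion, with two-group means profiled out and library sizes as
#' offsets.
#'
#' @inheritParams nb_exact_test
#' @return a single dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, group, norm_factors = NULL) {
  input <- prepare_test_input(counts, group, norm_factors)
  fit <- fitted_group_means(input)
  grid <- dispersion_grid()
  ll <- nb_loglik_grid(input$counts[!input$zero, , drop = FALSE],
                       fit$mu[!input$zero, , drop = FALSE], grid,
                       group_cols = list(input$group$idx1,
                                         input$group$idx2))
  tot <- colSums(ll)
  refine_grid_max(log(grid), tot, which.max(tot))
}

# Tagwise dispersions shrunk toward the genome-wide profile. Returns a
# list with per-gene phi and the common phi.
estimate_shrunk_dispersions <- function(input, prior_df = 20) {
  fit <- fitted_group_means(input)
  keep <- !input$zero
  grid <- dispersion_grid()
  ll <- nb_loglik_grid(input$counts[keep, , drop = FALSE],
                       fit$mu[keep, , drop = FALSE], grid,
                       group_cols = list(input$group$idx1,
                                         input$group$idx2))
  tot <- colSums(ll)
  common <- refine_grid_max(log(grid), tot, which.max(tot))
  n <- ncol(input$counts)
  df <- max(n - 2, 1)
  w <- prior_df / df
  shared <- colMeans(ll)
  lx <- log(grid)
  phi <- rep(common, nrow(input$counts))
  obj <- ll + matrix(w * shared, nrow = nrow(ll), ncol = length(grid),
                     byrow = TRUE)
  idx <- max.col(obj, ties.method = "first")
  phi_keep <- vapply(seq_len(nrow(obj)), function(g) {
    refine_grid_max(lx, obj[g, ], idx[g])
  }, numeric(1))
  phi[keep] <- phi_keep
  list(phi = phi, common = common)
}
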