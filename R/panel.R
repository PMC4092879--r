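# Per-gene negative binomial parameter panels.
#
# A panel is a tibble with columns gene_id, mu, phi under the NB2
# parameterization: variance = mu + phi * mu^2 (phi = 0 is Poisson).

new_nb_panel <- function(x) {
  structure(x, class = c("nb_panel", class(tibble())))
}

#' Construct a negative binomial gene parameter panel
#'
#' A panel holds one row per gene with its negative binomial mean `mu`
#' (expected read count per library) and dispersion `phi`, under the NB2
#' parameterization with variance \eqn{\mu + \phi \mu^2}.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param mu non-negative per-gene NB means.
#' @param phi non-negative per-gene NB dispersions.
#' @return a tibble of class `nb_panel` with columns `gene_id`, `mu`, `phi`.
#' @examples
#' nb_panel(c("g1", "g2"), mu = c(50, 200), phi = c(0.2, 0.05))
#' @export
nb_panel <- function(gene_id, mu, phi) {
  panel <- tibble(
    gene_id = as.character(gene_id),
    mu = as.numeric(mu),
    phi = as.numeric(phi)
  )
  validate_nb_panel(new_nb_panel(panel))
}

#' Validate a gene parameter panel
#'
#' Checks the panel invariants: at least one gene, unique gene identifiers,
#' finite `mu >= 0` and `phi >= 0`.
#'
#' @param panel an [nb_panel()] (or data frame with the same columns).
#' @return the validated panel, invisibly classed as `nb_panel`.
#' @export
validate_nb_panel <- function(panel) {
  required <- c("gene_id", "mu", "phi")
  if (!all(required %in% names(panel))) {
    abort("A panel needs columns gene_id, mu and phi.")
  }
  if (nrow(panel) < 1) {
    abort("A panel must contain at least one gene.")
  }
  if (anyDuplicated(panel$gene_id)) {
    abort("Panel gene_ids must be unique.")
  }
  if (anyNA(panel$mu) || anyNA(panel$phi) ||
      any(!is.finite(panel$mu)) || any(!is.finite(panel$phi))) {
    abort("Panel mu and phi must be finite and non-missing.")
  }
  if (any(panel$mu < 0) || any(panel$phi < 0)) {
    abort("Panel mu and phi must be non-negative.")
  }
  if (!inherits(panel, "nb_panel")) {
    panel <- new_nb_panel(as_tibble(panel))
  }
  panel
}

#' Generate a stand-in gene parameter panel
#'
#' Draws a synthetic per-gene parameter panel emulating bulk RNA-seq:
#' means from a log-normal law and dispersions from a gamma law. The
#' defaults give a median mean count of about 60 (spanning roughly 1 to a
#' few thousand) and a median dispersion of about 0.3 — typical of
#' heterogeneous human tissue cohorts. Use [estimate_nb_params()] instead
#' when a real count matrix is available.
#'
#' @param n_genes number of genes (>= 1).
#' @param mu_meanlog,mu_sdlog log-scale location and spread of the mean law
#'   (`mu_sdlog = 0` gives all genes the same mean).
#' @param phi_shape,phi_rate shape and rate of the gamma dispersion law
#'   (both > 0).
#' @param depth_lower_bound minimum per-gene mean; genes below it are
#'   resampled (see [truncate_panel_at_depth()]).
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @return an [nb_panel()] of `n_genes` genes.
#' @examples
#' panel <- make_standin_panel(100, seed = 1)
#' summary(panel$mu)
#' @export
make_standin_panel <- function(n_genes = 10000,
                               mu_meanlog = log(60),
                               mu_sdlog = 1.5,
                               phi_shape = 2,
                               phi_rate = 5.6,
                               depth_lower_bound = 0,
                               seed = NULL) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1) {
    abort("`n_genes` must be a single value >= 1.")
  }
  if (mu_sdlog < 0) {
    abort("`mu_sdlog` must be >= 0.")
  }
  if (phi_shape <= 0 || phi_rate <= 0) {
    abort("`phi_shape` and `phi_rate` must be > 0.")
  }
  if (depth_lower_bound < 0) {
    abort("`depth_lower_bound` must be >= 0.")
  }
  n_genes <- as.integer(n_genes)
  with_seed_if(seed, {
    panel <- nb_panel(
      gene_id = sprintf("gene_%05d", seq_len(n_genes)),
      mu = rlnorm(n_genes, meanlog = mu_meanlog, sdlog = mu_sdlog),
      phi = rgamma(n_genes, shape = phi_shape, rate = phi_rate)
    )
    attr(panel, "spec") <- list(
      mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
      phi_shape = phi_shape, phi_rate = phi_rate
    )
    if (depth_lower_bound > 0) {
      panel <- truncate_panel_at_depth(panel, depth_lower_bound)
    }
    panel
  })
}

#' Enforce a lower bound on panel means by resampling
#'
#' Genes whose NB mean falls below `depth_lower_bound` are redrawn until
#' the whole panel satisfies the bound; the panel size is preserved. For
#' panels generated by [make_standin_panel()] the redraw uses the original
#' log-normal law; for other panels it bootstraps from the panel's own
#' means at or above the bound.
#'
#' @param panel an [nb_panel()].
#' @param depth_lower_bound minimum mean count (>= 0); 0 leaves the panel
#'   unchanged.
#' @param max_rounds resampling rounds before giving up (guards against a
#'   bound outside the mean law's effective support).
#' @return the panel with every `mu >= depth_lower_bound`.
#' @export
truncate_panel_at_depth <- function(panel, depth_lower_bound, max_rounds = 1000) {
  panel <- validate_nb_panel(panel)
  if (depth_lower_bound < 0) {
    abort("`depth_lower_bound` must be >= 0.")
  }
  if (depth_lower_bound == 0) {
    return(panel)
  }
  spec <- attr(panel, "spec")
  pool <- panel$mu[panel$mu >= depth_lower_bound]
  below <- which(panel$mu < depth_lower_bound)
  rounds <- 0
  while (length(below) > 0) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      abort(sprintf(
        "Could not satisfy depth bound %g after %d resampling rounds.",
        depth_lower_bound, max_rounds
      ))
    }
    if (!is.null(spec)) {
      panel$mu[below] <- rlnorm(length(below), spec$mu_meanlog, spec$mu_sdlog)
    } else {
      if (length(pool) == 0) {
        abort("No panel means at or above the depth bound to resample from.")
      }
      panel$mu[below] <- sample(pool, length(below), replace = TRUE)
    }
    below <- which(panel$mu < depth_lower_bound)
  }
  panel
}

#' Estimate NB parameters from a count matrix
#'
#' Method-of-moments estimates of the per-gene negative binomial mean and
#' dispersion, computed within a reference group after total-count library
#' size normalization: \eqn{\hat\mu} is the mean normalized count and
#' \eqn{\hat\phi = \max(0, (s^2 - \hat\mu)/\hat\mu^2)}. Genes with
#' \eqn{\hat\mu = 0} get \eqn{\hat\phi = 0}.
#'
#' @param counts gene-by-sample matrix (or data frame with a gene_id first
#'   column) of non-negative integer counts.
#' @param group optional per-sample labels; estimation uses the reference
#'   group only. `NULL` treats all samples as one group.
#' @param reference_group which group label to estimate from (default: the
#'   first factor level).
#' @return an [nb_panel()] with one row per gene.
#' @examples
#' counts <- matrix(rpois(40, 20), nrow = 10)
#' estimate_nb_params(counts)
#' @export
estimate_nb_params <- function(counts, group = NULL, reference_group = NULL) {
  m <- as_count_matrix(counts, require_integer = TRUE)
  if (!is.null(group)) {
    g <- factor(group)
    if (length(g) != ncol(m)) {
      abort("`group` length must match the number of samples.")
    }
    ref <- reference_group %||% levels(g)[1]
    if (!ref %in% levels(g)) {
      abort(sprintf("Reference group '%s' not found in `group`.", ref))
    }
    m <- m[, g == ref, drop = FALSE]
  }
  if (ncol(m) < 2) {
    abort("At least 2 samples are needed to estimate a variance.")
  }
  f <- normalize_total_count(m)
  y <- sweep(m, 2, f, "/")
  mu <- rowMeans(y)
  s2 <- rowSums((y - mu)^2) / (ncol(y) - 1)
  phi <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  nb_panel(rownames(m), mu, phi)
}
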