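# Two-group negative binomial count simulator with gamma fold changes.
#
# Group 1 counts are NB(mu_g, phi_g); group 2 counts are NB(mu_g * fc_g,
# phi_g) with shared dispersion. For DE genes the fold change is
# (rho_m + rho*)^(d_m) with rho_m ~ Gamma(shape, rate) and d_m in {+1, -1};
# non-DE genes have fc = 1. Library sizes are equal by construction.

#' Assign differential expression status to genes
#'
#' Picks exactly `round(prop_de * n_genes)` genes as DE, splits them into
#' up- and down-regulated according to `up_down_ratio` (up count =
#' round of the up share, down = remainder), and scatters them uniformly
#' at random over the genome.
#'
#' @param config a [scenario_config()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return integer vector of length `n_genes` with values +1 (up), -1
#'   (down) and 0 (not DE).
#' @examples
#' table(assign_de_status(scenario_config(n_genes = 1000), seed = 1))
#' @export
assign_de_status <- function(config, seed = NULL) {
  G <- config$n_genes
  n_de <- round(config$prop_de * G)
  if (n_de < 1) {
    abort("prop_de * n_genes is below 1; no DE genes to assign.")
  }
  r <- config$up_down_ratio
  n_up <- round(n_de * r[1] / sum(r))
  n_down <- n_de - n_up
  with_seed_if(seed, {
    d <- integer(G)
    pos <- sample.int(G, n_de)
    d[pos[seq_len(n_up)]] <- 1L
    if (n_down > 0) {
      d[pos[n_up + seq_len(n_down)]] <- -1L
    }
    d
  })
}

#' Draw per-gene fold changes
#'
#' For each DE gene the magnitude increment \eqn{\rho_m} is drawn from
#' Gamma(`gamma_shape`, rate = `gamma_rate`) and the realized fold change
#' is \eqn{(\rho_m + \rho^*)^{d_m}}: at least \eqn{\rho^*} for
#' up-regulated genes, at most \eqn{1/\rho^*} for down-regulated ones, and
#' exactly 1 for non-DE genes.
#'
#' @param d direction vector with values in `{+1, -1, 0}` (see
#'   [assign_de_status()]).
#' @param config a [scenario_config()].
#' @param seed optional seed.
#' @return a tibble of class `truth_table` with columns `d`, `rho`
#'   (`NA` for non-DE genes) and `fc`.
#' @examples
#' draw_fold_changes(c(1L, -1L, 0L), scenario_config(n_genes = 3), seed = 1)
#' @export
draw_fold_changes <- function(d, config, seed = NULL) {
  if (!all(d %in% c(-1L, 0L, 1L))) {
    abort("`d` may only contain values -1, 0 and +1.")
  }
  with_seed_if(seed, {
    rho <- rep(NA_real_, length(d))
    de <- d != 0L
    rho[de] <- rgamma(sum(de), shape = config$gamma_shape,
                      rate = config$gamma_rate)
    fc <- rep(1, length(d))
    fc[de] <- (rho[de] + config$fc_lower_bound)^d[de]
    structure(
      tibble(d = as.integer(d), rho = rho, fc = fc),
      class = c("truth_table", class(tibble()))
    )
  })
}

#' Simulate counts for one dataset
#'
#' Draws a gene-by-sample integer count matrix: group 1 from
#' NB(`mu`, `phi`), group 2 from NB(`mu * fc`, `phi`), independent across
#' genes and samples. A dispersion of 0 yields Poisson counts.
#'
#' @param panel an [nb_panel()] (already depth-truncated) with one row per
#'   gene.
#' @param truth a `truth_table` from [draw_fold_changes()] of the same
#'   length.
#' @param config a [scenario_config()].
#' @param seed optional seed.
#' @return a `sim_experiment`: list with elements `counts` (matrix),
#'   `group` (1/2 labels), `truth` (tibble with `gene_id`, `d`, `rho`,
#'   `fc`), `panel` and `config`.
#' @export
simulate_counts <- function(panel, truth, config, seed = NULL) {
  panel <- validate_nb_panel(panel)
  if (nrow(panel) != nrow(truth)) {
    abort("`panel` and `truth` must cover the same genes.")
  }
  if (nrow(panel) != config$n_genes) {
    abort("Panel size does not match config$n_genes.")
  }
  n <- config$n_per_group
  G <- config$n_genes
  with_seed_if(seed, {
    mu1 <- panel$mu
    mu2 <- panel$mu * truth$fc
    counts <- matrix(0L, nrow = G, ncol = 2 * n)
    pois <- panel$phi <= 0
    size <- ifelse(pois, Inf, 1 / panel$phi)
    draw_col <- function(mu) {
      out <- integer(G)
      if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = size[!pois])
      }
      out
    }
    for (j in seq_len(n)) counts[, j] <- draw_col(mu1)
    for (j in seq_len(n)) counts[, n + j] <- draw_col(mu2)
    rownames(counts) <- panel$gene_id
    colnames(counts) <- c(sprintf("g1_s%02d", seq_len(n)),
                          sprintf("g2_s%02d", seq_len(n)))
    truth_out <- dplyr::bind_cols(tibble(gene_id = panel$gene_id), truth)
    structure(
      list(
        counts = counts,
        group = rep(c(1L, 2L), each = n),
        truth = structure(truth_out, class = c("truth_table",
                                               class(tibble()))),
        panel = panel,
        config = config
      ),
      class = "sim_experiment"
    )
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment '%s'>: %d genes x %d samples (%d vs %d), %d DE genes\n",
    x$config$name, nrow(x$counts), ncol(x$counts),
    sum(x$group == 1L), sum(x$group == 2L), sum(x$truth$d != 0L)
  ))
  invisible(x)
}

#' Simulate one experiment under a scenario
#'
#' Convenience wrapper chaining [assign_de_status()],
#' [draw_fold_changes()] and [simulate_counts()] under one seed.
#'
#' @inheritParams simulate_counts
#' @export
simulate_experiment <- function(config, panel, seed = NULL) {
  with_seed_if(seed, {
    d <- assign_de_status(config)
    truth <- draw_fold_changes(d, config)
    simulate_counts(panel, truth, config)
  })
}

#' Simulate the replicate datasets of a scenario
#'
#' Generates `config$n_datasets` independent experiments. DE gene
#' positions and fold changes are redrawn for every replicate; the gene
#' parameter panel is drawn once (or supplied) and held fixed across the
#' replicates, like a single reference cohort. Per-dataset seeds are
#' spawned deterministically from `config$seed`.
#'
#' @param config a [scenario_config()].
#' @param panel optional [nb_panel()]; when `NULL` a stand-in panel is
#'   generated via [make_standin_panel()].
#' @param panel_args list of overrides passed to [make_standin_panel()]
#'   when `panel` is `NULL`.
#' @return a list of `sim_experiment` objects of class `sim_scenario`,
#'   with the shared panel attached as attribute `"panel"`.
#' @examples
#' cfg <- scenario_preset("I", n_genes = 200, n_datasets = 2, seed = 1)
#' sims <- simulate_scenario(cfg)
#' length(sims)
#' @export
simulate_scenario <- function(config, panel = NULL, panel_args = list()) {
  with_seed_if(config$seed, {
    if (is.null(panel)) {
      args <- modifyList(
        list(n_genes = config$n_genes,
             depth_lower_bound = config$depth_lower_bound),
        panel_args
      )
      panel <- do.call(make_standin_panel, args)
    } else {
      panel <- truncate_panel_at_depth(panel, config$depth_lower_bound)
      if (nrow(panel) != config$n_genes) {
        abort("Supplied panel size does not match config$n_genes.")
      }
    }
    seeds <- spawn_seeds(config$n_datasets)
    sims <- lapply(seq_len(config$n_datasets), function(k) {
      simulate_experiment(config, panel, seed = seeds[k])
    })
    structure(sims, class = "sim_scenario", panel = panel, seeds = seeds)
  })
}

#' Re-estimate the fold-change gamma law from simulated magnitudes
#'
#' Fits a two-parameter gamma distribution by maximum likelihood to draws
#' of the fold-change magnitude increment \eqn{\rho_m}, e.g. to verify the
#' simulator's calibration.
#'
#' @param rho positive draws of \eqn{\rho_m} (e.g. `truth$rho`).
#' @return a tibble with columns `shape`, `rate` and their standard
#'   errors.
#' @examples
#' cfg <- scenario_config(n_genes = 10)
#' rho <- draw_fold_changes(rep(1L, 5000), cfg, seed = 1)$rho
#' estimate_fc_gamma(rho)
#' @export
estimate_fc_gamma <- function(rho) {
  rho <- rho[!is.na(rho)]
  if (length(rho) < 10) {
    abort("Need at least 10 draws to fit the gamma law.")
  }
  if (any(rho <= 0)) {
    abort("Gamma draws must be positive.")
  }
  # optim explores negative parameters; the NaN warnings are benign
  fit <- suppressWarnings(MASS::fitdistr(rho, "gamma"))
  tibble(
    shape = unname(fit$estimate["shape"]),
    rate = unname(fit$estimate["rate"]),
    shape_se = unname(fit$sd["shape"]),
    rate_se = unname(fit$sd["rate"]),
    n = length(rho)
  )
}
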