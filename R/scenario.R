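# Scenario configurations for the simulation designs.

#' Build a simulation scenario configuration
#'
#' A scenario fixes the design of one replicated two-group simulation:
#' samples per group, the proportion of differentially expressed (DE)
#' genes, the up/down split among them, the fold-change lower bound
#' \eqn{\rho^*}, the minimum per-gene baseline mean ("depth" bound), the
#' gene count and the number of replicate datasets. Fold-change magnitudes
#' are drawn as \eqn{\rho_m + \rho^*} with \eqn{\rho_m \sim}
#' Gamma(`gamma_shape`, rate = `gamma_rate`).
#'
#' @param name scenario label.
#' @param n_per_group samples per group (>= 1).
#' @param prop_de proportion of DE genes, strictly between 0 and 1.
#' @param up_down_ratio ratio of up- to down-regulated DE genes, either a
#'   numeric pair `c(up, down)` or a string like `"3:1"`.
#' @param fc_lower_bound fold-change lower bound \eqn{\rho^*} (>= 1).
#' @param depth_lower_bound minimum baseline NB mean (>= 0).
#' @param n_genes total genes simulated.
#' @param n_datasets replicate datasets per scenario.
#' @param gamma_shape,gamma_rate parameters of the gamma law for the
#'   fold-change magnitude increment \eqn{\rho_m}.
#' @param seed master seed for [simulate_scenario()]; `NULL` leaves the
#'   RNG stream untouched.
#' @return a list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config("custom", n_per_group = 5, prop_de = 0.1)
#' cfg$fc_lower_bound
#' @export
scenario_config <- function(name = "custom",
                            n_per_group = 10,
                            prop_de = 0.1,
                            up_down_ratio = c(1, 1),
                            fc_lower_bound = 1.5,
                            depth_lower_bound = 0,
                            n_genes = 10000,
                            n_datasets = 30,
                            gamma_shape = 0.87,
                            gamma_rate = 1.36,
                            seed = NULL) {
  if (is.character(up_down_ratio)) {
    parts <- suppressWarnings(as.numeric(strsplit(up_down_ratio, ":")[[1]]))
    if (length(parts) != 2 || anyNA(parts)) {
      abort("`up_down_ratio` string must look like \"3:1\".")
    }
    up_down_ratio <- parts
  }
  if (length(up_down_ratio) != 2 || any(up_down_ratio < 0) ||
      sum(up_down_ratio) <= 0) {
    abort("`up_down_ratio` must be two non-negative numbers, not both zero.")
  }
  if (prop_de <= 0 || prop_de >= 1) {
    abort("`prop_de` must be strictly between 0 and 1.")
  }
  if (n_per_group < 1) abort("`n_per_group` must be >= 1.")
  if (fc_lower_bound < 1) abort("`fc_lower_bound` must be >= 1.")
  if (depth_lower_bound < 0) abort("`depth_lower_bound` must be >= 0.")
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (n_datasets < 1) abort("`n_datasets` must be >= 1.")
  if (gamma_shape <= 0 || gamma_rate <= 0) {
    abort("`gamma_shape` and `gamma_rate` must be > 0.")
  }
  structure(
    list(
      name = as.character(name),
      n_per_group = as.integer(n_per_group),
      prop_de = prop_de,
      up_down_ratio = as.numeric(up_down_ratio),
      fc_lower_bound = fc_lower_bound,
      depth_lower_bound = depth_lower_bound,
      n_genes = as.integer(n_genes),
      n_datasets = as.integer(n_datasets),
      gamma_shape = gamma_shape,
      gamma_rate = gamma_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<scenario_config '%s'>\n",
      "  %d vs %d samples, %d genes, %d datasets\n",
      "  DE: %.0f%% (up:down %g:%g), fc lower bound %g, depth lower bound %g\n",
      "  rho_m ~ Gamma(shape %g, rate %g)%s\n"
    ),
    x$name, x$n_per_group, x$n_per_group, x$n_genes, x$n_datasets,
    100 * x$prop_de, x$up_down_ratio[1], x$up_down_ratio[2],
    x$fc_lower_bound, x$depth_lower_bound,
    x$gamma_shape, x$gamma_rate,
    if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)
  ))
  invisible(x)
}

#' Scenario presets
#'
#' The seven preset simulation designs shipped with the package, read from
#' the YAML files under `inst/extdata/scenarios/`.
#'
#' @return a tibble with one row per preset.
#' @examples
#' scenario_presets()
#' @export
scenario_presets <- function() {
  dir <- system.file("extdata", "scenarios", package = "countbench")
  files <- list.files(dir, pattern = "^scenario_.*\\.yaml$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    y <- yaml::read_yaml(f)
    tibble(
      name = y$name,
      n_per_group = as.integer(y$n_per_group),
      prop_de = as.numeric(y$prop_de),
      up = as.numeric(y$up), down = as.numeric(y$down),
      fc_lower_bound = as.numeric(y$fc_lower_bound),
      depth_lower_bound = as.numeric(y$depth_lower_bound)
    )
  })
  out <- dplyr::bind_rows(rows)
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII")
  out[order(match(out$name, roman)), ]
}

#' Fetch a preset scenario configuration
#'
#' @param name preset label, one of `"I"` ... `"VII"`.
#' @param n_genes,n_datasets,seed overrides for the preset defaults
#'   (10,000 genes, 30 datasets).
#' @return a [scenario_config()].
#' @examples
#' scenario_preset("I", n_genes = 1000, n_datasets = 2, seed = 1)
#' @export
scenario_preset <- function(name, n_genes = 10000, n_datasets = 30,
                            seed = NULL) {
  presets <- scenario_presets()
  if (!name %in% presets$name) {
    abort(sprintf(
      "Unknown scenario '%s'. Valid presets: %s.",
      name, paste(presets$name, collapse = ", ")
    ))
  }
  p <- presets[presets$name == name, ]
  scenario_config(
    name = p$name,
    n_per_group = p$n_per_group,
    prop_de = p$prop_de,
    up_down_ratio = c(p$up, p$down),
    fc_lower_bound = p$fc_lower_bound,
    depth_lower_bound = p$depth_lower_bound,
    n_genes = n_genes,
    n_datasets = n_datasets,
    seed = seed
  )
}
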