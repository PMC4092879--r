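test_that("DE assignment hits the configured counts and split", {
  cfg1 <- scenario_config(n_genes = 10000, prop_de = 0.10,
                          up_down_ratio = c(1, 1))
  d1 <- assign_de_status(cfg1, seed = 1)
  expect_equal(sum(d1 == 1L), 500)
  expect_equal(sum(d1 == -1L), 500)

  cfg3 <- scenario_config(n_genes = 10000, prop_de = 0.10,
                          up_down_ratio = c(3, 1))
  d3 <- assign_de_status(cfg3, seed = 1)
  expect_equal(sum(d3 == 1L), 750)
  expect_equal(sum(d3 == -1L), 250)

  cfg_small <- scenario_config(n_genes = 100, prop_de = 0.05)
  expect_equal(sum(assign_de_status(cfg_small, seed = 2) != 0L), 5)

  cfg_bad <- scenario_config(n_genes = 5, prop_de = 0.05)
  expect_error(assign_de_status(cfg_bad), "below 1")
})

test_that("fold changes follow (rho + rho*)^d with the gamma law", {
  cfg <- scenario_config(n_genes = 3, fc_lower_bound = 1.5)
  t0 <- draw_fold_changes(c(0L, 0L, 0L), cfg, seed = 1)
  expect_equal(t0$fc, c(1, 1, 1))
  expect_true(all(is.na(t0$rho)))

  tt <- draw_fold_changes(c(1L, -1L, 0L), cfg, seed = 2)
  expect_equal(tt$fc[1], tt$rho[1] + 1.5)
  expect_equal(tt$fc[2], 1 / (tt$rho[2] + 1.5))
  expect_equal(tt$fc[3], 1)

  cfg_big <- scenario_config(n_genes = 2e5)
  rho <- draw_fold_changes(rep(1L, 2e5), cfg_big, seed = 3)$rho
  expect_equal(mean(rho), 0.87 / 1.36, tolerance = 0.01)

  expect_error(draw_fold_changes(c(2L, 0L), cfg), "-1, 0")
})

test_that("simulated counts have NB moments and honor the fold change", {
  cfg <- scenario_config(n_per_group = 5000, prop_de = 0.5, n_genes = 3)
  panel <- nb_panel(c("a", "b", "c"), mu = c(100, 100, 50),
                    phi = c(0, 0, 0.4))
  truth <- structure(
    tibble::tibble(d = c(0L, 1L, 0L), rho = c(NA, 0.5, NA),
                   fc = c(1, 2, 1)),
    class = c("truth_table", class(tibble::tibble()))
  )
  sim <- simulate_counts(panel, truth, cfg, seed = 4)
  y <- sim$counts
  # phi = 0 gene is Poisson: index of dispersion about 1
  g1 <- y[1, sim$group == 1L]
  expect_equal(var(g1) / mean(g1), 1, tolerance = 0.1)
  # fold change scales the group-2 mean
  expect_equal(mean(y[2, sim$group == 2L]), 200, tolerance = 0.025)
  # NB2 variance mu + phi mu^2 = 50 + 0.4 * 2500 = 1050
  g3 <- c(y[3, ])
  expect_equal(var(g3), 1050, tolerance = 0.05)
  expect_true(all(y >= 0) && all(y == round(y)))
})

test_that("scenario simulation is seeded and respects the design", {
  cfg <- scenario_preset("II", n_genes = 300, n_datasets = 3, seed = 5)
  sims_a <- simulate_scenario(cfg)
  sims_b <- simulate_scenario(cfg)
  expect_equal(length(sims_a), 3)
  expect_identical(sims_a[[2]]$counts, sims_b[[2]]$counts)
  for (sim in sims_a) {
    expect_equal(sum(sim$group == 1L), 2)
    expect_equal(sum(sim$group == 2L), 2)
    expect_equal(dim(sim$counts), c(300L, 4L))
  }
  # panel fixed across replicates, DE positions redrawn
  expect_identical(sims_a[[1]]$panel, sims_a[[3]]$panel)
  expect_false(identical(sims_a[[1]]$truth$d, sims_a[[2]]$truth$d))
})

test_that("truth invariants hold across seeds", {
  cfg <- scenario_preset("I", n_genes = 2000, n_datasets = 1)
  for (seed in c(11, 12, 13)) {
    sim <- simulate_experiment(cfg,
                               make_standin_panel(2000, seed = 99,
                                                  depth_lower_bound = 5),
                               seed = seed)
    tt <- sim$truth
    expect_equal(mean(tt$fc == 1), 1 - round(0.1 * 2000) / 2000)
    expect_true(all(tt$fc[tt$d == 1L] >= 1.5))
    expect_true(all(tt$fc[tt$d == -1L] <= 1 / 1.5))
    expect_equal(sum(tt$d == 1L), 100)
    expect_equal(sum(tt$d == -1L), 100)
  }
})

test_that("the fitted gamma law is recoverable from simulator draws", {
  cfg <- scenario_config(n_genes = 10)
  rho <- draw_fold_changes(rep(1L, 1e5), cfg, seed = 21)$rho
  fit <- estimate_fc_gamma(rho)
  expect_equal(fit$shape, 0.87, tolerance = 0.02)
  expect_equal(fit$rate, 1.36, tolerance = 0.02)
})
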