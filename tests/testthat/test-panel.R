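test_that("method-of-moments estimates clamp zero-variance genes", {
  counts <- rbind(
    const = c(5L, 5L, 5L, 5L),
    zero = c(0L, 0L, 0L, 0L)
  )
  est <- estimate_nb_params(counts)
  expect_equal(est$mu[1], 5)
  expect_equal(est$phi[1], 0)
  expect_equal(est$mu[2], 0)
  expect_equal(est$phi[2], 0)
})

test_that("estimation recovers the Poisson limit and true NB dispersion", {
  set.seed(201)
  pois <- matrix(rpois(50 * 200, 100), nrow = 50)
  est <- estimate_nb_params(pois)
  expect_true(all(abs(est$phi) < 0.02))

  nb <- matrix(rnbinom(50 * 500, mu = 50, size = 1 / 0.4), nrow = 50)
  est2 <- estimate_nb_params(nb)
  expect_true(all(est2$phi > 0.3 & est2$phi < 0.5))
})

test_that("estimation rejects invalid input", {
  expect_error(estimate_nb_params(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(estimate_nb_params(matrix(c(-1L, 2L, 3L, 4L), 2)),
               "non-negative")
  expect_error(estimate_nb_params(matrix(1:4, nrow = 4)), "2 samples")
})

test_that("stand-in panels are seeded, sized, and honor degenerate spread", {
  a <- make_standin_panel(500, seed = 7)
  b <- make_standin_panel(500, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(make_standin_panel(10000, seed = 1)), 10000)
  flat <- make_standin_panel(50, mu_sdlog = 0, seed = 2)
  expect_equal(length(unique(flat$mu)), 1)
  expect_error(make_standin_panel(50, phi_shape = -1), "phi_shape")
})

test_that("depth truncation enforces the bound and is idempotent", {
  panel <- make_standin_panel(2000, seed = 3)
  expect_identical(truncate_panel_at_depth(panel, 0), panel)
  for (bound in c(5, 1)) {
    t1 <- truncate_panel_at_depth(panel, bound)
    expect_gte(min(t1$mu), bound)
    expect_equal(nrow(t1), nrow(panel))
    t2 <- truncate_panel_at_depth(t1, bound)
    expect_identical(t1$mu, t2$mu)
  }
})

test_that("panels without a generating law truncate by bootstrap", {
  panel <- nb_panel(letters[1:5], mu = c(0.5, 2, 8, 20, 100),
                    phi = rep(0.2, 5))
  set.seed(9)
  out <- truncate_panel_at_depth(panel, 5)
  expect_gte(min(out$mu), 5)
  expect_true(all(out$mu %in% c(8, 20, 100) | out$mu == panel$mu))
})

test_that("panel validation enforces the invariants", {
  expect_error(nb_panel(c("a", "a"), c(1, 2), c(0, 0)), "unique")
  expect_error(nb_panel("a", -1, 0), "non-negative")
  expect_error(nb_panel(character(0), numeric(0), numeric(0)), "at least one")
})

test_that("simulate-then-estimate round trip recovers the panel", {
  panel <- make_standin_panel(400, seed = 5)
  cfg <- scenario_config(n_per_group = 500, prop_de = 0.5, n_genes = 400)
  truth <- draw_fold_changes(rep(0L, 400), cfg, seed = 1)
  sim <- simulate_counts(panel, truth, cfg, seed = 2)
  est <- estimate_nb_params(sim$counts[, sim$group == 1L])
  rel_rmse <- function(a, b) sqrt(mean(((a - b) / b)^2))
  expect_lt(rel_rmse(est$mu, panel$mu), 0.05)
  expect_lt(rel_rmse(est$phi, panel$phi), 0.20)
})
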