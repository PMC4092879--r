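test_that("stage 1 holds its size on Poisson data and flags NB data", {
  set.seed(44)
  G <- 5000
  mu <- exp(runif(G, log(20), log(500)))
  pois <- matrix(rpois(G * 20, mu), nrow = G)
  res <- two_stage_poisson(pois, rep(1:2, each = 10))
  size <- mean(res$overdispersed)
  expect_gte(size, 0.03)
  expect_lte(size, 0.07)

  set.seed(45)
  nb <- matrix(rnbinom(2000 * 20, mu = 100, size = 1 / 0.5), nrow = 2000)
  res_nb <- two_stage_poisson(nb, rep(1:2, each = 10))
  expect_gt(mean(res_nb$overdispersed), 0.8)
})

test_that("identical groups give stage-2 p = 1", {
  m <- matrix(rep(c(10L, 50L), each = 8), nrow = 2, byrow = TRUE)
  res <- two_stage_poisson(m, rep(1:2, each = 4))
  expect_equal(res$p, rep(1, 2))
})

test_that("the two stage-2 p-value families are BH-adjusted separately", {
  sim <- tiny_experiment(n_genes = 300, seed = 71)
  res <- two_stage_poisson(sim$counts, sim$group)
  flagged <- res$overdispersed
  expect_equal(res$p_adj[flagged], bh_adjust(res$p[flagged]))
  expect_equal(res$p_adj[!flagged], bh_adjust(res$p[!flagged]))
  expect_true(all(is.finite(res$p_adj)))
})

test_that("all-zero genes get p = 1 under the policy", {
  m <- rbind(zero = rep(0L, 8), live = c(5L, 8L, 6L, 7L, 30L, 28L, 35L, 31L))
  res <- two_stage_poisson(m, rep(1:2, each = 4))
  expect_equal(res$p[1], 1)
  expect_equal(res$fc[1], 1)
})
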