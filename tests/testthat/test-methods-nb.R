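test_that("identical groups give p = 1 in every NB-family test", {
  m <- matrix(rep(c(10L, 20L, 30L, 40L), each = 6), nrow = 4, byrow = TRUE)
  group <- rep(1:2, each = 3)
  for (res in list(
    nb_exact_test(m, group, dispersion = 0.1),
    nb_pooled_test(m, group, dispersion = 0.1),
    nbp_test(m, group, phi0 = 0.1, alpha = 2)
  )) {
    expect_equal(res$p, rep(1, 4))
    expect_equal(res$fc, rep(1, 4))
  }
})

test_that("the exact test matches exhaustive enumeration on small totals", {
  worst <- 0
  for (phi in c(0.01, 0.1, 1.0)) {
    for (s in 1:30) {
      for (k1 in 0:s) {
        got <- countbench:::nb_exact_pvalue(k1, s - k1, 1, 1, phi)
        want <- oracle_exact_p(k1, s, 1, 1, phi)
        worst <- max(worst, abs(got - want))
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("the documented small instance matches the enumeration oracle", {
  # k1 = 3, k2 = 12, one sample per group, phi fixed at 0.1
  got <- nb_exact_test(rbind(g = c(3L, 12L)), c(1, 2), dispersion = 0.1,
                       norm_factors = c(1, 1))
  expect_equal(got$p, oracle_exact_p(3, 15, 1, 1, 0.1), tolerance = 1e-10)
})

test_that("strengthening a DE gene's signal never raises its exact p", {
  # doubling the group-2 counts of a DE gene at fixed dispersion
  base <- c(20L, 25L, 18L, 40L, 45L, 38L)
  doubled <- c(20L, 25L, 18L, 80L, 90L, 76L)
  group <- rep(1:2, each = 3)
  p1 <- nb_exact_test(rbind(g = base), group, dispersion = 0.2,
                      norm_factors = rep(1, 6))$p
  p2 <- nb_exact_test(rbind(g = doubled), group, dispersion = 0.2,
                      norm_factors = rep(1, 6))$p
  expect_lte(p2, p1)
})

test_that("windowed enumeration agrees with full enumeration on large totals", {
  # force the windowed path by shrinking full_limit
  for (phi in c(0.05, 0.5)) {
    for (k in list(c(2500, 2600), c(2400, 3200), c(5000, 2000))) {
      full <- countbench:::nb_exact_pvalue_one(k[1], k[2], 5, 5, phi,
                                               full_limit = 1e9)
      win <- countbench:::nb_exact_pvalue_one(k[1], k[2], 5, 5, phi,
                                              full_limit = 10)
      expect_equal(win, full, tolerance = 1e-9)
    }
  }
})

test_that("dispersion shrinkage recovers a common dispersion on NB data", {
  set.seed(51)
  G <- 800
  m <- matrix(rnbinom(G * 20, mu = 100, size = 1 / 0.3), nrow = G)
  common <- estimate_common_dispersion(m, rep(1:2, each = 10))
  expect_equal(common, 0.3, tolerance = 0.15)
})

test_that("trended test agrees with shrunk test when forced to one dispersion", {
  set.seed(52)
  m <- matrix(rnbinom(50 * 12, mu = 80, size = 5), nrow = 50)
  group <- rep(1:2, each = 6)
  a <- nb_exact_test(m, group, dispersion = 0.2)
  b <- nb_pooled_test(m, group, dispersion = 0.2)
  c2 <- nbp_test(m, group, phi0 = 0.2, alpha = 2)
  expect_lt(max(abs(a$p - b$p)), 1e-6)
  expect_lt(max(abs(a$p - c2$p)), 1e-6)
})

test_that("the dispersion trend recovers a known mean-dispersion law", {
  set.seed(42)
  G <- 5000
  mu <- exp(runif(G, log(20), log(2000)))
  phi <- 0.1 + 5 / mu
  m <- matrix(rnbinom(G * 20, mu = mu, size = 1 / phi), nrow = G)
  res <- nb_pooled_test(m, rep(1:2, each = 10))
  co <- attr(res, "details")$trend_coef
  expect_equal(unname(co["a0"]), 5, tolerance = 0.3)
  expect_equal(unname(co["a1"]), 0.1, tolerance = 0.3)
})

test_that("the power-law dispersion fit recovers its exponent", {
  set.seed(43)
  G <- 5000
  mu <- exp(runif(G, log(20), log(2000)))
  phi <- 2 * mu^(1.5 - 2)
  m <- matrix(rnbinom(G * 20, mu = mu, size = 1 / phi), nrow = G)
  res <- nbp_test(m, rep(1:2, each = 10))
  alpha <- attr(res, "details")$alpha
  expect_gte(alpha, 1.3)
  expect_lte(alpha, 1.7)
})

test_that("single-replicate groups need an explicit dispersion", {
  m <- rbind(g = c(3L, 12L))
  expect_error(nb_exact_test(m, c(1, 2)), "dispersion")
  expect_silent(nb_exact_test(m, c(1, 2), dispersion = 0.1,
                              norm_factors = c(1, 1)))
})

test_that("every NB-family test returns finite p in [0,1] with zero genes", {
  sim <- tiny_experiment(n_genes = 120, seed = 61)
  sim$counts[1, ] <- 0L
  for (method in c("nb_exact", "nb_pooled", "nbp")) {
    res <- de_test(sim$counts, sim$group, method = method)
    expect_true(all(is.finite(res$p)))
    expect_true(all(res$p >= 0 & res$p <= 1))
    expect_equal(res$p[1], 1)
    expect_true(all(res$fc > 0))
  }
})
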