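test_that("balanced pooled counts give z = 0 and the closed-form tail", {
  # symmetric gene: k1 = k2 with equal library sizes
  m <- rbind(
    sym = c(25L, 25L, 25L, 25L),
    onesided = c(5L, 5L, 0L, 0L),
    pad = c(100L, 100L, 105L, 105L)  # balances the group totals: N1 = N2
  )
  res <- poisson_ma_test(m, c(1, 1, 2, 2), norm_factors = rep(1, 4))
  expect_equal(res$p[res$gene_id == "sym"], 1)
  # k1 = 10, k2 = 0, N1 = N2: z = sqrt(10), p = 2 * pnorm(-sqrt(10))
  expect_equal(res$p[res$gene_id == "onesided"], 2 * pnorm(-sqrt(10)),
               tolerance = 1e-12)
  expect_equal(2 * pnorm(-sqrt(10)), 0.00157, tolerance = 1e-2)
})

test_that("p-values are approximately uniform under a pure Poisson null", {
  set.seed(41)
  G <- 10000
  mu <- exp(runif(G, log(50), log(500)))
  m <- matrix(rpois(G * 10, mu), nrow = G)
  res <- poisson_ma_test(m, rep(1:2, each = 5), norm_factors = rep(1, 10))
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("overdispersion inflates the Poisson test's false positive rate", {
  set.seed(42)
  G <- 3000
  m <- matrix(rnbinom(G * 20, mu = 100, size = 1 / 0.4), nrow = G)
  res <- poisson_ma_test(m, rep(1:2, each = 10))
  fpr <- mean(res$p <= 0.05)
  expect_gt(fpr, 0.5)
})

test_that("all-zero genes get p = 1 and fc = 1", {
  m <- rbind(a = c(0L, 0L, 0L, 0L), b = c(3L, 4L, 9L, 11L))
  res <- poisson_ma_test(m, c(1, 1, 2, 2))
  expect_equal(res$p[1], 1)
  expect_equal(res$fc[1], 1)
  expect_true(all(res$p >= 0 & res$p <= 1))
})
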