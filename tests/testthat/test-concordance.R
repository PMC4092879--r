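make_result <- function(id, p, fc, direction = NULL, method = id,
                        genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_along(p))
  countbench:::method_result(method, genes, p, fc, direction,
                             norm_factors = NULL)
}

test_that("Spearman matrices respect monotone invariance and sign", {
  set.seed(111)
  a <- rnorm(500)
  m <- cbind(a = a, b = exp(a), c = -a)
  sp <- spearman_matrix(m)
  expect_equal(sp["a", "b"], 1)
  expect_equal(sp["a", "c"], -1)
  expect_equal(sp, t(sp))
  expect_equal(unname(diag(sp)), rep(1, 3))

  noise <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(abs(spearman_matrix(noise)[1, 2]), 0.03)

  expect_warning(spearman_matrix(cbind(rep(1, 5), rnorm(5))), "Constant")
  expect_error(spearman_matrix(matrix(1:5, ncol = 1)), "2 methods")
})

test_that("ICC(2,1) behaves at its reference points", {
  set.seed(112)
  x <- rnorm(500)
  expect_equal(icc(cbind(x, x, x)), 1)

  noise <- matrix(rnorm(3e4), ncol = 3)
  expect_lt(abs(icc(noise)), 0.05)

  signal <- rnorm(2000, sd = 10)
  raters <- sapply(1:4, function(i) signal + rnorm(2000, sd = 1))
  expect_gt(icc(raters), 0.95)

  expect_warning(out <- icc(matrix(1, 4, 3)), "undefined")
  expect_true(is.na(out))
})

test_that("overlap report counts cells, singletons and frequencies", {
  p_hit <- c(0.001, 0.001, 0.9)
  p_miss <- c(0.9, 0.9, 0.9)
  # two methods calling identical sets: no singletons
  r1 <- make_result("m1", p_hit, c(4, 4, 1), direction = c(1, 1, 0))
  r2 <- make_result("m2", p_hit, c(4, 4, 1), direction = c(1, 1, 0))
  rep_same <- overlap_report(list(m1 = r1, m2 = r2), alpha = 0.05)
  expect_equal(sum(rep_same$singletons$n_singleton), 0)
  expect_equal(rep_same$venn$methods, "m1+m2")
  expect_equal(rep_same$venn$n_genes, 2L)

  # disjoint single-gene calls: two singletons
  r3 <- make_result("m3", c(0.001, 0.9, 0.9), c(4, 1, 1),
                    direction = c(1, 0, 0))
  r4 <- make_result("m4", c(0.9, 0.001, 0.9), c(1, 4, 1),
                    direction = c(0, 1, 0))
  rep_disj <- overlap_report(list(m3 = r3, m4 = r4), alpha = 0.05)
  expect_equal(sum(rep_disj$singletons$n_singleton), 2)

  # five methods calling one shared gene: identification frequency 5
  rs <- lapply(paste0("m", 1:5), function(nm) {
    make_result(nm, p_hit, c(4, 4, 1), direction = c(1, 1, 0))
  })
  names(rs) <- paste0("m", 1:5)
  rep5 <- overlap_report(rs, alpha = 0.05)
  expect_equal(max(rep5$identification_frequency$frequency), 5)

  expect_error(overlap_report(rs, alpha = 1.5), "alpha")
})

test_that("directionless methods are excluded from directional cells", {
  r1 <- make_result("dir", c(0.001, 0.9), c(4, 1), direction = c(1, 0))
  r2 <- make_result("nodir", c(0.001, 0.9), c(4, 1), direction = NULL)
  expect_message(rep <- overlap_report(list(dir = r1, nodir = r2),
                                       alpha = 0.05), "directionless")
  expect_equal(rep$directional_methods, "dir")
  expect_true(all(rep$venn$methods == "dir"))
  # but they still count toward identification frequency
  expect_equal(max(rep$identification_frequency$frequency), 2)
})

test_that("duplicated results give perfect concordance", {
  set.seed(113)
  p <- runif(100)
  fc <- exp(rnorm(100))
  r1 <- make_result("m1", p, fc, direction = sign(log(fc)))
  r2 <- make_result("m2", p, fc, direction = sign(log(fc)))
  rep <- concordance_report(list(m1 = r1, m2 = r2), alpha = 0.05)
  expect_equal(rep$spearman_fc["m1", "m2"], 1)
  expect_equal(rep$icc_fc, 1)
  expect_equal(rep$icc_p, 1)
})

test_that("mismatched gene universes are rejected by name", {
  r1 <- make_result("m1", c(0.1, 0.2), c(1, 2), direction = c(0, 1))
  r2 <- make_result("m2", c(0.1, 0.2), c(1, 2), direction = c(0, 1),
                    genes = c("x1", "x2"))
  expect_error(concordance_report(list(m1 = r1, m2 = r2)),
               "different gene universe")
  expect_error(concordance_report(list(m1 = r1)), "at least 2")
})
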