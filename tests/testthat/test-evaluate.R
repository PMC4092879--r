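test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(91)
  p <- runif(200)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("confusion summaries count hits by truth status", {
  res <- structure(
    tibble::tibble(gene_id = paste0("g", 1:4),
                   p = c(0.001, 0.5, 0.001, 0.5),
                   p_adj = c(0.004, 1, 0.004, 1),
                   fc = c(2, 1, 2, 1), direction = c(1, 0, 1, 0)),
    class = c("method_result", class(tibble::tibble())), method = "toy"
  )
  truth <- tibble::tibble(gene_id = paste0("g", 1:4),
                          d = c(1L, 1L, 0L, 0L))
  cc <- confusion_at_cutoffs(res, truth, cutoffs = 0.05)
  expect_equal(cc$tp, 1)
  expect_equal(cc$fp, 1)
  expect_equal(cc$ns, 2)
  expect_equal(cc$tpr, 0.5)
  expect_equal(cc$fpr, 0.5)

  none <- confusion_at_cutoffs(
    dplyr::mutate(res, p_adj = 1), truth, cutoffs = 0.001)
  expect_equal(none$ns, 0)
  expect_equal(none$fp + none$tp, 0)

  # at cutoff 1 every gene is called
  all_called <- confusion_at_cutoffs(res, truth, cutoffs = 1)
  expect_equal(all_called$ns, 4)

  expect_error(
    confusion_at_cutoffs(res, tibble::tibble(gene_id = "x", d = 1L)),
    "different gene sets"
  )
})

test_that("Ns is non-decreasing in the FDR cutoff", {
  sim <- tiny_experiment(n_genes = 300, seed = 92)
  res <- poisson_ma_test(sim$counts, sim$group)
  cc <- confusion_at_cutoffs(res, sim$truth, cutoffs = c(0.1, 0.05, 0.01))
  expect_true(all(diff(cc$ns) <= 0))  # rows ordered 0.1, 0.05, 0.01
  expect_true(all(cc$ns == cc$fp + cc$tp))
})

test_that("AUC matches the brute-force pair count and its invariances", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1L, 1L, 0L, 0L)), 0)
  set.seed(93)
  for (rep in 1:5) {
    n <- 150
    de <- rbinom(n, 1, 0.3) == 1
    if (!any(de) || all(de)) next
    scores <- round(rnorm(n, mean = de), 1)  # rounding forces ties
    expect_equal(roc_auc(scores, as.integer(de)),
                 bruteforce_auc(scores, de))
    # invariant under strictly increasing transforms
    expect_equal(roc_auc(exp(scores), as.integer(de)),
                 roc_auc(scores, as.integer(de)))
  }
  set.seed(94)
  null_auc <- roc_auc(runif(5000), rep(c(1L, 0L), each = 2500))
  expect_equal(null_auc, 0.5, tolerance = 0.04)
  expect_error(roc_auc(runif(5), rep(0L, 5)), "undefined")
})

test_that("scenario aggregation averages per-dataset metrics", {
  one <- tibble::tibble(dataset = 1, method = "m", cutoff = 0.1,
                        ns = 10, fp = 1, tp = 9, fpr = 0.1, tpr = 0.9)
  agg1 <- aggregate_scenario(one)
  expect_equal(agg1$ns, 10)

  two <- tibble::tibble(dataset = 1:2, method = "m",
                        auc = c(0.9, 0.94))
  expect_equal(aggregate_scenario(two)$auc, 0.92)
  expect_equal(aggregate_scenario(two[2:1, ])$auc, 0.92)
  expect_error(aggregate_scenario(two[0, ]), "No dataset")
})
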