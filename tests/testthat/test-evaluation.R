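test_that("stratified folds of 144 points form six folds of 14 and four of 15", {
  labels <- c(rep(1, 54), rep(-1, 90))
  fold <- kfold_partition(144, 10, seed = 3, labels = labels)
  sizes <- as.vector(table(fold))
  expect_equal(sort(sizes), c(rep(14, 6), rep(15, 4)))
  expect_equal(mean(sizes), 14.4)
  # every index in exactly one fold
  expect_equal(sort(unlist(lapply(1:10, function(k) which(fold == k)))), 1:144)
  # per-stratum balance
  pos_per_fold <- as.vector(table(fold[labels == 1]))
  expect_lte(diff(range(pos_per_fold)), 1)
  # determinism
  expect_identical(fold, kfold_partition(144, 10, seed = 3, labels = labels))
  expect_false(identical(fold, kfold_partition(144, 10, seed = 4, labels = labels)))
})

test_that("unstratified partitions still balance fold sizes", {
  fold <- kfold_partition(23, 4, seed = 1)
  expect_lte(diff(range(table(fold))), 1)
  expect_error(kfold_partition(3, 5), "n < K")
})

test_that("identical methods give a zero Friedman statistic and p = 1", {
  vals <- matrix(rep(c(0.7, 0.5, 0.3), each = 4), nrow = 3, byrow = TRUE)
  ft <- friedman_rank_test(vals, rep("one", 3))
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
  expect_equal(unname(ft$mean_ranks), rep(2.5, 4))
})

test_that("the Friedman statistic matches the textbook formula on a 3x4 table", {
  vals <- rbind(c(0.9, 0.7, 0.5, 0.3),
                c(0.8, 0.9, 0.4, 0.6),
                c(0.7, 0.6, 0.5, 0.8))
  ft <- friedman_rank_test(vals, rep("one", 3))
  # hand ranks (closest to one = rank 1):
  ranks <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(2, 3, 4, 1))
  R <- colMeans(ranks)
  stat <- 12 * 3 / (4 * 5) * (sum(R^2) - 4 * 25 / 4)
  expect_equal(ft$statistic, stat, tolerance = 1e-12)
  expect_equal(sum(ft$mean_ranks), 4 * 5 / 2)
})

test_that("the Friedman statistic agrees with stats::friedman.test", {
  set.seed(81)
  vals <- matrix(runif(6 * 4), 6, 4)  # untied continuous values
  ft <- friedman_rank_test(vals, rep("one", 6))
  ref <- stats::friedman.test(vals)
  expect_equal(ft$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ft$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the Nemenyi critical difference follows its closed form", {
  expect_equal(nemenyi_cd(4, 17, 0.05), 1.1376, tolerance = 1e-3)
  expect_equal(nemenyi_cd(4, 68), nemenyi_cd(4, 17) / 2, tolerance = 1e-12)
  cds <- vapply(c(5, 17, 40, 100), function(N) nemenyi_cd(4, N), numeric(1))
  expect_true(all(diff(cds) < 0))   # monotone decreasing in N
  expect_error(nemenyi_cd(1, 17), "k must be")
  expect_error(nemenyi_cd(4, 0), "N must be")
  expect_error(nemenyi_cd(4, 17, alpha = 0.9), "alpha")
})

test_that("repeated CV bookkeeping has the contracted shape and is deterministic", {
  ds <- generate_dataset(easy_config(n_pos = 10, n_neg = 15, seed = 2))
  bank <- small_bank()
  cv <- cv_config(K = 5, repetitions = 2, seed = 11)
  res <- suppressWarnings(run_repeated_cv(ds, bank, cv))
  expect_s3_class(res, "lk_cv_result")
  expect_equal(nrow(res$expert_metrics), nrow(bank) * 16 * 2)
  expect_equal(nrow(res$combiner_metrics), 4 * 16 * 2)
  expect_equal(sum(res$densities), 1, tolerance = 1e-9)
  res2 <- suppressWarnings(run_repeated_cv(ds, bank, cv))
  expect_equal(res$combiner_metrics$value, res2$combiner_metrics$value,
               tolerance = 1e-12)
  expect_equal(res$expert_metrics$value, res2$expert_metrics$value,
               tolerance = 1e-12)
})

test_that("all combiners exceed 95% accuracy on a well-separated dataset", {
  ds <- generate_dataset(easy_config(n_pos = 15, n_neg = 20, seed = 6))
  res <- suppressWarnings(
    run_repeated_cv(ds, small_bank(), cv_config(K = 5, repetitions = 2, seed = 1))
  )
  acc <- glance(res)
  expect_gt(acc$acc_average, 0.95)
  expect_gt(acc$acc_weighted, 0.95)
  expect_gt(acc$acc_majority, 0.95)
  expect_gt(acc$acc_soft_fusion, 0.95)
})

test_that("honest mode derives per-fold densities from training data only", {
  ds <- generate_dataset(easy_config(n_pos = 10, n_neg = 14, seed = 8))
  res <- suppressWarnings(
    run_repeated_cv(ds, small_bank(), cv_config(K = 3, repetitions = 1, seed = 2),
                    mode = "honest", inner_K = 3)
  )
  expect_equal(res$mode, "honest")
  expect_equal(nrow(res$combiner_metrics), 4 * 16)
  acc <- glance(res)
  expect_gt(acc$acc_soft_fusion, 0.9)
})

test_that("the paper-2014 density preset flows through the comparison", {
  ds <- generate_dataset(easy_config(n_pos = 10, n_neg = 15, seed = 4))
  res <- suppressWarnings(
    run_repeated_cv(ds, default_bank(), cv_config(K = 4, repetitions = 2, seed = 5),
                    density_source = "paper-2014")
  )
  expect_equal(as.numeric(res$avg_ranks), as.numeric(paper_2014_ranks()))
  comp <- compare_combiners(res)
  expect_s3_class(comp, "lk_comparison")
  expect_equal(comp$N, 17)
  expect_equal(comp$k, 4)
  expect_equal(sum(comp$mean_ranks), 4 * 5 / 2)
  expect_equal(rownames(comp$criteria), c(metric_names(), "avg_sd"))
  g <- glance(comp)
  expect_true(is.finite(g$friedman_statistic))
  expect_equal(g$cd, nemenyi_cd(4, 17))
  # preset requires the default bank
  expect_error(
    suppressWarnings(run_repeated_cv(ds, small_bank(), cv_config(K = 4, repetitions = 1),
                                     density_source = "paper-2014")),
    "default 27-expert bank")
})

test_that("tidy and autoplot views expose the CV result", {
  ds <- generate_dataset(easy_config(n_pos = 8, n_neg = 10, seed = 12))
  res <- suppressWarnings(
    run_repeated_cv(ds, small_bank(), cv_config(K = 3, repetitions = 1, seed = 3))
  )
  td <- tidy(res)
  expect_setequal(unique(td$method),
                  c("average", "weighted", "majority", "soft_fusion"))
  tde <- tidy(res, experts = TRUE)
  expect_true(all(small_bank()$id %in% tde$method))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
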