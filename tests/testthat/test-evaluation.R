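# ROC-AUC, repeated-run aggregation and the experiment harnesses.

test_that("roc_auc matches pair counting on fixed and random instances", {
  expect_equal(roc_auc(c(0, 1), c(0.1, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "single class")
  expect_error(roc_auc(c(0, 1), c(0.2, 0.4, 0.6)), "length")

  withr::with_seed(14, {
    for (i in 1:50) {
      n <- sample(4:20, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(stats::runif(n), 2)   # rounding forces ties
      expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    labels <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
    labels[1:2] <- 0:1
    scores <- stats::rnorm(60)
    expect_equal(roc_auc(labels, scores),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  })
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  withr::with_seed(16, {
    labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
    scores <- stats::rnorm(30)
    base <- roc_auc(labels, scores)
    expect_equal(roc_auc(labels, exp(scores)), base)
    expect_equal(roc_auc(labels, 3 * scores - 7), base)
    expect_equal(roc_auc(labels, rank(scores)), base)
  })
})

test_that("aggregate_runs computes mean and symmetric normal CI", {
  flat <- aggregate_runs(rep(0.80, 10))
  expect_equal(flat$mean_auc, 0.80)
  expect_equal(flat$ci_lo, 0.80)
  expect_equal(flat$ci_hi, 0.80)

  two <- aggregate_runs(c(0.7, 0.9))
  expect_equal(two$mean_auc, 0.8)
  # hand computation: 1.96 * sd/sqrt(2) = 1.96 * 0.1 = 0.196
  expect_equal(two$ci_hi - two$mean_auc, 0.196, tolerance = 1e-4)
  expect_equal(two$mean_auc - two$ci_lo, two$ci_hi - two$mean_auc,
               tolerance = 1e-12)
  expect_equal(two$mean_auc, mean(c(0.7, 0.9)))

  expect_error(aggregate_runs(0.8), ">= 2 runs")
  wider <- aggregate_runs(c(0.7, 0.9), ci_method = "t")
  expect_gt(wider$ci_hi, two$ci_hi)   # t interval wider at small n
})

test_that("run_experiment aggregates seeded repeated trainings", {
  task <- make_slice_task(slice_task_spec(n = 200, class_sep = 5,
                                          outlier_frac = 0, duplicate_frac = 0,
                                          seed = 30))
  man <- dataset_manifest(subset_dataset(task, split = "train"))
  agg <- run_experiment(man$sample_id, task, config = training_config(),
                        n_runs = 3, base_seed = 9)
  expect_gte(agg$mean_auc, 0.9)
  expect_equal(agg$n_runs, 3L)
  agg2 <- run_experiment(man$sample_id, task, config = training_config(),
                         n_runs = 3, base_seed = 9)
  expect_identical(attr(agg, "runs"), attr(agg2, "runs"))

  # a selected 30% subset of a separable task also reaches high AUC
  sub <- withr::with_seed(2, sample(man$sample_id, 42))
  while (length(unique(man$label[man$sample_id %in% sub])) < 2) {
    sub <- withr::with_seed(3, sample(man$sample_id, 42))
  }
  agg_sub <- run_experiment(sub, task, config = training_config(),
                            n_runs = 3, base_seed = 9)
  expect_gte(agg_sub$mean_auc, 0.9)

  expect_error(run_experiment(man$sample_id, task, n_runs = 1), ">= 2")
  one_class <- man$sample_id[man$label == 1]
  expect_error(run_experiment(one_class, task, n_runs = 2), "single class")
})

test_that("range_sweep requires equal widths and resolves ranges deterministically", {
  ranked <- synthetic_ranking(100)
  expect_error(range_sweep(ranked, NULL,
                           list(range_spec(0, 0.3), range_spec(0.1, 0.5))),
               "equal width")
  expect_identical(select_range(ranked, range_spec(0.2, 0.5)),
                   select_range(ranked, range_spec(0.2, 0.5)))
})

test_that("mid-uncertainty ranges outtrain the most-uncertain range on planted data", {
  wins <- 0L
  for (s in 1:10) {
    task <- make_slice_task(slice_task_spec(n = 300, seed = 200 + s))
    train <- subset_dataset(task, split = "train")
    seed_ids <- random_baseline(dataset_manifest(train)$sample_id, 0.3,
                                seed = 300 + s)
    cmt <- build_committee(subset_dataset(train, ids = seed_ids),
                           config = training_config(seed = s))
    ranked <- score_dataset(predict_profiles(cmt, train))
    res <- range_sweep(ranked, task,
                       list(range_spec(0, 0.3), range_spec(0.1, 0.4)),
                       config = training_config(seed = s), n_runs = 2,
                       base_seed = 400 + s)
    if (res$mean_auc[res$lo == 0.1] > res$mean_auc[res$lo == 0]) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 8L)
})

test_that("size_sweep produces both arms at equal cardinality plus a baseline", {
  task <- make_slice_task(slice_task_spec(n = 200, seed = 50))
  train <- subset_dataset(task, split = "train")
  seed_ids <- random_baseline(dataset_manifest(train)$sample_id, 0.3, seed = 51)
  cmt <- build_committee(subset_dataset(train, ids = seed_ids),
                         config = training_config(seed = 52))
  ranked <- score_dataset(predict_profiles(cmt, train))
  res <- size_sweep(ranked, task, fractions = c(0.2, 0.4),
                    plan = selection_plan(budget = 0.4, seed = 53),
                    config = training_config(seed = 52), n_runs = 2,
                    base_seed = 54)
  expect_equal(nrow(res), 4L)
  for (f in c(0.2, 0.4)) {
    ns <- res$n_train[res$fraction == f]
    expect_equal(ns[1], ns[2])   # fair comparison: identical cardinality
  }
  expect_s3_class(attr(res, "baseline"), "aggregate_result")
  expect_error(size_sweep(ranked, task, fractions = 0.85), "multiples of 0.10")
})
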