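# Evaluation harnesses: slice-level ROC-AUC, aggregation of repeated
# seeded runs into mean +/- 95% CI, and the three experiment drivers
# (subset-vs-baseline comparison, uncertainty-range sweep, sample-size
# sweep of uncertainty vs. random sampling).

#' ROC-AUC by the Mann-Whitney pair formulation
#'
#' The fraction of (positive, negative) pairs in which the positive sample
#' receives the higher score, ties credited 0.5 -- computed via midranks,
#' which is algebraically identical to all-pairs enumeration. Invariant
#' under any strictly monotone transform of the scores.
#'
#' @param labels binary vector (0/1 or logical); both classes must be
#'   present.
#' @param scores numeric vector of the same length (higher = more
#'   positive).
#' @return scalar in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stopf("labels (%d) and scores (%d) differ in length",
          length(labels), length(scores))
  }
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUC is undefined with a single class (%d positives, %d negatives)",
          n1, n0)
  }
  r <- rank(scores)   # midranks handle ties as 0.5 credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate repeated runs into mean and 95% confidence interval
#'
#' The convention for reporting repeated experiments: the mean AUC of
#' `n >= 2` runs with a symmetric normal-approximation interval
#' `mean +/- z_{0.975} * sd / sqrt(n)` (sample sd, n-1 denominator). A
#' Student-t interval is available via `ci_method = "t"`.
#'
#' @param aucs numeric vector of per-run AUCs (>= 2 runs).
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"normal"` (default) or `"t"`.
#' @return a list of class `aggregate_result` with `mean_auc`, `ci_lo`,
#'   `ci_hi`, `n_runs`, `sd`.
#' @export
aggregate_runs <- function(aucs, conf_level = 0.95, ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  aucs <- as.numeric(aucs)
  n <- length(aucs)
  if (n < 2L) {
    stopf("aggregate_runs needs >= 2 runs (got %d); a CI is undefined otherwise", n)
  }
  m <- mean(aucs)
  s <- stats::sd(aucs)
  alpha <- 1 - conf_level
  crit <- if (ci_method == "normal") stats::qnorm(1 - alpha / 2) else
    stats::qt(1 - alpha / 2, df = n - 1L)
  half <- crit * s / sqrt(n)
  structure(list(mean_auc = m, ci_lo = m - half, ci_hi = m + half,
                 n_runs = n, sd = s),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f - %.4f, n = %d)\n",
              x$mean_auc, x$ci_lo, x$ci_hi, x$n_runs))
  invisible(x)
}

#' Train on a chosen subset and evaluate AUC over repeated runs
#'
#' Runs `n_runs` independent trainings of the classifier on the id-subset
#' of the pool (run r uses seed `base_seed + r - 1`), scores the held-out
#' split with the probability of class 1, and aggregates the per-run AUCs.
#'
#' @param train_ids character vector of training sample ids (must contain
#'   both classes).
#' @param pool `slice_dataset` holding training, validation and test
#'   splits.
#' @param config a [training_config()].
#' @param classifier zero-argument classifier factory.
#' @param eval_split split evaluated (`"test"` or `"val"`).
#' @param n_runs number of repeated runs (>= 2; 10 is the reporting
#'   convention).
#' @param base_seed first run seed.
#' @param validation_split optional split name used for per-epoch
#'   checkpoint selection during training (e.g. `"val"`).
#' @return an `aggregate_result`; per-run AUCs in attribute `"runs"`.
#' @export
run_experiment <- function(train_ids, pool, config = training_config(),
                           classifier = reference_classifier,
                           eval_split = "test", n_runs = 10L,
                           base_seed = config$seed,
                           validation_split = NULL) {
  if (length(train_ids) == 0L) stopf("`train_ids` is empty")
  if (n_runs < 2L) {
    stopf("n_runs must be >= 2 (got %d); a CI is undefined otherwise", n_runs)
  }
  train_ds <- subset_dataset(pool, ids = train_ids)
  if (length(unique(dataset_manifest(train_ds)$label)) < 2L) {
    stopf("training subset contains a single class")
  }
  eval_ds <- subset_dataset(pool, split = eval_split)
  eval_labels <- dataset_manifest(eval_ds)$label
  val_ds <- if (!is.null(validation_split)) {
    subset_dataset(pool, split = validation_split)
  }
  aucs <- vapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r - 1L)
    clf <- fit(classifier(), train_ds, cfg, validation = val_ds)
    p <- predict_proba(clf, eval_ds)
    roc_auc(eval_labels, p[, "1"])
  }, numeric(1))
  out <- aggregate_runs(aucs)
  attr(out, "runs") <- aucs
  out
}

#' Sweep equal-width uncertainty ranges
#'
#' Trains on the samples inside each ranked-uncertainty range (constant
#' sample count across ranges, hence the equal-width requirement) and
#' evaluates each with [run_experiment()]. Used to locate which part of
#' the uncertainty distribution carries training value -- e.g. comparing
#' the 10--40% range against the most-uncertain 0--30% range.
#'
#' @param ranked a `ranked_scores` data frame.
#' @param pool `slice_dataset` with splits.
#' @param ranges list of [range_spec()]s of identical width.
#' @param ... passed to [run_experiment()].
#' @return data frame of class `range_sweep_result` with columns `lo`,
#'   `hi`, `mean_auc`, `ci_lo`, `ci_hi`, `n_runs`.
#' @export
range_sweep <- function(ranked, pool, ranges, ...) {
  stopifnot(length(ranges) >= 1L)
  ranges <- lapply(ranges, function(r) {
    if (is.numeric(r)) range_spec(r[1L], r[2L]) else r
  })
  widths <- vapply(ranges, function(r) r$hi - r$lo, numeric(1))
  if (max(widths) - min(widths) > 1e-9) {
    stopf("ranges must have equal width (got %s) so sample counts stay constant",
          paste(signif(widths, 4), collapse = ", "))
  }
  rows <- lapply(ranges, function(r) {
    ids <- select_range(ranked, r)
    agg <- run_experiment(ids, pool, ...)
    data.frame(lo = r$lo, hi = r$hi, mean_auc = agg$mean_auc,
               ci_lo = agg$ci_lo, ci_hi = agg$ci_hi, n_runs = agg$n_runs)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("range_sweep_result", "data.frame")
  out
}

#' Sample-size sweep: uncertainty sampling vs. the random baseline
#'
#' For each budget fraction (a multiple of 10% between 10% and 80% of the
#' training pool), draws the uncertainty arm by budget-sampling the
#' post-exclusion ranking and the random arm from the full pool, trains
#' and evaluates both with [run_experiment()], and fits a full-pool
#' baseline once. Both arms at a given fraction train on subsets of
#' identical cardinality.
#'
#' @param ranked `ranked_scores` over the training pool.
#' @param pool `slice_dataset` with splits.
#' @param fractions multiples of 0.10 within \[0.10, 0.80\].
#' @param plan a [selection_plan()] providing the exclusion fractions and
#'   the sweep's selection seed.
#' @param include_baseline fit the full-pool baseline (default `TRUE`).
#' @param ... passed to [run_experiment()].
#' @return data frame of class `sweep_result` with columns `method`,
#'   `fraction`, `n_train`, `mean_auc`, `ci_lo`, `ci_hi`, `n_runs`; the
#'   baseline `aggregate_result` is in attribute `"baseline"`.
#' @export
size_sweep <- function(ranked, pool, fractions = seq(0.1, 0.8, by = 0.1),
                       plan = selection_plan(), include_baseline = TRUE,
                       ...) {
  ok <- abs(fractions * 10 - round(fractions * 10)) < 1e-9 &
    fractions >= 0.1 - 1e-9 & fractions <= 0.8 + 1e-9
  if (!all(ok)) {
    stopf("fractions must be multiples of 0.10 in [0.10, 0.80]; offending value %g",
          fractions[!ok][1L])
  }
  n <- nrow(ranked)
  retained <- exclude_extremes(ranked, plan$exclude_top, plan$exclude_bottom)
  pool_ids <- ranked$sample_id
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    unc_ids <- sample_budget(retained, n, f, seed = derive_seed(plan$seed, i, 1L))
    rnd_ids <- random_baseline(pool_ids, f, seed = derive_seed(plan$seed, i, 2L))
    if (length(unc_ids) != length(rnd_ids)) {
      stopf("arm cardinalities differ at fraction %g (%d vs %d)",
            f, length(unc_ids), length(rnd_ids))
    }
    for (arm in c("uncertainty", "random")) {
      ids <- if (arm == "uncertainty") unc_ids else rnd_ids
      agg <- run_experiment(ids, pool, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(method = arm, fraction = f, n_train = length(ids),
                   mean_auc = agg$mean_auc, ci_lo = agg$ci_lo,
                   ci_hi = agg$ci_hi, n_runs = agg$n_runs)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  if (include_baseline) {
    attr(out, "baseline") <- run_experiment(pool_ids, pool, ...)
  }
  out
}

#' Write sweep or range-sweep results as TSV
#'
#' @param result a `sweep_result` or `range_sweep_result` data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_results_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
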