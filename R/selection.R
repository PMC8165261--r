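# Turning a ranked uncertainty list into a training subset: ranked-range
# slicing, extreme exclusion, seeded budget sampling, the random-sampling
# baseline, and annotation-cost accounting.

#' A fractional range on the descending-ranked uncertainty list
#'
#' Fractions are interpreted on the descending ranking: 0 is the most
#' uncertain end. The realized index window is the 0-based half-open slice
#' `[floor(lo * N), floor(hi * N))`, so adjacent ranges such as 10--40% and
#' 40--70% are disjoint and compose without overlap.
#'
#' @param lo lower fraction in \[0, 1).
#' @param hi upper fraction in (0, 1\]; `lo < hi`.
#' @return a list of class `range_spec`.
#' @export
range_spec <- function(lo, hi) {
  check_fraction(lo, "lo", lo = 0, hi = 1, hi_open = TRUE)
  check_fraction(hi, "hi", lo = 0, hi = 1, lo_open = TRUE)
  if (lo >= hi) stopf("`lo` (%g) must be < `hi` (%g)", lo, hi)
  structure(list(lo = lo, hi = hi), class = "range_spec")
}

#' Select the samples inside a ranked-uncertainty range
#'
#' @param ranked a `ranked_scores` data frame (descending by score).
#' @param range a [range_spec()], or a numeric length-2 vector `c(lo, hi)`.
#' @return character vector of sample ids at ranked positions
#'   `[floor(lo*N), floor(hi*N))` (0-based, half-open), in rank order.
#' @examples
#' \dontrun{
#' select_range(ranked, range_spec(0.10, 0.40))  # ranks 11..40 of N = 100
#' }
#' @export
select_range <- function(ranked, range) {
  stopifnot(inherits(ranked, "ranked_scores"))
  if (is.numeric(range) && length(range) == 2L) {
    range <- range_spec(range[1L], range[2L])
  }
  stopifnot(inherits(range, "range_spec"))
  n <- nrow(ranked)
  if (n == 0L) stopf("ranked list is empty")
  from <- floor(range$lo * n) + 1L   # 1-based inclusive
  to <- floor(range$hi * n)          # 1-based inclusive
  if (from > to) {
    stopf("range [%g, %g) selects no samples out of %d", range$lo, range$hi, n)
  }
  ranked$sample_id[from:to]
}

#' Drop the most and least uncertain extremes of the ranking
#'
#' Discards the top `exclude_top` fraction (highest uncertainty scores,
#' treated as outliers) and the bottom `exclude_bottom` fraction (lowest
#' scores, least informative) of the descending-ranked list; the framework
#' defaults discard 10% at each end. Equivalent to
#' `select_range(ranked, range_spec(exclude_top, 1 - exclude_bottom))`.
#'
#' @param ranked a `ranked_scores` data frame.
#' @param exclude_top,exclude_bottom fractions in \[0, 1) with sum < 1.
#' @return character vector of retained sample ids, in rank order.
#' @export
exclude_extremes <- function(ranked, exclude_top = 0.10, exclude_bottom = 0.10) {
  check_fraction(exclude_top, "exclude_top", lo = 0, hi = 1, hi_open = TRUE)
  check_fraction(exclude_bottom, "exclude_bottom", lo = 0, hi = 1, hi_open = TRUE)
  if (exclude_top + exclude_bottom >= 1) {
    stopf("exclusions overlap: exclude_top (%g) + exclude_bottom (%g) >= 1",
          exclude_top, exclude_bottom)
  }
  select_range(ranked, range_spec(exclude_top, 1 - exclude_bottom))
}

#' Convert a sample-size proportion to an example count
#'
#' Round-half-up of `fraction * total`, the correspondence used when a
#' budget is expressed as a proportion of the full training pool (e.g. 30%
#' of a 4,060-slice pool is 1,218 examples).
#'
#' @param fraction fraction in \[0, 1\].
#' @param total positive integer pool size.
#' @return non-negative integer count.
#' @export
proportion_to_count <- function(fraction, total) {
  check_fraction(fraction, "fraction", lo = 0, hi = 1)
  if (!is_scalar_number(total) || total < 1 || total != floor(total)) {
    stopf("`total` must be a positive integer")
  }
  round_half_up(fraction * total)
}

#' Random budget sample from the retained (post-exclusion) ids
#'
#' Draws a uniform sample without replacement whose size is
#' `proportion_to_count(budget, pool_size)` -- the budget is a fraction of
#' the FULL training pool, not of the retained set. Reproducible given
#' `seed`.
#'
#' @param retained_ids character vector of candidate ids (e.g. from
#'   [exclude_extremes()]).
#' @param pool_size size of the full training pool the budget refers to.
#' @param budget fraction in \[0, 1\] of the full pool to select.
#' @param seed integer RNG seed.
#' @return character vector of selected ids.
#' @export
sample_budget <- function(retained_ids, pool_size, budget, seed) {
  count <- proportion_to_count(budget, pool_size)
  if (count == 0L) return(character(0))
  if (count > length(retained_ids)) {
    stopf("budget of %d samples (%.0f%% of pool %d) exceeds the %d retained candidates",
          count, 100 * budget, pool_size, length(retained_ids))
  }
  withr::with_seed(seed, sample(retained_ids, count))
}

#' Random-sampling baseline over the full pool
#'
#' Uniform sample without replacement from the complete pool (no
#' exclusions), the control arm against which uncertainty sampling is
#' compared.
#'
#' @param pool_ids character vector of all pool ids.
#' @param budget fraction in (0, 1\].
#' @param seed integer RNG seed.
#' @return character vector of `proportion_to_count(budget, |pool|)` ids.
#' @export
random_baseline <- function(pool_ids, budget, seed) {
  if (length(pool_ids) == 0L) stopf("pool is empty")
  check_fraction(budget, "budget", lo = 0, hi = 1, lo_open = TRUE)
  count <- proportion_to_count(budget, length(pool_ids))
  withr::with_seed(seed, sample(pool_ids, count))
}

#' A full selection plan (exclusions + budget + seed)
#'
#' Bundles the framework's selection defaults: discard the top and bottom
#' 10% of the ranking, then sample 30% of the full pool from the remainder.
#'
#' @param exclude_top,exclude_bottom fractions in \[0, 1), sum < 1.
#' @param budget fraction of the FULL pool, with
#'   `budget <= 1 - exclude_top - exclude_bottom`.
#' @param seed integer RNG seed.
#' @return a list of class `selection_plan`.
#' @export
selection_plan <- function(exclude_top = 0.10, exclude_bottom = 0.10,
                           budget = 0.30, seed = 1L) {
  check_fraction(exclude_top, "exclude_top", lo = 0, hi = 1, hi_open = TRUE)
  check_fraction(exclude_bottom, "exclude_bottom", lo = 0, hi = 1, hi_open = TRUE)
  if (exclude_top + exclude_bottom >= 1) {
    stopf("exclude_top + exclude_bottom must be < 1")
  }
  check_fraction(budget, "budget", lo = 0, hi = 1)
  if (budget > 1 - exclude_top - exclude_bottom + 1e-12) {
    stopf("budget (%g) cannot exceed the retained fraction (%g)",
          budget, 1 - exclude_top - exclude_bottom)
  }
  structure(list(exclude_top = exclude_top, exclude_bottom = exclude_bottom,
                 budget = budget, seed = as.integer(seed)),
            class = "selection_plan")
}

#' Apply a selection plan to a ranked score list
#'
#' @param ranked a `ranked_scores` data frame.
#' @param plan a [selection_plan()].
#' @return character vector of selected sample ids.
#' @export
apply_selection_plan <- function(ranked, plan) {
  stopifnot(inherits(plan, "selection_plan"))
  retained <- exclude_extremes(ranked, plan$exclude_top, plan$exclude_bottom)
  sample_budget(retained, nrow(ranked), plan$budget, plan$seed)
}

#' Annotation-cost bounds for seed-labeled + actively selected subsets
#'
#' With a fraction `labeled_fraction` of the pool already labeled and a
#' selected budget of `budget_fraction`, the total fraction requiring
#' labels is the size of the union of the two subsets: at least
#' `max(labeled, budget)` (complete overlap) and at most
#' `min(1, labeled + budget)` (no overlap). Savings are the complement
#' (1 - needed). With the canonical 30% seed and 30% budget, between 40%
#' and 70% of annotation cost is saved (mean 55%). When the actual id sets
#' are supplied, the realized union is reported as `actual_needed`.
#'
#' @param labeled_fraction fraction of the pool labeled up-front, in (0, 1\].
#' @param budget_fraction selected fraction, in (0, 1\].
#' @param initially_labeled_ids,selected_ids optional character id sets.
#' @param pool_size required when id sets are given.
#' @return a list of class `cost_report` with fields `labeled_fraction`,
#'   `budget_fraction`, `min_needed`, `max_needed`, `min_saving`,
#'   `max_saving`, `mean_saving` and (optionally) `actual_needed`,
#'   `actual_saving`.
#' @export
annotation_cost <- function(labeled_fraction, budget_fraction,
                            initially_labeled_ids = NULL,
                            selected_ids = NULL, pool_size = NULL) {
  check_fraction(labeled_fraction, "labeled_fraction", lo = 0, hi = 1, lo_open = TRUE)
  check_fraction(budget_fraction, "budget_fraction", lo = 0, hi = 1, lo_open = TRUE)
  min_needed <- max(labeled_fraction, budget_fraction)
  max_needed <- min(1, labeled_fraction + budget_fraction)
  rep <- list(labeled_fraction = labeled_fraction,
              budget_fraction = budget_fraction,
              min_needed = min_needed, max_needed = max_needed,
              min_saving = 1 - max_needed, max_saving = 1 - min_needed,
              mean_saving = ((1 - max_needed) + (1 - min_needed)) / 2)
  have_ids <- !is.null(initially_labeled_ids) || !is.null(selected_ids)
  if (have_ids) {
    if (is.null(initially_labeled_ids) || is.null(selected_ids)) {
      stopf("both id sets must be supplied together")
    }
    if (is.null(pool_size)) {
      stopf("`pool_size` is required when id sets are supplied")
    }
    actual <- length(union(initially_labeled_ids, selected_ids)) / pool_size
    rep$actual_needed <- actual
    rep$actual_saving <- 1 - actual
  }
  structure(rep, class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> seed-labeled %.0f%%, budget %.0f%% of pool\n",
              100 * x$labeled_fraction, 100 * x$budget_fraction))
  cat(sprintf("  labeling needed: %.0f%% - %.0f%% of the pool\n",
              100 * x$min_needed, 100 * x$max_needed))
  cat(sprintf("  annotation saving: %.0f%% - %.0f%% (mean %.0f%%)\n",
              100 * x$min_saving, 100 * x$max_saving, 100 * x$mean_saving))
  if (!is.null(x$actual_needed)) {
    cat(sprintf("  realized: %.1f%% needed (%.1f%% saved)\n",
                100 * x$actual_needed, 100 * x$actual_saving))
  }
  invisible(x)
}

#' Write / read a selected id list as newline-delimited text
#'
#' @param ids character vector of sample ids.
#' @param path file path.
#' @return `read_id_list` returns a character vector.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname write_id_list
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stopf("id list not found: '%s'", path)
  readLines(path)
}
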