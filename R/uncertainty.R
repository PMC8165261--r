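# Committee uncertainty scoring: predictive entropy plus pairwise
# Kullback-Leibler disagreement, and the descending-ranked score list that
# drives sample selection.

# Probabilities are clipped into [PROB_EPS, 1] before any log or division,
# without renormalization: saturated classifier outputs (exact 0s) would
# otherwise produce infinite divergences, and the perturbation at 1e-12 is
# far below every tolerance used downstream.
PROB_EPS <- 1e-12

clip_probs <- function(p) {
  pmin(pmax(p, PROB_EPS), 1)
}

#' Validate a discrete probability distribution
#'
#' A valid distribution has at least two classes, entries in \[0, 1\], and
#' entries summing to 1 within `tol`. Violations report the first offending
#' index so callers can locate bad classifier output.
#'
#' @param p numeric vector of class probabilities.
#' @param tol tolerance on the unit-sum constraint.
#' @param arg name used in error messages.
#' @return `p`, invisibly.
#' @export
validate_distribution <- function(p, tol = 1e-6, arg = "p") {
  if (!is.numeric(p) || length(p) < 2L) {
    stopf("`%s` must be a numeric vector of >= 2 class probabilities", arg)
  }
  bad <- which(p < -tol | p > 1 + tol | !is.finite(p))
  if (length(bad) > 0L) {
    stopf("`%s` is not a valid distribution: entry %d (%g) outside [0, 1]",
          arg, bad[1L], p[bad[1L]])
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stopf("`%s` is not a valid distribution: entries sum to %.8f, not 1",
          arg, s)
  }
  invisible(p)
}

#' Shannon entropy of a discrete distribution (nats)
#'
#' \eqn{H(p) = -\sum_i p_i \log p_i} with natural logarithm and
#' \eqn{0 \log 0 = 0}. The result lies in \eqn{[0, \log C]} for C classes:
#' zero exactly at degenerate (one-hot) distributions and maximal at the
#' uniform distribution.
#'
#' @param p numeric vector of class probabilities (validated).
#' @return non-negative scalar, in nats.
#' @examples
#' entropy(c(0.5, 0.5))   # log(2)
#' entropy(c(1, 0))       # 0
#' @export
entropy <- function(p) {
  validate_distribution(p, arg = "p")
  q <- clip_probs(p)
  -sum(q * log(q))
}

#' Kullback-Leibler divergence between two distributions (nats)
#'
#' \eqn{D(p\,\|\,q) = \sum_i p_i \log(p_i / q_i)}, natural logarithm. Both
#' arguments are clipped to \eqn{[10^{-12}, 1]} before the ratio, so
#' saturated outputs give a large finite divergence instead of `Inf`. The
#' divergence is non-negative (Gibbs' inequality) and zero iff `p == q`
#' entrywise within the clipping tolerance.
#'
#' @param p,q numeric probability vectors of equal length.
#' @return non-negative scalar, in nats.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
#' @export
kl_divergence <- function(p, q) {
  validate_distribution(p, arg = "p")
  validate_distribution(q, arg = "q")
  if (length(p) != length(q)) {
    stopf("`p` and `q` must have the same number of classes (%d vs %d)",
          length(p), length(q))
  }
  pc <- clip_probs(p)
  qc <- clip_probs(q)
  sum(pc * log(pc / qc))
}

#' Bundle committee member predictions for a set of samples
#'
#' Container for the per-sample class-probability profiles produced by an
#' M-member committee: an `M x N x C` array (member, sample, class) plus the
#' N sample identifiers.
#'
#' @param sample_ids character vector of N unique sample identifiers.
#' @param probs numeric array of dimension `M x N x C` with `M >= 2`,
#'   `C >= 2`; every `probs[m, n, ]` must be a valid distribution.
#' @return an object of class `committee_profiles`.
#' @export
committee_profiles <- function(sample_ids, probs) {
  if (!is.array(probs) || length(dim(probs)) != 3L) {
    stopf("`probs` must be an M x N x C array")
  }
  d <- dim(probs)
  if (d[1L] < 2L) stopf("committee size M must be >= 2, got %d", d[1L])
  if (d[3L] < 2L) stopf("number of classes C must be >= 2, got %d", d[3L])
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != d[2L]) {
    stopf("%d sample_ids for %d samples", length(sample_ids), d[2L])
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0L) {
    stopf("duplicate sample_id: '%s'", dup[1L])
  }
  tol <- 1e-6
  if (any(probs < -tol | probs > 1 + tol | !is.finite(probs))) {
    bad <- which(probs < -tol | probs > 1 + tol | !is.finite(probs),
                 arr.ind = TRUE)[1L, ]
    stopf("invalid probability at member %d, sample '%s', class %d",
          bad[1L], sample_ids[bad[2L]], bad[3L])
  }
  sums <- apply(probs, c(1L, 2L), sum)
  if (any(abs(sums - 1) > tol)) {
    bad <- which(abs(sums - 1) > tol, arr.ind = TRUE)[1L, ]
    stopf("distribution of member %d for sample '%s' sums to %.8f, not 1",
          bad[1L], sample_ids[bad[2L]], sums[bad[1L], bad[2L]])
  }
  structure(list(sample_ids = sample_ids, probs = probs),
            class = "committee_profiles")
}

#' @export
print.committee_profiles <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<committee_profiles> M = %d members, N = %d samples, C = %d classes\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Uncertainty score of one sample from its committee profile
#'
#' The informativeness score of a sample is the sum of each member's
#' predictive entropy plus the Kullback-Leibler divergence over all ordered
#' pairs of distinct members. Summing both directions of every unordered
#' pair realizes the symmetric divergence between members; the total is the
#' committee's disagreement about the sample.
#'
#' @param members numeric `M x C` matrix, one row per committee member
#'   (each row a valid distribution), `M >= 2`.
#' @param sample_id optional identifier carried into the result.
#' @return a list of class `uncertainty_record` with fields `sample_id`,
#'   `entropy_sum`, `kl_sum`, `score` (all in nats;
#'   `score = entropy_sum + kl_sum`).
#' @examples
#' committee_score(rbind(c(0.5, 0.5), c(0.25, 0.75)))
#' @export
committee_score <- function(members, sample_id = NA_character_) {
  if (!is.matrix(members)) members <- as.matrix(members)
  m <- nrow(members)
  if (m < 2L) {
    stopf("committee_score needs M >= 2 members (pairwise disagreement is undefined for M = %d)", m)
  }
  for (i in seq_len(m)) {
    validate_distribution(members[i, ], arg = sprintf("member %d", i))
  }
  ent <- sum(apply(members, 1L, entropy))
  kl <- 0
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a != b) kl <- kl + kl_divergence(members[a, ], members[b, ])
    }
  }
  structure(list(sample_id = sample_id, entropy_sum = ent, kl_sum = kl,
                 score = ent + kl),
            class = "uncertainty_record")
}

#' @export
print.uncertainty_record <- function(x, ...) {
  cat(sprintf("<uncertainty_record> %s: entropy_sum %.6f + kl_sum %.6f = %.6f nats\n",
              x$sample_id, x$entropy_sum, x$kl_sum, x$score))
  invisible(x)
}

#' Score every sample and rank by descending uncertainty
#'
#' Computes the committee uncertainty score for each profile and returns
#' the descending-sorted score list. Ties are broken by ascending
#' `sample_id` (C-locale radix order), so the ranking is fully
#' deterministic.
#'
#' @param profiles a [committee_profiles] object.
#' @return a `data.frame` of class `ranked_scores` with columns
#'   `sample_id`, `entropy_sum`, `kl_sum`, `score`, `rank` (1-based), in
#'   rank order.
#' @export
score_dataset <- function(profiles) {
  if (!inherits(profiles, "committee_profiles")) {
    stopf("`profiles` must be a committee_profiles object")
  }
  P <- clip_probs(profiles$probs)              # M x N x C
  m <- dim(P)[1L]
  # entropy: sum over members and classes per sample
  ent_terms <- -P * log(P)
  entropy_sum <- apply(ent_terms, 2L, sum)
  # KL over ordered member pairs, vectorized per pair
  n <- dim(P)[2L]
  kl_sum <- numeric(n)
  logP <- log(P)
  member_slice <- function(arr, a) matrix(arr[a, , ], nrow = n)  # N x C
  for (a in seq_len(m)) {
    Pa <- member_slice(P, a)
    La <- member_slice(logP, a)
    for (b in seq_len(m)) {
      if (a == b) next
      kl_sum <- kl_sum + rowSums(Pa * (La - member_slice(logP, b)))
    }
  }
  score <- entropy_sum + kl_sum
  ord <- order(-score, profiles$sample_ids, method = "radix")
  out <- data.frame(sample_id = profiles$sample_ids[ord],
                    entropy_sum = entropy_sum[ord],
                    kl_sum = kl_sum[ord],
                    score = score[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_scores", "data.frame")
  out
}

#' Write / read a ranked score list as TSV
#'
#' Columns `sample_id`, `entropy_sum`, `kl_sum`, `score`, `rank`, written
#' in rank order with full double precision.
#'
#' @param ranked a `ranked_scores` data frame.
#' @param path file path.
#' @return `read_score_list` returns a `ranked_scores` data frame.
#' @export
write_score_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_scores"))
  df <- as.data.frame(ranked)
  for (col in c("entropy_sum", "kl_sum", "score")) {
    df[[col]] <- formatC(df[[col]], format = "g", digits = 17)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_list
#' @export
read_score_list <- function(path) {
  if (!file.exists(path)) stopf("score list not found: '%s'", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sample_id = "character"))
  class(df) <- c("ranked_scores", "data.frame")
  df
}

#' Write / read committee probability profiles as long-format TSV
#'
#' One row per (sample, member, class): columns `sample_id`,
#' `member_index`, `class_index` (both 1-based) and `prob`. Sample order on
#' read follows first appearance in the file.
#'
#' @param profiles a [committee_profiles] object.
#' @param path file path.
#' @return `read_profiles` returns a [committee_profiles] object.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "committee_profiles"))
  d <- dim(profiles$probs)
  idx <- expand.grid(member_index = seq_len(d[1L]),
                     sample = seq_len(d[2L]),
                     class_index = seq_len(d[3L]))
  df <- data.frame(sample_id = profiles$sample_ids[idx$sample],
                   member_index = idx$member_index,
                   class_index = idx$class_index,
                   prob = formatC(profiles$probs[as.matrix(idx)],
                                  format = "g", digits = 17),
                   stringsAsFactors = FALSE)
  df <- df[order(idx$sample, idx$member_index, idx$class_index), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stopf("profiles file not found: '%s'", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sample_id = "character"))
  ids <- unique(df$sample_id)
  m <- max(df$member_index)
  cc <- max(df$class_index)
  probs <- array(NA_real_, dim = c(m, length(ids), cc))
  n_idx <- match(df$sample_id, ids)
  probs[cbind(df$member_index, n_idx, df$class_index)] <- df$prob
  if (anyNA(probs)) stopf("incomplete profile table in '%s'", path)
  committee_profiles(ids, probs)
}
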