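# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's vectorized code paths: plain loops and
# textbook formulas only.

# -- oracles ----------------------------------------------------------------

# entropy with explicit 0*log(0) = 0 handling
oracle_entropy <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

# KL with the same epsilon-clipping convention, via an explicit loop
oracle_kl <- function(p, q, eps = 1e-12) {
  s <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1)
    qi <- min(max(q[i], eps), 1)
    s <- s + pi * log(pi / qi)
  }
  s
}

# per-sample committee score from an M x C matrix, by double loop
oracle_committee_score <- function(mat, base = exp(1)) {
  ent <- 0
  for (m in seq_len(nrow(mat))) ent <- ent + oracle_entropy(mat[m, ])
  kl <- 0
  for (a in seq_len(nrow(mat))) {
    for (b in seq_len(nrow(mat))) {
      if (a != b) kl <- kl + oracle_kl(mat[a, ], mat[b, ])
    }
  }
  (ent + kl) / log(base)
}

# all-pairs AUC enumeration, ties credited 0.5
oracle_auc <- function(labels, scores) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# -- fixture builders -------------------------------------------------------

random_distribution <- function(n_classes) {
  x <- stats::rexp(n_classes)
  x / sum(x)
}

random_profiles <- function(n, m = 3L, n_classes = 2L, seed = 1L) {
  withr::with_seed(seed, {
    probs <- array(0, dim = c(m, n, n_classes))
    for (i in seq_len(m)) {
      for (j in seq_len(n)) probs[i, j, ] <- random_distribution(n_classes)
    }
    committee_profiles(sprintf("s%03d", seq_len(n)), probs)
  })
}

# ranked list with known ids and strictly decreasing scores
synthetic_ranking <- function(n) {
  df <- data.frame(sample_id = sprintf("id%03d", seq_len(n)),
                   entropy_sum = 0, kl_sum = 0,
                   score = seq(n, 1), rank = seq_len(n),
                   stringsAsFactors = FALSE)
  class(df) <- c("ranked_scores", "data.frame")
  df
}

# a linearly separable two-blob slice task: class means 0 and `gap`
two_blob_dataset <- function(n = 60L, side = 6L, gap = 2, seed = 1L) {
  withr::with_seed(seed, {
    d <- side * side * 3L
    label <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * d, sd = 0.3), n, d) + gap * label
    manifest <- data.frame(sample_id = sprintf("b%03d", seq_len(n)),
                           patient_id = sprintf("b%03d", seq_len(n)),
                           z_index = 0L, label = label,
                           split = "train", tag = NA_character_,
                           stringsAsFactors = FALSE)
    slice_dataset(array(X, dim = c(n, side, side, 3L)), manifest)
  })
}

tiny_phantom_cohort <- function(n_hgg = 2L, n_lgg = 1L, shape = c(16L, 16L, 24L),
                                min_tumor_planes = 20L, seed = 1L) {
  make_phantom_cohort(phantom_spec(n_hgg = n_hgg, n_lgg = n_lgg, shape = shape,
                                   min_tumor_planes = min_tumor_planes,
                                   seed = seed))
}
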