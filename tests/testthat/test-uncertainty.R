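# Entropy, KL divergence, committee scores and the ranked score list.

test_that("entropy matches closed forms and hand-computed values", {
  expect_equal(entropy(c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(entropy(c(1, 0)), 0, tolerance = 1e-9)
  # frozen from the independent loop oracle: -0.8 log 0.8 - 0.2 log 0.2
  expect_equal(entropy(c(0.8, 0.2)), 0.5004024235381879, tolerance = 1e-9)
  expect_equal(entropy(c(0.8, 0.2)), oracle_entropy(c(0.8, 0.2)),
               tolerance = 1e-9)
})

test_that("entropy is maximal at uniform and zero at degenerate distributions", {
  for (k in 2:4) {
    uniform <- rep(1 / k, k)
    h_max <- entropy(uniform)
    expect_equal(h_max, log(k), tolerance = 1e-9)
    degenerate <- c(1, rep(0, k - 1))
    expect_equal(entropy(degenerate), 0, tolerance = 1e-9)
    withr::with_seed(100 + k, {
      for (rep in 1:25) {
        p <- random_distribution(k)
        expect_lte(entropy(p), h_max + 1e-12)
        expect_gte(entropy(p), 0)
      }
    })
  }
})

test_that("invalid distributions are rejected with the offending index", {
  expect_error(entropy(c(-0.1, 1.1)), "entry 1")
  expect_error(entropy(c(0.5, 0.4)), "sum to")
  expect_error(entropy(0.5), ">= 2")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.7, 0.2)), "sum to")
})

test_that("KL divergence matches hand-computed values and is zero iff p == q", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-12)
  expect_equal(kl_divergence(c(1, 0), c(1, 0)), 0, tolerance = 1e-9)
  # frozen from the oracle: 0.5 log 2 + 0.5 log(2/3)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.14384103622589045, tolerance = 1e-9)
  expect_error(kl_divergence(c(0.5, 0.5), c(0.2, 0.3, 0.5)),
               "same number of classes")
})

test_that("KL divergence is non-negative over many random pairs (Gibbs)", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      k <- sample(2:4, 1)
      p <- random_distribution(k)
      q <- random_distribution(k)
      expect_gte(kl_divergence(p, q), -1e-12)
    }
  })
})

test_that("committee score sums member entropies and ordered-pair KL", {
  certain <- rbind(c(1, 0), c(1, 0), c(1, 0))
  expect_equal(committee_score(certain)$score, 0, tolerance = 1e-9)

  uniform <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  rec <- committee_score(uniform)
  expect_equal(rec$score, 3 * log(2), tolerance = 1e-9)
  expect_equal(rec$kl_sum, 0, tolerance = 1e-12)

  # frozen from the loop oracle: H(.5,.5)+H(.25,.75) and both ordered KLs
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  rec2 <- committee_score(two)
  expect_equal(rec2$entropy_sum, 1.2554823251787535, tolerance = 1e-9)
  expect_equal(rec2$kl_sum, 0.2746530721670274, tolerance = 1e-9)
  expect_equal(rec2$score, 1.5301353973457807, tolerance = 1e-9)
  expect_equal(rec2$score, rec2$entropy_sum + rec2$kl_sum)

  expect_error(committee_score(matrix(c(0.5, 0.5), nrow = 1)), "M >= 2")
})

test_that("kl_sum is invariant under permutation of committee members", {
  withr::with_seed(7, {
    for (i in 1:20) {
      mat <- t(replicate(4, random_distribution(3)))
      perm <- mat[sample(4), ]
      expect_equal(committee_score(mat)$kl_sum, committee_score(perm)$kl_sum,
                   tolerance = 1e-12)
    }
  })
})

test_that("score_dataset ranks descending with ascending-id tie-break", {
  # three distinct scores sort descending
  probs <- array(0, dim = c(2, 3, 2))
  probs[, 1, ] <- rbind(c(0.99, 0.01), c(0.99, 0.01))  # low score
  probs[, 2, ] <- rbind(c(0.5, 0.5), c(0.5, 0.5))      # high score
  probs[, 3, ] <- rbind(c(0.8, 0.2), c(0.8, 0.2))      # middle
  ranked <- score_dataset(committee_profiles(c("x", "y", "z"), probs))
  expect_equal(ranked$sample_id, c("y", "z", "x"))
  expect_equal(ranked$rank, 1:3)
  expect_true(all(diff(ranked$score) <= 0))

  # identical profiles, ids given in reverse order: "a" must rank first
  tie <- array(rep(c(0.5, 0.5), each = 4), dim = c(2, 2, 2))
  ranked_tie <- score_dataset(committee_profiles(c("b", "a"), tie))
  expect_equal(ranked_tie$sample_id, c("a", "b"))

  expect_error(committee_profiles(c("a", "a"), tie), "duplicate sample_id")
})

test_that("score_dataset agrees with per-sample brute-force recomputation", {
  profiles <- random_profiles(50, m = 3, n_classes = 3, seed = 11)
  ranked <- score_dataset(profiles)
  expected <- vapply(seq_along(profiles$sample_ids), function(j) {
    oracle_committee_score(profiles$probs[, j, ])
  }, numeric(1))
  ord <- order(-expected, profiles$sample_ids, method = "radix")
  expect_equal(ranked$sample_id, profiles$sample_ids[ord])
  expect_equal(ranked$score,
               expected[match(ranked$sample_id, profiles$sample_ids)],
               tolerance = 1e-9)
})

test_that("changing the log base rescales scores but preserves the ranking", {
  profiles <- random_profiles(40, m = 3, n_classes = 2, seed = 23)
  ranked <- score_dataset(profiles)
  base2 <- vapply(seq_along(profiles$sample_ids), function(j) {
    oracle_committee_score(profiles$probs[, j, ], base = 2)
  }, numeric(1))
  nat <- ranked$score[match(profiles$sample_ids, ranked$sample_id)]
  expect_equal(base2, nat / log(2), tolerance = 1e-9)
  ord2 <- order(-base2, profiles$sample_ids, method = "radix")
  expect_equal(profiles$sample_ids[ord2], ranked$sample_id)
})

test_that("score lists and profiles survive a TSV round trip", {
  profiles <- random_profiles(12, m = 3, n_classes = 2, seed = 3)
  ranked <- score_dataset(profiles)
  dir <- withr::local_tempdir()
  write_score_list(ranked, file.path(dir, "scores.tsv"))
  back <- read_score_list(file.path(dir, "scores.tsv"))
  expect_equal(back$sample_id, ranked$sample_id)
  expect_equal(back$score, ranked$score, tolerance = 1e-12)

  write_profiles(profiles, file.path(dir, "profiles.tsv"))
  pback <- read_profiles(file.path(dir, "profiles.tsv"))
  expect_equal(pback$sample_ids, profiles$sample_ids)
  expect_equal(pback$probs, profiles$probs, tolerance = 1e-12)
})
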