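# Volumetric-to-slice pipeline: tumor-plane detection, per-patient
# extraction, cohort builds and patient-level splits.

test_that("find_tumor_slices locates planes with any non-zero label", {
  empty <- array(0L, dim = c(4, 4, 6))
  expect_equal(find_tumor_slices(empty), integer(0))

  single <- array(0L, dim = c(8, 8, 10))
  single[3, 4, 6] <- 2L          # plane z = 5 (0-based)
  expect_equal(find_tumor_slices(single), 5L)

  withr::with_seed(8, {
    seg <- array(sample(c(0L, 0L, 0L, 1L, 2L, 4L), 6 * 5 * 12, replace = TRUE),
                 dim = c(6, 5, 12))
    got <- find_tumor_slices(seg)
    # brute-force plane-by-plane membership scan
    expected <- integer(0)
    for (z in seq_len(12)) {
      plane <- seg[, , z]
      has <- FALSE
      for (v in as.vector(plane)) if (v %in% c(1, 2, 4)) has <- TRUE
      if (has) expected <- c(expected, z - 1L)
    }
    expect_equal(got, expected)
  })

  bad <- array(3L, dim = c(2, 2, 2))
  expect_error(find_tumor_slices(bad), "outside \\{0,1,2,4\\}")
})

test_that("extracted slices come from tumor planes and inherit the grade label", {
  cohort <- tiny_phantom_cohort(n_hgg = 1, n_lgg = 1, shape = c(16, 16, 24),
                                min_tumor_planes = 20, seed = 3)
  hgg <- cohort[[1]]
  lgg <- cohort[[2]]
  ds <- extract_patient_slices(hgg, k = 20, target_size = 16, seed = 2)
  man <- dataset_manifest(ds)
  expect_equal(nrow(man), 20L)
  expect_true(all(man$label == 1L))
  tumor_planes <- find_tumor_slices(hgg$segmentation)
  expect_true(all(man$z_index %in% tumor_planes))
  expect_false(anyDuplicated(man$z_index) > 0)

  lds <- extract_patient_slices(lgg, k = 5, target_size = 16, seed = 2)
  expect_true(all(dataset_manifest(lds)$label == 0L))
})

test_that("strict mode rejects patients with too few tumor planes; permissive warns", {
  cohort <- tiny_phantom_cohort(n_hgg = 1, n_lgg = 0, shape = c(12, 12, 16),
                                min_tumor_planes = 10, seed = 5)
  p <- cohort[[1]]
  n_planes <- length(find_tumor_slices(p$segmentation))
  expect_error(extract_patient_slices(p, k = n_planes + 5, target_size = 12),
               "only")
  expect_warning(
    ds <- extract_patient_slices(p, k = n_planes + 5, target_size = 12,
                                 strict = FALSE),
    "only")
  expect_equal(n_slices(ds), n_planes)
})

test_that("channels are min-max normalized and resized to the target size", {
  cohort <- tiny_phantom_cohort(n_hgg = 1, n_lgg = 0, shape = c(30, 30, 12),
                                min_tumor_planes = 8, seed = 7)
  p <- cohort[[1]]
  ds <- extract_patient_slices(p, k = 4, target_size = 24, seed = 1)
  expect_equal(dim(ds$images), c(4L, 24L, 24L, 3L))
  expect_gte(min(ds$images), 0)
  expect_lte(max(ds$images), 1)

  # per-channel min-max normalization makes extraction scale-invariant
  scaled <- p
  scaled$modalities <- lapply(p$modalities, function(v) v * 10)
  ds_scaled <- extract_patient_slices(scaled, k = 4, target_size = 24, seed = 1)
  expect_equal(ds_scaled$images, ds$images, tolerance = 1e-9)
})

test_that("cohort builds satisfy the exact count identities", {
  cohort <- tiny_phantom_cohort(n_hgg = 3, n_lgg = 2, shape = c(12, 12, 34),
                                min_tumor_planes = 30, seed = 11)
  imbalanced <- build_slice_dataset(cohort, k_hgg = 20, k_lgg = 20,
                                    target_size = 12, seed = 1)
  expect_equal(n_slices(imbalanced), 20L * 5L)
  balanced <- build_slice_dataset(cohort, k_hgg = 10, k_lgg = 30,
                                  target_size = 12, seed = 1)
  expect_equal(n_slices(balanced), 10L * 3L + 30L * 2L)
  man <- dataset_manifest(balanced)
  expect_equal(sum(man$label == 1), 30L)   # balanced: HGG slices == LGG slices
  expect_equal(sum(man$label == 0), 60L)

  expect_error(build_slice_dataset(list()), "non-empty")
})

test_that("every emitted slice's source plane contains tumor (post hoc)", {
  cohort <- tiny_phantom_cohort(n_hgg = 2, n_lgg = 1, shape = c(12, 12, 24),
                                min_tumor_planes = 20, seed = 13)
  ds <- build_slice_dataset(cohort, target_size = 12, seed = 2)
  man <- dataset_manifest(ds)
  seg_by_patient <- setNames(lapply(cohort, function(p) p$segmentation),
                             vapply(cohort, function(p) p$patient_id, ""))
  for (i in seq_len(nrow(man))) {
    plane <- seg_by_patient[[man$patient_id[i]]][, , man$z_index[i] + 1L]
    expect_true(any(plane %in% c(1L, 2L, 4L)))
  }
})

test_that("patient splits follow largest-remainder stratified apportionment", {
  info <- data.frame(patient_id = sprintf("P%04d", 1:335),
                     grade = c(rep("HGG", 259), rep("LGG", 76)))
  assignment <- split_patients(info, sizes = c(203, 66, 66), seed = 9)
  tab <- table(assignment$grade, assignment$split)
  expect_equal(tab["HGG", "train"], 157L)
  expect_equal(tab["HGG", "val"], 51L)
  expect_equal(tab["HGG", "test"], 51L)
  expect_equal(tab["LGG", "train"], 46L)
  expect_equal(tab["LGG", "val"], 15L)
  expect_equal(tab["LGG", "test"], 15L)
  # partition: disjoint, covering, deterministic
  split_sizes <- table(assignment$split)
  expect_equal(as.integer(split_sizes[c("train", "val", "test")]),
               c(203L, 66L, 66L))
  expect_false(anyNA(assignment$split))
  expect_identical(assignment, split_patients(info, sizes = c(203, 66, 66),
                                              seed = 9))
  expect_error(split_patients(info, sizes = c(200, 66, 66)), "sum to")
})

test_that("no patient contributes slices to more than one split", {
  cohort <- tiny_phantom_cohort(n_hgg = 4, n_lgg = 2, shape = c(12, 12, 24),
                                min_tumor_planes = 20, seed = 15)
  ds <- build_slice_dataset(cohort, target_size = 12, seed = 3)
  assignment <- split_patients(cohort, sizes = c(4, 1, 1), seed = 3)
  ds <- assign_split(ds, assignment)
  man <- dataset_manifest(ds)
  per_patient <- tapply(man$split, man$patient_id,
                        function(s) length(unique(s)))
  expect_true(all(per_patient == 1L))
})
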