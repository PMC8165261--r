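# Synthetic data: phantom volumetric cohorts (stand-ins for multi-modality
# glioma scans with voxel-wise segmentation) and planted-structure 2D slice
# tasks with known outlier / redundant subpopulations. Everything the other
# modules need is generated here, so no external imaging data is required.

#' Specification of a phantom volumetric cohort
#'
#' Each phantom patient carries four modality volumes (Gaussian background
#' plus a grade-shifted ellipsoidal lesion) and a segmentation map with
#' nested lesion shells labeled 1 (necrotic core), 4 (enhancing tumor) and
#' 2 (edema). The lesion is guaranteed to span at least
#' `min_tumor_planes` axial planes, so per-patient slice extraction at
#' `k <= min_tumor_planes` always succeeds in strict mode.
#'
#' @param n_hgg,n_lgg patient counts per grade.
#' @param shape integer `c(X, Y, Z)` voxel dimensions.
#' @param min_tumor_planes minimum axial extent of the lesion.
#' @param intensity_contrast lesion mean shift for an HGG lesion (LGG
#'   lesions get 60% of it), in units of the background SD spread.
#' @param noise_sd per-voxel Gaussian noise SD.
#' @param seed integer master seed; each patient derives a stable child
#'   seed from it.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_hgg, n_lgg, shape = c(16L, 16L, 24L),
                         min_tumor_planes = 20L, intensity_contrast = 1.0,
                         noise_sd = 0.1, seed = 1L) {
  if (!is_scalar_number(n_hgg) || !is_scalar_number(n_lgg) ||
      n_hgg < 0 || n_lgg < 0 || n_hgg + n_lgg < 1) {
    stopf("patient counts must be non-negative with at least one patient")
  }
  if (length(shape) != 3L || any(shape < 4)) {
    stopf("`shape` must be c(X, Y, Z) with all dims >= 4")
  }
  if (min_tumor_planes > shape[3L]) {
    stopf("min_tumor_planes (%d) exceeds Z (%d): lesion cannot fit",
          min_tumor_planes, shape[3L])
  }
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(list(n_hgg = as.integer(n_hgg), n_lgg = as.integer(n_lgg),
                 shape = as.integer(shape),
                 min_tumor_planes = as.integer(min_tumor_planes),
                 intensity_contrast = intensity_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Baseline intensity and lesion-contrast multiplier per modality; the
# enhancing shell is brightest post-contrast (T1C), mimicking gadolinium
# uptake.
MODALITY_BASE <- c(T1 = 1.0, T1C = 1.2, T2 = 0.8, FLAIR = 1.1)
MODALITY_LESION_FACTOR <- c(T1 = 0.5, T1C = 1.5, T2 = 1.0, FLAIR = 0.8)

make_one_phantom <- function(spec, patient_id, grade, child_seed) {
  X <- spec$shape[1L]; Y <- spec$shape[2L]; Z <- spec$shape[3L]
  rz <- ceiling((spec$min_tumor_planes - 1L) / 2)
  if (2L * rz + 1L > Z) {
    stopf("lesion of axial extent %d cannot fit in Z = %d", 2 * rz + 1, Z)
  }
  withr::with_seed(child_seed, {
    rx <- max(2L, floor(X / 3))
    ry <- max(2L, floor(Y / 3))
    cx <- sample(seq(rx + 1L, X - rx), 1L)
    cy <- sample(seq(ry + 1L, Y - ry), 1L)
    cz <- sample(seq(rz + 1L, Z - rz), 1L)
    # normalized squared ellipsoid radius over the voxel grid
    dx2 <- ((seq_len(X) - cx) / rx)^2
    dy2 <- ((seq_len(Y) - cy) / ry)^2
    dz2 <- ((seq_len(Z) - cz) / rz)^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    seg <- array(0L, dim = c(X, Y, Z))
    seg[r2 <= 1] <- 2L          # outer shell: edema
    seg[r2 <= 0.64] <- 4L       # middle shell: enhancing tumor
    seg[r2 <= 0.25] <- 1L       # core: necrotic / non-enhancing
    lesion <- r2 <= 1
    grade_factor <- if (grade == "HGG") 1.0 else 0.6
    modalities <- lapply(MODALITY_NAMES, function(mod) {
      vol <- array(stats::rnorm(X * Y * Z, mean = MODALITY_BASE[[mod]],
                                sd = spec$noise_sd), dim = c(X, Y, Z))
      shift <- spec$intensity_contrast * grade_factor *
        MODALITY_LESION_FACTOR[[mod]]
      vol[lesion] <- vol[lesion] + shift
      # extra post-contrast enhancement of the enhancing shell
      if (mod == "T1C") vol[seg == 4L] <- vol[seg == 4L] + 0.5 * shift
      vol
    })
    names(modalities) <- MODALITY_NAMES
    patient_volume(patient_id, modalities, seg, grade)
  })
}

#' Generate a phantom patient cohort
#'
#' @param spec a [phantom_spec()].
#' @return list of [patient_volume()] objects (HGG patients first),
#'   bitwise-reproducible given the spec seed.
#' @export
make_phantom_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grades <- c(rep("HGG", spec$n_hgg), rep("LGG", spec$n_lgg))
  ids <- sprintf("P%04d", seq_along(grades))
  lapply(seq_along(grades), function(i) {
    make_one_phantom(spec, ids[i], grades[i], derive_seed(spec$seed, i))
  })
}

#' Specification of a planted-structure 2D slice task
#'
#' Emulates the informativeness structure of a slice-level training pool:
#' most samples are ordinary class-conditional draws, a `duplicate_frac`
#' subpopulation consists of near-copies of the per-class prototype
#' (redundant, maximally typical -- no marginal training value), and an
#' `outlier_frac` subpopulation carries flipped labels and inflated pixel
#' noise (misleading -- a committee should disagree about them). Sample
#' images are `image_side x image_side x 3` with unit per-pixel noise for
#' normal samples; `class_sep` is the separation of the two class means
#' along a fixed unit-norm direction, i.e. the d' of the underlying
#' two-class problem.
#'
#' @param n total samples (>= 10).
#' @param image_side side length in pixels.
#' @param class_sep class-mean separation (0 = no signal).
#' @param outlier_frac,duplicate_frac subpopulation fractions, sum < 1.
#' @param class_balance fraction of samples whose true class is 1.
#' @param split_fractions named fractions `train`/`val`/`test` summing to
#'   1. All outliers and duplicates are planted in the training split;
#'   validation and test remain clean draws so held-out AUC measures
#'   generalization.
#' @param seed integer master seed.
#' @return a list of class `slice_task_spec`.
#' @export
slice_task_spec <- function(n = 400L, image_side = 16L, class_sep = 4.0,
                            outlier_frac = 0.10, duplicate_frac = 0.10,
                            class_balance = 0.5,
                            split_fractions = c(train = 0.7, val = 0.15,
                                                test = 0.15),
                            seed = 1L) {
  if (!is_scalar_number(n) || n < 10) stopf("`n` must be >= 10")
  if (!is_scalar_number(image_side) || image_side < 2) {
    stopf("`image_side` must be >= 2")
  }
  check_fraction(class_sep, "class_sep", lo = 0, hi = Inf)
  check_fraction(outlier_frac, "outlier_frac", lo = 0, hi = 1, hi_open = TRUE)
  check_fraction(duplicate_frac, "duplicate_frac", lo = 0, hi = 1, hi_open = TRUE)
  if (outlier_frac + duplicate_frac >= 1) {
    stopf("outlier_frac + duplicate_frac must be < 1")
  }
  check_fraction(class_balance, "class_balance", lo = 0, hi = 1,
                 lo_open = TRUE, hi_open = TRUE)
  if (abs(sum(split_fractions) - 1) > 1e-9 ||
      !all(c("train", "val", "test") %in% names(split_fractions))) {
    stopf("`split_fractions` must be named train/val/test and sum to 1")
  }
  structure(list(n = as.integer(n), image_side = as.integer(image_side),
                 class_sep = class_sep, outlier_frac = outlier_frac,
                 duplicate_frac = duplicate_frac,
                 class_balance = class_balance,
                 split_fractions = split_fractions, seed = as.integer(seed)),
            class = "slice_task_spec")
}

#' Generate a planted-structure slice task
#'
#' @param spec a [slice_task_spec()].
#' @return a `slice_dataset` whose manifest `tag` column is one of
#'   `normal`, `outlier`, `duplicate`. Outlier and duplicate counts are
#'   round-half-up of their fraction times `n`.
#' @export
make_slice_task <- function(spec) {
  stopifnot(inherits(spec, "slice_task_spec"))
  n <- spec$n
  side <- spec$image_side
  d <- side * side * 3L
  n_out <- round_half_up(spec$outlier_frac * n)
  n_dup <- round_half_up(spec$duplicate_frac * n)

  # fixed task geometry: the unit-norm discriminative direction u
  geom <- withr::with_seed(derive_seed(spec$seed, 0L), {
    u <- stats::rnorm(d)
    u <- u / sqrt(sum(u^2))
    list(u = u)
  })

  plan <- withr::with_seed(derive_seed(spec$seed, 0L, stream = 1L), {
    true_class <- integer(n)
    true_class[sample.int(n, round_half_up(spec$class_balance * n))] <- 1L
    tag <- rep("normal", n)
    special <- sample.int(n, n_out + n_dup)
    tag[special[seq_len(n_out)]] <- "outlier"
    if (n_dup > 0L) tag[special[n_out + seq_len(n_dup)]] <- "duplicate"
    # splits: planted structure lives in train; val/test get clean normals
    n_train <- round_half_up(spec$split_fractions[["train"]] * n)
    n_val <- round_half_up(spec$split_fractions[["val"]] * n)
    if (n_train < n_out + n_dup) {
      stopf("training split (%d) too small to hold %d planted samples",
            n_train, n_out + n_dup)
    }
    split <- rep(NA_character_, n)
    split[tag != "normal"] <- "train"
    normals <- which(tag == "normal")
    normals <- sample(normals)   # random order for the remaining slots
    n_train_normals <- n_train - n_out - n_dup
    split[normals[seq_len(n_train_normals)]] <- "train"
    split[normals[n_train_normals + seq_len(n_val)]] <- "val"
    split[is.na(split)] <- "test"
    list(true_class = true_class, tag = tag, split = split)
  })

  half <- spec$class_sep / 2
  images <- matrix(NA_real_, n, d)
  label <- integer(n)
  for (i in seq_len(n)) {
    ci <- plan$true_class[i]
    sgn <- if (ci == 1L) 1 else -1
    x <- withr::with_seed(derive_seed(spec$seed, i, stream = 2L), {
      switch(plan$tag[i],
        normal = sgn * half * geom$u + stats::rnorm(d),
        # near-copies of the class prototype itself: maximally typical,
        # redundant samples with no marginal training value
        duplicate = sgn * half * geom$u + stats::rnorm(d, sd = 0.05),
        # weak true-class signal drowned in inflated noise; label flipped
        outlier = sgn * 0.25 * half * geom$u + stats::rnorm(d, sd = 3))
    })
    images[i, ] <- x
    label[i] <- if (plan$tag[i] == "outlier") 1L - ci else ci
  }

  manifest <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    patient_id = sprintf("s%04d", seq_len(n)),
    z_index = 0L,
    label = label,
    split = plan$split,
    tag = plan$tag,
    stringsAsFactors = FALSE)
  slice_dataset(array(images, dim = c(n, side, side, 3L)), manifest)
}

#' Write a phantom cohort in NIfTI + CSV-index layout
#'
#' One `.nii.gz` file per modality plus one segmentation file per patient,
#' discovered through `index.csv` (columns `patient_id`, `grade`, one path
#' column per volume). This is the same layout [read_cohort()] and the
#' command-line `slices` stage consume.
#'
#' @param cohort list of [patient_volume()] objects.
#' @param dir output directory.
#' @return the index file path, invisibly.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    paths <- c(vapply(MODALITY_NAMES, function(mod) {
      f <- sprintf("%s_%s.nii.gz", p$patient_id, mod)
      RNifti::writeNifti(p$modalities[[mod]], file.path(dir, f))
      f
    }, character(1)),
    seg = {
      f <- sprintf("%s_seg.nii.gz", p$patient_id)
      RNifti::writeNifti(p$segmentation, file.path(dir, f))
      f
    })
    data.frame(patient_id = p$patient_id, grade = p$grade,
               t1 = paths[["T1"]], t1c = paths[["T1C"]], t2 = paths[["T2"]],
               flair = paths[["FLAIR"]], seg = paths[["seg"]],
               stringsAsFactors = FALSE)
  })
  index <- do.call(rbind, rows)
  path <- file.path(dir, "index.csv")
  utils::write.csv(index, path, row.names = FALSE)
  invisible(path)
}

#' Read a patient cohort from a NIfTI + CSV-index directory
#'
#' @param dir directory containing `index.csv` and the NIfTI volumes it
#'   references.
#' @return list of [patient_volume()] objects.
#' @export
read_cohort <- function(dir) {
  index_path <- file.path(dir, "index.csv")
  if (!file.exists(index_path)) {
    stopf("cohort index not found: expected '%s'", index_path)
  }
  index <- utils::read.csv(index_path, colClasses = "character")
  read_vol <- function(path) {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  }
  lapply(seq_len(nrow(index)), function(i) {
    row <- index[i, ]
    mods <- list(T1 = read_vol(file.path(dir, row$t1)),
                 T1C = read_vol(file.path(dir, row$t1c)),
                 T2 = read_vol(file.path(dir, row$t2)),
                 FLAIR = read_vol(file.path(dir, row$flair)))
    seg_raw <- read_vol(file.path(dir, row$seg))
    seg <- array(as.integer(round(seg_raw)), dim = dim(seg_raw))
    patient_volume(row$patient_id, mods, seg, row$grade)
  })
}
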