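# Building labeled 2D slice datasets from volumetric patient records:
# tumor-plane detection, per-patient slice sampling, channel selection
# (T1, T1C, T2), min-max normalization, bilinear resizing, grade labeling,
# and stratified patient-level splits.

MODALITY_NAMES <- c("T1", "T1C", "T2", "FLAIR")
TUMOR_LABELS <- c(1L, 2L, 4L)   # necrotic core, edema, enhancing tumor
SLICE_CHANNELS <- c("T1", "T1C", "T2")

#' One patient's co-registered volumes, segmentation and grade
#'
#' @param patient_id identifier string.
#' @param modalities named list with 3D numeric arrays `T1`, `T1C`, `T2`,
#'   `FLAIR`, all of identical `X x Y x Z` shape. FLAIR is carried but
#'   never emitted into slice channels.
#' @param segmentation 3D integer array of the same shape with voxel
#'   labels in `{0, 1, 2, 4}` (background, necrotic/non-enhancing core,
#'   peritumoral edema, enhancing tumor); any non-zero voxel marks tumor.
#' @param grade `"HGG"` or `"LGG"` (case-insensitive).
#' @return an object of class `patient_volume`.
#' @export
patient_volume <- function(patient_id, modalities, segmentation, grade) {
  grade <- toupper(grade)
  if (!grade %in% c("HGG", "LGG")) {
    stopf("grade must be 'HGG' or 'LGG', got '%s'", grade)
  }
  if (!all(MODALITY_NAMES %in% names(modalities))) {
    stopf("modalities must include %s", paste(MODALITY_NAMES, collapse = ", "))
  }
  modalities <- modalities[MODALITY_NAMES]
  shapes <- vapply(modalities, function(a) paste(dim(a), collapse = "x"),
                   character(1))
  if (length(unique(c(shapes, paste(dim(segmentation), collapse = "x")))) != 1L) {
    stopf("all modality volumes and the segmentation must share one shape")
  }
  bad <- setdiff(unique(as.vector(segmentation)), c(0L, TUMOR_LABELS))
  if (length(bad) > 0L) {
    stopf("segmentation contains label(s) outside {0,1,2,4}: %s",
          paste(bad, collapse = ", "))
  }
  structure(list(patient_id = as.character(patient_id),
                 modalities = modalities,
                 segmentation = segmentation, grade = grade),
            class = "patient_volume")
}

#' @export
print.patient_volume <- function(x, ...) {
  cat(sprintf("<patient_volume> %s (%s), %s voxels, %d tumor planes\n",
              x$patient_id, x$grade,
              paste(dim(x$segmentation), collapse = "x"),
              length(find_tumor_slices(x$segmentation))))
  invisible(x)
}

#' Axial planes containing tumor tissue
#'
#' Scans the third array axis (the axial direction) and returns the
#' 0-based indices of every plane holding at least one voxel labeled 1, 2
#' or 4.
#'
#' @param segmentation 3D integer array with values in `{0, 1, 2, 4}`.
#' @return ascending integer vector of 0-based plane indices (possibly
#'   empty).
#' @export
find_tumor_slices <- function(segmentation) {
  if (length(dim(segmentation)) != 3L) {
    stopf("`segmentation` must be a 3D array")
  }
  bad <- setdiff(unique(as.vector(segmentation)), c(0L, TUMOR_LABELS))
  if (length(bad) > 0L) {
    stopf("segmentation contains label(s) outside {0,1,2,4}: %s",
          paste(bad, collapse = ", "))
  }
  z <- dim(segmentation)[3L]
  flat <- matrix(segmentation != 0, ncol = z)
  which(colSums(flat) > 0) - 1L
}

# Min-max normalize a matrix to [0, 1]; constant planes map to 0.
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2L] - rng[1L] < .Machine$double.eps) {
    return(m * 0)
  }
  (m - rng[1L]) / (rng[2L] - rng[1L])
}

# Bilinear resize of a 2D matrix to size x size (no-op when already there).
resize_bilinear <- function(m, size) {
  if (all(dim(m) == c(size, size))) return(m)
  as.matrix(EBImage::resize(m, w = size, h = size, filter = "bilinear"))
}

#' Extract labeled 2D slices from one patient volume
#'
#' Samples `k` distinct tumor-bearing axial planes uniformly without
#' replacement, then for each plane stacks the T1, T1C and T2 channels,
#' min-max normalizes each channel to \[0, 1\] and resizes it to
#' `target_size x target_size` by bilinear interpolation. Slices inherit
#' the patient's grade as their label (HGG = 1, LGG = 0).
#'
#' @param patient a [patient_volume()].
#' @param k number of slices to extract.
#' @param target_size output side length in pixels (e.g. 224).
#' @param seed integer RNG seed for the plane sample.
#' @param strict if `TRUE` (default), a patient with fewer than `k` tumor
#'   planes is an error; if `FALSE`, all available planes are taken with a
#'   warning.
#' @return a `slice_dataset` of (up to) `k` slices.
#' @export
extract_patient_slices <- function(patient, k = 20L, target_size = 224L,
                                   seed = 1L, strict = TRUE) {
  stopifnot(inherits(patient, "patient_volume"))
  if (!is_scalar_number(k) || k < 1) stopf("`k` must be a positive integer")
  zs <- find_tumor_slices(patient$segmentation)
  if (length(zs) < k) {
    msg <- sprintf("patient %s has only %d tumor planes (< k = %d)",
                   patient$patient_id, length(zs), k)
    if (strict) stopf("%s", msg)
    warning(msg, call. = FALSE)
    chosen <- zs
  } else {
    chosen <- withr::with_seed(seed, sort(sample(zs, k)))
  }
  n <- length(chosen)
  images <- array(NA_real_, dim = c(n, target_size, target_size,
                                    length(SLICE_CHANNELS)))
  for (i in seq_len(n)) {
    z1 <- chosen[i] + 1L   # 0-based plane -> R index
    for (c in seq_along(SLICE_CHANNELS)) {
      plane <- patient$modalities[[SLICE_CHANNELS[c]]][, , z1]
      images[i, , , c] <- resize_bilinear(minmax01(plane), target_size)
    }
  }
  manifest <- data.frame(
    sample_id = sprintf("%s_z%03d", patient$patient_id, chosen),
    patient_id = patient$patient_id,
    z_index = chosen,
    label = if (patient$grade == "HGG") 1L else 0L,
    split = NA_character_, tag = NA_character_,
    stringsAsFactors = FALSE)
  slice_dataset(images, manifest)
}

#' Build a slice dataset from a patient cohort
#'
#' Concatenates [extract_patient_slices()] over the cohort, taking
#' `k_hgg` slices per HGG patient and `k_lgg` per LGG patient. The
#' canonical imbalanced build uses 20/20; the balanced variant uses 10
#' slices per HGG patient and 30 per LGG patient, which equalizes class
#' totals when HGG:LGG patient counts are near 3:1.
#'
#' @param cohort non-empty list of [patient_volume()] objects.
#' @param k_hgg,k_lgg slices per patient by grade.
#' @param target_size output side length in pixels.
#' @param seed integer seed; each patient receives a derived child seed, so
#'   the extraction for patient i does not depend on cohort size.
#' @param strict see [extract_patient_slices()].
#' @return a `slice_dataset`; its manifest doubles as the dataset manifest
#'   (per-split / per-class totals via `table()`).
#' @export
build_slice_dataset <- function(cohort, k_hgg = 20L, k_lgg = 20L,
                                target_size = 224L, seed = 1L,
                                strict = TRUE) {
  if (!is.list(cohort) || length(cohort) == 0L) {
    stopf("`cohort` must be a non-empty list of patient_volume objects")
  }
  parts <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    stopifnot(inherits(p, "patient_volume"))
    k <- if (p$grade == "HGG") k_hgg else k_lgg
    parts[[i]] <- extract_patient_slices(p, k = k, target_size = target_size,
                                         seed = derive_seed(seed, i),
                                         strict = strict)
  }
  bind_datasets(parts)
}

#' Stratified patient-level split
#'
#' Partitions patients into train/validation/test cohorts of the given
#' sizes while keeping each split's HGG:LGG ratio as close as possible to
#' the full cohort's. Per-split class counts are allocated by
#' largest-remainder apportionment of each class across the splits
#' (quotas `size_s * N_class / N`), then patients are assigned at random
#' within class given the seed. Splitting at patient level guards against
#' leakage: no patient's slices can appear in more than one split.
#'
#' @param cohort list of [patient_volume()] objects, or a data frame with
#'   columns `patient_id` and `grade`.
#' @param sizes integer vector of three split sizes (train, val, test)
#'   summing to the cohort size.
#' @param seed integer RNG seed.
#' @return a data frame of class `split_assignment` with columns
#'   `patient_id`, `grade`, `split`.
#' @export
split_patients <- function(cohort, sizes = c(203L, 66L, 66L), seed = 1L) {
  if (is.data.frame(cohort)) {
    info <- data.frame(patient_id = as.character(cohort$patient_id),
                       grade = toupper(cohort$grade),
                       stringsAsFactors = FALSE)
  } else {
    info <- data.frame(
      patient_id = vapply(cohort, function(p) p$patient_id, character(1)),
      grade = vapply(cohort, function(p) p$grade, character(1)),
      stringsAsFactors = FALSE)
  }
  if (length(sizes) != 3L) stopf("`sizes` must give (train, val, test)")
  n <- nrow(info)
  if (sum(sizes) != n) {
    stopf("split sizes sum to %d but the cohort has %d patients",
          sum(sizes), n)
  }
  split_names <- c("train", "val", "test")
  info$split <- NA_character_
  for (grade in unique(info$grade)) {
    ids <- info$patient_id[info$grade == grade]
    quota <- sizes * length(ids) / n
    base <- floor(quota)
    rem <- length(ids) - sum(base)
    if (rem > 0L) {
      extra <- order(-(quota - base), seq_along(quota))[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    shuffled <- withr::with_seed(derive_seed(seed, match(grade, c("HGG", "LGG"))),
                                 sample(ids))
    assign <- rep(split_names, times = base)
    info$split[match(shuffled, info$patient_id)] <- assign
  }
  class(info) <- c("split_assignment", "data.frame")
  info
}

#' Stamp a patient-level split assignment onto a slice dataset
#'
#' @param data a `slice_dataset`.
#' @param assignment a `split_assignment` from [split_patients()].
#' @return the dataset with its manifest `split` column filled.
#' @export
assign_split <- function(data, assignment) {
  man <- dataset_manifest(data)
  idx <- match(man$patient_id, assignment$patient_id)
  if (anyNA(idx)) {
    stopf("patient '%s' has no split assignment",
          man$patient_id[which(is.na(idx))[1L]])
  }
  data$manifest$split <- assignment$split[idx]
  data
}
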