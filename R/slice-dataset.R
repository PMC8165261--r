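# The labeled 2D slice dataset container: an N x S x S x 3 image array
# plus a manifest of provenance (patient, axial index, label, split, tag).

MANIFEST_COLS <- c("sample_id", "patient_id", "z_index", "label", "split", "tag")

#' Construct a labeled slice dataset
#'
#' @param images numeric array `N x S x S x 3` (channels ordered T1, T1C,
#'   T2 for pipeline-built datasets).
#' @param manifest data frame with columns `sample_id`, `patient_id`,
#'   `z_index` (0-based axial plane), `label` (0 = LGG, 1 = HGG), `split`
#'   (`train` / `val` / `test` or `NA`), `tag` (free-form provenance tag,
#'   `NA` for real data).
#' @return an object of class `slice_dataset`.
#' @export
slice_dataset <- function(images, manifest) {
  if (!is.array(images) || length(dim(images)) != 4L) {
    stopf("`images` must be an N x S x S x C array")
  }
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  for (col in setdiff(MANIFEST_COLS, names(manifest))) {
    manifest[[col]] <- NA
  }
  manifest <- manifest[, MANIFEST_COLS]
  manifest$sample_id <- as.character(manifest$sample_id)
  manifest$patient_id <- as.character(manifest$patient_id)
  if (nrow(manifest) != dim(images)[1L]) {
    stopf("manifest has %d rows for %d images", nrow(manifest), dim(images)[1L])
  }
  key <- paste(manifest$patient_id, manifest$z_index)
  if (anyDuplicated(key)) {
    stopf("duplicate (patient_id, z_index) pair: %s", key[duplicated(key)][1L])
  }
  if (anyDuplicated(manifest$sample_id)) {
    stopf("duplicate sample_id: %s",
          manifest$sample_id[duplicated(manifest$sample_id)][1L])
  }
  structure(list(images = images, manifest = manifest),
            class = "slice_dataset")
}

#' Access the manifest of a slice dataset
#' @param data a `slice_dataset`.
#' @return the manifest data frame.
#' @export
dataset_manifest <- function(data) {
  stopifnot(inherits(data, "slice_dataset"))
  data$manifest
}

#' Number of slices in a dataset
#' @param data a `slice_dataset`.
#' @export
n_slices <- function(data) {
  nrow(dataset_manifest(data))
}

#' @export
print.slice_dataset <- function(x, ...) {
  d <- dim(x$images)
  man <- x$manifest
  cat(sprintf("<slice_dataset> %d slices of %dx%dx%d, %d patients\n",
              d[1L], d[2L], d[3L], d[4L], length(unique(man$patient_id))))
  if (!all(is.na(man$label))) {
    tab <- table(man$label)
    cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!all(is.na(man$split))) {
    tab <- table(man$split)
    cat("  splits: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a slice dataset by sample id and/or split
#'
#' @param data a `slice_dataset`.
#' @param ids optional character vector of sample ids to keep (result
#'   follows manifest order, not `ids` order).
#' @param split optional split name(s) to keep.
#' @param strip_labels if `TRUE`, labels in the result are set to `NA`
#'   (an explicitly unlabeled pool).
#' @return a `slice_dataset`.
#' @export
subset_dataset <- function(data, ids = NULL, split = NULL, strip_labels = FALSE) {
  man <- dataset_manifest(data)
  keep <- rep(TRUE, nrow(man))
  if (!is.null(ids)) {
    missing <- setdiff(ids, man$sample_id)
    if (length(missing) > 0L) {
      stopf("unknown sample_id(s): %s%s", paste(utils::head(missing, 3), collapse = ", "),
            if (length(missing) > 3) ", ..." else "")
    }
    keep <- keep & man$sample_id %in% ids
  }
  if (!is.null(split)) keep <- keep & man$split %in% split
  idx <- which(keep)
  if (length(idx) == 0L) stopf("subset is empty")
  man2 <- man[idx, , drop = FALSE]
  rownames(man2) <- NULL
  if (strip_labels) man2$label <- NA_integer_
  slice_dataset(data$images[idx, , , , drop = FALSE], man2)
}

#' Concatenate slice datasets with identical image geometry
#' @param ... `slice_dataset` objects.
#' @return a `slice_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "slice_dataset")) {
    parts <- parts[[1L]]
  }
  stopifnot(length(parts) >= 1L)
  dims <- lapply(parts, function(p) dim(p$images)[-1L])
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stopf("datasets have differing image geometry")
  }
  ns <- vapply(parts, n_slices, integer(1))
  total <- sum(ns)
  geo <- dims[[1L]]
  images <- array(NA_real_, dim = c(total, geo))
  at <- 0L
  for (p in parts) {
    n <- n_slices(p)
    if (n > 0L) images[at + seq_len(n), , , ] <- p$images
    at <- at + n
  }
  manifest <- do.call(rbind, lapply(parts, dataset_manifest))
  rownames(manifest) <- NULL
  slice_dataset(images, manifest)
}

#' Write / read a slice dataset as plain-text files
#'
#' The on-disk layout is `<name>_manifest.csv` (the manifest),
#' `<name>_images.tsv` (one row per slice: the flattened pixel vector in
#' the same fixed order used by the classifiers) and `<name>_meta.json`
#' (image geometry). Plain text keeps the containers portable and
#' diff-able; datasets at desk scale are small.
#'
#' @param data a `slice_dataset`.
#' @param dir output directory (created if needed).
#' @param name file-name stem.
#' @return `read_slice_dataset` returns a `slice_dataset`.
#' @export
write_slice_dataset <- function(data, dir, name = "slices") {
  stopifnot(inherits(data, "slice_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(data$images)
  utils::write.csv(dataset_manifest(data),
                   file.path(dir, paste0(name, "_manifest.csv")),
                   row.names = FALSE)
  X <- matrix(data$images, nrow = d[1L])
  utils::write.table(format(X, digits = 9, trim = TRUE, scientific = TRUE),
                     file.path(dir, paste0(name, "_images.tsv")),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n = d[1L], side = d[2L], channels = d[4L]),
                       file.path(dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_slice_dataset
#' @export
read_slice_dataset <- function(dir, name = "slices") {
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  if (!file.exists(meta_path)) {
    stopf("slice dataset not found: expected '%s'", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  manifest <- utils::read.csv(file.path(dir, paste0(name, "_manifest.csv")),
                              colClasses = c(sample_id = "character",
                                             patient_id = "character"))
  X <- as.matrix(utils::read.table(file.path(dir, paste0(name, "_images.tsv")),
                                   sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  images <- array(X, dim = c(meta$n, meta$side, meta$side, meta$channels))
  slice_dataset(images, manifest)
}
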