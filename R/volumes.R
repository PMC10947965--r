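#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

VALID_LOBES <- c("frontal", "parietal", "temporal", "occipital", "other")
VALID_HEMIS <- c("L", "R", "bilateral")

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    abort("`affine` must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    abort("affine upper-left 3x3 block is singular")
  storage.mode(affine) <- "double"
  dimnames(affine) <- NULL
  affine
}

new_volume <- function(data, affine, subclass) {
  if (length(dim(data)) != 3L) abort("volume data must be a 3-D array")
  structure(list(data = data, affine = check_affine(affine)),
            class = c(subclass, "uwmc_volume"))
}

#' Spatial containers: intensity volumes, binary masks, label volumes
#'
#' All per-subject images live on one affine-defined grid: `data` is a 3-D
#' array indexed by 0-based voxel (i, j, k), and `affine` maps voxel indices
#' to world RAS millimetres, `world = affine %*% c(i, j, k, 1)`. Functions
#' that combine volumes verify grid identity (shape and affine within 1e-4)
#' and refuse mismatches rather than resampling: spatial normalisation is an
#' upstream registration step, and silent resampling hides its errors.
#'
#' @param data A 3-D array. For `binary_mask()` values must be logical or
#'   0/1; for `label_volume()` non-negative integers with 0 = unlabeled.
#' @param affine A 4x4 voxel-to-world (RAS mm) matrix with invertible 3x3
#'   block.
#' @param table For `label_volume()`, a data frame with columns `id`,
#'   `name`, `lobe`, `hemisphere`, `in_abeta_set`, `in_tau_set` (see
#'   [read_label_table()]); every nonzero voxel value must appear in it.
#' @return An object of class `uwmc_volume` (subclasses
#'   `uwmc_intensity`, `uwmc_mask`, `uwmc_labels`) holding `data` and
#'   `affine`; label volumes additionally carry `table` as a tibble.
#' @examples
#' aff <- diag(4)
#' m <- binary_mask(array(0, c(2, 2, 2)), aff)
#' sum(m$data)
#' @export
intensity_volume <- function(data, affine) {
  if (!all(is.finite(data))) abort("intensity volume contains non-finite values")
  storage.mode(data) <- "double"
  new_volume(data, affine, "uwmc_intensity")
}

#' @rdname intensity_volume
#' @export
binary_mask <- function(data, affine) {
  if (is.logical(data)) {
    out <- data
  } else {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      abort("mask values must all be 0 or 1; refusing to threshold silently")
    out <- array(as.logical(data), dim = dim(data))
  }
  new_volume(out, affine, "uwmc_mask")
}

#' @rdname intensity_volume
#' @export
label_volume <- function(data, affine, table) {
  if (any(data < 0) || any(data != round(data)))
    abort("label data must be non-negative integers")
  storage.mode(data) <- "integer"
  table <- validate_label_table(table)
  present <- setdiff(unique(as.vector(data)), 0L)
  orphans <- setdiff(present, table$id)
  if (length(orphans))
    abort(paste0("label ids present in image but missing from table: ",
                 paste(sort(orphans), collapse = ", ")))
  vol <- new_volume(data, affine, "uwmc_labels")
  vol$table <- table
  vol
}

validate_label_table <- function(table) {
  table <- as_tibble(table)
  need <- c("id", "name", "lobe", "hemisphere", "in_abeta_set", "in_tau_set")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    abort(paste0("label table missing columns: ", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(table$id)) abort("label table ids must be unique")
  if (any(table$id <= 0)) abort("label ids must be positive")
  if (!all(table$lobe %in% VALID_LOBES))
    abort(paste0("lobe must be one of: ", paste(VALID_LOBES, collapse = ", ")))
  if (!all(table$hemisphere %in% VALID_HEMIS))
    abort(paste0("hemisphere must be one of: ", paste(VALID_HEMIS, collapse = ", ")))
  table$id <- as.integer(table$id)
  table$in_abeta_set <- as.logical(table$in_abeta_set)
  table$in_tau_set <- as.logical(table$in_tau_set)
  table
}

#' @export
print.uwmc_volume <- function(x, ...) {
  kind <- setdiff(class(x), "uwmc_volume")[1]
  cat(sprintf("<%s> %s voxels\n", kind, paste(dim(x$data), collapse = " x ")))
  if (!is.null(x$table)) cat(sprintf("  %d labels\n", nrow(x$table)))
  invisible(x)
}

#' Verify two volumes share one grid
#'
#' @param a,b `uwmc_volume` objects.
#' @param tol Maximum absolute elementwise affine difference tolerated.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
stopifnot_same_grid <- function(a, b, tol = 1e-4) {
  if (!all(dim(a$data) == dim(b$data)))
    abort(sprintf("grid shape mismatch: %s vs %s",
                  paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x")))
  if (max(abs(a$affine - b$affine)) > tol)
    abort("affine mismatch between volumes (tolerance 1e-4); resample upstream")
  invisible(TRUE)
}

voxel_volume_mm3 <- function(affine) abs(det(affine[1:3, 1:3]))

# world (n x 3, mm) -> 0-based nearest voxel indices (n x 3)
world_to_voxel <- function(points, affine, inv = NULL) {
  inv <- inv %||% solve(affine)
  p <- cbind(points, 1) %*% t(inv)
  round(p[, 1:3, drop = FALSE])
}

voxel_to_world <- function(idx, affine) {
  p <- cbind(idx, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}

# values of a 3-D array at 0-based voxel triplets; `outside` for off-grid
lookup_voxels <- function(data, idx, outside = NA) {
  dm <- dim(data)
  ok <- idx[, 1] >= 0 & idx[, 1] < dm[1] &
        idx[, 2] >= 0 & idx[, 2] < dm[2] &
        idx[, 3] >= 0 & idx[, 3] < dm[3]
  out <- rep(outside, nrow(idx))
  if (any(ok)) {
    flat <- idx[ok, 1] + dm[1] * (idx[ok, 2] + dm[2] * idx[ok, 3]) + 1
    out[ok] <- data[flat]
  }
  out
}

#' Read a NIfTI volume as an intensity image, binary mask, or labeled parcellation
#'
#' Thin wrapper over [RNifti::readNifti()] enforcing the package's spatial
#' contract: 0-based voxel indices, world RAS mm via the image xform.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind One of `"intensity"`, `"mask"`, `"label"`.
#' @param label_table For `kind = "label"`: a label-table file path (TSV read
#'   with [read_label_table()]) or a data frame. Required because NIfTI
#'   stores no region names.
#' @return An `uwmc_volume` of the matching subclass.
#' @export
read_volume <- function(path, kind = c("intensity", "mask", "label"), label_table = NULL) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  data <- as.array(img)
  dm <- dim(data)
  if (length(dm) == 4L && dm[4] == 1L) dm <- dm[1:3]
  data <- array(as.vector(data), dim = dm)
  switch(kind,
    intensity = intensity_volume(data, affine),
    mask = binary_mask(data, affine),
    label = {
      if (is.null(label_table)) abort("kind = 'label' requires `label_table`")
      tab <- if (is.character(label_table)) read_label_table(label_table) else label_table
      label_volume(round(data), affine, tab)
    })
}

#' Write a volume to NIfTI
#'
#' @param vol An `uwmc_volume`.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- vol$data
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write a region label table
#'
#' The table is a TSV side-file with columns `id`, `name`, `lobe`
#' (`frontal`/`parietal`/`temporal`/`occipital`/`other`), `hemisphere`
#' (`L`/`R`/`bilateral`), and logical `in_abeta_set`, `in_tau_set` flags
#' marking membership in the amyloid- and tau-vulnerable region sets used for
#' pathology-specific pair extraction.
#'
#' A default table for a Desikan-Killiany cortical parcellation plus CIC
#' striatal regions ships at
#' `system.file("extdata", "dk_cic_label_table_synthetic.tsv", package = "uwmc")`.
#' Its pathology-set flags are a synthetic reconstruction from the
#' field-standard composites (42 bilateral amyloid-PET composite regions;
#' the 6 bilateral meta-temporal regions), not a study-specific list; supply
#' your own table when your region sets differ.
#'
#' @param path TSV file path.
#' @param table For `write_label_table()`, the table to write.
#' @return A validated tibble.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_label_table(tab)
}

#' @rdname read_label_table
#' @export
write_label_table <- function(table, path) {
  utils::write.table(validate_label_table(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
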