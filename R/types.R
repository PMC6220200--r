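#' Construct an image volume
#'
#' The basic unit every stage of the pipeline consumes: a 3D grid of scalar
#' MR-like intensities (arbitrary units) together with the physical voxel
#' spacing in millimetres. Arrays are indexed `(x, y, z)` with `z` the
#' slice (coronal-section) axis; voxel centers sit at `(i*sx, j*sy, k*sz)`
#' (0-based indices) in physical coordinates.
#'
#' @param data numeric 3D array of intensities; all values must be finite.
#' @param spacing numeric length-3 vector `(sx, sy, sz)` in mm, all positive.
#' @param side hip laterality, one of `"left"`, `"right"`, `"unknown"`.
#'   Drives the realism of left-right flip augmentation.
#' @param subject_id opaque subject identifier.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), side = "unknown",
                         subject_id = "") {
  data <- as_grid3d(data)
  spacing <- check_spacing(spacing)
  if (!all(is.finite(data))) {
    stop("image_volume: data contains non-finite values", call. = FALSE)
  }
  side <- match.arg(side, c("left", "right", "unknown"))
  structure(
    list(data = data, spacing = spacing, side = side,
         subject_id = as.character(subject_id)),
    class = "image_volume"
  )
}

#' Construct a binary label mask
#'
#' Ground truth and predicted segmentations share this type: a 3D grid of
#' exactly 0/1 aligned to an [image_volume()].
#'
#' @param data array coercible to 3D whose values are exactly 0 or 1
#'   (logical arrays are accepted).
#' @inheritParams image_volume
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), subject_id = "") {
  data <- as_grid3d(data)
  if (is.logical(data)) data[] <- as.numeric(data)
  spacing <- check_spacing(spacing)
  if (anyNA(data) || !all(data == 0 | data == 1)) {
    stop("label_mask: values must be exactly 0 or 1", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, subject_id = as.character(subject_id)),
    class = "label_mask"
  )
}

#' Construct a per-voxel foreground probability map
#'
#' The output of every network forward pass: probability that each voxel
#' belongs to the trabecular bone of the proximal femur, in `[0, 1]`.
#'
#' @param data numeric 3D array with values in `[0, 1]`.
#' @inheritParams image_volume
#' @return an object of class `probability_map`.
#' @export
probability_map <- function(data, spacing = c(1, 1, 1), subject_id = "") {
  data <- as_grid3d(data)
  spacing <- check_spacing(spacing)
  if (anyNA(data) || any(data < 0) || any(data > 1)) {
    stop("probability_map: values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, subject_id = as.character(subject_id)),
    class = "probability_map"
  )
}

as_grid3d <- function(data) {
  if (is.null(dim(data))) stop("expected an array, got a vector", call. = FALSE)
  d <- dim(data)
  if (length(d) == 2L) {
    dim(data) <- c(d, 1L)
  } else if (length(d) != 3L) {
    stop("expected a 3D array, got ", length(d), " dimensions", call. = FALSE)
  }
  storage.mode(data) <- if (is.logical(data)) "logical" else "double"
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (mm)", call. = FALSE)
  }
  spacing
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, side %s\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$side))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %s> %s voxels, %d foreground\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              sum(x$data == 1)))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map %s> %s voxels, range [%.3f, %.3f]\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Check two grids for voxelwise alignment
#'
#' @param a,b image_volume / label_mask / probability_map objects.
#' @return invisibly `TRUE`; errors on shape or spacing mismatch.
#' @keywords internal
check_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("grids are not aligned: shapes ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    stop("grids are not aligned: spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}
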