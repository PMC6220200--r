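#' Read a 3D volume from a NIfTI-1 file
#'
#' Minimal NIfTI-1 reader covering the single-file `.nii` / `.nii.gz`
#' layout used throughout this package: 3D scalar images with datatypes
#' uint8, int16, int32, float32 or float64, little- or big-endian, with
#' `scl_slope`/`scl_inter` honoured. Volumes with an axis-aligned affine
#' are reoriented to a canonical axis order (all axes increasing) on read;
#' the file's affine is retained in the `"affine"` attribute for
#' write-back.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param what one of `"image"`, `"mask"`, `"probability"`; selects the
#'   returned class.
#' @param subject_id optional subject identifier; defaults to the file stem.
#' @return an [image_volume()], [label_mask()] or [probability_map()].
#' @export
read_volume <- function(path, what = c("image", "mask", "probability"),
                        subject_id = NULL) {
  what <- match.arg(what)
  if (!file.exists(path)) {
    stop("read_volume: file not found: ", path, call. = FALSE)
  }
  con <- nii_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"
    if (!identical(swap_int32(sizeof_hdr), 348L)) {
      stop("read_volume: not a NIfTI-1 file (bad sizeof_hdr): ", path,
           call. = FALSE)
    }
  }
  readBin(con, "raw", 36L)                                   # unused fields
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                   # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)                                  # descrip etc.
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # qform_code
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "numeric", 6L, size = 4L, endian = endian)    # quaternion
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- rawToChar(readBin(con, "raw", 3L))
  readBin(con, "raw", 1L)
  if (!magic %in% c("n+1", "ni1")) {
    stop("read_volume: not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  }

  nd <- dims[1L]
  shape <- dims[seq(2L, length.out = max(nd, 0L))]
  if (nd < 3L || nd > 3L && any(shape[-(1:3)] != 1L)) {
    stop("read_volume: expected a 3D scalar image, got dim = [",
         paste(shape, collapse = ", "), "]: ", path, call. = FALSE)
  }
  shape <- shape[1:3]
  if (any(shape < 1L)) {
    stop("read_volume: degenerate image dimensions in ", path, call. = FALSE)
  }

  n <- prod(shape)
  # skip the gap between the 348-byte header and vox_offset (extensions)
  gap <- max(0, round(vox_offset) - 348L)
  if (gap > 0) readBin(con, "raw", gap)
  data <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"   = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    "8"   = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    "16"  = readBin(con, "numeric", n, size = 4L, endian = endian),
    "64"  = readBin(con, "numeric", n, size = 8L, endian = endian),
    "256" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "512" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                               endian = endian)),
    stop("read_volume: unsupported NIfTI datatype ", datatype, call. = FALSE))
  if (length(data) < n) {
    stop("read_volume: truncated data section in ", path, call. = FALSE)
  }
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- shape

  spacing <- abs(pixdim[2:4])
  affine <- NULL
  if (sform_code > 0L) {
    affine <- srow
    rot <- srow[, 1:3, drop = FALSE]
    cn <- sqrt(colSums(rot^2))
    if (all(cn > 0)) spacing <- cn
    # canonical reorientation for axis-aligned affines only
    if (all(abs(rot) < 1e-6 | abs(abs(rot) - rep(cn, each = 3)) < 1e-6)) {
      perm <- apply(abs(rot), 2L, which.max)
      if (identical(sort(perm), 1:3)) {
        inv <- order(perm)                 # source axis feeding world axis j
        signs <- rot[cbind(perm, 1:3)][inv]
        if (!identical(inv, 1:3) || any(signs < 0)) {
          data <- aperm(data, inv)
          spacing <- spacing[inv]
          for (ax in which(signs < 0)) {
            idx <- rep(list(quote(expr = )), 3L)
            idx[[ax]] <- dim(data)[ax]:1
            data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
          }
          affine <- NULL                   # stale after reorientation
        }
      }
    }
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)

  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  out <- switch(what,
    image = image_volume(data, spacing, subject_id = subject_id),
    mask = label_mask(round(data), spacing, subject_id = subject_id),
    probability = probability_map(pmin(pmax(data, 0), 1), spacing,
                                  subject_id = subject_id))
  attr(out, "affine") <- affine
  out
}

#' Write a volume, mask or probability map to a NIfTI-1 file
#'
#' Masks are stored as unsigned 8-bit integers, probability maps as 32-bit
#' floats and image volumes as 64-bit floats. Spacing is written to
#' `pixdim` and to a diagonal sform affine (or the affine retained by
#' [read_volume()], if present). Paths ending in `.gz` are gzip-compressed.
#'
#' @param v an [image_volume()], [label_mask()] or [probability_map()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!inherits(v, c("image_volume", "label_mask", "probability_map"))) {
    stop("write_volume: unsupported object of class ",
         paste(class(v), collapse = "/"), call. = FALSE)
  }
  check_spacing(v$spacing)
  if (!all(is.finite(v$data))) {
    stop("write_volume: non-finite voxel values", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("write_volume: directory does not exist: ", dir, call. = FALSE)
  }

  if (inherits(v, "label_mask")) {
    datatype <- 2L; bitpix <- 8L
  } else if (inherits(v, "probability_map")) {
    datatype <- 16L; bitpix <- 32L
  } else {
    datatype <- 64L; bitpix <- 64L
  }

  shape <- dim(v$data)
  affine <- attr(v, "affine")
  if (is.null(affine)) {
    affine <- cbind(diag(v$spacing), c(0, 0, 0))
  }

  con <- nii_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                              # sizeof_hdr
  w_raw(36L)                               # data_type..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))      # dim[8]
  w_raw(14L)                               # intent_p1..intent_code
  w_i16(datatype)
  w_i16(bitpix)
  w_i16(0L)                                # slice_start
  w_f32(c(1, v$spacing, 0, 0, 0, 0))       # pixdim[8] (qfac = 1)
  w_f32(352)                               # vox_offset
  w_f32(1); w_f32(0)                       # scl_slope, scl_inter
  w_raw(132L)                              # slice_end..glmin + descrip/aux
  w_i16(0L)                                # qform_code
  w_i16(1L)                                # sform_code
  w_f32(numeric(6L))                       # quaternion b,c,d + offsets
  w_f32(t(affine))                         # srow_x/y/z
  w_raw(16L)                               # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)
  w_raw(4L)                                # pad to vox_offset = 352

  if (datatype == 2L) {
    writeBin(as.integer(v$data), con, size = 1L)
  } else if (datatype == 16L) {
    writeBin(as.numeric(v$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(v$data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

nii_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}
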