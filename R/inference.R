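# apply a model (or test stub) to one network input array
model_apply <- function(model, x) {
  if (!is.null(model$forward_fun)) return(model$forward_fun(x))
  softmax2(net_forward(model, x))
}

#' Mirror-pad the in-plane axes of an image
#'
#' Reflection padding (the edge voxel is not duplicated) by `margin`
#' voxels on each side of the first two axes, extrapolating the missing
#' content outside the field of view for unpadded-network inference.
#'
#' @param x a matrix, a `(nx, ny, C)` array, or an [image_volume()] (its
#'   data is padded in-plane).
#' @param margin voxels per side; must be smaller than each in-plane
#'   extent.
#' @return padded object of the same kind.
#' @export
mirror_pad <- function(x, margin) {
  if (inherits(x, "image_volume")) {
    x$data <- mirror_pad(x$data, margin)
    return(x)
  }
  margin <- as.integer(rep(margin, length.out = 2L))
  if (all(margin == 0L)) return(x)
  d <- dim(x)
  if (any(margin < 0L) || margin[1L] >= d[1L] || margin[2L] >= d[2L]) {
    stop("mirror_pad: margin must be in [0, extent - 1]", call. = FALSE)
  }
  refl <- function(n, m) {
    if (m == 0L) seq_len(n)
    else c((m + 1L):2L, seq_len(n), (n - 1L):(n - m))
  }
  ix <- refl(d[1L], margin[1L])
  iy <- refl(d[2L], margin[2L])
  if (length(d) == 2L) x[ix, iy, drop = FALSE]
  else if (length(d) == 3L) x[ix, iy, , drop = FALSE]
  else stop("mirror_pad: expected 2 or 3 dimensions", call. = FALSE)
}

# smallest admissible unpadded tile size and the constant U shrink, per axis
tile_admissible <- function(spec) {
  for (s in 8:4096) {
    o <- tryCatch(output_shape(spec, rep(s, spec$dims))[1L],
                  error = function(e) NULL)
    if (!is.null(o)) return(list(s_min = s, shrink = s - o,
                                 step = as.integer(2^spec$L)))
  }
  stop("no admissible tile size for this architecture", call. = FALSE)
}

#' Plan a covering grid of tiles for unpadded inference
#'
#' Computes a minimal regular grid of tiles whose output windows exactly
#' cover the in-plane image: per axis the tile count is
#' `ceil(extent / output_extent)` and output offsets are spread evenly
#' with symmetric overlaps. Every input window lies inside the
#' mirror-padded image support. With an output window smaller than half
#' the extent on both axes, this reproduces the 3 x 3 = 9-patch tiling
#' used for full-field-of-view inference.
#'
#' @param image_shape in-plane image shape `(nx, ny)`.
#' @param spec an unpadded [architecture_spec()]; may be `NULL` when
#'   `tile_output_shape` is given directly.
#' @param tile_input_shape optional input window shape; defaults to the
#'   largest admissible shape whose output window does not exceed the
#'   image.
#' @param tile_output_shape optional explicit output window shape
#'   (bypasses the shape algebra; for stubs and tests).
#' @return a `tile_plan`: margins, window shapes, per-axis counts, and a
#'   data.frame of 0-based input/output window offsets.
#' @export
plan_tiles <- function(image_shape, spec = NULL, tile_input_shape = NULL,
                       tile_output_shape = NULL) {
  n <- as.integer(image_shape[1:2])
  if (is.null(tile_output_shape)) {
    if (is.null(spec) || is_padded(spec)) {
      stop("plan_tiles: an unpadded spec (or explicit tile_output_shape) is required",
           call. = FALSE)
    }
    adm <- tile_admissible(spec)
    if (is.null(tile_input_shape)) {
      tile_input_shape <- vapply(n, function(nx) {
        s <- adm$s_min
        if (nx + adm$shrink >= s) {
          s <- s + ((nx + adm$shrink - s) %/% adm$step) * adm$step
        }
        s
      }, integer(1L))
    }
    tile_input_shape <- as.integer(rep(tile_input_shape, length.out = 2L))
    tile_output_shape <- output_shape(spec, tile_input_shape)
  } else {
    tile_output_shape <- as.integer(rep(tile_output_shape, length.out = 2L))
    if (is.null(tile_input_shape)) tile_input_shape <- tile_output_shape
    tile_input_shape <- as.integer(rep(tile_input_shape, length.out = 2L))
  }
  margin <- (tile_input_shape - tile_output_shape) %/% 2L
  if (any((tile_input_shape - tile_output_shape) %% 2L != 0L)) {
    stop("plan_tiles: input/output window difference must be even",
         call. = FALSE)
  }
  o <- pmin(tile_output_shape, n)
  counts <- pmax(1L, as.integer(ceiling(n / tile_output_shape)))
  offs <- lapply(1:2, function(ax) {
    if (counts[ax] == 1L) 0L
    else as.integer(round(seq(0L, n[ax] - o[ax], length.out = counts[ax])))
  })
  grid <- expand.grid(ox = offs[[1L]], oy = offs[[2L]])
  structure(list(image_shape = n, tile_input = tile_input_shape,
                 tile_output = o, margin = margin, counts = counts,
                 offsets = grid),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> image %s, %d tiles (%s), input %s -> output %s, margin %s\n",
              paste(x$image_shape, collapse = "x"), nrow(x$offsets),
              paste(x$counts, collapse = "x"),
              paste(x$tile_input, collapse = "x"),
              paste(x$tile_output, collapse = "x"),
              paste(x$margin, collapse = "/")))
  invisible(x)
}

# per-voxel visit counts implied by a plan (used by coverage checks)
tile_visit_counts <- function(plan) {
  cnt <- matrix(0L, plan$image_shape[1L], plan$image_shape[2L])
  for (r in seq_len(nrow(plan$offsets))) {
    ix <- plan$offsets$ox[r] + seq_len(plan$tile_output[1L])
    iy <- plan$offsets$oy[r] + seq_len(plan$tile_output[2L])
    cnt[ix, iy] <- cnt[ix, iy] + 1L
  }
  cnt
}

#' Tiled inference with mirrored extrapolation and overlap averaging
#'
#' Runs an unpadded 2D model over every three-slice stack of a volume:
#' each stack is mirror-padded, every tile of the plan is evaluated, and
#' per-voxel probabilities are averaged over all output windows covering
#' the voxel (uniform averaging; every voxel is visited at least once).
#'
#' @param model a 2D `femur_cnn` (or a stub with a `forward_fun`).
#' @param v an [image_volume()].
#' @param plan a [plan_tiles()] plan; defaults to the plan for this
#'   image/spec.
#' @return a [probability_map()].
#' @export
predict_tiled <- function(model, v, plan = NULL) {
  stopifnot(inherits(v, "image_volume"))
  g <- dim(v$data)
  if (is.null(plan)) plan <- plan_tiles(g[1:2], model$spec)
  if (!identical(as.integer(plan$image_shape), as.integer(g[1:2]))) {
    stop("predict_tiled: plan does not match the image shape", call. = FALSE)
  }
  arr <- if (identical(model$norm, "zscore")) normalize_intensities(v$data)
         else v$data
  m <- plan$margin
  prob <- array(0, g)
  cnt <- tile_visit_counts(plan)
  if (any(cnt < 1L)) stop("predict_tiled: plan does not cover the image",
                          call. = FALSE)
  for (k in seq_len(g[3L])) {
    ks <- pmin(pmax((k - 1L):(k + 1L), 1L), g[3L])   # replicate edge slices
    stack <- array(arr[, , ks], c(g[1:2], 3L))
    padded <- mirror_pad(stack, m)
    acc <- matrix(0, g[1L], g[2L])
    for (r in seq_len(nrow(plan$offsets))) {
      ox <- plan$offsets$ox[r]; oy <- plan$offsets$oy[r]
      tin <- padded[ox + seq_len(plan$tile_input[1L]),
                    oy + seq_len(plan$tile_input[2L]), , drop = FALSE]
      out <- model_apply(model, tin)
      ix <- ox + seq_len(plan$tile_output[1L])
      iy <- oy + seq_len(plan$tile_output[2L])
      acc[ix, iy] <- acc[ix, iy] + out[seq_along(ix), seq_along(iy)]
    }
    prob[, , k] <- acc / cnt
  }
  probability_map(pmin(pmax(prob, 0), 1), v$spacing,
                  subject_id = v$subject_id)
}

#' Whole-image inference for padded networks
#'
#' A single forward pass per three-slice stack (2D) or per volume (3D);
#' the output has the input's shape, so no mirroring or tiling is
#' needed. Extents that are not multiples of `2^L` are zero-padded to the
#' next multiple and the output is cropped back. For 2D models the
#' missing neighbours of edge slices are filled by replicating the
#' boundary slice.
#'
#' @param model a padded `femur_cnn`.
#' @param v an [image_volume()].
#' @return a [probability_map()].
#' @export
predict_padded <- function(model, v) {
  stopifnot(inherits(v, "image_volume"))
  spec <- model$spec
  if (!is.null(spec) && !is_padded(spec)) {
    stop("predict_padded: model is unpadded; use predict_tiled()",
         call. = FALSE)
  }
  g <- dim(v$data)
  arr <- if (identical(model$norm, "zscore")) normalize_intensities(v$data)
         else v$data
  mult <- 2L^(spec$L %||% 0L)
  dims <- spec$dims %||% 2L                # stubs without a spec: per-slice
  if (dims == 3L) {
    target <- as.integer(ceiling(g / mult) * mult)
    x <- array(0, c(target, 1L))
    x[seq_len(g[1L]), seq_len(g[2L]), seq_len(g[3L]), 1L] <- arr
    p <- model_apply(model, x)
    prob <- p[seq_len(g[1L]), seq_len(g[2L]), seq_len(g[3L])]
    dim(prob) <- g
  } else {
    target <- as.integer(ceiling(g[1:2] / mult) * mult)
    prob <- array(0, g)
    for (k in seq_len(g[3L])) {
      ks <- pmin(pmax((k - 1L):(k + 1L), 1L), g[3L])
      x <- array(0, c(target, 3L))
      x[seq_len(g[1L]), seq_len(g[2L]), ] <- arr[, , ks]
      p <- model_apply(model, x)
      prob[, , k] <- p[seq_len(g[1L]), seq_len(g[2L])]
    }
  }
  probability_map(pmin(pmax(prob, 0), 1), v$spacing,
                  subject_id = v$subject_id)
}

# route a volume through the inference path matching the model's spec
predict_volume <- function(model, v) {
  if (!is.null(model$spec) && !is_padded(model$spec)) {
    predict_tiled(model, v)
  } else {
    predict_padded(model, v)
  }
}

#' Threshold a probability map into a binary mask
#'
#' Voxels with probability strictly greater than `t` become foreground;
#' ties at exactly `t` go to background.
#'
#' @param p a [probability_map()].
#' @param t threshold in `[0, 1]`.
#' @return a [label_mask()].
#' @export
binarize <- function(p, t = 0.5) {
  stopifnot(inherits(p, "probability_map"))
  if (!is.finite(t) || t < 0 || t > 1) {
    stop("binarize: threshold must lie in [0, 1]", call. = FALSE)
  }
  label_mask(p$data > t, p$spacing, subject_id = p$subject_id)
}

#' Keep only the largest connected foreground component
#'
#' Removes clusters smaller than the maximum-volume connected component
#' (the proximal femur forms a single connected volume and covers the
#' most voxels). Ties are broken towards the component whose seed voxel
#' comes first in array scan order (axis 1 fastest). Idempotent; an
#' empty mask is returned unchanged with a warning.
#'
#' @param m a [label_mask()].
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner
#'   adjacency).
#' @return a [label_mask()].
#' @export
largest_component <- function(m, connectivity = 26L) {
  stopifnot(inherits(m, "label_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  if (!any(m$data == 1)) {
    warning("largest_component: empty mask returned unchanged", call. = FALSE)
    return(m)
  }
  keep <- cc_largest(array(as.integer(m$data), dim(m$data)), connectivity)
  label_mask(keep, m$spacing, subject_id = m$subject_id)
}

#' Full prediction path for one subject
#'
#' Produces the probability map (tiled or whole-image per the model's
#' padding), optionally upsamples it bicubically to the original
#' acquisition grid, thresholds it, and applies the
#' largest-connected-component filter. By default post-processing is
#' applied for 2D models only; the 3D network captures the global
#' connectivity of the femur during training and does not require it.
#'
#' @param model a `femur_cnn`.
#' @param v an [image_volume()] on the model's working grid.
#' @param t threshold in `[0, 1]`.
#' @param postprocess `NULL` for the per-dims default, or a logical.
#' @param original_grid optional in-plane shape `(nx, ny)` of the
#'   original grid to evaluate against.
#' @return `list(prob = probability_map, mask = label_mask)`.
#' @export
predict_subject <- function(model, v, t = 0.5, postprocess = NULL,
                            original_grid = NULL) {
  prob <- predict_volume(model, v)
  if (!is.null(original_grid)) {
    prob <- resample_inplane(prob, original_grid)
  }
  if (is.null(postprocess)) {
    postprocess <- !is.null(model$spec) && model$spec$dims == 2L
  }
  mask <- binarize(prob, t)
  if (postprocess && any(mask$data == 1)) {
    mask <- largest_component(mask)
  }
  list(prob = prob, mask = mask)
}
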