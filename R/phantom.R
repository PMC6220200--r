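#' Parameters of the synthetic femur-like phantom
#'
#' The phantom emulates the appearance a proximal-femur segmentation
#' network learns from structural MR: a bright-marrow femur-shaped
#' foreground (spherical head, cylindrical neck meeting a cylindrical
#' shaft segment at the neck-shaft angle) with band-limited trabecular
#' texture, a darkened cortical rim at the bone boundary, a darker
#' soft-tissue background, and i.i.d. Gaussian acquisition noise. Optional
#' corruptions model the two failure modes seen in clinical data: an
#' intra-bone lesion (hypointense focus) and an in-plane fold-over
#' (aliasing) artifact.
#'
#' Geometry is expressed in millimetres. The default desk-scale grid is
#' 96 x 96 x 48 voxels at (0.5, 0.5, 1.5) mm spacing, preserving the
#' strong through-plane anisotropy of the 0.234 x 0.234 x 1.5 mm
#' acquisition while staying CPU-trainable; full-scale grids are
#' supported but not default.
#'
#' @param grid_shape integer triple `(nx, ny, nz)`.
#' @param spacing mm triple.
#' @param head_radius,neck_radius,neck_length,shaft_radius,shaft_length
#'   femoral geometry, mm.
#' @param neck_shaft_angle angle between neck and shaft axes, degrees.
#' @param marrow_intensity,background_intensity mean intensities of
#'   foreground marrow and soft-tissue background (arbitrary MR units).
#' @param trabecular_amplitude standard deviation of the zero-mean
#'   trabecular texture added inside the bone.
#' @param trabecular_scale correlation length of the texture, mm.
#' @param noise_sd standard deviation of global Gaussian noise.
#' @param cortical_rim_mm thickness of the darkened cortical shell, mm.
#' @param lesion optional `list(center =, radius =, intensity_drop =)`;
#'   `center` in mm in the volume frame (voxel `(i,j,k)` center at
#'   `((i-1)sx, (j-1)sy, (k-1)sz)`).
#' @param foldover optional `list(wrap_fraction =, gain =)`,
#'   `wrap_fraction` in (0, 0.5).
#' @return a validated `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(96L, 96L, 48L),
                           spacing = c(0.5, 0.5, 1.5),
                           head_radius = 9, neck_radius = 5,
                           neck_length = 11, shaft_radius = 6.5,
                           shaft_length = 20, neck_shaft_angle = 130,
                           marrow_intensity = 180,
                           background_intensity = 60,
                           trabecular_amplitude = 12,
                           trabecular_scale = 1.5,
                           noise_sd = 8, cortical_rim_mm = 1.0,
                           lesion = NULL, foldover = NULL) {
  grid_shape <- as.integer(grid_shape)
  spacing <- check_spacing(spacing)
  geom <- c(head_radius = head_radius, neck_radius = neck_radius,
            neck_length = neck_length, shaft_radius = shaft_radius,
            shaft_length = shaft_length, neck_shaft_angle = neck_shaft_angle,
            trabecular_scale = trabecular_scale,
            cortical_rim_mm = cortical_rim_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("phantom_params: grid_shape must be three integers >= 8",
         call. = FALSE)
  }
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("phantom_params: all geometric parameters must be positive",
         call. = FALSE)
  }
  if (neck_shaft_angle <= 90 || neck_shaft_angle >= 180) {
    stop("phantom_params: neck_shaft_angle must lie in (90, 180) degrees",
         call. = FALSE)
  }
  if (trabecular_amplitude < 0 || noise_sd < 0) {
    stop("phantom_params: amplitudes must be non-negative", call. = FALSE)
  }
  if (marrow_intensity <= background_intensity) {
    stop("phantom_params: marrow must be brighter than background",
         call. = FALSE)
  }
  if (!is.null(foldover)) {
    wf <- foldover$wrap_fraction
    if (is.null(wf) || wf <= 0 || wf >= 0.5) {
      stop("phantom_params: foldover wrap_fraction must lie in (0, 0.5)",
           call. = FALSE)
    }
  }
  if (!is.null(lesion)) {
    if (is.null(lesion$center) || length(lesion$center) != 3L ||
        is.null(lesion$radius) || lesion$radius <= 0) {
      stop("phantom_params: lesion needs a mm center triple and radius > 0",
           call. = FALSE)
    }
    lesion$intensity_drop <- lesion$intensity_drop %||% 0
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 head_radius = head_radius, neck_radius = neck_radius,
                 neck_length = neck_length, shaft_radius = shaft_radius,
                 shaft_length = shaft_length,
                 neck_shaft_angle = neck_shaft_angle,
                 marrow_intensity = marrow_intensity,
                 background_intensity = background_intensity,
                 trabecular_amplitude = trabecular_amplitude,
                 trabecular_scale = trabecular_scale,
                 noise_sd = noise_sd, cortical_rim_mm = cortical_rim_mm,
                 lesion = lesion, foldover = foldover),
            class = "phantom_params")
}

# landmark points of the femur model in mm, relative to the grid center;
# side = "left" mirrors the lateral (x) direction.
phantom_geometry <- function(params, side = "right") {
  tilt <- (180 - params$neck_shaft_angle) * pi / 180
  sgn <- if (identical(side, "left")) -1 else 1
  u_shaft <- c(0, 1, 0)
  u_neck <- c(sgn * sin(tilt), cos(tilt), 0)
  extent <- (params$grid_shape - 1) * params$spacing
  center <- extent / 2
  y_top <- params$shaft_length + params$neck_length * cos(tilt) +
    params$head_radius
  s0 <- center + c(-sgn * 0.18 * extent[1L], -y_top / 2, 0)
  s1 <- s0 + params$shaft_length * u_shaft
  n1 <- s1 + params$neck_length * u_neck
  list(s0 = s0, s1 = s1, head_center = n1, u_neck = u_neck)
}

# membership test of the head/neck/shaft union at arbitrary mm points,
# with all radii shrunk by `shrink` (used to carve out the cortical rim)
phantom_member <- function(px, py, pz, geom, params, shrink = 0) {
  rs <- params$shaft_radius - shrink
  rn <- params$neck_radius - shrink
  rh <- params$head_radius - shrink
  inside <- rep(FALSE, length(px))
  if (rh > 0) {
    inside <- (px - geom$head_center[1L])^2 + (py - geom$head_center[2L])^2 +
      (pz - geom$head_center[3L])^2 <= rh^2
  }
  inside <- inside |
    cylinder_member(px, py, pz, geom$s0, geom$s1, rs, shrink) |
    cylinder_member(px, py, pz, geom$s1, geom$head_center, rn, shrink)
  inside
}

cylinder_member <- function(px, py, pz, a, b, r, shrink = 0) {
  if (r <= 0) return(rep(FALSE, length(px)))
  ab <- b - a
  len <- sqrt(sum(ab^2))
  u <- ab / len
  dx <- px - a[1L]; dy <- py - a[2L]; dz <- pz - a[3L]
  t <- dx * u[1L] + dy * u[2L] + dz * u[3L]
  perp2 <- (dx - t * u[1L])^2 + (dy - t * u[2L])^2 + (dz - t * u[3L])^2
  t >= shrink & t <= len - shrink & perp2 <= r^2
}

#' Generate one synthetic femur phantom with its ground-truth mask
#'
#' @param params a [phantom_params()].
#' @param seed integer seed; output is bit-identical for equal
#'   `(params, seed)`.
#' @param side hip laterality, `"right"` (default) or `"left"`; mirrors
#'   the geometry laterally.
#' @return `list(image = image_volume, mask = label_mask)`.
#' @seealso [generate_cohort()], [apply_foldover()], [apply_lesion()]
#' @export
generate_phantom <- function(params, seed = 0L, side = "right") {
  stopifnot(inherits(params, "phantom_params"))
  g <- params$grid_shape
  sp <- params$spacing
  geom <- phantom_geometry(params, side)

  px <- rep((seq_len(g[1L]) - 1) * sp[1L], times = g[2L] * g[3L])
  py <- rep(rep((seq_len(g[2L]) - 1) * sp[2L], each = g[1L]), times = g[3L])
  pz <- rep((seq_len(g[3L]) - 1) * sp[3L], each = g[1L] * g[2L])

  mask <- phantom_member(px, py, pz, geom, params)
  check_clipping(geom, params)
  dim(mask) <- g

  interior <- phantom_member(px, py, pz, geom, params,
                             shrink = params$cortical_rim_mm)
  dim(interior) <- g
  rim <- mask & !interior

  contrast <- params$marrow_intensity - params$background_intensity
  img <- array(params$background_intensity, g)
  img[mask] <- params$marrow_intensity
  img[rim] <- params$background_intensity + 0.3 * contrast

  with_seed(seed, {
    if (params$trabecular_amplitude > 0) {
      tex <- trabecular_texture(g, params$trabecular_scale / sp)
      img[interior] <- img[interior] +
        params$trabecular_amplitude * tex[interior]
    }
    if (params$noise_sd > 0) {
      img <- img + array(stats::rnorm(prod(g), sd = params$noise_sd), g)
    }
  })

  sid <- sprintf("phantom-%d", seed)
  image <- image_volume(img, sp, side = side, subject_id = sid)
  mask <- label_mask(mask, sp, subject_id = sid)

  if (!is.null(params$lesion)) {
    image <- apply_lesion(image, mask, params$lesion$center,
                          params$lesion$radius,
                          params$lesion$intensity_drop,
                          background = params$background_intensity)
  }
  if (!is.null(params$foldover)) {
    image <- apply_foldover(image, params$foldover$wrap_fraction,
                            params$foldover$gain,
                            seed = derive_seed(seed, "foldover"))
  }
  list(image = image, mask = mask)
}

# error when more than 5% of the geometric foreground falls outside the
# grid: such a phantom is degenerate (its mask is visibly clipped)
check_clipping <- function(geom, params) {
  g <- params$grid_shape
  sp <- params$spacing
  r <- max(params$head_radius, params$neck_radius, params$shaft_radius)
  pts <- rbind(geom$s0, geom$s1, geom$head_center)
  lo <- pmin(apply(pts, 2L, min) - r, 0)
  hi <- pmax(apply(pts, 2L, max) + r, (g - 1) * sp)
  xs <- lapply(1:3, function(ax) seq(lo[ax], hi[ax], by = sp[ax]))
  px <- rep(xs[[1L]], times = length(xs[[2L]]) * length(xs[[3L]]))
  py <- rep(rep(xs[[2L]], each = length(xs[[1L]])), times = length(xs[[3L]]))
  pz <- rep(xs[[3L]], each = length(xs[[1L]]) * length(xs[[2L]]))
  inside <- phantom_member(px, py, pz, geom, params)
  total <- sum(inside)
  ext <- (g - 1) * sp
  ingrid <- inside & px >= 0 & px <= ext[1L] & py >= 0 & py <= ext[2L] &
    pz >= 0 & pz <= ext[3L]
  if (total == 0) stop("degenerate phantom: empty foreground", call. = FALSE)
  clipped <- 1 - sum(ingrid) / total
  if (clipped > 0.05) {
    stop(sprintf("degenerate phantom: %.1f%% of the foreground is clipped by the grid",
                 100 * clipped), call. = FALSE)
  }
  invisible(clipped)
}

# band-limited texture: white Gaussian noise smoothed to the requested
# correlation length (voxels, per axis), then re-standardized
trabecular_texture <- function(g, sigma_vox) {
  tex <- array(stats::rnorm(prod(g)), g)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.3) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    tex <- convolve_axis(tex, k, ax)
  }
  (tex - mean(tex)) / stats::sd(tex)
}

# circular separable convolution along one axis of a 3D array
convolve_axis <- function(x, k, ax) {
  g <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  d <- dim(xp)
  m <- matrix(xp, nrow = d[1L])
  half <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = d[1L], ncol = ncol(m))
  for (o in -half:half) {
    idx <- ((seq_len(d[1L]) - 1 + o) %% d[1L]) + 1L
    out <- out + k[o + half + 1L] * m[idx, , drop = FALSE]
  }
  dim(out) <- d
  aperm(out, order(perm))
}

#' Generate a cohort of phantoms with laterality and stratum labels
#'
#' Draws each subject's geometric and intensity parameters uniformly from
#' per-field ranges, assigns left/right laterality with probability 0.5
#' each, and attaches a binary stratum label (emulating clinical fracture
#' status) with success probability 36/86, for use by stratified
#' cross-validation.
#'
#' @param n number of subjects.
#' @param params_ranges named list of `c(lo, hi)` ranges overriding the
#'   defaults in [cohort_default_ranges()]; fields absent from the list
#'   stay at their [phantom_params()] defaults.
#' @param seed integer seed.
#' @param base_params [phantom_params()] supplying all non-ranged fields.
#' @param stratum_prob probability of a stratum-positive subject.
#' @return list of subjects, each
#'   `list(image, mask, side, stratum, params, seed)`.
#' @export
generate_cohort <- function(n, params_ranges = cohort_default_ranges(base_params),
                            seed = 0L, base_params = phantom_params(),
                            stratum_prob = 36 / 86) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("generate_cohort: n must be >= 1", call. = FALSE)
  for (nm in names(params_ranges)) {
    rg <- params_ranges[[nm]]
    if (length(rg) != 2L || anyNA(rg) || rg[2L] < rg[1L]) {
      stop("generate_cohort: invalid range for ", nm, call. = FALSE)
    }
  }
  draws <- with_seed(derive_seed(seed, "cohort"), {
    list(params = lapply(seq_len(n), function(i) {
           vapply(params_ranges, function(rg) stats::runif(1, rg[1L], rg[2L]),
                  numeric(1L))
         }),
         side = ifelse(stats::runif(n) < 0.5, "left", "right"),
         stratum = as.integer(stats::runif(n) < stratum_prob))
  })
  lapply(seq_len(n), function(i) {
    p <- base_params
    for (nm in names(draws$params[[i]])) p[[nm]] <- draws$params[[i]][[nm]]
    class(p) <- "phantom_params"
    sseed <- derive_seed(seed, sprintf("subject-%d", i))
    ph <- generate_phantom(p, seed = sseed, side = draws$side[i])
    sid <- sprintf("subj-%03d", i)
    ph$image$subject_id <- sid
    ph$mask$subject_id <- sid
    list(image = ph$image, mask = ph$mask, side = draws$side[i],
         stratum = draws$stratum[i], params = p, seed = sseed)
  })
}

#' @rdname generate_cohort
#' @param base a [phantom_params()] the ranges are centered on.
#' @export
cohort_default_ranges <- function(base = phantom_params()) {
  rg <- lapply(c("head_radius", "neck_radius", "neck_length",
                 "shaft_radius", "shaft_length"),
               function(nm) base[[nm]] * c(0.9, 1.1))
  names(rg) <- c("head_radius", "neck_radius", "neck_length",
                 "shaft_radius", "shaft_length")
  c(rg, list(neck_shaft_angle = base$neck_shaft_angle + c(-10, 10)))
}

#' Add a fold-over (aliasing) artifact to a volume
#'
#' Models MR wrap-around: the outer `wrap_fraction` of the in-plane field
#' of view on one side (chosen from `seed`) is flipped and added onto the
#' opposite edge, scaled by `gain`. The paired ground-truth mask is by
#' construction unaffected; callers keep the original mask.
#'
#' @param v an [image_volume()].
#' @param wrap_fraction fraction of the lateral field of view that wraps,
#'   in (0, 0.5).
#' @param gain intensity scale of the wrapped content; 0 is the identity.
#' @param seed integer seed (selects the wrapping side).
#' @return the corrupted [image_volume()].
#' @export
apply_foldover <- function(v, wrap_fraction, gain, seed = 0L) {
  stopifnot(inherits(v, "image_volume"))
  if (wrap_fraction <= 0 || wrap_fraction >= 0.5) {
    stop("apply_foldover: wrap_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  nx <- dim(v$data)[1L]
  w <- max(1L, round(wrap_fraction * nx))
  from_left <- with_seed(seed, stats::runif(1) < 0.5)
  out <- v$data
  if (from_left) {
    band <- v$data[w:1, , , drop = FALSE]           # flipped left band
    out[(nx - w + 1L):nx, , ] <- out[(nx - w + 1L):nx, , , drop = FALSE] +
      gain * band
  } else {
    band <- v$data[nx:(nx - w + 1L), , , drop = FALSE]
    out[1:w, , ] <- out[1:w, , , drop = FALSE] + gain * band
  }
  image_volume(out, v$spacing, side = v$side, subject_id = v$subject_id)
}

#' Add a hypointense intra-bone lesion
#'
#' Reduces intensities inside the sphere `(center, radius)` intersected
#' with the mask by `intensity_drop`, floored at the background
#' intensity, emulating cyst-like hypointense foci. The mask is
#' unchanged.
#'
#' @param v an [image_volume()].
#' @param m the paired [label_mask()].
#' @param center mm triple in the volume frame (voxel `(i,j,k)` center at
#'   `((i-1)sx, (j-1)sy, (k-1)sz)`).
#' @param radius lesion radius, mm.
#' @param intensity_drop amount subtracted inside the lesion.
#' @param background floor intensity.
#' @return the corrupted [image_volume()].
#' @export
apply_lesion <- function(v, m, center, radius, intensity_drop,
                         background = min(v$data)) {
  stopifnot(inherits(v, "image_volume"), inherits(m, "label_mask"))
  check_aligned(v, m)
  g <- dim(v$data)
  sp <- v$spacing
  px <- rep((seq_len(g[1L]) - 1) * sp[1L], times = g[2L] * g[3L])
  py <- rep(rep((seq_len(g[2L]) - 1) * sp[2L], each = g[1L]), times = g[3L])
  pz <- rep((seq_len(g[3L]) - 1) * sp[3L], each = g[1L] * g[2L])
  inside <- (px - center[1L])^2 + (py - center[2L])^2 +
    (pz - center[3L])^2 <= radius^2
  dim(inside) <- g
  hit <- inside & m$data == 1
  if (!any(hit)) {
    stop("apply_lesion: lesion sphere does not intersect the mask",
         call. = FALSE)
  }
  out <- v$data
  out[hit] <- pmax(out[hit] - intensity_drop, background)
  image_volume(out, sp, side = v$side, subject_id = v$subject_id)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% 2147483629L)
  expr
}
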