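#' Resample each axial-plane slice of a volume
#'
#' Every in-plane (x, y) slice is resampled independently to `target_xy`
#' with bicubic (Keys cubic convolution, a = -0.5) interpolation; the
#' out-of-plane slice axis is untouched. Spacing is rescaled so the
#' physical field of view is preserved. Label masks are resampled with
#' nearest-neighbour interpolation so they stay binary; probability maps
#' are clipped back into `[0, 1]` after interpolation.
#'
#' This is the contract used to map between acquisition-resolution grids
#' (e.g. 512 x 512) and network working grids (e.g. 256 x 256), in either
#' direction.
#'
#' @param v an [image_volume()], [label_mask()] or [probability_map()].
#' @param target_xy integer pair: target in-plane shape `(nx, ny)`,
#'   each at least 8.
#' @return object of the same class as `v` on the new grid.
#' @export
resample_inplane <- function(v, target_xy) {
  target_xy <- as.integer(target_xy)
  if (length(target_xy) != 2L || anyNA(target_xy) || any(target_xy < 8L)) {
    stop("resample_inplane: target_xy must be two integers >= 8",
         call. = FALSE)
  }
  d <- dim(v$data)
  nearest <- inherits(v, "label_mask")
  ax <- interp_matrix(d[1L], target_xy[1L], nearest)
  ay <- interp_matrix(d[2L], target_xy[2L], nearest)
  out <- array(0, c(target_xy, d[3L]))
  for (k in seq_len(d[3L])) {
    out[, , k] <- ax %*% v$data[, , k] %*% t(ay)
  }
  new_spacing <- c(v$spacing[1:2] * d[1:2] / target_xy, v$spacing[3L])
  if (inherits(v, "label_mask")) {
    label_mask(round(out), new_spacing, subject_id = v$subject_id)
  } else if (inherits(v, "probability_map")) {
    probability_map(pmin(pmax(out, 0), 1), new_spacing,
                    subject_id = v$subject_id)
  } else {
    image_volume(out, new_spacing, side = v$side, subject_id = v$subject_id)
  }
}

# m x n interpolation matrix mapping a length-n axis to length m with the
# pixel-center convention src = (i + 0.5) * n/m - 0.5 (0-based), replicated
# edges. Keys' cubic convolution kernel sums to one at every phase, so
# constants are preserved exactly and m == n yields the identity.
interp_matrix <- function(n, m, nearest = FALSE) {
  a <- matrix(0, m, n)
  src <- (seq_len(m) - 0.5) * n / m - 0.5       # 0-based source coordinate
  if (nearest) {
    j <- pmin(pmax(round(src), 0), n - 1)
    a[cbind(seq_len(m), j + 1)] <- 1
    return(a)
  }
  base <- floor(src)
  for (o in -1:2) {
    j <- base + o
    w <- keys_kernel(src - j)
    j <- pmin(pmax(j, 0), n - 1)                # clamp: edge replication
    idx <- cbind(seq_len(m), j + 1)
    a[idx] <- a[idx] + w
  }
  a
}

keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  near <- t <= 1
  w[near] <- (a + 2) * t[near]^3 - (a + 3) * t[near]^2 + 1
  far <- t > 1 & t < 2
  w[far] <- a * t[far]^3 - 5 * a * t[far]^2 + 8 * a * t[far] - 4 * a
  w
}
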