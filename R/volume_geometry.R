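#' Volumetric analysis grid
#'
#' A `volume_grid` couples the array geometry every map in an analysis shares:
#' array shape, voxel spacing in mm, a 4x4 voxel-to-world affine, and the
#' binary analysis mask (for gray-matter morphometry, the GM mask). All maps
#' in one analysis live on exactly one grid.
#'
#' @param shape Integer vector of length 3, array dimensions in voxels.
#' @param voxel_size Numeric vector of length 3, voxel spacing in mm
#'   (default 1.5 mm isotropic, the spacing at which a 5-mm searchlight
#'   holds exactly 171 voxels).
#' @param affine 4x4 voxel-to-world matrix (mm). Default: diagonal of
#'   `voxel_size` with zero origin, i.e. world = (index - 1) * spacing for
#'   1-based indices.
#' @param mask Logical array of dimension `shape`; default all `TRUE`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(1.5, 1.5, 1.5), affine = NULL,
                        mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    stop_invalid("`shape` must be 3 positive integers")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop_invalid("`voxel_size` must be 3 strictly positive reals (mm)")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    stop_invalid("`affine` must be a 4x4 matrix")
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), shape)) {
    stop_invalid("mask dimension %s does not match grid shape %s",
                 paste(dim(mask), collapse = "x"),
                 paste(shape, collapse = "x"))
  }
  if (anyNA(mask)) stop_invalid("mask must not contain NA")
  if (!any(mask)) stop_invalid("mask must contain at least one TRUE voxel")
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine, mask = mask),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm spacing, %d in mask\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Convert 1-based voxel indices to world coordinates (mm)
#'
#' @param grid A [volume_grid()].
#' @param index Integer vector of length 3 or a matrix with 3 columns
#'   (1-based voxel indices).
#' @return Numeric vector or matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, index) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  homo <- cbind(idx - 1, 1) # affine maps 0-based indices
  out <- homo %*% t(grid$affine)
  out <- out[, 1:3, drop = !is.matrix(index)]
  out
}

#' Searchlight sphere offsets
#'
#' All integer voxel offsets whose center-to-center Euclidean distance in mm
#' is at most `radius_mm` (inclusive boundary). On a 1.5 mm isotropic grid a
#' 5-mm sphere contains exactly 171 voxels.
#'
#' @param radius_mm Non-negative sphere radius in mm.
#' @param voxel_size Voxel spacing, 3 strictly positive reals (mm).
#' @return An object of class `offset_set`: list with `radius_mm` and
#'   `offsets` (integer matrix, one row per offset, including the origin).
#' @export
sphere_offsets <- function(radius_mm, voxel_size = c(1.5, 1.5, 1.5)) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L ||
      !is.finite(radius_mm) || radius_mm < 0) {
    stop_invalid("`radius_mm` must be a single non-negative number")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop_invalid("`voxel_size` must be 3 strictly positive reals (mm)")
  }
  r <- floor(radius_mm / voxel_size)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
    (g$dz * voxel_size[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  off <- as.matrix(g[keep, , drop = FALSE])
  dimnames(off) <- NULL
  # origin first, then by distance (deterministic feature order)
  ord <- order(d2[keep], off[, 1], off[, 2], off[, 3])
  structure(list(radius_mm = radius_mm, voxel_size = voxel_size,
                 offsets = off[ord, , drop = FALSE]),
            class = "offset_set")
}

#' @export
print.offset_set <- function(x, ...) {
  cat(sprintf("<offset_set> radius %.3g mm, %d offsets\n",
              x$radius_mm, nrow(x$offsets)))
  invisible(x)
}

#' Sphere membership clipped to the grid and mask
#'
#' Voxels of the sphere centered at `center` that lie inside both the grid
#' bounds and the analysis mask. The center itself is always a member.
#'
#' @param center Integer vector of length 3, 1-based voxel index; must lie in
#'   the mask.
#' @param offsets An `offset_set` from [sphere_offsets()].
#' @param grid A [volume_grid()].
#' @return Integer matrix of member voxel indices (1-based), one row each;
#'   the first row is `center`.
#' @export
in_mask_sphere <- function(center, offsets, grid) {
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) ||
      any(center > grid$shape)) {
    stop_invalid("`center` must be a 3-vector inside the grid bounds")
  }
  if (!grid$mask[center[1], center[2], center[3]]) {
    stop_invalid("`center` (%s) is outside the mask",
                 paste(center, collapse = ","))
  }
  pts <- sweep(offsets$offsets, 2, center, "+")
  inb <- pts[, 1] >= 1 & pts[, 2] >= 1 & pts[, 3] >= 1 &
    pts[, 1] <= grid$shape[1] & pts[, 2] <= grid$shape[2] &
    pts[, 3] <= grid$shape[3]
  pts <- pts[inb, , drop = FALSE]
  keep <- grid$mask[pts]
  pts[keep, , drop = FALSE]
}
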