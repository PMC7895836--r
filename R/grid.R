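#' Sampling grid of a common-space volume
#'
#' A grid couples the array dimensions of a volume with its voxel-to-world
#' affine (mm, RAS-like frame, e.g. MNI space). Every volume entering one
#' analysis must live on a single shared grid: field stacks, masks and
#' statistic maps are never resampled by this package.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 voxel-to-world matrix; the upper-left 3x3 block must be
#'   invertible. Voxel indices are 0-based in this convention, so world
#'   coordinates of voxel (i,j,k) are `affine %*% c(i,j,k,1)`.
#' @return An object of class `ef_grid` with elements `shape`, `affine` and
#'   `voxel_volume` (mm^3, the absolute determinant of the 3x3 block).
#' @examples
#' g <- ef_grid(c(24, 28, 24), diag(c(4, 4, 4, 1)))
#' g$voxel_volume  # 64 mm^3
#' @export
ef_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be 3 positive integers")
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  d <- abs(det(affine[1:3, 1:3]))
  if (d <= 0) stop("affine upper-left 3x3 block is singular")
  structure(list(shape = shape, affine = affine, voxel_volume = d),
            class = "ef_grid")
}

#' @export
print.ef_grid <- function(x, ...) {
  cat("<ef_grid> ", paste(x$shape, collapse = " x "),
      " voxels, voxel volume ", format(x$voxel_volume), " mm^3\n", sep = "")
  invisible(x)
}

#' Test two grids for identity
#'
#' Grids are identical when shapes are equal and affines agree within `tol`
#' elementwise; this is the co-registration contract for an analysis.
#'
#' @param a,b `ef_grid` objects.
#' @param tol absolute elementwise tolerance on the affine (mm).
#' @return logical scalar.
#' @export
grids_identical <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(found, expected, what = "volume") {
  if (!grids_identical(found, expected))
    stop(what, " is not on the expected grid (shape/affine mismatch): ",
         "subjects are probably not co-registered to one space", call. = FALSE)
  invisible(TRUE)
}

#' Map 0-based voxel indices to world (mm) coordinates
#'
#' @param grid an `ef_grid`.
#' @param ijk matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  xyz <- cbind(ijk, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world (mm) coordinates to 0-based voxel indices
#'
#' Inverse of [voxel_to_world()]; returns fractional indices (callers round).
#'
#' @param grid an `ef_grid`.
#' @param xyz matrix (n x 3) or vector of world coordinates in mm.
#' @return n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind2mat(xyz)
  ijk <- cbind(xyz, 1) %*% t(solve(grid$affine))
  ijk[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3, byrow = TRUE) else as.matrix(x)
}

# 1-based linear (column-major) index of 0-based voxel triples on a grid
linear_index <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}
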