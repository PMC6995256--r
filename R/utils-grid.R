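#' Build a voxel-to-mm affine for a regular grid
#'
#' Constructs the 4x4 affine mapping 0-based voxel indices to MNI millimetre
#' coordinates for an axis-aligned grid with isotropic voxels. The grid
#' centre voxel maps to `mni_center`.
#'
#' @param grid_shape integer vector of length 3, voxel counts per axis.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param mni_center mm coordinate that the grid centre maps to
#'   (default the MNI origin).
#' @return a 4x4 numeric affine matrix.
#' @export
grid_affine <- function(grid_shape, voxel_size_mm = 3, mni_center = c(0, 0, 0)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size_mm > 0)
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size_mm
  aff[1:3, 4] <- mni_center - voxel_size_mm * (grid_shape - 1) / 2
  aff
}

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param ijk numeric matrix (n x 3) or vector of 0-based voxel indices.
#' @param affine 4x4 voxel-to-mm affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Convert mm coordinates to nearest 0-based voxel indices
#'
#' @param xyz numeric matrix (n x 3) or vector of mm coordinates.
#' @param affine 4x4 voxel-to-mm affine (must be invertible).
#' @return n x 3 matrix of 0-based voxel indices (rounded to nearest voxel).
#' @export
mm_to_voxel <- function(xyz, affine) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  inv <- solve(affine)
  out <- cbind(xyz, 1) %*% t(inv)
  round(out[, 1:3, drop = FALSE])
}

# linear (1-based) index <-> 0-based ijk for a 3D grid
ijk_to_linear <- function(ijk, grid_shape) {
  ijk <- matrix(as.integer(round(ijk)), ncol = 3)
  1L + ijk[, 1] + grid_shape[1] * (ijk[, 2] + grid_shape[2] * ijk[, 3])
}

linear_to_ijk <- function(idx, grid_shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% grid_shape[1]
  j <- (idx0 %/% grid_shape[1]) %% grid_shape[2]
  k <- idx0 %/% (grid_shape[1] * grid_shape[2])
  cbind(i = i, j = j, k = k)
}

# all 0-based voxel indices within radius_mm of an mm point; returns matrix
voxels_in_sphere <- function(center_mm, radius_mm, grid_shape, affine) {
  ctr_vox <- drop(solve(affine) %*% c(center_mm, 1))[1:3]
  vox_mm <- abs(diag(affine)[1:3])
  half <- ceiling(radius_mm / vox_mm)
  lo <- pmax(floor(ctr_vox) - half, 0)
  hi <- pmin(ceiling(ctr_vox) + half, grid_shape - 1)
  if (any(lo > hi)) {
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "k"))))
  }
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- voxel_to_mm(g, affine)
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  g[d2 <= radius_mm^2, , drop = FALSE]
}
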