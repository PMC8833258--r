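#' Sampling grid for 3D volumes
#'
#' Describes the voxel lattice shared by density templates, masks and BOLD
#' series: the number of voxels per axis, the voxel size in millimetres and a
#' 4x4 voxel-to-world affine. The default affine is a pure scaling by the voxel
#' size, which is all the synthetic pipeline needs; resampling honours any
#' invertible affine.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3 (or scalar), mm per axis (> 0).
#' @param affine optional 4x4 voxel-to-world matrix; must be invertible.
#'   Defaults to `diag(c(voxel_size, 1))` (0-based voxel indices).
#' @return an object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(24, 24, 24), 2)
#' g
#' @export
volume_grid <- function(shape, voxel_size = 2, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("`shape` must be three integers >= 1", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.double(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("`affine` must be invertible", call. = FALSE)
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("%s voxels @ %s mm", paste(x$shape, collapse = "x"),
          paste(signif(x$voxel_size, 3), collapse = "x"))
}

n_voxels <- function(grid) prod(grid$shape)

same_grid <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

# 0-based voxel index matrix (n x 3) for every voxel of the grid, column-major.
grid_voxel_coords <- function(grid) {
  s <- grid$shape
  cbind(
    rep.int(seq_len(s[1]) - 1L, times = s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), times = s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
}

# Map 0-based voxel coordinates (n x 3) to world mm via the grid affine.
voxel_to_world <- function(grid, vox) {
  h <- cbind(vox, 1)
  t(grid$affine %*% t(h))[, 1:3, drop = FALSE]
}

world_to_voxel <- function(grid, world) {
  h <- cbind(world, 1)
  t(solve(grid$affine) %*% t(h))[, 1:3, drop = FALSE]
}
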