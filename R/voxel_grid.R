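#' Voxel grid geometry
#'
#' A `voxel_grid` couples an array shape with a 4x4 voxel-to-world affine
#' (RAS+ world coordinates, mm, 0-based voxel indices). The affine is
#' authoritative: spacing is defined as the column norms of its 3x3 block.
#' When only a spacing is given, an axis-aligned grid is built; its default
#' origin centres the grid on the world origin so that the mid-sagittal
#' plane x = 0 bisects it.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, voxel edge lengths in mm.
#'   Ignored (except for a consistency check) when `affine` is supplied.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @param origin optional world coordinate (mm) of voxel (0,0,0); only used
#'   when `affine` is absent. Default centres the grid at the world origin.
#' @return A `voxel_grid` object with fields `shape`, `spacing`, `affine`.
#' @examples
#' g <- voxel_grid(c(64, 64, 64), spacing = c(0.7, 0.7, 0.7))
#' voxel_volume_ul(g)  # 0.343 microlitres
#' @export
voxel_grid <- function(shape, spacing = NULL, affine = NULL, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    if (is.null(spacing)) stop("either `spacing` or `affine` is required")
    spacing <- as.numeric(spacing)
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin
  } else {
    affine <- as.matrix(affine)
    stopifnot(identical(dim(affine), c(4L, 4L)))
    if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
      stop("affine last row must be (0,0,0,1)")
    if (abs(det(affine[1:3, 1:3])) < 1e-12)
      stop("affine 3x3 block is singular")
    sp <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (!is.null(spacing) && max(abs(sp - spacing)) > 1e-6)
      stop("`spacing` inconsistent with affine column norms")
    spacing <- sp
  }
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 6), collapse = " x ")))
  invisible(x)
}

#' Voxel volume in microlitres
#'
#' Product of the voxel spacings; 1 mm^3 = 1 microlitre, so a 0.7 mm
#' isotropic grid has 0.343 ul voxels.
#'
#' @param grid a [voxel_grid()].
#' @return voxel volume in microlitres.
#' @export
voxel_volume_ul <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

#' Convert voxel indices to world coordinates (and back)
#'
#' Indices are 0-based; `ijk` and `xyz` are n x 3 matrices (or length-3
#' vectors). World coordinates are mm, RAS+.
#'
#' @param grid a [voxel_grid()].
#' @param ijk,xyz n x 3 coordinate matrix.
#' @return n x 3 matrix of mapped coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind3(ijk)
  t(tcrossprod(grid$affine[1:3, 1:3], ijk)) +
    matrix(grid$affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  inv <- solve(grid$affine)
  t(tcrossprod(inv[1:3, 1:3], xyz)) +
    matrix(inv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
}

# coerce a length-3 vector or n x 3 matrix to matrix form
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# all voxel centres of a grid as an n x 3 0-based index matrix (column-major)
grid_indices <- function(grid) {
  s <- grid$shape
  cbind(rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
        rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
        rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
}

# world x coordinate of every voxel centre, in array (column-major) order
grid_world_x <- function(grid) {
  s <- grid$shape
  A <- grid$affine
  xi <- A[1, 1] * (seq_len(s[1]) - 1) + A[1, 4]
  xj <- A[1, 2] * (seq_len(s[2]) - 1)
  xk <- A[1, 3] * (seq_len(s[3]) - 1)
  c(outer(outer(xi, xj, "+"), xk, "+"))
}

#' Compare two grids for geometric equality
#'
#' @param a,b [voxel_grid()] objects.
#' @param tol absolute tolerance on affine entries.
#' @return `TRUE` if shapes match and affines agree within `tol`.
#' @export
grid_equal <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

# TRUE if the 3x3 block has orthogonal columns (world metric separable along
# voxel axes) -- the condition under which the distance-transform fast path
# and axis flips are valid
grid_orthogonal <- function(grid, tol = 1e-6) {
  M <- grid$affine[1:3, 1:3]
  G <- crossprod(M)
  max(abs(G - diag(diag(G)))) <= tol
}

stop_geometry <- function(msg) stop(structure(
  class = c("atlasforge_geometry_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))))
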