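#' World-to-world affine transform
#'
#' Homogeneous 4x4 map acting on RAS+ world coordinates (mm). Transforms are
#' stored as forward maps; resampling pulls values back through the inverse.
#'
#' @param matrix 4x4 numeric matrix, last row (0,0,0,1).
#' @return an `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  stopifnot(identical(dim(matrix), c(4L, 4L)))
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row must be (0,0,0,1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("3x3 block is singular")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' Dense displacement field
#'
#' Forward map `x -> x + d(x)` with `d` sampled on a voxel grid;
#' displacements are world-space mm (the externally computed diffeomorphic
#' leg of a reflection warp, e.g. a SyN warp exported as an ITK field).
#'
#' @param vectors (nx, ny, nz, 3) array of mm displacements.
#' @param grid the [voxel_grid()] the vectors live on.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(vectors, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  vectors <- array(as.double(vectors), dim(vectors))
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L ||
      !identical(dim(vectors)[1:3], as.integer(grid$shape)))
    stop_geometry("displacement vectors must be (nx, ny, nz, 3) on the grid")
  if (any(!is.finite(vectors))) stop("displacement field must be finite")
  structure(list(vectors = vectors, grid = grid),
            class = "displacement_field")
}

#' Transform chains
#'
#' An ordered composition of forward transform steps: an optional
#' mid-sagittal reflection (only as the first step), then affines and/or a
#' dense displacement field. `apply_chain()` resamples by pull-back: each
#' output voxel centre is mapped through the chain inverse and the input is
#' sampled there.
#'
#' @param ... steps: `"reflection"` (or `reflection(plane_x)`),
#'   [affine_transform()] and [displacement_field()] objects.
#' @param interpolation `"bspline3"` (default), `"linear"` or `"nearest"`.
#' @return a `transform_chain`.
#' @export
transform_chain <- function(..., interpolation = c("bspline3", "linear",
                                                   "nearest")) {
  interpolation <- match.arg(interpolation)
  steps <- list(...)
  steps <- steps[!vapply(steps, is.null, logical(1))]
  steps <- lapply(steps, function(s) {
    if (identical(s, "reflection")) reflection() else s
  })
  ok <- vapply(steps, function(s)
    inherits(s, c("reflection_step", "affine_transform",
                  "displacement_field")), logical(1))
  if (!all(ok)) stop("chain steps must be reflections, affines or fields")
  refl <- vapply(steps, inherits, logical(1), "reflection_step")
  if (sum(refl) > 1L || (any(refl) && which(refl) != 1L))
    stop("a reflection may appear at most once, and only as the first step")
  structure(list(steps = steps, interpolation = interpolation),
            class = "transform_chain")
}

#' @rdname transform_chain
#' @param plane_x world x coordinate (mm) of the mid-sagittal plane.
#' @export
reflection <- function(plane_x = 0) {
  structure(list(plane_x = plane_x), class = "reflection_step")
}

# map world points through the inverse of one forward step
invert_step_points <- function(step, pts) {
  if (inherits(step, "reflection_step")) {
    pts[, 1] <- 2 * step$plane_x - pts[, 1]
    return(pts)
  }
  if (inherits(step, "affine_transform")) {
    inv <- solve(step$matrix)
    return(t(tcrossprod(inv[1:3, 1:3], pts)) +
             matrix(inv[1:3, 4], nrow(pts), 3, byrow = TRUE))
  }
  invert_field_points(step, pts)
}

# sample a displacement field (trilinear) at world points
sample_field <- function(field, pts) {
  vox <- world_to_voxel(field$grid, pts)
  dims <- as.integer(field$grid$shape)
  nvox <- prod(dims)
  vapply(1:3, function(ax)
    cpp_sample3d(field$vectors[(1 + (ax - 1) * nvox):(ax * nvox)],
                 dims, vox, 1L), numeric(nrow(pts)))
}

# fixed-point inversion of y + d(y) = p: iterate y <- p - d(y)
invert_field_points <- function(field, pts, tol_voxel = 0.01, max_iter = 20L) {
  tol_mm <- tol_voxel * min(field$grid$spacing)
  y <- pts
  for (i in seq_len(max_iter)) {
    d <- sample_field(field, y)
    ynew <- pts - d
    if (max(abs(ynew - y)) < tol_mm) return(ynew)
    y <- ynew
  }
  y
}

#' Reflect a volume about the mid-sagittal plane
#'
#' Maps world point (x, y, z) to (2 * plane_x - x, y, z). Requires the grid
#' to be axis-aligned in world x and symmetric about the plane so that voxel
#' centres map exactly onto voxel centres; the reflection is then an exact
#' array flip (bit-exact involution, binary stays binary).
#'
#' @param vol a [labeled_volume()].
#' @param plane_x world x of the reflection plane (mm, default 0: the
#'   mid-sagittal plane of an AC-PC aligned template).
#' @return the reflected [labeled_volume()] on the same grid.
#' @export
reflect_midsagittal <- function(vol, plane_x = 0) {
  stopifnot(inherits(vol, "labeled_volume"))
  A <- vol$grid$affine
  # world x must depend on exactly one voxel axis
  ax <- which(abs(A[1, 1:3]) > 1e-9)
  if (length(ax) != 1L || any(abs(A[2:3, ax]) > 1e-9))
    stop_geometry("grid is oblique in world x; reflection unsupported")
  n <- vol$grid$shape[ax]
  # index i maps to s - i where x(s - i) = 2*plane_x - x(i)
  s <- (2 * plane_x - 2 * A[1, 4]) / A[1, ax]
  if (abs(s - round(s)) > 1e-6)
    stop_geometry("grid is not symmetric about the reflection plane")
  s <- round(s)
  idx_new <- s - (seq_len(n) - 1L) + 1L  # 1-based source index for each target
  out <- array(0, dim(vol$data))
  keep <- idx_new >= 1L & idx_new <= n
  src <- vol$data
  if (ax == 1L) out[keep, , ] <- src[idx_new[keep], , ]
  else if (ax == 2L) out[, keep, ] <- src[, idx_new[keep], ]
  else out[, , keep] <- src[, , idx_new[keep]]
  vol_like(vol, out)
}

#' Resample a volume through a transform chain
#'
#' Pull-back sampling: for each voxel centre of `out_grid`, the world point
#' is mapped through the inverse of the (forward) chain and the input volume
#' is sampled there with the chain's interpolation. Points falling outside
#' the input field of view evaluate to 0. Third-order B-spline interpolation
#' of probability maps can overshoot \[0, 1\] at sharp edges; the output is
#' clipped and the pre-clip range is recorded in attribute
#' `"preclip_range"`. Binary input is promoted to probability under smooth
#' interpolation (use `"nearest"` to keep it binary).
#'
#' @param vol input [labeled_volume()].
#' @param chain a [transform_chain()].
#' @param out_grid the [voxel_grid()] to sample onto (default: input grid).
#' @return a [labeled_volume()] on `out_grid`.
#' @export
apply_chain <- function(vol, chain, out_grid = vol$grid) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(chain, "transform_chain"))
  interp <- chain$interpolation
  kind <- vol$kind
  if (kind == "binary" && interp != "nearest") kind <- "probability"
  if (kind == "index" && interp != "nearest")
    stop("index volumes require nearest interpolation")
  pts <- voxel_to_world(out_grid, grid_indices(out_grid))
  for (step in rev(chain$steps)) pts <- invert_step_points(step, pts)
  vox <- world_to_voxel(vol$grid, pts)
  dims <- as.integer(vol$grid$shape)
  src <- vol$data
  mode <- switch(interp, nearest = 0L, linear = 1L, bspline3 = 3L)
  if (mode == 3L) src <- cpp_bspline_coeffs(src, dims)
  vals <- cpp_sample3d(src, dims, vox, mode)
  preclip <- range(vals)
  if (kind == "probability") vals <- pmin(pmax(vals, 0), 1)
  out <- labeled_volume(array(vals, out_grid$shape), out_grid, kind)
  attr(out, "preclip_range") <- preclip
  out
}

#' Map a left-hemisphere probability label to the right hemisphere
#'
#' Applies the reflection warp -- mid-sagittal reflection, then an affine,
#' then an optional dense displacement field -- to a left-hemisphere
#' probabilistic label, resampling with third-order B-spline interpolation
#' and clipping to \[0, 1\]. The union (voxel-wise max) of input and output
#' gives the bilateral label. If more than `overlap_warn_frac` of the output
#' probability mass lands back in the source hemisphere, a warning is issued
#' (this usually indicates a bad transform).
#'
#' @param left_prob probability [labeled_volume()] supported in the
#'   left hemisphere (world x < `plane_x`).
#' @param affine optional [affine_transform()] (forward, mm).
#' @param field optional [displacement_field()].
#' @param plane_x mid-sagittal plane (default 0).
#' @param out_grid output grid (default: the input's native grid).
#' @param overlap_warn_frac source-hemisphere mass fraction that triggers a
#'   warning (default 0.05).
#' @return right-hemisphere probability [labeled_volume()].
#' @export
reflection_warp <- function(left_prob, affine = NULL, field = NULL,
                            plane_x = 0, out_grid = left_prob$grid,
                            overlap_warn_frac = 0.05) {
  stopifnot(inherits(left_prob, "labeled_volume"),
            left_prob$kind %in% c("probability", "binary"))
  chain <- transform_chain(reflection(plane_x), affine, field,
                           interpolation = "bspline3")
  out <- apply_chain(left_prob, chain, out_grid)
  total <- sum(out$data)
  if (total > 0) {
    wx <- grid_world_x(out_grid)
    frac <- sum(out$data[wx < plane_x]) / total
    if (frac > overlap_warn_frac)
      warning(sprintf(paste0("%.1f%% of the mapped probability mass lies in ",
                             "the source hemisphere; check the transform"),
                      100 * frac))
  }
  out
}
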