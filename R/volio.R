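#' Read a volume from a NIfTI-1 file
#'
#' The voxel grid is taken from the file's spatial transform (sform
#' preferred, then qform). Values are validated against `expected_kind`:
#' binary files holding a single non-zero label id `k` (as written by
#' ITK-SNAP, one id per region) are normalised from {0, k} to {0, 1};
#' probability maps with interpolation overshoot inside `clip_tol` of
#' \[0, 1\] are clipped with a warning, larger excursions are an error.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param expected_kind the `kind` tag to validate against, see
#'   [labeled_volume()].
#' @param clip_tol tolerance for clipping probability overshoot
#'   (default 1e-6).
#' @return a [labeled_volume()].
#' @export
read_volume <- function(path, expected_kind = c("intensity", "binary",
                                                "probability", "index"),
                        clip_tol = 1e-6) {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    dim(data) <- dim(data)[1:3]
  if (length(dim(data)) != 3L)
    stop("expected a 3-D volume, got dimensions ",
         paste(dim(data), collapse = "x"))
  grid <- grid_from_image(img, dim(data))
  if (expected_kind == "binary") {
    ids <- sort(unique(c(data)))
    ids <- ids[ids != 0]
    if (length(ids) > 1L)
      stop("binary volume holds multiple label ids (",
           paste(ids, collapse = ", "), "); split by id first")
    if (length(ids) == 1L) data <- (data == ids[1]) + 0
  } else if (expected_kind == "probability") {
    r <- range(data)
    if (r[1] < -clip_tol || r[2] > 1 + clip_tol)
      stop(sprintf("probability map outside [0,1] beyond tolerance: [%g, %g]",
                   r[1], r[2]))
    if (r[1] < 0 || r[2] > 1) {
      warning(sprintf("clipped probability overshoot within tolerance ([%g, %g])",
                      r[1], r[2]))
      data <- pmin(pmax(data, 0), 1)
    }
  }
  labeled_volume(data, grid, expected_kind)
}

grid_from_image <- function(img, shape3) {
  m <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  m <- matrix(as.numeric(m), 4, 4)
  voxel_grid(shape3, affine = m)
}

#' Write a volume to a NIfTI-1 file
#'
#' Probability and intensity volumes are stored as 32-bit float; binary as
#' uint8; index maps as uint16. The grid affine is written as the sform
#' (code 2) and the spacings as pixdim.
#'
#' @param vol a [labeled_volume()].
#' @param path output `.nii` or `.nii.gz` path; parent directory must exist.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  dt <- switch(vol$kind, probability = "float", intensity = "float",
               binary = "uint8", index = "uint16")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$grid$spacing
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read / write a world-to-world affine as a 4-line text matrix
#'
#' The format is four whitespace-delimited rows of four numbers
#' (homogeneous mm world-to-world map).
#'
#' @param path text file path.
#' @return [read_affine()] returns an [affine_transform()].
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("affine file must be 4x4")
  affine_transform(m)
}

#' @rdname read_affine
#' @param xf an [affine_transform()] to write.
#' @export
write_affine <- function(xf, path) {
  stopifnot(inherits(xf, "affine_transform"))
  write.table(format(xf$matrix, digits = 17), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a dense displacement field
#'
#' Stored as a 4-D NIfTI with the vector dimension last (nx, ny, nz, 3);
#' displacements are world-space mm.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return [read_displacement_field()] returns a `displacement_field`.
#' @export
read_displacement_field <- function(path) {
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (length(dim(v)) == 5L && dim(v)[4] == 1L) {
    # ITK convention stores vectors in the 5th dimension
    v <- array(v, dim(v)[c(1:3, 5)])
  }
  if (length(dim(v)) != 4L || dim(v)[4] != 3L)
    stop("displacement field must be (nx, ny, nz, 3)")
  grid <- grid_from_image(img, dim(v)[1:3])
  displacement_field(v, grid)
}

#' @rdname read_displacement_field
#' @param field a [displacement_field()] to write.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- field$grid$spacing
  img <- RNifti::`sform<-`(img, structure(field$grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
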