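#' Labelled volumes
#'
#' A `labeled_volume` is a 3-D array bound to a [voxel_grid()] with a `kind`
#' tag describing its value domain:
#' * `"binary"` -- one observer's segmentation of one region, values in {0,1};
#' * `"probability"` -- a probabilistic label, values in \[0,1\];
#' * `"intensity"` -- an image (template, phantom contrast), any finite value;
#' * `"index"` -- an integer region-id map (0 = background).
#'
#' @param data numeric array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @param kind one of `"binary"`, `"probability"`, `"intensity"`, `"index"`.
#' @return a `labeled_volume`.
#' @export
labeled_volume <- function(data, grid, kind = c("intensity", "binary",
                                                "probability", "index")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(data)) || !identical(as.integer(dim(data)),
                                       as.integer(grid$shape)))
    stop_geometry("data shape does not match grid shape")
  # plain double array, no foreign classes or attributes
  data <- array(as.double(data), as.integer(grid$shape))
  validate_kind(data, kind)
  structure(list(data = data, grid = grid, kind = kind),
            class = "labeled_volume")
}

validate_kind <- function(data, kind) {
  if (anyNA(data)) stop("volume contains NA values")
  if (kind == "binary") {
    if (!all(data == 0 | data == 1))
      stop("binary volume must contain only 0 and 1")
  } else if (kind == "probability") {
    r <- range(data)
    if (r[1] < 0 || r[2] > 1)
      stop(sprintf("probability volume outside [0,1]: range [%g, %g]",
                   r[1], r[2]))
  } else if (kind == "index") {
    if (any(data < 0) || any(data != round(data)))
      stop("index volume must contain non-negative integers")
  } else {
    if (any(!is.finite(data))) stop("intensity volume must be finite")
  }
  invisible(TRUE)
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume:%s> %s voxels, spacing %s mm, range [%g, %g]\n",
              x$kind, paste(x$grid$shape, collapse = "x"),
              paste(signif(x$grid$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
as.array.labeled_volume <- function(x, ...) x$data

#' @export
dim.labeled_volume <- function(x) dim(x$data)

# construct a volume of the same kind/grid with new data (skips re-validation
# of geometry; used on hot paths)
vol_like <- function(x, data, kind = x$kind) {
  structure(list(data = data, grid = x$grid, kind = kind),
            class = "labeled_volume")
}

# number of foreground voxels of a binary volume
foreground_count <- function(x) sum(x$data != 0)

check_same_grid <- function(a, b, what = "volumes", tol = 1e-5) {
  if (!grid_equal(a$grid, b$grid, tol))
    stop_geometry(sprintf("%s are not on the same voxel grid", what))
  invisible(TRUE)
}
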