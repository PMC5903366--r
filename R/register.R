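#' Registration configuration
#'
#' Settings for the internal multi-resolution affine registration (the
#' affine leg of a reflection warp). Optimisation is deterministic: it
#' always starts from the identity and uses quasi-Newton descent on the
#' chosen similarity at each pyramid level.
#'
#' @param levels strictly decreasing integer downsampling factors,
#'   default `c(4, 2, 1)`.
#' @param iterations optimiser iteration budget per level (recycled).
#' @param step initial finite-difference scale passed to the optimiser
#'   (`ndeps`), in parameter units.
#' @param similarity `"mean-squares"` (only internal metric) or
#'   `"cross-correlation"` (negated Pearson correlation).
#' @param tol relative convergence tolerance.
#' @return a `registration_config`.
#' @export
registration_config <- function(levels = c(4L, 2L, 1L),
                                iterations = c(200L, 200L, 100L),
                                step = 1e-3,
                                similarity = c("mean-squares",
                                               "cross-correlation"),
                                tol = 1e-9) {
  similarity <- match.arg(similarity)
  levels <- as.integer(levels)
  if (any(diff(levels) >= 0)) stop("levels must be strictly decreasing")
  iterations <- rep_len(as.integer(iterations), length(levels))
  if (any(iterations <= 0L)) stop("iterations must be positive")
  structure(list(levels = levels, iterations = iterations, step = step,
                 similarity = similarity, tol = tol),
            class = "registration_config")
}

# block-mean downsampling by integer factor; the new grid's voxel (0,0,0)
# sits at the world centre of its source block
downsample_volume <- function(vol, f) {
  if (f <= 1L) return(vol)
  s <- vol$grid$shape
  ns <- pmax(s %/% f, 1L)
  crop <- vol$data[seq_len(ns[1] * f), seq_len(ns[2] * f), seq_len(ns[3] * f),
                   drop = FALSE]
  dim(crop) <- c(f, ns[1], f, ns[2], f, ns[3])
  small <- apply(crop, c(2, 4, 6), mean)
  A <- vol$grid$affine
  Anew <- A
  Anew[1:3, 1:3] <- A[1:3, 1:3] * f
  Anew[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  labeled_volume(small, voxel_grid(ns, affine = Anew), "intensity")
}

# 9-DOF parameterisation: t (mm), Euler angles (rad), log-scales, all
# centred on `centre`
params_to_affine <- function(p, centre) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  M <- Rz %*% Ry %*% Rx %*% diag(exp(p[7:9]))
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- p[1:3] + centre - M %*% centre
  affine_transform(A)
}

#' Intensity-driven affine registration
#'
#' Estimates the forward world-to-world affine (9 degrees of freedom:
#' translation, rotation, anisotropic scale about the fixed-image centre)
#' such that `apply_chain(moving, chain(affine), fixed$grid)` matches
#' `fixed`. Multi-resolution descent on the configured similarity,
#' deterministically initialised at the identity; no random numbers are
#' drawn. If the iteration budget is exhausted before convergence the
#' best-so-far transform is returned with attribute `"converged" = FALSE`.
#'
#' @param moving,fixed intensity or probability [labeled_volume()]s with
#'   overlapping fields of view.
#' @param cfg a [registration_config()].
#' @return an [affine_transform()] with attribute `"converged"`.
#' @export
register_affine <- function(moving, fixed, cfg = registration_config()) {
  stopifnot(inherits(moving, "labeled_volume"),
            inherits(fixed, "labeled_volume"))
  if (!moving$kind %in% c("intensity", "probability") ||
      !fixed$kind %in% c("intensity", "probability"))
    stop("registration requires intensity or probability volumes")
  centre <- colMeans(voxel_to_world(fixed$grid,
                                    rbind(c(0, 0, 0), fixed$grid$shape - 1)))
  p <- rep(0, 9)
  converged <- TRUE
  for (lev in seq_along(cfg$levels)) {
    f <- cfg$levels[lev]
    mv <- downsample_volume(vol_like(moving, moving$data, "intensity"), f)
    fx <- downsample_volume(vol_like(fixed, fixed$data, "intensity"), f)
    fpts <- voxel_to_world(fx$grid, grid_indices(fx$grid))
    fvals <- c(fx$data)
    dims <- as.integer(mv$grid$shape)
    inv_grid <- solve(mv$grid$affine)
    metric <- function(par) {
      # guard: reject wild line-search excursions (rotations beyond ~90 deg,
      # scale factors beyond e^1.5) before the matrix degenerates
      if (!all(is.finite(par)) || any(abs(par[4:9]) > 1.5)) return(1e10)
      inv <- solve(params_to_affine(par, centre)$matrix)
      pts <- t(tcrossprod(inv[1:3, 1:3], fpts)) +
        matrix(inv[1:3, 4], nrow(fpts), 3, byrow = TRUE)
      vox <- t(tcrossprod(inv_grid[1:3, 1:3], pts)) +
        matrix(inv_grid[1:3, 4], nrow(pts), 3, byrow = TRUE)
      mvals <- cpp_sample3d(mv$data, dims, vox, 1L)
      if (cfg$similarity == "mean-squares") mean((mvals - fvals)^2)
      else {
        if (sd(mvals) < 1e-12) return(1)
        -stats::cor(mvals, fvals)
      }
    }
    pscale <- c(1, 1, 1, rep(0.05, 6))
    if (lev == 1L) {
      # translation-first pass at the coarsest level decouples the shift
      # from rotation/scale before the full 9-DOF descent
      tfit <- stats::optim(p[1:3], function(t3) metric(c(t3, p[4:9])),
                           method = "BFGS",
                           control = list(maxit = cfg$iterations[1],
                                          reltol = cfg$tol,
                                          ndeps = rep(cfg$step, 3)))
      p[1:3] <- tfit$par
    }
    fit <- stats::optim(p, metric, method = "BFGS",
                        control = list(maxit = cfg$iterations[lev],
                                       reltol = cfg$tol,
                                       parscale = pscale,
                                       ndeps = rep(cfg$step, 9)))
    p <- fit$par
    if (lev == length(cfg$levels)) converged <- fit$convergence == 0L
  }
  out <- params_to_affine(p, centre)
  attr(out, "converged") <- converged
  out
}

#' Registration preset used for the published template build
#'
#' Returns (and optionally copies) the JSON preset recording the SyN
#' diffeomorphic registration parameters used to build the CIT168 group
#' templates, for users driving an external registration backend (ANTs).
#' The diffeomorphic optimiser itself is out of scope for this package;
#' only the affine leg is implemented internally.
#'
#' @return the parsed preset as a list.
#' @export
syn_preset <- function() {
  path <- system.file("extdata", "syn_cit168.json", package = "atlasforge")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::fromJSON(txt)
  else txt
}
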