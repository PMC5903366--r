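#' Phantom study specification
#'
#' Describes a synthetic validation study: ellipsoidal ground-truth regions
#' in the left hemisphere with soft (Gaussian) boundaries, a mirrored right
#' hemisphere with controlled per-region volume asymmetry, and a panel of
#' simulated observers who each delineate every region on every validation
#' template with spatially smooth boundary jitter.
#'
#' All randomness flows from the single master `seed` through a documented
#' splitting scheme (one derived stream per template/observer/region), so a
#' spec generates byte-identical outputs on every run.
#'
#' @param grid the [voxel_grid()]; default 64^3 at 0.7 mm isotropic,
#'   centred on the world origin (the template spacing at desk scale).
#' @param regions data.frame with columns `acronym`, `cx`, `cy`, `cz`
#'   (centre, mm, left hemisphere: cx < 0) and `ax`, `ay`, `az`
#'   (semi-axes, mm); optional `rx`, `ry`, `rz` Euler angles (rad).
#' @param boundary_softness Gaussian edge scale of the ground-truth
#'   probability field, mm. The 0.5 iso-surface is the exact ellipsoid
#'   regardless of softness.
#' @param asymmetry right/left volume ratio r per region (scalar recycled);
#'   ground-truth laterality is 100 (1 - r) / (1 + r).
#' @param n_observers,n_templates panel size; the classic design is 3
#'   observers x 8 templates.
#' @param jitter expected observer boundary displacement, mm.
#' @param seed master integer seed.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid = voxel_grid(c(64L, 64L, 64L),
                                           spacing = c(0.7, 0.7, 0.7)),
                         regions = default_phantom_regions(4L),
                         boundary_softness = 0.7,
                         asymmetry = 1.0,
                         n_observers = 3L,
                         n_templates = 8L,
                         jitter = 0.7,
                         seed = 42L) {
  stopifnot(inherits(grid, "voxel_grid"), is.data.frame(regions),
            all(c("acronym", "cx", "cy", "cz", "ax", "ay", "az") %in%
                  names(regions)),
            all(regions[c("ax", "ay", "az")] > 0),
            boundary_softness >= 0, jitter >= 0,
            n_observers >= 1L, n_templates >= 1L)
  asymmetry <- rep_len(asymmetry, nrow(regions))
  stopifnot(all(asymmetry > 0))
  structure(list(grid = grid, regions = regions,
                 boundary_softness = boundary_softness,
                 asymmetry = asymmetry,
                 n_observers = as.integer(n_observers),
                 n_templates = as.integer(n_templates),
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom region layout
#'
#' Up to 16 axis-aligned ellipsoids named after the subcortical vocabulary,
#' placed on a lattice in the left hemisphere of the default 64^3 / 0.7 mm
#' grid with semi-axes loosely tracking the relative sizes of the real
#' nuclei (largest for Pu/Ca, smallest for HN/VTA). Regions are disjoint at
#' their 0.5 iso-surfaces.
#'
#' @param n number of regions (1..16), taken in vocabulary order.
#' @return data.frame usable as the `regions` field of [phantom_spec()].
#' @export
default_phantom_regions <- function(n = 4L) {
  stopifnot(n >= 1L, n <= 16L)
  vocab <- subcortical_vocabulary()$acronym
  semi <- matrix(c(
    3.2, 3.0, 2.8,   # Pu
    3.1, 2.9, 2.6,   # Ca
    2.0, 1.8, 1.6,   # NAC
    1.6, 1.5, 1.4,   # EXA
    2.4, 2.1, 1.9,   # GPe
    2.1, 1.9, 1.7,   # GPi
    1.5, 1.3, 1.2,   # VeP
    1.8, 1.5, 1.4,   # SNc
    2.0, 1.8, 1.6,   # SNr
    1.6, 1.4, 1.3,   # PBP
    1.8, 1.6, 1.4,   # STH
    1.3, 1.2, 1.1,   # VTA
    2.6, 2.3, 2.0,   # HTH
    2.2, 2.0, 1.8,   # RN
    1.5, 1.4, 1.3,   # MN
    1.2, 1.1, 1.0),  # HN
    ncol = 3, byrow = TRUE)
  slots <- expand.grid(cx = c(-8, -15), cy = c(-13, 0, 13),
                       cz = c(-13, 0, 13))
  data.frame(acronym = vocab[seq_len(n)],
             slots[seq_len(n), ], semi[seq_len(n), , drop = FALSE] |>
               `colnames<-`(c("ax", "ay", "az")),
             row.names = NULL, stringsAsFactors = FALSE)
}

# approximate signed distance (mm, negative inside) to an ellipsoid surface:
# (normalised radius - 1) scaled by the geometric-mean semi-axis
ellipsoid_signed_distance <- function(grid, centre, semi, euler = c(0, 0, 0)) {
  pts <- voxel_to_world(grid, grid_indices(grid))
  pts <- sweep(pts, 2, centre)
  if (any(euler != 0)) {
    R <- euler_rotation(euler)
    pts <- pts %*% R  # world -> ellipsoid frame
  }
  r <- sqrt((pts[, 1] / semi[1])^2 + (pts[, 2] / semi[2])^2 +
              (pts[, 3] / semi[3])^2)
  array((r - 1) * prod(semi)^(1 / 3), grid$shape)
}

euler_rotation <- function(e) {
  cx <- cos(e[1]); sx <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cz <- cos(e[3]); sz <- sin(e[3])
  matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
    matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
    matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
}

# per-region signed-distance fields for one hemisphere
phantom_distance_fields <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  reg <- spec$regions
  euler_cols <- c("rx", "ry", "rz")
  lapply(seq_len(nrow(reg)), function(i) {
    centre <- c(reg$cx[i], reg$cy[i], reg$cz[i])
    semi <- c(reg$ax[i], reg$ay[i], reg$az[i])
    euler <- if (all(euler_cols %in% names(reg)))
      unlist(reg[i, euler_cols]) else c(0, 0, 0)
    if (side == "right") {
      centre[1] <- -centre[1]
      semi <- semi * spec$asymmetry[i]^(1 / 3)
      euler <- -euler
    }
    ellipsoid_signed_distance(spec$grid, centre, semi, euler)
  })
}

signed_distance_to_prob <- function(d, softness) {
  if (softness <= 0) (d < 0) + 0 else pnorm(-d / softness)
}

#' Generate phantom ground truth
#'
#' Builds the left- and right-hemisphere ground-truth probabilistic
#' atlases (ellipsoid signed distance passed through a Gaussian edge of
#' scale `boundary_softness`; the right hemisphere mirrors the left with
#' semi-axes scaled to the requested volume asymmetry) plus an intensity
#' image -- region contrast over a smooth background blob -- for
#' registration tests. Regions overlapping at the 0.5 level are an error.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `left`, `right` ([prob_atlas()]s), and
#'   `intensity` (a [labeled_volume()]). Each probability label carries
#'   attributes `"boundary_softness"` and `"signed_distance"`.
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  acr <- spec$regions$acronym
  sides <- lapply(c(left = "left", right = "right"), function(sd) {
    dfields <- phantom_distance_fields(spec, sd)
    overlap <- Reduce(`+`, lapply(dfields, function(d) (d < 0) + 0))
    if (max(overlap) > 1)
      stop("phantom regions overlap at the 0.5 iso-surface")
    labels <- lapply(seq_along(dfields), function(i) {
      l <- labeled_volume(signed_distance_to_prob(dfields[[i]],
                                                  spec$boundary_softness),
                          spec$grid, "probability")
      attr(l, "boundary_softness") <- spec$boundary_softness
      attr(l, "signed_distance") <- dfields[[i]]
      l
    })
    prob_atlas(setNames(labels, acr))
  })
  pts <- voxel_to_world(spec$grid, grid_indices(spec$grid))
  bg <- 0.3 * exp(-rowSums(pts^2) / (2 * 12^2))
  contrast <- rep_len(c(0.9, 0.6, 0.75, 0.5), nrow(spec$regions))
  img <- array(bg, spec$grid$shape)
  for (i in seq_along(sides$left$labels))
    img <- img + contrast[i] * (sides$left$labels[[i]]$data +
                                  sides$right$labels[[i]]$data)
  list(left = sides$left, right = sides$right,
       intensity = labeled_volume(img, spec$grid, "intensity"))
}

#' Analytic ground-truth volumes and laterality
#'
#' Closed-form ellipsoid volumes 4/3 pi a b c (ul) per region and side,
#' with the analytic laterality 100 (1 - r) / (1 + r) implied by the
#' asymmetry ratio r.
#'
#' @param spec a [phantom_spec()].
#' @return data.frame with columns `region`, `v_left_ul`, `v_right_ul`,
#'   `laterality_pct`.
#' @export
phantom_truth_volumes <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vl <- 4 / 3 * pi * spec$regions$ax * spec$regions$ay * spec$regions$az
  vr <- vl * spec$asymmetry
  data.frame(region = spec$regions$acronym, v_left_ul = vl, v_right_ul = vr,
             laterality_pct = laterality(vl, vr))
}

# smooth unit-variance noise field: white Gaussian noise smoothed with a
# Gaussian kernel of scale sigma_mm, rescaled to empirical SD 1
smooth_noise_field <- function(grid, sigma_mm, seed) {
  dims <- as.integer(grid$shape)
  with_preserved_rng({
    set.seed(as.integer(seed))
    w <- rnorm(prod(dims))
  })
  s <- cpp_gaussian_smooth(w, dims, sigma_mm / grid$spacing)
  array(s / sd(s), dims)
}

# derived stream seed; injective over templates < 10007/101, observers < 101
# and regions < 101
stream_seed <- function(master, template, observer, region) {
  off <- template * 10007 + observer * 101 + region
  as.integer((master + 2654435761 * off) %% 2147483647)
}

#' Simulate one observer's delineation of one region
#'
#' Adds a spatially smooth, zero-mean random perturbation (correlation
#' scale about twice the boundary softness) to the ground-truth signed
#' distance and thresholds at the 0.5 iso-surface. The perturbation
#' amplitude is `jitter * sqrt(pi / 2)`, so the expected absolute boundary
#' displacement is `jitter` mm (the signed distance has unit gradient near
#' the boundary). `jitter = 0` reproduces the thresholded truth exactly.
#'
#' @param truth a ground-truth probability label from
#'   [make_ground_truth()].
#' @param jitter expected boundary displacement, mm.
#' @param seed integer seed for this observer's draw.
#' @param softness boundary softness used to recover the signed distance
#'   (defaults to the label's `"boundary_softness"` attribute); must be
#'   positive for `jitter > 0`.
#' @return a binary [labeled_volume()].
#' @export
simulate_observer <- function(truth, jitter, seed,
                              softness = attr(truth, "boundary_softness")) {
  stopifnot(inherits(truth, "labeled_volume"),
            truth$kind == "probability", jitter >= 0)
  d <- attr(truth, "signed_distance")
  if (is.null(d)) {
    if (is.null(softness) || softness <= 0)
      stop("a positive `softness` is required to invert the probability map")
    d <- -qnorm(truth$data) * softness
  }
  if (jitter == 0)
    return(vol_like(truth, (d < 0) + 0, "binary"))
  if (is.null(softness) || softness <= 0)
    stop("jitter > 0 requires a positive boundary softness")
  eps <- smooth_noise_field(truth$grid, 2 * softness, seed)
  amp <- jitter * sqrt(pi / 2)
  vol_like(truth, (d + amp * eps < 0) + 0, "binary")
}

#' Simulate a full multi-observer validation study
#'
#' For every template and observer, draws an independent smooth boundary
#' perturbation per region (seeded from the master seed via
#' template/observer/region stream splitting) and assigns each voxel to the
#' region with the most negative jittered signed distance, provided it is
#' negative -- one observer paints one integer image, so the per-cell
#' labels are mutually exclusive by construction.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `labels` (an [observer_label_set()]),
#'   `truth_left`, `truth_right` ([prob_atlas()]s), `intensity`, and
#'   `spec`.
#' @export
make_study <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- make_ground_truth(spec)
  acr <- spec$regions$acronym
  dfields <- lapply(truth$left$labels, attr, "signed_distance")
  amp <- spec$jitter * sqrt(pi / 2)
  region_v <- character(0)
  observer_v <- character(0)
  template_v <- character(0)
  label_l <- list()
  for (t in seq_len(spec$n_templates)) {
    for (o in seq_len(spec$n_observers)) {
      jit <- lapply(seq_along(acr), function(r) {
        d <- dfields[[r]]
        if (spec$jitter > 0 && spec$boundary_softness > 0)
          d <- d + amp * smooth_noise_field(spec$grid,
                                            2 * spec$boundary_softness,
                                            stream_seed(spec$seed, t, o, r))
        d
      })
      dmin <- Reduce(pmin, jit)
      winner <- array(0L, spec$grid$shape)
      for (r in seq_along(acr)) {
        hit <- jit[[r]] == dmin & dmin < 0 & winner == 0L
        winner[hit] <- r
      }
      for (r in seq_along(acr)) {
        region_v <- c(region_v, acr[r])
        observer_v <- c(observer_v, sprintf("obs%d", o))
        template_v <- c(template_v, sprintf("tpl%02d", t))
        label_l[[length(label_l) + 1L]] <-
          labeled_volume((winner == r) + 0, spec$grid, "binary")
      }
    }
  }
  entries <- data.frame(region = region_v, observer = observer_v,
                        template = template_v, stringsAsFactors = FALSE)
  entries$label <- label_l
  list(labels = observer_label_set(entries, acr),
       truth_left = truth$left, truth_right = truth$right,
       intensity = truth$intensity, spec = spec)
}

#' Write a phantom study to disk
#'
#' Writes every observer label as NIfTI, the intensity template, a
#' `manifest.tsv` (columns `region`, `observer`, `template`, `path`) and
#' the ground-truth atlases under `truth/`.
#'
#' @param study output of [make_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  e <- study$labels$entries
  paths <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    paths[i] <- file.path(dir, sprintf("%s_%s_%s.nii.gz", e$region[i],
                                       e$observer[i], e$template[i]))
    write_volume(e$label[[i]], paths[i])
  }
  manifest <- data.frame(region = e$region, observer = e$observer,
                         template = e$template, path = paths)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_volume(study$intensity, file.path(dir, "template.nii.gz"))
  for (r in names(study$truth_left$labels)) {
    write_volume(study$truth_left$labels[[r]],
                 file.path(dir, "truth", sprintf("%s_left.nii.gz", r)))
    write_volume(study$truth_right$labels[[r]],
                 file.path(dir, "truth", sprintf("%s_right.nii.gz", r)))
  }
  invisible(dir)
}

#' Load an observer label set from a manifest
#'
#' The manifest is a TSV with columns `region`, `observer`, `template`,
#' `path`; each path is a NIfTI binary label. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest TSV.
#' @param vocabulary region vocabulary (default: the regions present, in
#'   order of first appearance).
#' @return an [observer_label_set()].
#' @export
read_label_manifest <- function(path, vocabulary = NULL) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "observer", "template", "path") %in% names(man)))
  if (is.null(vocabulary)) vocabulary <- unique(man$region)
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(path), man$path))
  man$label <- lapply(paths, read_volume, expected_kind = "binary")
  observer_label_set(man[c("region", "observer", "template", "label")],
                     vocabulary)
}
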