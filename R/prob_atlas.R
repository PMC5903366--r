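#' Multi-observer label sets
#'
#' Container for one validation study: per-(region, observer, template)
#' binary labels on a shared grid, plus the region vocabulary. Within each
#' (observer, template) cell the regions must be mutually exclusive (an
#' observer paints a single integer image, so a voxel carries at most one
#' label); a violation is an error.
#'
#' @param entries data.frame with columns `region`, `observer`, `template`
#'   and a list-column `label` of binary [labeled_volume()]s.
#' @param vocabulary character vector (or data.frame with columns `acronym`,
#'   `name`) of region acronyms, in canonical order.
#' @return an `observer_label_set`.
#' @export
observer_label_set <- function(entries, vocabulary) {
  if (is.data.frame(vocabulary)) vocabulary <- vocabulary$acronym
  vocabulary <- as.character(vocabulary)
  stopifnot(is.data.frame(entries),
            all(c("region", "observer", "template", "label") %in%
                  names(entries)))
  if (anyDuplicated(entries[c("region", "observer", "template")]))
    stop("duplicate (region, observer, template) entries")
  if (!all(entries$region %in% vocabulary))
    stop("entries contain regions absent from the vocabulary")
  labs <- entries$label
  grid <- labs[[1]]$grid
  for (l in labs) {
    stopifnot(inherits(l, "labeled_volume"), l$kind == "binary")
    check_same_grid(l, labs[[1]], "observer labels")
  }
  cells <- split(seq_len(nrow(entries)),
                 paste(entries$observer, entries$template, sep = "\r"))
  for (ix in cells) {
    if (length(ix) < 2L) next
    tot <- Reduce(`+`, lapply(labs[ix], function(l) l$data))
    if (max(tot) > 1)
      stop(sprintf("regions overlap for observer '%s', template '%s'",
                   entries$observer[ix[1]], entries$template[ix[1]]))
  }
  structure(list(entries = entries, vocabulary = vocabulary, grid = grid),
            class = "observer_label_set")
}

#' @export
print.observer_label_set <- function(x, ...) {
  cat(sprintf(paste0("<observer_label_set> %d labels: %d regions x %d ",
                     "observers x %d templates\n"),
              nrow(x$entries), length(unique(x$entries$region)),
              length(unique(x$entries$observer)),
              length(unique(x$entries$template))))
  invisible(x)
}

# fetch one label volume (or NULL)
set_label <- function(set, region, observer, template) {
  i <- which(set$entries$region == region &
               set$entries$observer == observer &
               set$entries$template == template)
  if (length(i) == 0L) NULL else set$entries$label[[i]]
}

#' Probabilistic atlas
#'
#' A named list of per-region probability maps on one grid, with the region
#' vocabulary and the provenance of the contributing (observer, template)
#' delineations. When built from mutually exclusive observer sets, the
#' per-voxel sum over regions cannot exceed 1 (up to float tolerance).
#'
#' @param labels named list (region acronym -> probability
#'   [labeled_volume()]).
#' @param provenance optional data.frame of contributing
#'   (observer, template) pairs.
#' @return a `prob_atlas`.
#' @export
prob_atlas <- function(labels, provenance = NULL) {
  stopifnot(is.list(labels), length(labels) >= 1L, !is.null(names(labels)))
  for (l in labels) {
    stopifnot(inherits(l, "labeled_volume"), l$kind == "probability")
    check_same_grid(l, labels[[1]], "atlas labels")
  }
  structure(list(labels = labels, vocabulary = names(labels),
                 grid = labels[[1]]$grid, provenance = provenance),
            class = "prob_atlas")
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> %d regions (%s) on %s voxels\n",
              length(x$labels), paste(x$vocabulary, collapse = ", "),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Fuse binary labels into a probabilistic label
#'
#' Voxel-wise (weighted) mean of the observers' binary maps: with equal
#' weights the value at a voxel is simply the fraction of contributing
#' delineations that include it, so unanimity gives probability 1.
#'
#' @param labels list of binary [labeled_volume()]s on a common grid.
#' @param weights optional non-negative per-label weights (default equal).
#' @return a probability [labeled_volume()].
#' @export
build_prob_label <- function(labels, weights = NULL) {
  if (length(labels) == 0L) stop("at least one label is required")
  for (l in labels) {
    stopifnot(inherits(l, "labeled_volume"))
    check_same_grid(l, labels[[1]], "labels")
  }
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(length(weights) == length(labels), all(weights >= 0))
  if (sum(weights) == 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  acc <- array(0, labels[[1]]$grid$shape)
  for (i in seq_along(labels)) acc <- acc + w[i] * labels[[i]]$data
  labeled_volume(pmin(pmax(acc, 0), 1), labels[[1]]$grid, "probability")
}

#' Fuse an observer label set into a probabilistic atlas
#'
#' Per region, averages all available (observer, template) binary labels
#' with equal weights (simple averaging; no observer performance
#' weighting).
#'
#' @param set an [observer_label_set()].
#' @return a [prob_atlas()].
#' @export
fuse_atlas <- function(set) {
  stopifnot(inherits(set, "observer_label_set"))
  labels <- lapply(setNames(nm = set$vocabulary), function(r) {
    ix <- which(set$entries$region == r)
    if (length(ix) == 0L) return(NULL)
    build_prob_label(set$entries$label[ix])
  })
  labels <- labels[!vapply(labels, is.null, logical(1))]
  prov <- unique(set$entries[c("observer", "template")])
  prob_atlas(labels, provenance = prov)
}

#' Random half-split for validation templates
#'
#' Splits `1:n_total` into two disjoint halves by seeded sampling without
#' replacement, mirroring a validation design in which a random half of the
#' subjects is averaged into one template and the complement into another.
#' Four distinct seeds yield the classic eight-template design
#' (4 splits x 2 halves).
#'
#' @param n_total even number of subjects.
#' @param seed integer seed; the split is reproducible given the seed, and
#'   the caller's RNG state is left untouched.
#' @return list with integer index vectors `sample` and `complement`.
#' @export
make_validation_split <- function(n_total, seed) {
  if (n_total %% 2 != 0) stop("n_total must be even")
  with_preserved_rng({
    set.seed(as.integer(seed))
    half <- sort(sample.int(n_total, n_total / 2))
  })
  list(sample = half, complement = setdiff(seq_len(n_total), half))
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  expr
}

#' Voxel-wise average of intensity volumes
#'
#' Simple arithmetic mean across subjects on a common grid, as used for
#' seed/validation template construction.
#'
#' @param vols list of intensity [labeled_volume()]s.
#' @return the mean intensity [labeled_volume()].
#' @export
average_volumes <- function(vols) {
  stopifnot(length(vols) >= 1L)
  for (v in vols) {
    stopifnot(inherits(v, "labeled_volume"))
    check_same_grid(v, vols[[1]], "volumes")
  }
  acc <- Reduce(`+`, lapply(vols, function(v) v$data)) / length(vols)
  labeled_volume(acc, vols[[1]]$grid, "intensity")
}

#' Deterministic labels from a probabilistic atlas
#'
#' Assigns each voxel to the region of maximal probability, provided that
#' probability strictly exceeds `threshold` (the conventional P > 0.5 rule:
#' a voxel at exactly 0.5 stays background). Ties between regions are broken
#' by vocabulary order and counted in attribute `"n_ties"`.
#'
#' @param atlas a [prob_atlas()].
#' @param threshold strict lower bound in \[0, 1); default 0.5.
#' @return an index [labeled_volume()]; region ids follow
#'   `atlas$vocabulary` (attribute `"regions"`), 0 = background.
#' @export
prob2det <- function(atlas, threshold = 0.5) {
  stopifnot(inherits(atlas, "prob_atlas"))
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  P <- vapply(atlas$labels, function(l) c(l$data),
              numeric(prod(atlas$grid$shape)))
  pmax_ <- P[, 1]
  amax <- rep.int(1L, nrow(P))
  nt <- 0L
  if (ncol(P) > 1L) for (j in 2:ncol(P)) {
    nt <- nt + sum(P[, j] == pmax_ & pmax_ > threshold)
    hit <- P[, j] > pmax_
    pmax_[hit] <- P[hit, j]
    amax[hit] <- j
  }
  idx <- ifelse(pmax_ > threshold, amax, 0L)
  if (nt > 0L)
    message(nt, " voxel(s) had tied maximal probabilities; ",
            "assigned by vocabulary order")
  out <- labeled_volume(array(as.double(idx), atlas$grid$shape),
                        atlas$grid, "index")
  attr(out, "regions") <- atlas$vocabulary
  attr(out, "n_ties") <- nt
  out
}

#' Per-region binary masks from a deterministic label map
#'
#' @param det index [labeled_volume()] from [prob2det()].
#' @return named list of binary [labeled_volume()]s.
#' @export
det_masks <- function(det) {
  regions <- attr(det, "regions")
  stopifnot(det$kind == "index", !is.null(regions))
  lapply(setNames(seq_along(regions), regions), function(i)
    vol_like(det, (det$data == i) + 0, "binary"))
}

#' Cumulative relative frequency of a probabilistic label
#'
#' CRF(t) = #\{voxels with 0 < p <= t\} / #\{voxels with p > 0\}: the
#' fraction of a label's non-zero voxels at or below each probability
#' threshold. Flat curves that rise only near 1 indicate consistently
#' delineated labels; convex curves with mass at low probabilities indicate
#' uncertain boundaries. The curve is non-decreasing and ends at 1.
#'
#' @param prob probability [labeled_volume()] with at least one non-zero
#'   voxel.
#' @param thresholds ascending threshold values in (0, 1\], or a single
#'   count of evenly spaced bins (default 100).
#' @return a `crf_curve`: data.frame with columns `threshold`, `crf`.
#' @export
crf <- function(prob, thresholds = 100) {
  stopifnot(inherits(prob, "labeled_volume"),
            prob$kind == "probability")
  p <- prob$data[prob$data > 0]
  if (length(p) == 0L) stop("all-zero probability map: CRF undefined")
  if (length(thresholds) == 1L && thresholds >= 2 &&
      thresholds == round(thresholds)) {
    k <- as.integer(thresholds)
    thresholds <- seq_len(k) / k
  }
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE) ||
      thresholds[1] <= 0 || thresholds[length(thresholds)] > 1)
    stop("thresholds must be strictly ascending values in (0, 1]")
  vals <- vapply(thresholds, function(t) mean(p <= t), numeric(1))
  structure(data.frame(threshold = thresholds, crf = vals),
            class = c("crf_curve", "data.frame"), n_nonzero = length(p))
}

#' CRF curves for every region of an atlas
#'
#' @param atlas a [prob_atlas()].
#' @param thresholds passed to [crf()].
#' @return data.frame with columns `region`, `threshold`, `crf`.
#' @export
crf_table <- function(atlas, thresholds = 100) {
  stopifnot(inherits(atlas, "prob_atlas"))
  do.call(rbind, lapply(atlas$vocabulary, function(r) {
    cc <- crf(atlas$labels[[r]], thresholds)
    data.frame(region = r, threshold = cc$threshold, crf = cc$crf)
  }))
}
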