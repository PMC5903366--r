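#' Dice coefficient of two binary labels
#'
#' D = 2|A n B| / (|A| + |B|): the intersection volume over the mean volume
#' of the two labels, in \[0, 1\]. Symmetric. Comparing two empty labels is
#' an error (never silently 0 or 1); one empty label against a non-empty
#' one gives 0.
#'
#' @param a,b binary [labeled_volume()]s on a common grid.
#' @return the Dice coefficient.
#' @export
dice <- function(a, b) {
  check_binary_pair(a, b)
  na <- sum(a$data)
  nb <- sum(b$data)
  if (na + nb == 0)
    stop("Dice is undefined for two empty labels")
  2 * sum(a$data * b$data) / (na + nb)
}

#' Directed (forward) Hausdorff distance in mm
#'
#' For each foreground voxel of `a`, the minimum Euclidean world-space
#' distance (mm, voxel centres) to any foreground voxel of `b`; H is the
#' maximum of these minima. Order-sensitive: H(A,B) = 0 exactly when A is a
#' subset of B, while H(B,A) may be large. Anisotropic grids are handled
#' through the world coordinates.
#'
#' The fast path computes an exact Euclidean distance transform of `b` and
#' reads it at `a`'s voxels; it applies whenever the grid's world metric is
#' separable along voxel axes (orthogonal affine columns). Oblique grids
#' fall back to exact brute force.
#'
#' @param a,b non-empty binary [labeled_volume()]s on a common grid.
#' @return distance in mm.
#' @seealso [directed_hausdorff_brute()] for the all-pairs reference
#'   implementation.
#' @export
directed_hausdorff <- function(a, b) {
  check_binary_pair(a, b)
  if (sum(a$data) == 0 || sum(b$data) == 0)
    stop("directed Hausdorff is undefined for empty labels")
  if (grid_orthogonal(a$grid)) {
    d2 <- cpp_edt_sq(c(b$data != 0), as.integer(a$grid$shape),
                     a$grid$spacing)
    sqrt(max(d2[c(a$data != 0)]))
  } else {
    directed_hausdorff_brute(a, b)
  }
}

#' @describeIn directed_hausdorff Exact all-pairs computation over the two
#'   voxel-centre point sets; quadratic cost, intended as the independent
#'   reference for small labels.
#' @export
directed_hausdorff_brute <- function(a, b) {
  check_binary_pair(a, b)
  if (sum(a$data) == 0 || sum(b$data) == 0)
    stop("directed Hausdorff is undefined for empty labels")
  pa <- voxel_to_world(a$grid, which_fg(a))
  pb <- voxel_to_world(b$grid, which_fg(b))
  cpp_hausdorff_brute(pa, pb)
}

# 0-based foreground voxel indices (n x 3)
which_fg <- function(x) {
  which(x$data != 0, arr.ind = TRUE) - 1L
}

check_binary_pair <- function(a, b) {
  stopifnot(inherits(a, "labeled_volume"), inherits(b, "labeled_volume"),
            a$kind == "binary", b$kind == "binary")
  check_same_grid(a, b, "labels")
}

#' Pairwise rater-reliability comparisons
#'
#' Builds the per-comparison Dice and directed Hausdorff table underlying a
#' rater-reliability report.
#'
#' * `mode = "inter"`: for each region and template, every unordered
#'   observer pair contributes one row (with 3 observers and 8 templates:
#'   24 comparisons per region).
#' * `mode = "intra"`: for each region and observer, every unordered
#'   template pair contributes one row (3 observers, 8 templates, all
#'   pairs: 84 comparisons per region). `template_pairs = "complement"`
#'   restricts to consecutive template pairs (the split/complement halves
#'   of each validation draw).
#'
#' The Hausdorff value reported per unordered pair is the mean of the two
#' directed distances; both raw directions are kept in columns `h_ab` and
#' `h_ba`. Missing (region, observer, template) cells are skipped and
#' counted in attribute `"n_missing"`.
#'
#' @param set an [observer_label_set()].
#' @param mode `"inter"` or `"intra"`.
#' @param template_pairs `"all"` (default) or `"complement"`.
#' @return data.frame with columns `region`, `a`, `b`, `template` /
#'   `observer`, `dice`, `hausdorff_mm`, `h_ab`, `h_ba`.
#' @export
pairwise_report <- function(set, mode = c("inter", "intra"),
                            template_pairs = c("all", "complement")) {
  mode <- match.arg(mode)
  template_pairs <- match.arg(template_pairs)
  stopifnot(inherits(set, "observer_label_set"))
  observers <- sort(unique(set$entries$observer))
  templates <- sort(unique(set$entries$template))
  regions <- intersect(set$vocabulary, unique(set$entries$region))
  if (mode == "inter" && length(observers) < 2L)
    stop("inter-rater comparisons need at least two observers")
  if (mode == "intra" && length(templates) < 2L)
    stop("intra-rater comparisons need at least two templates")
  rows <- list()
  n_missing <- 0L
  compare <- function(region, la, lb, a_id, b_id, ctx_name, ctx_val) {
    if (is.null(la) || is.null(lb)) {
      n_missing <<- n_missing + 1L
      return(NULL)
    }
    hab <- directed_hausdorff(la, lb)
    hba <- directed_hausdorff(lb, la)
    out <- data.frame(region = region, a = a_id, b = b_id,
                      dice = dice(la, lb),
                      hausdorff_mm = (hab + hba) / 2,
                      h_ab = hab, h_ba = hba)
    out[[ctx_name]] <- ctx_val
    out
  }
  if (mode == "inter") {
    pairs <- utils::combn(observers, 2, simplify = FALSE)
    for (r in regions) for (tp in templates) for (pr in pairs)
      rows[[length(rows) + 1L]] <-
        compare(r, set_label(set, r, pr[1], tp), set_label(set, r, pr[2], tp),
                pr[1], pr[2], "template", tp)
  } else {
    tpairs <- if (template_pairs == "all")
      utils::combn(templates, 2, simplify = FALSE)
    else
      lapply(seq_len(length(templates) %/% 2),
             function(i) templates[c(2 * i - 1, 2 * i)])
    for (r in regions) for (ob in observers) for (pr in tpairs)
      rows[[length(rows) + 1L]] <-
        compare(r, set_label(set, r, ob, pr[1]), set_label(set, r, ob, pr[2]),
                pr[1], pr[2], "observer", ob)
  }
  if (n_missing > 0L)
    message(n_missing, " comparison(s) skipped due to missing labels")
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "mode") <- mode
  attr(out, "n_missing") <- n_missing
  out
}

#' Summarise pairwise comparisons per region
#'
#' Mean and sample standard deviation (n - 1 denominator) of the Dice
#' coefficient and the Hausdorff distance, per region, with the number of
#' comparisons. A region with a single comparison gets SD 0 and
#' `sd_degenerate = TRUE`.
#'
#' @param pairs output of [pairwise_report()].
#' @return data.frame with columns `region`, `dice_mean`, `dice_sd`,
#'   `hausdorff_mean_mm`, `hausdorff_sd_mm`, `n`, `sd_degenerate`.
#' @export
summarize_similarity <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
  out <- do.call(rbind, lapply(split(pairs, pairs$region), function(g) {
    n <- nrow(g)
    data.frame(region = g$region[1],
               dice_mean = mean(g$dice),
               dice_sd = if (n > 1L) sd(g$dice) else 0,
               hausdorff_mean_mm = mean(g$hausdorff_mm),
               hausdorff_sd_mm = if (n > 1L) sd(g$hausdorff_mm) else 0,
               n = n,
               sd_degenerate = n == 1L)
  }))
  rownames(out) <- NULL
  attr(out, "mode") <- attr(pairs, "mode")
  out
}
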