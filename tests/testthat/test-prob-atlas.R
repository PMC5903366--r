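test_that("label fusion is the exact voxel-wise labelling fraction", {
  g <- tiny_grid(8)
  set.seed(7)
  labs <- replicate(3, random_bin_vol(g, 0.3), simplify = FALSE)
  p <- build_prob_label(labs)
  counts <- Reduce(`+`, lapply(labs, function(l) l$data))
  expect_identical(p$data, counts / 3)  # exact rational check

  # a voxel labelled by 2 of 3 observers gets 2/3
  expect_true(any(counts == 2))
  expect_equal(unique(p$data[counts == 2]), 2 / 3)

  # unanimity over 24 delineations gives certainty
  labs24 <- replicate(24, bin_vol(g, c(4, 4, 4)), simplify = FALSE)
  expect_equal(build_prob_label(labs24)$data[4, 4, 4], 1.0)

  # empty inputs give an empty map; no inputs is an error
  expect_equal(sum(build_prob_label(list(bin_vol(g, NULL)))$data), 0)
  expect_error(build_prob_label(list()), "at least one")

  # weights
  pw <- build_prob_label(labs[1:2], weights = c(3, 1))
  expect_equal(pw$data, (3 * labs[[1]]$data + labs[[2]]$data) / 4)
  expect_error(build_prob_label(labs[1:2], weights = c(0, 0)), "zero")

  # grid mismatch
  other <- random_bin_vol(tiny_grid(8, 0.5))
  expect_error(build_prob_label(list(labs[[1]], other)), "grid")
})

test_that("observer sets enforce per-cell region exclusivity", {
  g <- tiny_grid(6)
  a <- bin_vol(g, rbind(c(2, 2, 2), c(3, 3, 3)))
  b <- bin_vol(g, c(5, 5, 5))
  entries <- data.frame(region = c("Pu", "Ca"), observer = "obs1",
                        template = "tpl01", stringsAsFactors = FALSE)
  entries$label <- list(a, b)
  set <- observer_label_set(entries, c("Pu", "Ca"))
  expect_s3_class(set, "observer_label_set")

  entries$label <- list(a, bin_vol(g, c(3, 3, 3)))  # overlaps region Pu
  expect_error(observer_label_set(entries, c("Pu", "Ca")), "overlap")
})

test_that("validation splits are disjoint halves, reproducible by seed", {
  sp <- make_validation_split(168, seed = 1)
  expect_length(sp$sample, 84)
  expect_length(sp$complement, 84)
  expect_setequal(c(sp$sample, sp$complement), 1:168)
  expect_length(intersect(sp$sample, sp$complement), 0)
  expect_identical(make_validation_split(168, seed = 1), sp)
  expect_false(identical(make_validation_split(168, seed = 2)$sample,
                         sp$sample))

  # four seeds give the eight-template design: 8 index sets of size n/2
  halves <- unlist(lapply(1:4, function(s) {
    x <- make_validation_split(8, s)
    list(x$sample, x$complement)
  }), recursive = FALSE)
  expect_length(halves, 8L)
  expect_true(all(lengths(halves) == 4L))

  expect_error(make_validation_split(7, 1), "even")

  # caller's RNG stream is not disturbed
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_validation_split(10, 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("template averaging is the voxel-wise mean with CLT noise decay", {
  g <- tiny_grid(12)
  v <- labeled_volume(array(rnorm(prod(g$shape)), g$shape), g, "intensity")
  expect_equal(average_volumes(list(v, v, v))$data, v$data)
  neg <- labeled_volume(-v$data, g, "intensity")
  expect_equal(max(abs(average_volumes(list(v, neg))$data)), 0)

  set.seed(11)
  vols <- replicate(84, labeled_volume(array(rnorm(prod(g$shape), sd = 1),
                                             g$shape), g, "intensity"),
                    simplify = FALSE)
  resid <- sd(average_volumes(vols)$data)
  expect_lt(abs(resid / (1 / sqrt(84)) - 1), 0.15)
})

test_that("deterministic labels follow strict P > threshold argmax rules", {
  g <- tiny_grid(4)
  mk <- function(vals) labeled_volume(array(vals, g$shape), g, "probability")
  a1 <- array(0, g$shape); a1[1, 1, 1] <- 0.6; a1[2, 1, 1] <- 0.5
  a2 <- array(0, g$shape); a2[1, 1, 1] <- 0.3; a2[3, 1, 1] <- 0.8
  atlas <- prob_atlas(list(Pu = mk(a1), Ca = mk(a2)))
  det <- prob2det(atlas)
  expect_equal(det$data[1, 1, 1], 1)  # 0.6 beats 0.3, assigned to Pu
  expect_equal(det$data[2, 1, 1], 0)  # exactly 0.5 stays background
  expect_equal(det$data[3, 1, 1], 2)

  # all probabilities at or below threshold -> empty map
  low <- prob_atlas(list(Pu = mk(array(0.5, g$shape))))
  expect_equal(sum(prob2det(low)$data), 0)

  # ties resolved to the first region in vocabulary order, and counted
  t1 <- array(0, g$shape); t1[2, 2, 2] <- 0.7
  tatlas <- prob_atlas(list(Pu = mk(t1), Ca = mk(t1)))
  expect_message(dtie <- prob2det(tatlas), "tied")
  expect_equal(dtie$data[2, 2, 2], 1)
  expect_equal(attr(dtie, "n_ties"), 1L)

  expect_error(prob2det(atlas, threshold = 1), "threshold")

  # masks derived from the index map are mutually exclusive
  masks <- det_masks(det)
  expect_lte(max(masks$Pu$data + masks$Ca$data), 1)
})

test_that("raising the prob2det threshold never grows a region", {
  g <- tiny_grid(8)
  set.seed(13)
  mk <- function() labeled_volume(array(runif(prod(g$shape)), g$shape) *
                                    array(runif(prod(g$shape)) < 0.5,
                                          g$shape), g, "probability")
  atlas <- prob_atlas(list(A = mk(), B = mk(), C = mk()))
  prev <- NULL
  for (th in seq(0, 0.9, by = 0.1)) {
    masks <- det_masks(prob2det(atlas, th))
    sizes <- vapply(masks, function(m) sum(m$data), numeric(1))
    if (!is.null(prev)) expect_true(all(sizes <= prev))
    prev <- sizes
  }
})

test_that("CRF curves match hand-counted fractions and are monotone", {
  g <- voxel_grid(c(2L, 2L, 1L), spacing = c(1, 1, 1))
  p <- labeled_volume(array(c(0.25, 0.25, 0.25, 0.75), g$shape), g,
                      "probability")
  cc <- crf(p, thresholds = c(0.25, 0.5, 0.75, 1))
  expect_equal(cc$crf[cc$threshold == 0.5], 0.75)  # 3 of 4 non-zero voxels
  expect_equal(cc$crf[cc$threshold == 1], 1)

  # a maximally certain label: zero mass below 1, all mass at 1
  ones <- labeled_volume(array(c(1, 1, 0, 0), g$shape), g, "probability")
  c2 <- crf(ones, thresholds = c(0.5, 0.99, 1))
  expect_equal(c2$crf, c(0, 0, 1))

  # crf at the maximum observed probability is 1
  set.seed(17)
  g8 <- tiny_grid(8)
  pr <- labeled_volume(array(runif(512) * (runif(512) < 0.3), g8$shape),
                       g8, "probability")
  c3 <- crf(pr, thresholds = sort(c(max(pr$data), runif(20) * 0.99)))
  expect_equal(c3$crf[c3$threshold == max(pr$data)], 1)
  expect_true(all(diff(c3$crf) >= 0))

  zero <- labeled_volume(array(0, g8$shape), g8, "probability")
  expect_error(crf(zero), "all-zero")
  expect_error(crf(pr, thresholds = c(0.5, 0.4)), "ascending")
})

test_that("fused atlases keep per-voxel region sums at or below one", {
  spec <- phantom_spec(regions = default_phantom_regions(3),
                       n_observers = 2L, n_templates = 2L, seed = 8,
                       grid = voxel_grid(c(48L, 48L, 48L),
                                         spacing = c(0.7, 0.7, 0.7)))
  st <- make_study(spec)
  atlas <- fuse_atlas(st$labels)
  total <- Reduce(`+`, lapply(atlas$labels, function(l) l$data))
  expect_lte(max(total), 1 + 1e-6)
  expect_equal(nrow(atlas$provenance), 4L)  # 2 observers x 2 templates
})
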