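test_that("phantom generation is fully deterministic under a fixed seed", {
  spec <- phantom_spec(regions = default_phantom_regions(2),
                       n_observers = 2L, n_templates = 2L, seed = 21,
                       grid = voxel_grid(c(40L, 40L, 40L),
                                         spacing = c(0.7, 0.7, 0.7)))
  s1 <- make_study(spec)
  s2 <- make_study(spec)
  for (i in seq_len(nrow(s1$labels$entries)))
    expect_identical(s1$labels$entries$label[[i]]$data,
                     s2$labels$entries$label[[i]]$data)
  # a different seed produces different delineations
  s3 <- make_study(phantom_spec(regions = default_phantom_regions(2),
                                n_observers = 2L, n_templates = 2L,
                                seed = 22,
                                grid = spec$grid))
  expect_false(identical(s1$labels$entries$label[[1]]$data,
                         s3$labels$entries$label[[1]]$data))
})

test_that("hard-edged ground truth matches the analytic ellipsoid volume", {
  reg <- data.frame(acronym = "Pu", cx = -9, cy = 0, cz = 0,
                    ax = 5, ay = 4, az = 3)
  gt <- make_ground_truth(phantom_spec(regions = reg, boundary_softness = 0))
  v <- prob_volume(gt$left$labels$Pu)
  truth <- 4 / 3 * pi * 5 * 4 * 3  # 251.33 ul
  expect_lt(abs(v / truth - 1), 0.03)

  # symmetric phantom: exactly zero laterality on the mirrored grid
  expect_equal(volume_table(gt$left, gt$right)$laterality_pct, 0,
               tolerance = 1e-9)
})

test_that("overlapping region specs are rejected", {
  reg <- data.frame(acronym = c("A", "B"), cx = c(-8, -9), cy = c(0, 0),
                    cz = c(0, 0), ax = c(3, 3), ay = c(3, 3), az = c(3, 3))
  expect_error(make_ground_truth(phantom_spec(regions = reg)), "overlap")
})

test_that("zero jitter reproduces the thresholded truth for every observer", {
  spec <- phantom_spec(regions = data.frame(acronym = "Pu", cx = -5, cy = 0,
                                            cz = 0, ax = 3.2, ay = 3,
                                            az = 2.8),
                       jitter = 0,
                       grid = voxel_grid(c(32L, 32L, 32L),
                                         spacing = c(0.7, 0.7, 0.7)))
  truth <- make_ground_truth(spec)$left$labels$Pu
  o1 <- simulate_observer(truth, jitter = 0, seed = 1)
  o2 <- simulate_observer(truth, jitter = 0, seed = 2)
  expect_identical(o1$data, (attr(truth, "signed_distance") < 0) + 0)
  expect_equal(dice(o1, o2), 1.0)
  expect_equal(directed_hausdorff(o1, o2), 0.0)

  # the probability map alone (without the cached distance field) suffices
  bare <- labeled_volume(truth$data, truth$grid, "probability")
  o3 <- simulate_observer(bare, jitter = 0, seed = 1,
                          softness = spec$boundary_softness)
  expect_identical(o3$data, o1$data)
})

test_that("increasing jitter strictly degrades inter-observer agreement", {
  reg <- data.frame(acronym = "Pu", cx = -9, cy = 0, cz = 0,
                    ax = 4.5, ay = 4, az = 3.5)
  truth <- make_ground_truth(phantom_spec(regions = reg))$left$labels$Pu
  mean_dice <- vapply(c(0.3, 0.7, 1.4), function(j) {
    obs <- lapply(1:3, function(s) simulate_observer(truth, j, seed = 100 + s))
    prs <- utils::combn(3, 2, simplify = FALSE)
    mean(vapply(prs, function(p) dice(obs[[p[1]]], obs[[p[2]]]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
})

test_that("a full study has the designed cell structure", {
  spec <- phantom_spec(regions = default_phantom_regions(2),
                       n_observers = 3L, n_templates = 2L, seed = 5,
                       grid = voxel_grid(c(40L, 40L, 40L),
                                         spacing = c(0.7, 0.7, 0.7)))
  st <- make_study(spec)
  e <- st$labels$entries
  expect_equal(nrow(e), 2 * 3 * 2)  # regions x observers x templates
  expect_equal(length(unique(e$observer)), 3L)
  expect_equal(length(unique(e$template)), 2L)
  # mutual exclusivity is guaranteed by construction (constructor validates)
  expect_s3_class(st$labels, "observer_label_set")
  # ground truth retained for recovery checks
  expect_s3_class(st$truth_left, "prob_atlas")
  expect_s3_class(st$truth_right, "prob_atlas")
})

test_that("studies round-trip through disk manifests", {
  spec <- phantom_spec(regions = default_phantom_regions(2),
                       n_observers = 2L, n_templates = 1L, seed = 9,
                       grid = voxel_grid(c(24L, 24L, 24L),
                                         spacing = c(0.7, 0.7, 0.7)))
  st <- make_study(spec)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  set2 <- read_label_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(set2$entries), nrow(st$labels$entries))
  for (i in seq_len(nrow(set2$entries))) {
    orig <- st$labels$entries
    j <- which(orig$region == set2$entries$region[i] &
                 orig$observer == set2$entries$observer[i] &
                 orig$template == set2$entries$template[i])
    expect_identical(set2$entries$label[[i]]$data, orig$label[[j]]$data)
  }
})

test_that("CRF mass at low probability separates noisy small labels", {
  # a large consistent region vs a small noisy one: the small label's CRF
  # accumulates more mass below p = 0.5 (the convex-curve phenomenon)
  reg <- data.frame(acronym = c("Pu", "HN"), cx = c(-9, -9), cy = c(-9, 9),
                    cz = c(0, 0), ax = c(5, 1.4), ay = c(4.5, 1.3),
                    az = c(4, 1.2))
  spec <- phantom_spec(regions = reg, n_observers = 3L, n_templates = 4L,
                       seed = 31)
  atlas <- fuse_atlas(make_study(spec)$labels)
  crf_at <- function(r) crf(atlas$labels[[r]], thresholds = c(0.5, 1))$crf[1]
  expect_gt(crf_at("HN"), crf_at("Pu"))
})

test_that("fused phantom atlases recover deterministic truth masks", {
  reg <- data.frame(acronym = "Pu", cx = -9, cy = 0, cz = 0,
                    ax = 5, ay = 4, az = 3)
  spec <- phantom_spec(regions = reg, boundary_softness = 0.35,
                       jitter = 0.3, n_observers = 3L, n_templates = 8L,
                       seed = 11)
  st <- make_study(spec)
  atlas <- fuse_atlas(st$labels)
  det <- det_masks(prob2det(atlas, 0.5))$Pu
  truth_mask <- labeled_volume(
    (attr(st$truth_left$labels$Pu, "signed_distance") < 0) + 0,
    spec$grid, "binary")
  expect_gte(dice(det, truth_mask), 0.9)
})
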