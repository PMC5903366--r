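test_that("mid-sagittal reflection is an exact involution preserving counts", {
  g <- tiny_grid(11, 1)  # odd grid: one voxel column exactly on the plane
  set.seed(3)
  for (i in 1:5) {
    b <- random_bin_vol(g, 0.15)
    r <- reflect_midsagittal(b)
    expect_identical(reflect_midsagittal(r)$data, b$data)
    expect_equal(sum(r$data), sum(b$data))
    expect_true(all(r$data %in% c(0, 1)))
  }
})

test_that("reflection maps world x = +7 to x = -7 and fixes the plane", {
  g <- tiny_grid(15, 1)  # world x from -7 to 7
  b <- labeled_volume(array(0, g$shape), g, "binary")
  b$data[15, 8, 8] <- 1  # world (7, 0, 0)
  r <- reflect_midsagittal(b, plane_x = 0)
  fg <- which(r$data != 0, arr.ind = TRUE)
  expect_equal(unname(fg), matrix(c(1L, 8L, 8L), 1))  # world (-7, 0, 0)
  expect_equal(atlasforge:::grid_world_x(g)[which(r$data != 0)], -7)

  # voxel centred on the plane maps to itself
  onplane <- labeled_volume(array(0, g$shape), g, "binary")
  onplane$data[8, 4, 11] <- 1
  expect_identical(reflect_midsagittal(onplane)$data, onplane$data)
})

test_that("reflection rejects grids oblique or asymmetric in x", {
  A <- diag(4)
  A[1:2, 1] <- c(0.9, 0.1)  # world x mixes two voxel axes
  g <- voxel_grid(c(6L, 6L, 6L), affine = A)
  v <- labeled_volume(array(0, g$shape), g, "binary")
  expect_error(reflect_midsagittal(v), "oblique")

  g2 <- voxel_grid(c(6L, 6L, 6L), spacing = c(1, 1, 1),
                   origin = c(0.3, 0, 0))
  v2 <- labeled_volume(array(0, g2$shape), g2, "binary")
  expect_error(reflect_midsagittal(v2), "symmetric")
})

test_that("chain resampling reproduces identity and constants, clips edges", {
  g <- tiny_grid(12, 1)
  set.seed(4)
  v <- labeled_volume(array(runif(prod(g$shape)), g$shape), g, "intensity")
  out <- apply_chain(v, transform_chain(affine_transform(diag(4))))
  expect_lt(max(abs(out$data - v$data)), 1e-6)

  # constants are reproduced by the cubic B-spline under any smooth chain
  const <- labeled_volume(array(0.4, g$shape), g, "probability")
  A <- diag(4); A[1:3, 4] <- c(0.3, -0.2, 0.15)
  outc <- apply_chain(const, transform_chain(affine_transform(A)))
  interior <- outc$data[3:10, 3:10, 3:10]
  expect_lt(max(abs(interior - 0.4)), 1e-6)

  # a step edge pushed through a half-voxel shift must overshoot pre-clip
  step <- array(0, g$shape); step[1:6, , ] <- 1
  sv <- labeled_volume(step, g, "probability")
  A2 <- diag(4); A2[1, 4] <- 0.5
  outs <- apply_chain(sv, transform_chain(affine_transform(A2)))
  pre <- attr(outs, "preclip_range")
  expect_true(pre[1] < 0 || pre[2] > 1)   # clipping was actually triggered
  expect_gte(min(outs$data), 0)
  expect_lte(max(outs$data), 1)
})

test_that("nearest-neighbour resampling preserves the index value set", {
  g <- tiny_grid(10, 1)
  idx <- labeled_volume(array(sample(c(0, 2, 5), prod(g$shape), TRUE),
                              g$shape), g, "index")
  A <- diag(4); A[1:3, 4] <- c(1, -1, 2)  # whole-voxel shift
  out <- apply_chain(idx, transform_chain(affine_transform(A),
                                          interpolation = "nearest"), g)
  expect_true(all(out$data %in% c(0, 2, 5)))
  expect_identical(out$kind, "index")
})

test_that("a constant displacement field acts as a translation", {
  g <- tiny_grid(14, 1)
  pts <- t(atlasforge:::voxel_to_world(g, atlasforge:::grid_indices(g)))
  v <- labeled_volume(array(exp(-colSums(pts^2) / 18), g$shape), g,
                      "intensity")
  shift <- c(1.3, -0.6, 0.9)
  fld <- displacement_field(array(rep(shift, each = prod(g$shape)),
                                  c(g$shape, 3)), g)
  A <- diag(4); A[1:3, 4] <- shift
  via_field <- apply_chain(v, transform_chain(fld))
  via_affine <- apply_chain(v, transform_chain(affine_transform(A)))
  interior <- as.matrix(expand.grid(4:11, 4:11, 4:11))
  expect_lt(max(abs(via_field$data[interior] - via_affine$data[interior])),
            1e-4)
})

test_that("probability mass is conserved under rigid resampling", {
  g <- tiny_grid(16, 1)
  pts <- t(atlasforge:::voxel_to_world(g, atlasforge:::grid_indices(g)))
  v <- labeled_volume(array(exp(-colSums(pts^2) / 8), g$shape), g,
                      "probability")
  th <- 0.12
  A <- diag(4)
  A[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A[1:3, 4] <- c(0.4, -0.3, 0.6)
  out <- apply_chain(v, transform_chain(affine_transform(A)))
  expect_lt(abs(prob_volume(out) / prob_volume(v) - 1), 0.01)
})

test_that("reflection warp maps a left label to a matching right label", {
  spec <- phantom_spec(regions = data.frame(acronym = "Pu", cx = -8, cy = 0,
                                            cz = 0, ax = 4, ay = 3.5, az = 3),
                       boundary_softness = 0.5,
                       grid = voxel_grid(c(48L, 48L, 48L),
                                         spacing = c(0.7, 0.7, 0.7)))
  left <- make_ground_truth(spec)$left$labels$Pu
  right <- reflection_warp(left)
  expect_lt(abs(prob_volume(right) / prob_volume(left) - 1), 0.005)
  # mass sits in the right hemisphere
  wx <- atlasforge:::grid_world_x(right$grid)
  expect_gt(sum(right$data[wx > 0]) / sum(right$data), 0.99)

  # a pure scaling changes volume by its Jacobian
  S <- diag(c(1.1, 1.1, 1.1, 1))
  scaled <- reflection_warp(left, affine_transform(S))
  expect_lt(abs(prob_volume(scaled) / (1.1^3 * prob_volume(left)) - 1), 0.02)

  # empty in, empty out
  empty <- labeled_volume(array(0, left$grid$shape), left$grid, "probability")
  expect_equal(sum(reflection_warp(empty)$data), 0)

  # a transform dumping mass back into the source hemisphere warns
  bad <- diag(4); bad[1, 4] <- -25
  expect_warning(reflection_warp(left, affine_transform(bad)),
                 "source hemisphere")
})

test_that("chain construction enforces reflection placement", {
  A <- affine_transform(diag(4))
  expect_error(transform_chain(A, reflection()), "first step")
  expect_error(transform_chain(reflection(), reflection()), "at most once")
  ch <- transform_chain(reflection(), A)
  expect_length(ch$steps, 2L)
})
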