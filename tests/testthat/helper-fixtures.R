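# in-code fixtures shared across the suite

# isotropic grid centred on the world origin
tiny_grid <- function(n = 10L, spacing = 1) {
  voxel_grid(rep(n, 3L), spacing = rep(spacing, 3L))
}

# binary volume with foreground at the given 1-based voxel indices (n x 3)
bin_vol <- function(grid, idx) {
  a <- array(0, grid$shape)
  if (length(idx)) {
    idx <- matrix(idx, ncol = 3)
    a[idx] <- 1
  }
  labeled_volume(a, grid, "binary")
}

# random non-empty binary volume
random_bin_vol <- function(grid, p = 0.1) {
  a <- array(as.numeric(stats::runif(prod(grid$shape)) < p), grid$shape)
  if (sum(a) == 0) a[1, 1, 1] <- 1
  labeled_volume(a, grid, "binary")
}

# smooth two-blob intensity image for registration tests
blob_image <- function(grid = voxel_grid(c(32L, 32L, 32L),
                                         spacing = c(0.7, 0.7, 0.7))) {
  pts <- t(atlasforge:::voxel_to_world(grid, atlasforge:::grid_indices(grid)))
  blob <- function(centre, s) exp(-colSums((pts - centre)^2) / (2 * s^2))
  labeled_volume(array(0.8 * blob(c(-3, 2, 1), 4) +
                         0.5 * blob(c(4, -3, -2), 2.5), grid$shape),
                 grid, "intensity")
}

# an exactly translated copy: same data, grid origin shifted by `shift` mm
translated_copy <- function(vol, shift) {
  g <- vol$grid
  labeled_volume(vol$data,
                 voxel_grid(g$shape, spacing = g$spacing,
                            origin = g$affine[1:3, 4] + shift),
                 vol$kind)
}

# translation recovered by a fitted affine = displacement at the fixed centre
recovered_translation <- function(fit, fixed_grid) {
  ctr <- colMeans(atlasforge:::voxel_to_world(fixed_grid,
                                              rbind(c(0, 0, 0),
                                                    fixed_grid$shape - 1)))
  as.numeric((fit$matrix %*% c(ctr, 1))[1:3] - ctr)
}

# small observer set: one region, labels supplied as a named list
# entries[[observer]][[template]]
make_set <- function(labels_by_cell, region = "Pu", vocabulary = region) {
  region_v <- character(0); obs_v <- character(0); tpl_v <- character(0)
  lab <- list()
  for (ob in names(labels_by_cell)) for (tp in names(labels_by_cell[[ob]])) {
    region_v <- c(region_v, region)
    obs_v <- c(obs_v, ob)
    tpl_v <- c(tpl_v, tp)
    lab[[length(lab) + 1L]] <- labels_by_cell[[ob]][[tp]]
  }
  entries <- data.frame(region = region_v, observer = obs_v, template = tpl_v,
                        stringsAsFactors = FALSE)
  entries$label <- lab
  observer_label_set(entries, vocabulary)
}
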