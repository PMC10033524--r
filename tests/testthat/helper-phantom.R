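# Shared fixtures, generated in code at test time.

# A small phantom already at network-input scale (no ROI crop needed).
small_phantom_config <- function(seed = 1L, noise_sd = 0,
                                 grid = c(64L, 64L, 16L),
                                 tumor_angle = pi / 4) {
  phantom_config(grid_shape = grid,
                 bladder_center = grid / 2,
                 bladder_radii = c(0.32, 0.38, 0.34) * grid,
                 wall_thickness = 2,
                 tumor_radius = 5,
                 tumor_angle = tumor_angle,
                 noise_sd = noise_sd,
                 seed = seed)
}

# A preprocessed training sample (normalized image + labels + one-hot).
small_phantom_sample <- function(seed = 1L, noise_sd = 0,
                                 grid = c(64L, 64L, 16L),
                                 tumor_angle = pi / 4) {
  ph <- generate_phantom(small_phantom_config(seed, noise_sd, grid, tumor_angle))
  labels <- encode_masks(ph$masks)
  list(image = normalize_volume(ph$image$voxels), labels = labels,
       onehot = to_onehot(labels), case_id = ph$image$case_id)
}

# Template with enough headroom for generate_cohort's +/-20% geometry jitter.
cohort_phantom_config <- function(grid = c(64L, 64L, 16L), noise_sd = 10,
                                  seed = 1L) {
  phantom_config(grid_shape = grid,
                 bladder_center = grid / 2,
                 bladder_radii = c(0.24, 0.27, 0.30) * c(grid[1:2], grid[3]),
                 wall_thickness = 2,
                 tumor_radius = 4,
                 noise_sd = noise_sd,
                 seed = seed)
}

# Full-size phantom case (512 x 512 x 32) for ROI-path tests.
fullsize_phantom <- function(seed = 1L, noise_sd = 30) {
  cfg <- phantom_config(noise_sd = noise_sd, seed = seed)
  generate_phantom(cfg)
}

# Random binary mask of the given shape.
random_mask <- function(dims, p = 0.3) {
  array(as.numeric(stats::runif(prod(dims)) < p), dims)
}

# Random valid label volume in the {0, 255, 125} convention.
random_labels <- function(dims) {
  array(sample(c(0, 255, 125), prod(dims), replace = TRUE), dims)
}

# One-voxel 26-neighbourhood dilation (pure R, used as a small oracle).
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    src_r <- pmin(pmax(seq_len(d[1]) + dr, 1), d[1])
    src_c <- pmin(pmax(seq_len(d[2]) + dc, 1), d[2])
    src_s <- pmin(pmax(seq_len(d[3]) + ds, 1), d[3])
    out <- out | mask[src_r, src_c, src_s]
  }
  out
}
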