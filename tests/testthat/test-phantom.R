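test_that("noiseless phantom is piecewise constant over the four regions", {
  cfg <- small_phantom_config(noise_sd = 0)
  ph <- generate_phantom(cfg)
  vals <- sort(unique(as.vector(ph$image$voxels)))
  expect_identical(vals, sort(c(cfg$intensity_background, cfg$intensity_wall,
                                cfg$intensity_tumor, cfg$intensity_lumen)))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- small_phantom_config(seed = 9L, noise_sd = 25)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$masks$wall, b$masks$wall)
  expect_identical(a$masks$tumor, b$masks$tumor)
  cfg2 <- small_phantom_config(seed = 10L, noise_sd = 25)
  expect_false(identical(generate_phantom(cfg2)$image$voxels, a$image$voxels))
})

test_that("wall-shell voxel count matches the analytic ellipsoid-shell volume", {
  # radii >= 20 voxels keep the discretization error well under 10%
  cfg <- phantom_config(grid_shape = c(460L, 460L, 56L),
                        bladder_center = c(229, 229, 27),
                        bladder_radii = c(55, 50, 24),
                        wall_thickness = 4, tumor_radius = 6,
                        noise_sd = 0, seed = 1L)
  outer_r <- cfg$bladder_radii
  inner_r <- outer_r - cfg$wall_thickness
  analytic <- 4 / 3 * pi * (prod(outer_r) - prod(inner_r))
  ph <- generate_phantom(cfg)
  # shell membership computed independently from voxel coordinates, used
  # only to restore the tumor voxels carved out of the wall mask
  norm2 <- function(center, radii) {
    r <- (seq_len(cfg$grid_shape[1]) - 1 - center[1])^2 / radii[1]^2
    c_ <- (seq_len(cfg$grid_shape[2]) - 1 - center[2])^2 / radii[2]^2
    s <- (seq_len(cfg$grid_shape[3]) - 1 - center[3])^2 / radii[3]^2
    outer(outer(r, c_, `+`), s, `+`)
  }
  in_shell <- norm2(cfg$bladder_center, outer_r) <= 1 &
    norm2(cfg$bladder_center, inner_r) > 1
  shell_count <- sum(ph$masks$wall) + sum(ph$masks$tumor == 1 & in_shell)
  expect_lt(abs(shell_count - analytic) / analytic, 0.10)
})

test_that("a tumor that misses the wall shell raises a detachment error", {
  # sub-voxel tumor whose discrete sphere lands entirely in the lumen
  detach_cfg <- phantom_config(grid_shape = c(64L, 64L, 16L),
                               bladder_center = c(31.6, 31.7, 8),
                               bladder_radii = c(20.7, 22.356, 6),
                               wall_thickness = 2, tumor_radius = 1,
                               tumor_angle = pi / 2, noise_sd = 0, seed = 1L)
  expect_error(generate_phantom(detach_cfg), "detached")
})

test_that("config invariants reject impossible geometries", {
  expect_error(phantom_config(bladder_radii = c(3, 3, 3), wall_thickness = 4),
               "wall_thickness")
  expect_error(phantom_config(grid_shape = c(64L, 64L, 16L),
                              bladder_center = c(32, 32, 8),
                              bladder_radii = c(40, 20, 6)),
               "fit inside")
  # on ROI-capable grids the bladder must sit inside the [100, 400) window
  expect_error(phantom_config(bladder_center = c(120, 245, 15)),
               "\\[100, 400\\)")
})

test_that("masks are binary, disjoint, wall-attached and the lumen connected", {
  for (seed in 1:4) {
    ang <- seed * 1.4
    cfg <- small_phantom_config(seed = seed, noise_sd = 10,
                                grid = c(96L, 96L, 24L), tumor_angle = ang)
    ph <- generate_phantom(cfg)
    wall <- ph$masks$wall
    tumor <- ph$masks$tumor
    expect_true(all(wall %in% c(0, 1)))
    expect_true(all(tumor %in% c(0, 1)))
    expect_identical(dim(wall), dim(tumor))
    expect_equal(sum(wall * tumor), 0)
    # 26-connectivity contact: some wall voxel within the tumor's 1-voxel halo
    halo <- dilate1(tumor == 1)
    expect_true(any(halo & wall == 1))
    # lumen (inner ellipsoid minus tumor) is one connected component
    inner <- bladderseg:::ellipsoid_mask(cfg$grid_shape, cfg$bladder_center,
                                         cfg$bladder_radii - cfg$wall_thickness)
    lumen_mask <- inner & tumor == 0
    expect_equal(bladderseg:::flood_count_cpp(lumen_mask, dim(lumen_mask)),
                 sum(lumen_mask))
  }
})

test_that("generate_cohort writes the contracted files deterministically", {
  tmp1 <- withr::local_tempdir()
  tmp2 <- withr::local_tempdir()
  tmpl <- cohort_phantom_config(grid = c(96L, 96L, 24L))
  d1 <- generate_cohort(3, tmpl, seed = 5L, out_dir = tmp1)
  expect_length(d1, 3)
  for (d in d1)
    expect_setequal(list.files(d), c("image.nrrd", "wall.nrrd", "tumor.nrrd"))
  m1 <- read.csv(file.path(tmp1, "manifest.csv"))
  expect_equal(nrow(m1), 3)
  generate_cohort(3, tmpl, seed = 5L, out_dir = tmp2)
  m2 <- read.csv(file.path(tmp2, "manifest.csv"))
  expect_identical(m1, m2)
  d3 <- generate_cohort(3, tmpl, seed = 6L, out_dir = withr::local_tempdir())
  m3 <- read.csv(file.path(dirname(d3[1]), "manifest.csv"))
  expect_false(identical(m1$radius_r, m3$radius_r))
})
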