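test_that("ROI extraction crops the fixed [100,400) window to 300x300x32", {
  withr::local_seed(1)
  x <- array(rnorm(512 * 512 * 32), c(512, 512, 32))
  out <- extract_roi(x)
  expect_identical(dim(out), c(300L, 300L, 32L))
  expect_identical(out, x[101:400, 101:400, ])

  # window placement: ones inside [100,400)^2, zeros elsewhere -> all ones
  y <- array(0, c(512, 512, 32))
  y[101:400, 101:400, ] <- 1
  expect_true(all(extract_roi(y) == 1))

  # deeper volume: centre crop keeps slices 4..35 (0-based), i.e. (40-32)/2 = 4
  z <- array(rnorm(512 * 512 * 40), c(512, 512, 40))
  expect_identical(extract_roi(z), z[101:400, 101:400, 5:36])

  # shallower volume: symmetric zero padding
  w <- array(1, c(512, 512, 28))
  out <- extract_roi(w)
  expect_identical(dim(out), c(300L, 300L, 32L))
  expect_true(all(out[, , 1:2] == 0) && all(out[, , 31:32] == 0))
  expect_true(all(out[, , 3:30] == 1))

  expect_error(extract_roi(array(0, c(256, 256, 32))), "resize or pad")
})

test_that("resize preserves constants, label sets, and approximate areas", {
  # constant volume stays constant
  expect_equal(resize_volume(array(7, c(30, 30, 8)), c(12, 12, 8)),
               array(7, c(12, 12, 8)))

  # nearest-neighbour mask resize preserves the label set
  ph <- fullsize_phantom(seed = 2, noise_sd = 0)
  labels <- encode_masks(ph$masks)
  roi <- extract_roi(labels)
  small <- resize_volume(roi, c(128, 128, 32), is_mask = TRUE)
  expect_identical(dim(small), c(128L, 128L, 32L))
  expect_true(all(small %in% c(0, 255, 125)))

  # wall-shell voxel count scales roughly with in-plane area (128/300)^2
  n_before <- sum(roi == 255)
  n_after <- sum(small == 255)
  ratio <- n_after / n_before
  expect_lt(abs(ratio - (128 / 300)^2) / (128 / 300)^2, 0.25)
})

test_that("normalization hits the mean-0 / sd-1 contract", {
  ph <- fullsize_phantom(seed = 3, noise_sd = 30)
  v <- normalize_volume(ph$image$voxels)
  expect_lt(abs(mean(v)), 1e-6)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-4)

  # degenerate constant volume maps to zeros
  expect_equal(normalize_volume(array(5, c(4, 4, 4))), array(0, c(4, 4, 4)))

  # affine invariance: normalize(a v + b) == normalize(v) for a > 0
  withr::local_seed(4)
  x <- array(rnorm(10 * 10 * 5), c(10, 10, 5))
  expect_equal(normalize_volume(3.7 * x + 11), normalize_volume(x),
               tolerance = 1e-10)
})

test_that("label encoding maps wall to 255, tumor to 125, tumor wins overlap", {
  wall <- array(c(1, 0, 1, 0), c(2, 2, 1))
  tumor <- array(c(0, 1, 1, 0), c(2, 2, 1))
  lab <- encode_masks(list(wall = wall, tumor = tumor))
  expect_equal(lab[1, 1, 1], 255)  # wall only
  expect_equal(lab[2, 1, 1], 125)  # tumor only
  expect_equal(lab[1, 2, 1], 125)  # overlap resolves to tumor
  expect_equal(lab[2, 2, 1], 0)    # background
  expect_equal(encode_masks(list(wall = wall * 0, tumor = tumor * 0)),
               array(0, c(2, 2, 1)))
  expect_error(encode_masks(list(wall = wall, tumor = array(0, c(3, 2, 1)))),
               "disagree")
})

test_that("one-hot encode/decode are exact inverses with correct counts", {
  withr::local_seed(5)
  for (rep in 1:3) {
    lab <- random_labels(c(7, 6, 5))
    oh <- to_onehot(lab)
    expect_identical(dim(oh), c(7L, 6L, 5L, 3L))
    # channels sum to exactly 1 everywhere
    expect_true(all(oh[, , , 1] + oh[, , , 2] + oh[, , , 3] == 1))
    # channel sums equal class voxel counts (counting oracle)
    expect_equal(sum(oh[, , , 1]), sum(lab == 0))
    expect_equal(sum(oh[, , , 2]), sum(lab == 255))
    expect_equal(sum(oh[, , , 3]), sum(lab == 125))
    expect_identical(from_onehot(oh), lab)
  }
  # single tumor voxel -> channel 3 has exactly one 1
  lab <- array(0, c(4, 4, 2))
  lab[2, 3, 1] <- 125
  expect_equal(sum(to_onehot(lab)[, , , 3]), 1)
  expect_error(to_onehot(array(7, c(2, 2, 1))), "outside")
})

test_that("full preprocessing meets the model input contract", {
  ph <- fullsize_phantom(seed = 6, noise_sd = 20)
  pp <- preprocess_case(ph)
  expect_identical(dim(pp$image), c(128L, 128L, 32L))
  expect_identical(dim(pp$labels), c(128L, 128L, 32L))
  expect_identical(dim(pp$onehot), c(128L, 128L, 32L, 3L))
  expect_lt(abs(mean(pp$image)), 1e-6)
  expect_true(all(pp$labels %in% c(0, 255, 125)))
  # the organ survives the crop: both foreground classes present
  expect_gt(sum(pp$labels == 255), 0)
  expect_gt(sum(pp$labels == 125), 0)
})
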