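test_that("zero-angle rotation and zero-magnitude elastic are identities", {
  s <- small_phantom_sample(seed = 1, grid = c(32L, 32L, 8L))
  r <- rotate_case(s$image, s$labels, 0, flip = FALSE)
  expect_equal(r$image, s$image, tolerance = 1e-12)
  expect_identical(r$labels, s$labels)

  e <- elastic_case(s$image, s$labels, alpha = 0, sigma = 4)
  expect_equal(e$image, s$image, tolerance = 1e-12)
  expect_identical(e$labels, s$labels)
})

test_that("horizontal flip is an involution", {
  s <- small_phantom_sample(seed = 2, grid = c(32L, 32L, 8L))
  f1 <- rotate_case(s$image, s$labels, 0, flip = TRUE)
  f2 <- rotate_case(f1$image, f1$labels, 0, flip = TRUE)
  expect_equal(f2$image, s$image, tolerance = 1e-12)
  expect_identical(f2$labels, s$labels)
  expect_false(identical(f1$labels, s$labels))
})

test_that("rotation by +7 then -7 degrees nearly recovers the labels", {
  s <- small_phantom_sample(seed = 3, grid = c(64L, 64L, 16L))
  r1 <- rotate_case(s$image, s$labels, 7)
  r2 <- rotate_case(r1$image, r1$labels, -7)
  fg <- s$labels != 0
  agree <- sum(r2$labels[fg] == s$labels[fg]) / sum(fg)
  expect_gte(agree, 0.95)
})

test_that("elastic warps are seeded, label-preserving and near volume-preserving", {
  s <- small_phantom_sample(seed = 4, grid = c(64L, 64L, 16L))
  set.seed(42)
  e1 <- elastic_case(s$image, s$labels, alpha = 3, sigma = 8)
  set.seed(42)
  e2 <- elastic_case(s$image, s$labels, alpha = 3, sigma = 8)
  expect_identical(e1$image, e2$image)
  expect_identical(e1$labels, e2$labels)
  expect_true(all(e1$labels %in% c(0, 255, 125)))
  # per-class voxel counts move by < 10% under the default deformation
  for (v in c(0, 255, 125)) {
    n0 <- sum(s$labels == v)
    n1 <- sum(e1$labels == v)
    expect_lt(abs(n1 - n0) / n0, 0.10)
  }
})

test_that("image and labels move together under every augmentation", {
  # a marker voxel placed in the image must land where its label lands
  dims <- c(48L, 48L, 12L)
  image <- array(0, dims)
  labels <- array(0, dims)
  image[30, 35, 6] <- 100
  labels[30, 35, 6] <- 125
  set.seed(7)
  scen <- augmentation_scenario(na = 5, seed = 7)
  out <- augment_case(image, labels, scen)
  for (a in out) {
    lab_pos <- which(a$labels == 125)
    img_pos <- which(a$image > 1)
    # every surviving marker label sits on (or adjacent to) high image mass
    if (length(lab_pos) && length(img_pos)) {
      li <- arrayInd(lab_pos[1], dims)
      mi <- arrayInd(which.max(a$image), dims)
      expect_lte(max(abs(li - mi)), 1L)
    }
  }
})

test_that("augment_case emits exactly na volumes with valid labels", {
  s <- small_phantom_sample(seed = 5, grid = c(32L, 32L, 8L))
  set.seed(11)
  out10 <- augment_case(s$image, s$labels, augmentation_scenario(na = 10))
  expect_length(out10, 10)
  out5 <- augment_case(s$image, s$labels, augmentation_scenario(na = 5))
  expect_length(out5, 5)
  for (a in c(out10, out5))
    expect_true(all(a$labels %in% c(0, 255, 125)))
  # composition: na = 10 -> 6 rotations (3 flipped) + 4 elastic (2 flipped)
  tr <- vapply(out10, function(a) a$transform, "")
  expect_equal(sum(grepl("^rotate", tr)), 6)
  expect_equal(sum(grepl("^elastic", tr)), 4)
  expect_equal(sum(grepl("flip", tr)), 5)
  expect_error(augmentation_scenario(na = 7), "composition")
  expect_error(augmentation_scenario(na = 10, n_pos_rot = 3, n_neg_rot = 3,
                                     n_elastic = 3), "even|equal")
})

test_that("training-set arithmetic matches x + x*na plus one validation volume", {
  dims <- c(16L, 16L, 8L)
  mk <- function(i) list(image = array(rnorm(prod(dims)), dims),
                         labels = random_labels(dims),
                         case_id = sprintf("c%02d", i))
  withr::local_seed(1)
  cases7 <- lapply(1:7, mk)
  s5 <- build_training_set(cases7, augmentation_scenario(na = 5, seed = 3))
  expect_length(s5$train, 42)   # 7 + 7*5
  expect_length(s5$val, 7)
  s10 <- build_training_set(cases7, augmentation_scenario(na = 10, seed = 3))
  expect_length(s10$train, 77)  # 7 + 7*10
  cases14 <- lapply(1:14, mk)
  s14 <- build_training_set(cases14, augmentation_scenario(na = 5, seed = 3))
  expect_length(s14$train, 84)  # 14 + 14*5
  # train and validation share no augmented volume
  expect_false(any(duplicated(c(
    lapply(s5$train, function(x) x$image),
    lapply(s5$val, function(x) x$image)))))
})

test_that("build_training_set is a pure function of (cases, seed)", {
  dims <- c(16L, 16L, 8L)
  withr::local_seed(2)
  cases <- lapply(1:2, function(i) list(image = array(rnorm(prod(dims)), dims),
                                        labels = random_labels(dims)))
  a <- build_training_set(cases, augmentation_scenario(na = 5, seed = 9))
  b <- build_training_set(cases, augmentation_scenario(na = 5, seed = 9))
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$train, `[[`, "image"), lapply(b$train, `[[`, "image"))
  c_ <- build_training_set(cases, augmentation_scenario(na = 5, seed = 10))
  expect_false(identical(a$manifest, c_$manifest))
  expect_error(build_training_set(list(), augmentation_scenario(na = 5)),
               "at least one")
})
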