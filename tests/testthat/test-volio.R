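test_that("NRRD write/read round-trips voxel values exactly", {
  withr::local_seed(1)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(x, p, spacing = c(0.5, 0.5, 3), type = "double")
  r <- read_nrrd(p)
  expect_identical(r$data, x)
  expect_equal(r$spacing, c(0.5, 0.5, 3))
  # integer payloads round-trip exactly too
  xi <- array(sample(0:255, 8 * 8 * 4, TRUE), c(8, 8, 4))
  write_nrrd(xi, p, spacing = c(1, 1, 1), type = "int")
  expect_equal(read_nrrd(p)$data, xi + 0)
  # gzip encoding
  write_nrrd(x, p, spacing = c(1, 1, 1), type = "double", encoding = "gzip")
  expect_identical(read_nrrd(p)$data, x)
  # float (32-bit) narrows but preserves float-representable values
  xf <- array(as.numeric(sample(0:100, 8 * 8 * 4, TRUE)) / 4, c(8, 8, 4))
  write_nrrd(xf, p, spacing = c(1, 1, 1), type = "float")
  expect_identical(read_nrrd(p)$data, xf)
})

test_that("a slice-major file is returned re-ordered to (rows, cols, slices)", {
  withr::local_seed(2)
  x <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  p <- withr::local_tempfile(fileext = ".nrrd")
  # store slice-fastest on disk; the reader must restore canonical order
  write_nrrd(x, p, spacing = c(1, 1, 1), type = "double",
             labels = c("slice", "row", "col"))
  r <- read_nrrd(p)
  expect_identical(r$data, x)
  # and the raw payload really is permuted on disk
  hdr_sizes <- read_nrrd_header_sizes(p)
  expect_identical(hdr_sizes, c(4L, 6L, 5L))
})

test_that("missing spacing falls back to (1,1,1) with a warning", {
  x <- array(1:24, c(2, 3, 4))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(x, p, type = "int")  # no spacing given
  expect_warning(r <- read_nrrd(p), "spacing")
  expect_equal(r$spacing, c(1, 1, 1))
})

test_that("malformed and non-3D NRRD files produce named errors", {
  p <- withr::local_tempfile(fileext = ".nrrd")
  writeLines(c("NOTNRRD"), p)
  expect_error(read_nrrd(p), "magic")
  writeLines(c("NRRD0004", "type: double", "sizes: 2 2", "encoding: raw", ""), p)
  expect_error(read_nrrd(p), "dimension")
  writeLines(c("NRRD0004", "dimension: 2", "sizes: 2 2", "type: double",
               "encoding: raw", ""), p)
  expect_error(read_nrrd(p), "3D|dimensional")
  expect_error(read_nrrd(file.path(tempdir(), "nope.nrrd")), "not found")
})

test_that("load_case binds the three files and enforces alignment", {
  tmp <- withr::local_tempdir()
  ph <- generate_phantom(small_phantom_config(seed = 3L, noise_sd = 5))
  write_case(file.path(tmp, "case_a"), ph$image, ph$masks)
  case <- load_case(file.path(tmp, "case_a"))
  expect_identical(dim(case$image$voxels), dim(case$masks$wall))
  expect_equal(case$image$case_id, "case_a")
  expect_true(all(case$masks$wall %in% c(0, 1)))

  # {0, 255}-valued mask file is coerced to {0, 1}
  wall255 <- case$masks$wall * 255
  write_nrrd(wall255, file.path(tmp, "case_a", "wall.nrrd"), spacing = c(1, 1, 1), type = "uchar")
  case2 <- load_case(file.path(tmp, "case_a"))
  expect_identical(sort(unique(as.vector(case2$masks$wall))),
                   sort(unique(c(0, case$masks$wall))))
  expect_equal(sum(case2$masks$wall), sum(case$masks$wall))

  # wrong-shape tumor mask triggers an alignment error listing shapes
  write_nrrd(array(0, c(4, 4, 2)), file.path(tmp, "case_a", "tumor.nrrd"),
             spacing = c(1, 1, 1), type = "uchar")
  expect_error(load_case(file.path(tmp, "case_a")), "shapes disagree")

  # missing component is named
  file.remove(file.path(tmp, "case_a", "tumor.nrrd"))
  expect_error(load_case(file.path(tmp, "case_a")), "tumor")
})

test_that("detached-header NRRD files are read", {
  withr::local_seed(4)
  tmp <- withr::local_tempdir()
  x <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  raw_path <- file.path(tmp, "payload.raw")
  con <- file(raw_path, "wb")
  writeBin(as.double(x), con, size = 8, endian = "little")
  close(con)
  hdr <- file.path(tmp, "vol.nhdr")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 5 4 3",
               "encoding: raw", "endian: little", "spacings: 1 1 1",
               "data file: payload.raw", ""), hdr)
  expect_identical(read_nrrd(hdr)$data, x)
})
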