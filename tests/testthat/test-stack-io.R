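test_that("write/read round-trip preserves voxels and calibration exactly", {
  g <- generate_stack(small_params(seed = 2L), keep_aligned = FALSE,
                      keep_masks = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_stack(g$stack, dir)
  rd <- read_stack(paths[setdiff(names(paths), "sidecar")],
                   calibration = list(pixel_size_xy = 0.1,
                                      section_thickness = 0.07))
  for (ch in names(g$stack$channels)) {
    expect_identical(rd$channels[[ch]], g$stack$channels[[ch]])
  }
  expect_equal(rd$pixel_size_xy, 0.1)
  expect_equal(rd$section_thickness, 0.07)
})

test_that("calibration is required, never assumed", {
  g <- generate_stack(small_params(seed = 2L), keep_aligned = FALSE,
                      keep_masks = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_stack(g$stack, dir)
  expect_error(read_stack(paths[1], calibration = NULL), "calibration")
  expect_error(read_stack(paths[1],
                          calibration = list(pixel_size_xy = 0.1)),
               "calibration")
})

test_that("mismatched channel shapes raise a structural error naming the channel", {
  expect_error(
    channel_stack(list(a = array(0, c(4, 4, 3)), bad = array(0, c(4, 4, 2))),
                  0.1, 0.07),
    "bad")
  dir <- withr::local_tempdir()
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.1, 8, 8)),
                  file.path(dir, "a.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(list(matrix(0.1, 8, 8)),
                  file.path(dir, "b.tif"), bits.per.sample = 16L)
  expect_error(
    read_stack(c(a = file.path(dir, "a.tif"), b = file.path(dir, "b.tif")),
               calibration = list(pixel_size_xy = 0.1,
                                  section_thickness = 0.07)),
    "'b'")
})

test_that("mixed 8-bit and 16-bit channel files keep their stored counts", {
  dir <- withr::local_tempdir()
  a16 <- matrix(as.numeric(sample.int(65535, 64)), 8, 8)
  a8 <- matrix(as.numeric(sample.int(255, 64)), 8, 8)
  tiff::writeTIFF(list(a16 / 65535), file.path(dir, "hi.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(list(a8 / 255), file.path(dir, "lo.tif"),
                  bits.per.sample = 8L)
  rd <- read_stack(c(hi = file.path(dir, "hi.tif"),
                     lo = file.path(dir, "lo.tif")),
                   calibration = list(pixel_size_xy = 0.1,
                                      section_thickness = 0.07))
  expect_equal(rd$channels$hi[, , 1], a16)
  expect_equal(rd$channels$lo[, , 1], a8)
})

test_that("result writing is deterministic and provenance-hashed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  tab <- list(density = data.frame(animal = c("a", "b"), value = c(1.5, 2.5)))
  cfg <- list(alpha = 1, beta = "x")
  m1 <- write_results(tab, dir1, config = cfg, seed = 7L)
  m2 <- write_results(tab, dir2, config = cfg, seed = 7L)
  expect_identical(readBin(file.path(dir1, "density.csv"), "raw", 1e5),
                   readBin(file.path(dir2, "density.csv"), "raw", 1e5))
  expect_identical(m1$config_hash, m2$config_hash)
  # manifest only, for an empty table set
  dir3 <- withr::local_tempdir()
  write_results(list(), dir3, config = cfg, seed = 1L)
  expect_identical(list.files(dir3), "manifest.json")
  # any parameter change changes the hash
  m3 <- write_results(tab, dir1, config = list(alpha = 2, beta = "x"), seed = 7L)
  expect_false(identical(m1$config_hash, m3$config_hash))
})
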