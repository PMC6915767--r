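# A stack of identical sections with enough structure to register on.
flat_stack <- function(n_sections = 4, seed = 1, noise_sd = 25) {
  g <- generate_stack(small_params(seed = seed, shift_sd_px = 0,
                                   n_sections = 3L, noise_sd = noise_sd),
                      keep_aligned = FALSE, keep_masks = FALSE)
  sec <- g$stack$channels$synaptophysin[, , 2]
  a <- array(rep(sec, n_sections), c(dim(sec), n_sections))
  channel_stack(list(synaptophysin = a), 0.1, 0.07)
}

test_that("a stack of identical sections registers to all-zero shifts", {
  st <- flat_stack()
  est <- estimate_shifts(st)
  expect_equal(unname(est$shifts), matrix(0, 4, 2))
})

test_that("injected integer shifts are recovered exactly", {
  st <- flat_stack(3)
  tf <- section_transforms(rbind(c(0, 0), c(3, -2), c(1, 4)))
  mis <- apply_transforms(st, tf)$stack
  est <- estimate_shifts(mis, upsample = 1)
  expect_identical(unname(est$shifts), unname(-tf$shifts))
  # and on full generator output with random integer misalignment
  g <- generate_stack(small_params(seed = 21L))
  est2 <- estimate_shifts(g$stack, upsample = 1)
  expect_identical(unname(est2$shifts), unname(-g$truth$true_shifts))
})

test_that("subpixel shifts of magnitude <= 2 px are recovered within 0.5 px", {
  for (s in 31:33) {
    g <- generate_stack(small_params(seed = s, subpixel_shifts = TRUE,
                                     shift_sd_px = 1))
    est <- estimate_shifts(g$stack)
    expect_lt(max(abs(est$shifts + g$truth$true_shifts)), 0.5)
  }
})

test_that("identity transforms return the input voxel-identical", {
  g <- generate_stack(small_params(seed = 4L), keep_aligned = FALSE,
                      keep_masks = FALSE)
  tf <- section_transforms(matrix(0, dim(g$stack)[3], 2))
  out <- apply_transforms(g$stack, tf)
  expect_identical(out$stack$channels, g$stack$channels)
  expect_true(all(out$valid))
})

test_that("subpixel shift then unshift stays correlated > 0.99 on the valid region", {
  st <- flat_stack(3)
  tf <- section_transforms(rbind(c(0, 0), c(1.4, -0.7), c(-0.3, 1.8)))
  d <- dim(st$channels[[1]])
  rows <- 5:(d[1] - 4); cols <- 5:(d[2] - 4)   # clear of border effects
  # the Fourier phase-ramp shift is exactly self-inverse
  fwd <- apply_transforms(st, tf, interpolation = "fourier")
  back <- apply_transforms(fwd$stack, invert_transforms(tf),
                           interpolation = "fourier")
  for (s in 2:3) {
    expect_gt(stats::cor(as.vector(back$stack$channels[[1]][rows, cols, s]),
                         as.vector(st$channels[[1]][rows, cols, s])),
              0.99)
  }
  # bilinear round trip smooths but stays highly correlated
  fwd2 <- apply_transforms(st, tf)
  back2 <- apply_transforms(fwd2$stack, invert_transforms(tf))
  for (s in 2:3) {
    expect_gt(stats::cor(as.vector(back2$stack$channels[[1]][rows, cols, s]),
                         as.vector(st$channels[[1]][rows, cols, s])),
              0.9)
  }
})

test_that("registering an already-registered stack gives shifts within 0.5 px of zero", {
  g <- generate_stack(small_params(seed = 12L))
  reg <- apply_transforms(g$stack, estimate_shifts(g$stack, upsample = 1))$stack
  re <- estimate_shifts(reg)
  expect_lt(max(abs(re$shifts)), 0.5)
})

test_that("blank reference sections inherit the predecessor's shift with a warning", {
  st <- flat_stack(4)
  st$channels$synaptophysin[, , 3] <- 0
  tf <- section_transforms(rbind(c(0, 0), c(2, 1), c(0, 0), c(0, 0)))
  mis <- apply_transforms(st, tf)$stack
  expect_warning(est <- estimate_shifts(mis, upsample = 1), "blank")
  # section 3 is blank: its composed shift equals section 2's
  expect_equal(est$shifts[3, ], est$shifts[2, ])
})

test_that("transforms survive a CSV round trip and length mismatches error", {
  tf <- section_transforms(rbind(c(0, 0), c(1.25, -2.5), c(3, 4)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_transforms(tf, f)
  expect_equal(read_transforms(f)$shifts, tf$shifts)
  g <- generate_stack(small_params(seed = 4L, n_sections = 6L),
                      keep_aligned = FALSE, keep_masks = FALSE)
  expect_error(apply_transforms(g$stack, tf), "sections")
})
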