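plaque_stack <- function(seed = 2L, core = 5, halo = 8) {
  p <- synth_params(field_size_px = c(256L, 256L), n_sections = 6L,
                    punctum_density = c(synaptophysin = 0.3),
                    plaque_spec = list(list(center_um = c(12.8, 12.8),
                                            core_radius_um = core,
                                            halo_radius_um = halo)),
                    shift_sd_px = 0, seed = seed)
  generate_stack(p, keep_aligned = FALSE, keep_masks = FALSE)
}

test_that("a plaque-free field gives empty masks and infinite distances", {
  g <- generate_stack(small_params(seed = 3L))
  pm <- detect_plaques(g$stack, core_channel = "tau")  # tau: sparse puncta only
  # min plaque area removes puncta-scale objects entirely
  expect_equal(sum(pm$core_mask), 0)
  expect_true(all(is.infinite(pm$edge_distance)))
  expect_equal(classify_near_far(pm$edge_distance[1, 1, 1]), "far")
})

test_that("a 5 um disc core is detected with area within 10% of pi r^2", {
  g <- plaque_stack()
  pm <- detect_plaques(g$stack)
  b <- plaque_burden(pm$core_mask[, , 3], 0.1)
  expect_equal(b$plaque_count, 1)
  expect_lt(abs(b$total_area_um2 - pi * 25) / (pi * 25), 0.10)
})

test_that("components below the minimum plaque area are removed", {
  m <- array(FALSE, c(64, 64, 1))
  m[10:29, 10:29, 1] <- TRUE        # 400 px = 4 um^2 at 0.1 um/px
  m[50:52, 50:52, 1] <- TRUE        # 9 px, sub-threshold at 1 um^2
  st <- channel_stack(list(thios = m * 600 + 100), 0.1, 0.07)
  pm <- detect_plaques(st, min_plaque_area_um2 = 1)
  b <- plaque_burden(pm$core_mask, 0.1)
  expect_equal(b$plaque_count, 1)
})

test_that("near/far classification follows the strict <20 um rule", {
  expect_equal(classify_near_far(10), "near")
  expect_equal(classify_near_far(19.9), "near")
  expect_equal(classify_near_far(20), "far")
  expect_equal(classify_near_far(Inf), "far")
  expect_error(classify_near_far(-1), "non-negative")
})

test_that("halo subtraction is exact set arithmetic", {
  pan <- matrix(FALSE, 20, 20); pan[1:10, 1:10] <- TRUE        # 100 px
  core <- matrix(FALSE, 20, 20); core[1:5, 1:8] <- TRUE        # 40 px subset
  hb <- halo_burden(pan, core, 0.1)
  expect_equal(sum(hb$halo_mask), 60)
  # core == pan -> empty halo
  expect_equal(halo_burden(pan, pan, 0.1)$percent_area, 0)
  # halo U core == pan when core is a subset of pan
  expect_identical(hb$halo_mask[, , 1] | core, pan)
  expect_error(halo_burden(pan, core[1:10, ]), "shape")
})

test_that("synthetic annulus halo area is within 10% of the analytic value", {
  g <- plaque_stack(seed = 5L)
  pm <- detect_plaques(g$stack, pan_channel = "abeta")
  hb <- halo_burden(pm$pan_mask[, , 3], pm$core_mask[, , 3], 0.1)
  analytic <- pi * (8^2 - 5^2)          # 122.5 um^2
  expect_lt(abs(hb$total_area_um2 - analytic) / analytic, 0.10)
})

test_that("region volume estimation is the exact section sum", {
  expect_equal(estimate_region_volume(c(2, 2, 2), 1000, 2), 12)
  expect_equal(estimate_region_volume(numeric(0)), 0)
  ramp <- seq(0.5, 5, by = 0.5)
  expect_equal(estimate_region_volume(ramp, 500, 2),
               sum(ramp) * 0.5 * 2)
  expect_error(estimate_region_volume(c(1, -1)), "non-negative")
})

test_that("the edge-distance field matches analytic point-to-disc distance", {
  # exact rasterized disc of radius 50 px (5 um) at the centre
  d <- c(201, 201, 3)
  m <- array(FALSE, d)
  for (r in 1:201) {
    w <- which((r - 101)^2 + ((1:201) - 101)^2 <= 50^2)
    if (length(w)) m[r, w, 2] <- TRUE
  }
  ef <- edge_distance_field(m, 0.1, 0.07)
  # in-plane probes in the plaque's section
  for (off in c(60, 80, 100)) {
    expect_lt(abs(ef[101, 101 + off, 2] - (off - 50) * 0.1), 0.1)
  }
  expect_equal(ef[101, 101, 2], 0)
  # out-of-plane probe combines the physical z offset
  d2 <- ef[101, 181, 2]
  expect_lt(abs(ef[101, 181, 3] - sqrt(d2^2 + 0.07^2)), 1e-6)
})

test_that("sampled ROIs carry labels consistent with the distance field", {
  # corner plaque in a 38.4 um field: both near and far tissue exist
  p <- synth_params(field_size_px = c(384L, 384L), n_sections = 4L,
                    punctum_density = c(synaptophysin = 0.2),
                    plaque_spec = list(list(center_um = c(8, 8),
                                            core_radius_um = 4,
                                            halo_radius_um = 6)),
                    shift_sd_px = 0, seed = 7L)
  g <- generate_stack(p, keep_aligned = FALSE, keep_masks = FALSE)
  pm <- detect_plaques(g$stack)
  rois <- sample_rois(g$stack, pm, roi_size_um = 3, n_near = 3, n_far = 3,
                      seed = 5L)
  expect_equal(nrow(rois), 6)
  mid_s <- ceiling(dim(g$stack)[3] / 2)
  for (i in seq_len(nrow(rois))) {
    r <- rois$row0[i] + rois$size_px[i] %/% 2
    c <- rois$col0[i] + rois$size_px[i] %/% 2
    expect_equal(rois$near_far[i],
                 classify_near_far(pm$edge_distance[r, c, mid_s]))
  }
  # reproducible under the same seed, and no overlap by construction
  rois2 <- sample_rois(g$stack, pm, roi_size_um = 3, n_near = 3, n_far = 3,
                       seed = 5L)
  expect_identical(rois, rois2)
  expect_equal(nrow(sample_rois(g$stack, pm, 3, 0, 0)), 0)
})

test_that("a plaque-free field yields zero near ROIs with a warning", {
  g <- generate_stack(small_params(seed = 8L))
  pm <- detect_plaques(g$stack, core_channel = "tau")
  expect_warning(rois <- sample_rois(g$stack, pm, roi_size_um = 2,
                                     n_near = 2, n_far = 2, seed = 1L),
                 "near")
  expect_equal(sum(rois$near_far == "near"), 0)
})
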