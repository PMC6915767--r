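test_that("empty generator settings give a background-only stack with empty truth", {
  p <- small_params(punctum_density = c(synaptophysin = 0),
                    noise_speck_rate = 0, marker_positive_fraction = numeric(0))
  g <- generate_stack(p)
  expect_equal(nrow(g$truth$puncta), 0)
  expect_equal(nrow(g$truth$specks), 0)
  expect_false(any(g$truth$masks$synaptophysin))
  # intensities are background plus noise only
  a <- g$truth$aligned$channels$synaptophysin
  expect_lt(max(a), p$background_level + 8 * p$noise_sd)
  expect_equal(unname(g$truth$true_densities[["synaptophysin"]]), 0)
})

test_that("generation is voxel-identical for a fixed seed", {
  g1 <- generate_stack(small_params(seed = 42L))
  g2 <- generate_stack(small_params(seed = 42L))
  expect_identical(g1$stack$channels, g2$stack$channels)
  expect_identical(g1$truth$puncta, g2$truth$puncta)
  expect_identical(g1$truth$true_shifts, g2$truth$true_shifts)
  g3 <- generate_stack(small_params(seed = 43L))
  expect_false(identical(g1$stack$channels, g3$stack$channels))
})

test_that("punctum counts are Poisson and marker labels binomial over a seed sweep", {
  # 10 x 10 x 1.4 um volume at density 1.0 -> Poisson mean 140
  lambda <- 140
  counts <- integer(100)
  labels <- c(pos = 0L, tot = 0L)
  for (s in seq_len(100)) {
    p <- synth_params(field_size_px = c(100L, 100L), n_sections = 20L,
                      punctum_density = c(synaptophysin = 1.0),
                      min_separation_um = 0,      # pure Poisson placement
                      marker_positive_fraction = c(tau = 0.05),
                      noise_speck_rate = 0, noise_sd = 0, shift_sd_px = 0,
                      seed = 1000L + s)
    g <- generate_stack(p, keep_aligned = FALSE, keep_masks = FALSE)
    counts[s] <- nrow(g$truth$puncta)
    labels["pos"] <- labels["pos"] + sum(g$truth$puncta$tau_pos)
    labels["tot"] <- labels["tot"] + nrow(g$truth$puncta)
  }
  se_mean <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se_mean)
  # label fraction over >= 2000 puncta within 3 binomial SE of 5%
  expect_gt(labels["tot"], 2000)
  frac <- labels["pos"] / labels["tot"]
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / labels["tot"]))
})

test_that("rendered truth is consistent: puncta span their sections, specks one", {
  p <- small_params(noise_sd = 0, shift_sd_px = 0, seed = 5L)
  g <- generate_stack(p)
  px <- p$pixel_size_xy
  d <- dim(g$truth$aligned$channels[[1]])
  for (i in seq_len(nrow(g$truth$puncta))) {
    pu <- g$truth$puncta[i, ]
    r <- min(max(round(pu$y_um / px + 0.5), 1), d[1])
    c <- min(max(round(pu$x_um / px + 0.5), 1), d[2])
    ch <- g$truth$aligned$channels[[pu$channel]]
    rr <- intersect(r + (-1:1), 1:d[1]); cc <- intersect(c + (-1:1), 1:d[2])
    for (s in pu$sec_start:pu$sec_end) {
      expect_gt(ch[r, c, s], p$background_level)
      expect_true(any(g$truth$masks[[pu$channel]][rr, cc, s]))
    }
    expect_gte(pu$span, 2)
  }
  # specks: mask content in exactly the one listed section at that xy
  for (i in seq_len(nrow(g$truth$specks))) {
    sp <- g$truth$specks[i, ]
    r <- min(max(round(sp$y_um / px + 0.5), 1), d[1])
    c <- min(max(round(sp$x_um / px + 0.5), 1), d[2])
    ch <- g$truth$aligned$channels[[sp$channel]]
    expect_gt(ch[r, c, sp$section], p$background_level)
  }
})

test_that("applying the inverse of the true shifts restores the aligned stack", {
  g <- generate_stack(small_params(seed = 11L))
  inv <- invert_transforms(section_transforms(g$truth$true_shifts))
  res <- apply_transforms(g$stack, inv)
  for (ch in names(res$stack$channels)) {
    expect_identical(res$stack$channels[[ch]][res$valid],
                     g$truth$aligned$channels[[ch]][res$valid])
  }
})

test_that("a plaque that cannot fit in the field is rejected with a sizing error", {
  p <- small_params(plaque_spec = list(list(center_um = c(5, 5),
                                            core_radius_um = 4,
                                            halo_radius_um = 8)))
  expect_error(generate_stack(p), "too small")
})

test_that("trajectory regimes honour their constructions", {
  tr <- generate_trajectory(60, "center_only", seed = 3L)
  ctr <- tr$arena_cm / 2
  expect_true(all(pmax(abs(tr$samples$x_cm - ctr),
                       abs(tr$samples$y_cm - ctr)) <= 10))
  expect_equal(total_distance(generate_trajectory(30, "immobile")), 0)
  # one wall-following lap at 2 cm from the walls: 4 x 36 = 144 cm
  lap <- generate_trajectory(144, "wall_follow", speed_cm_s = 1, dt_s = 1)
  expect_equal(total_distance(lap), 144)
  expect_error(generate_trajectory(60, dt_s = 0), "dt_s")
  expect_error(generate_trajectory(0), "duration")
})

test_that("genotype cohorts are multinomial with the requested proportions", {
  expect_equal(unname(generate_genotype_cohort(0)), rep(0L, 4))
  expect_equal(unname(generate_genotype_cohort(50, c(a = 1, b = 0, c = 0, d = 0))),
               c(50L, 0L, 0L, 0L))
  counts <- generate_genotype_cohort(4000, seed = 9L)
  expect_equal(sum(counts), 4000L)
  se <- sqrt(4000 * 0.25 * 0.75)            # ~27.4
  expect_true(all(abs(counts - 1000) < 3 * se))
})
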