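make_punctum <- function(vox) list(id = 1L, channel = "PSD95", voxels = vox)

test_that("overlap fractions are exact voxel arithmetic", {
  vox <- cbind(row = rep(1:2, each = 5), col = rep(1:5, 2), section = 1L)
  colnames(vox) <- c("row", "col", "section")
  full <- array(TRUE, c(4, 6, 2))
  none <- array(FALSE, c(4, 6, 2))
  half <- none; half[1, 1:5, 1] <- TRUE
  p <- make_punctum(vox)
  expect_equal(overlap_fraction(p, full), 1)
  expect_equal(overlap_fraction(p, none), 0)
  expect_equal(overlap_fraction(p, half), 0.5)
  expect_error(overlap_fraction(make_punctum(vox[0, , drop = FALSE]), full),
               "empty")
  expect_error(overlap_fraction(make_punctum(cbind(row = 9, col = 1, section = 1)),
                                none), "bounds")
})

test_that("positivity uses an inclusive 50% minimum", {
  expect_true(classify_positive(0.5))
  expect_false(classify_positive(0.49))
  expect_true(classify_positive(1.0))
  expect_error(classify_positive(1.2), "0, 1")
})

test_that("strata with no puncta report n = 0 with an absent fraction", {
  ps <- link_3d(mask_stack(array(FALSE, c(6, 6, 3))))
  cr <- coloc_rates(ps, list(tau = array(FALSE, c(6, 6, 3))))
  expect_equal(cr$n_puncta, 0L)
  expect_true(is.na(cr$fraction))
})

test_that("marker masks disjoint from all puncta give all-zero rates", {
  m <- array(FALSE, c(12, 12, 4))
  m[2:3, 2:3, 1:2] <- TRUE
  m[8:9, 8:9, 2:3] <- TRUE
  ps <- link_3d(mask_stack(m))
  far <- array(FALSE, c(12, 12, 4)); far[11:12, 1:2, ] <- TRUE
  cr <- coloc_rates(ps, list(tau = far, abeta = far))
  expect_true(all(cr$fraction == 0))
  expect_true(all(cr$n_positive == 0))
})

test_that("lowering the overlap threshold never decreases a positive count", {
  g <- generate_stack(small_params(seed = 15L,
                                   marker_positive_fraction = c(tau = 0.3)))
  reg <- apply_transforms(g$stack, estimate_shifts(g$stack, upsample = 1))$stack
  ps <- filter_single_section(link_3d(binarize_stack(reg, "PSD95")))
  masks <- list(tau = g$truth$masks$tau)
  thrs <- c(0.7, 0.5, 0.3, 0.1)
  counts <- vapply(thrs, function(t) coloc_rates(ps, masks, threshold = t)$n_positive,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("double positivity never exceeds either single-marker count", {
  g <- generate_stack(small_params(seed = 16L,
                                   marker_positive_fraction = c(tau = 0.2,
                                                                abeta = 0.3)))
  reg <- apply_transforms(g$stack, estimate_shifts(g$stack, upsample = 1))$stack
  ps <- filter_single_section(link_3d(binarize_stack(reg, "PSD95")))
  cr <- coloc_rates(ps, list(tau = g$truth$masks$tau,
                             abeta = g$truth$masks$abeta))
  dbl <- cr$n_positive[cr$marker == "double"]
  expect_true(all(dbl <= cr$n_positive[cr$marker != "double"]))
  expect_gt(dbl, 0)  # at 20% x 30% independent labels, doubles do occur
})

test_that("a known positive fraction is recovered within binomial error", {
  tot <- c(n = 0, pos = 0); truth_pos <- 0; truth_n <- 0
  for (s in 1:3) {
    p <- small_params(punctum_density = c(PSD95 = 1.0),
                      marker_positive_fraction = c(abeta = 0.10), seed = 40L + s)
    g <- generate_stack(p)
    reg <- apply_transforms(g$stack, estimate_shifts(g$stack, upsample = 1))$stack
    ps <- filter_single_section(link_3d(binarize_stack(reg, "PSD95")))
    cr <- coloc_rates(ps, list(abeta = g$truth$masks$abeta))
    tot <- tot + c(cr$n_puncta, cr$n_positive)
    truth_pos <- truth_pos + sum(g$truth$puncta$abeta_pos)
    truth_n <- truth_n + nrow(g$truth$puncta)
  }
  p_true <- truth_pos / truth_n
  expect_lt(abs(tot[["pos"]] / tot[["n"]] - p_true),
            3 * sqrt(p_true * (1 - p_true) / tot[["n"]]))
})
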