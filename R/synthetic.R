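#' Parameters for the synthetic array-tomography generator
#'
#' Bundles the acquisition geometry and object statistics used by
#' [generate_stack()]. Defaults emulate an array-tomography ribbon of
#' 70 nm sections imaged at 0.1 µm/px, with presynaptic
#' (synaptophysin) and postsynaptic (PSD95) puncta at cortical synapse
#' densities, optional tau / pan-amyloid-beta marker channels, optional
#' fibrillar plaques (dense ThioS-positive core surrounded by an
#' oligomeric halo visible only in the pan-Abeta channel), per-section
#' rigid misalignment, and single-section noise specks.
#'
#' @param field_size_px image size as `c(rows, cols)` in pixels.
#' @param n_sections number of serial sections.
#' @param pixel_size_xy xy pixel size, µm/px.
#' @param section_thickness section thickness, µm (0.07 = 70 nm ribbons).
#' @param punctum_density named vector, puncta per µm³ for each synaptic
#'   channel.
#' @param punctum_radius_um `c(mean, sd)` of the punctum half-maximum
#'   radius in µm.
#' @param punctum_span_sections mean number of sections a punctum spans
#'   (every generated punctum spans at least 2).
#' @param min_separation_um hard-core minimum centre-to-centre xy
#'   distance between same-channel puncta with overlapping section
#'   ranges; keeps puncta resolvable, as real quantified puncta are.
#' @param noise_speck_rate single-section specks per µm³ per channel.
#' @param marker_positive_fraction named vector `marker -> probability`
#'   that a synaptic punctum is positive for that marker; positive
#'   puncta get a co-centred blob rendered in the marker channel.
#' @param marker_radius_factor marker blob radius relative to its
#'   synaptic punctum.
#' @param plaque_spec list of plaques, each
#'   `list(center_um = c(x, y), core_radius_um, halo_radius_um)`.
#' @param shift_sd_px standard deviation of the per-section rigid
#'   misalignment (px); section 1 is the reference and never shifted.
#' @param subpixel_shifts if `FALSE` (default) misalignments are rounded
#'   to whole pixels (lossless to undo); if `TRUE` they stay real-valued
#'   and are applied by bilinear interpolation.
#' @param background_level,punctum_amplitude,noise_sd intensity units:
#'   constant background, peak punctum amplitude above background, and
#'   Gaussian noise standard deviation.
#' @param roi_size_um default side length of square analysis ROIs.
#' @param seed integer seed; all randomness in [generate_stack()] flows
#'   from it.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(field_size_px = c(128L, 128L),
                         n_sections = 15L,
                         pixel_size_xy = 0.1,
                         section_thickness = 0.07,
                         punctum_density = c(synaptophysin = 0.7, PSD95 = 0.9),
                         punctum_radius_um = c(mean = 0.2, sd = 0.04),
                         punctum_span_sections = 5,
                         min_separation_um = 0.7,
                         noise_speck_rate = 0.05,
                         marker_positive_fraction = c(tau = 0.01, abeta = 0.05),
                         marker_radius_factor = 1.5,
                         plaque_spec = list(),
                         shift_sd_px = 2,
                         subpixel_shifts = FALSE,
                         background_level = 100,
                         punctum_amplitude = 500,
                         noise_sd = 25,
                         roi_size_um = 10,
                         seed = 1L) {
  p <- list(field_size_px = as.integer(field_size_px),
            n_sections = as.integer(n_sections),
            pixel_size_xy = pixel_size_xy,
            section_thickness = section_thickness,
            punctum_density = punctum_density,
            punctum_radius_um = punctum_radius_um,
            punctum_span_sections = punctum_span_sections,
            min_separation_um = min_separation_um,
            noise_speck_rate = noise_speck_rate,
            marker_positive_fraction = marker_positive_fraction,
            marker_radius_factor = marker_radius_factor,
            plaque_spec = plaque_spec,
            shift_sd_px = shift_sd_px,
            subpixel_shifts = isTRUE(subpixel_shifts),
            background_level = background_level,
            punctum_amplitude = punctum_amplitude,
            noise_sd = noise_sd,
            roi_size_um = roi_size_um,
            seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  stopifnot(length(p$field_size_px) == 2L, all(p$field_size_px >= 8L),
            p$n_sections >= 2L,
            p$pixel_size_xy > 0, p$section_thickness > 0,
            all(p$punctum_density >= 0),
            p$punctum_radius_um[["mean"]] > 0, p$punctum_radius_um[["sd"]] >= 0,
            p$punctum_span_sections >= 2,
            p$min_separation_um >= 0,
            p$noise_speck_rate >= 0,
            all(p$marker_positive_fraction >= 0),
            all(p$marker_positive_fraction <= 1),
            p$marker_radius_factor > 0,
            p$shift_sd_px >= 0,
            p$background_level >= 0, p$punctum_amplitude > 0, p$noise_sd >= 0,
            p$roi_size_um > 0)
  if (length(p$punctum_density) &&
      is.null(names(p$punctum_density))) {
    stop("`punctum_density` must be a named vector (channel -> density)")
  }
  for (pl in p$plaque_spec) {
    stopifnot(length(pl$center_um) == 2L,
              pl$core_radius_um > 0,
              pl$halo_radius_um >= pl$core_radius_um)
  }
  invisible(p)
}

# Near-top-hat radial profile: amp at the centre, amp/2 exactly at r = R.
# Order 8 makes the footprint steep-edged, like a diffraction-limited
# punctum sampled at ~0.1 um/px.
.blob_profile <- function(r2, R, amp, order = 8) {
  amp * exp(-log(2) * (sqrt(r2) / R)^order)
}

# Add one blob to sections `secs` of array `a` (and optionally mark its
# half-maximum footprint in logical array `mask`). cx/cy in pixel-centre
# coordinates (x = col, y = row).
.render_blob <- function(a, mask, cx, cy, R_px, amp, secs) {
  d <- dim(a)
  r0 <- max(1L, floor(cy - 2 * R_px)); r1 <- min(d[1], ceiling(cy + 2 * R_px))
  c0 <- max(1L, floor(cx - 2 * R_px)); c1 <- min(d[2], ceiling(cx + 2 * R_px))
  if (r0 > r1 || c0 > c1) return(list(a = a, mask = mask))
  rows <- r0:r1; cols <- c0:c1
  r2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  patch <- .blob_profile(r2, R_px, amp)
  for (s in secs) a[rows, cols, s] <- a[rows, cols, s] + patch
  if (!is.null(mask)) {
    foot <- r2 <= R_px^2
    for (s in secs) mask[rows, cols, s] <- mask[rows, cols, s] | foot
  }
  list(a = a, mask = mask)
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Renders puncta, marker blobs, plaques and specks into calibrated
#' intensity volumes, adds background and Gaussian noise, quantizes to
#' 16-bit counts, and finally misaligns the sections by rigid
#' per-section translations. The returned truth records every rendered
#' object, the applied shifts, the half-maximum truth masks (in the
#' aligned frame), and the noisy pre-misalignment stack, so every
#' downstream stage can be validated against known ground truth.
#'
#' @param params a [synth_params()] object.
#' @param keep_aligned keep the pre-misalignment stack in the truth
#'   (needed by registration round-trip tests).
#' @param keep_masks keep per-channel half-maximum truth masks.
#' @return `list(stack = channel_stack, truth = list(...))`. Truth
#'   fields: `puncta` (data frame: channel, centroid µm, radius,
#'   section range, one `<marker>_pos` column per marker), `specks`,
#'   `true_shifts` (n_sections x 2 matrix of applied (dx, dy) px),
#'   `plaques`, `true_densities` (puncta/µm³ actually placed), `masks`,
#'   `aligned` (pre-misalignment [channel_stack()]), `params`.
#' @export
generate_stack <- function(params, keep_aligned = TRUE, keep_masks = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  d <- c(p$field_size_px, p$n_sections)
  px <- p$pixel_size_xy
  field_um <- p$field_size_px * px          # (rows, cols) extent in µm
  vol_um3 <- prod(field_um) * p$n_sections * p$section_thickness

  for (pl in p$plaque_spec) {
    ctr <- pl$center_um
    if (ctr[1] - pl$halo_radius_um < 0 || ctr[2] - pl$halo_radius_um < 0 ||
        ctr[1] + pl$halo_radius_um > field_um[2] ||
        ctr[2] + pl$halo_radius_um > field_um[1]) {
      stop(sprintf(
        "field (%.1f x %.1f um) too small to contain plaque halo of radius %.1f um at (%.1f, %.1f)",
        field_um[2], field_um[1], pl$halo_radius_um, ctr[1], ctr[2]))
    }
  }

  markers <- names(p$marker_positive_fraction)
  syn_channels <- names(p$punctum_density)
  plaque_channels <- if (length(p$plaque_spec)) c("thios", "abeta") else character(0)
  all_channels <- unique(c(syn_channels, markers, plaque_channels))

  with_seed(p$seed, {
    imgs <- lapply(all_channels, function(ch) array(0, d))
    names(imgs) <- all_channels
    masks <- lapply(all_channels, function(ch) array(FALSE, d))
    names(masks) <- all_channels

    puncta <- list()
    specks <- list()

    for (ch in syn_channels) {
      n_target <- rpois(1, p$punctum_density[[ch]] * vol_um3)
      placed <- 0L
      acc_x <- acc_y <- acc_s0 <- acc_s1 <- numeric(0)
      rows_ch <- list()
      while (placed < n_target) {
        ok <- FALSE
        for (try_i in seq_len(200L)) {
          span <- max(2L, min(p$n_sections,
                              as.integer(round(rnorm(1, p$punctum_span_sections, 1)))))
          s0 <- sample.int(p$n_sections - span + 1L, 1L)
          s1 <- s0 + span - 1L
          x <- runif(1, 0, field_um[2])
          y <- runif(1, 0, field_um[1])
          if (length(acc_x)) {
            clash <- (acc_s0 <= s1 & acc_s1 >= s0) &
              ((acc_x - x)^2 + (acc_y - y)^2 < p$min_separation_um^2)
            if (any(clash)) next
          }
          ok <- TRUE
          break
        }
        if (!ok) {
          at_log("channel %s: could not place punctum %d/%d under min separation",
                 ch, placed + 1L, n_target, level = "debug")
          break
        }
        r_um <- max(1.2 * px, min(rnorm(1, p$punctum_radius_um[["mean"]],
                                        p$punctum_radius_um[["sd"]]),
                                  3 * p$punctum_radius_um[["mean"]]))
        amp <- p$punctum_amplitude * runif(1, 0.8, 1.2)
        labels <- vapply(markers, function(m)
          runif(1) < p$marker_positive_fraction[[m]], logical(1))
        acc_x <- c(acc_x, x); acc_y <- c(acc_y, y)
        acc_s0 <- c(acc_s0, s0); acc_s1 <- c(acc_s1, s1)
        placed <- placed + 1L
        rows_ch[[placed]] <- c(list(channel = ch, x_um = x, y_um = y,
                                    z_um = ((s0 + s1) / 2 - 0.5) * p$section_thickness,
                                    radius_um = r_um, sec_start = s0,
                                    sec_end = s1, span = s1 - s0 + 1L,
                                    amplitude = amp),
                               as.list(labels))

        cx <- x / px + 0.5; cy <- y / px + 0.5
        rb <- .render_blob(imgs[[ch]], masks[[ch]], cx, cy, r_um / px, amp, s0:s1)
        imgs[[ch]] <- rb$a; masks[[ch]] <- rb$mask
        for (m in markers[labels]) {
          rb <- .render_blob(imgs[[m]], masks[[m]], cx, cy,
                             p$marker_radius_factor * r_um / px, amp, s0:s1)
          imgs[[m]] <- rb$a; masks[[m]] <- rb$mask
        }
      }
      puncta <- c(puncta, rows_ch)
    }

    # single-section noise specks, per channel
    speck_channels <- setdiff(all_channels, "thios")
    for (ch in speck_channels) {
      n_sp <- rpois(1, p$noise_speck_rate * vol_um3)
      for (i in seq_len(n_sp)) {
        x <- runif(1, 0, field_um[2]); y <- runif(1, 0, field_um[1])
        s <- sample.int(p$n_sections, 1L)
        r_um <- max(1.2 * px, rnorm(1, p$punctum_radius_um[["mean"]],
                                    p$punctum_radius_um[["sd"]]))
        rb <- .render_blob(imgs[[ch]], masks[[ch]], x / px + 0.5, y / px + 0.5,
                           r_um / px, p$punctum_amplitude * runif(1, 0.8, 1.2),
                           s)
        imgs[[ch]] <- rb$a; masks[[ch]] <- rb$mask
        specks[[length(specks) + 1L]] <- list(channel = ch, x_um = x, y_um = y,
                                              section = s)
      }
    }

    # plaques: dense core in ThioS and pan-Abeta, oligomeric halo only
    # in pan-Abeta
    for (pl in p$plaque_spec) {
      cx <- pl$center_um[1] / px + 0.5; cy <- pl$center_um[2] / px + 0.5
      secs <- seq_len(p$n_sections)
      rb <- .render_blob(imgs[["thios"]], masks[["thios"]], cx, cy,
                         pl$core_radius_um / px, p$punctum_amplitude, secs)
      imgs[["thios"]] <- rb$a; masks[["thios"]] <- rb$mask
      rb <- .render_blob(imgs[["abeta"]], masks[["abeta"]], cx, cy,
                         pl$core_radius_um / px, p$punctum_amplitude, secs)
      imgs[["abeta"]] <- rb$a; masks[["abeta"]] <- rb$mask
      rb <- .render_blob(imgs[["abeta"]], masks[["abeta"]], cx, cy,
                         pl$halo_radius_um / px, 0.45 * p$punctum_amplitude, secs)
      imgs[["abeta"]] <- rb$a; masks[["abeta"]] <- rb$mask
    }

    # background + noise, quantized to integer 16-bit counts
    for (ch in all_channels) {
      a <- imgs[[ch]] + p$background_level
      if (p$noise_sd > 0) a <- a + rnorm(length(a), 0, p$noise_sd)
      imgs[[ch]] <- pmin(pmax(round(a), 0), 65535)
    }

    aligned <- channel_stack(imgs, px, p$section_thickness,
                             provenance = sprintf("synthetic seed=%d", p$seed))

    # per-section rigid misalignment (section 1 = reference)
    shifts <- cbind(dx = c(0, rnorm(p$n_sections - 1L, 0, p$shift_sd_px)),
                    dy = c(0, rnorm(p$n_sections - 1L, 0, p$shift_sd_px)))
    if (!p$subpixel_shifts) shifts <- round(shifts)
    mis <- apply_transforms(aligned, section_transforms(shifts))

    puncta_df <- if (length(puncta)) {
      do.call(rbind, lapply(puncta, function(r) as.data.frame(r)))
    } else {
      cols <- c("channel", "x_um", "y_um", "z_um", "radius_um", "sec_start",
                "sec_end", "span", "amplitude", markers)
      df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
      names(df) <- cols
      df
    }
    if (length(markers) && nrow(puncta_df)) {
      names(puncta_df)[match(markers, names(puncta_df))] <-
        paste0(markers, "_pos")
    } else if (length(markers)) {
      names(puncta_df)[match(markers, names(puncta_df), nomatch = 0)] <-
        paste0(markers, "_pos")[markers %in% names(puncta_df)]
    }
    specks_df <- if (length(specks)) {
      do.call(rbind, lapply(specks, as.data.frame))
    } else {
      data.frame(channel = character(0), x_um = numeric(0),
                 y_um = numeric(0), section = integer(0))
    }
    dens <- vapply(syn_channels, function(ch)
      sum(puncta_df$channel == ch) / vol_um3, numeric(1))

    truth <- list(puncta = puncta_df,
                  specks = specks_df,
                  true_shifts = shifts,
                  plaques = p$plaque_spec,
                  true_densities = dens,
                  masks = if (keep_masks) masks else NULL,
                  aligned = if (keep_aligned) aligned else NULL,
                  volume_um3 = vol_um3,
                  params = p)
    list(stack = mis$stack, truth = truth)
  })
}

#' Generate an open-field trajectory
#'
#' Simulates a mouse in a square open-field arena. Besides a generic
#' correlated random walk, constructed regimes are available for
#' validating zone metrics: `"center_only"` never leaves the central
#' inner zone, `"wall_follow"` runs a square circuit at a fixed margin
#' from the walls, and `"immobile"` does not move.
#'
#' @param duration_s session length in seconds.
#' @param step_model one of `"random_walk"`, `"wall_follow"`,
#'   `"center_only"`, `"immobile"`.
#' @param arena_cm arena side length (40 cm standard box).
#' @param dt_s sampling interval (s), must be positive.
#' @param speed_cm_s nominal locomotion speed.
#' @param wall_margin_cm distance from the walls for `"wall_follow"`.
#' @param seed integer seed.
#' @return a [trajectory()] object.
#' @export
generate_trajectory <- function(duration_s = 600, step_model = "random_walk",
                                arena_cm = 40, dt_s = 0.1, speed_cm_s = 5,
                                wall_margin_cm = 2, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (!is.numeric(dt_s) || dt_s <= 0) stop("sampling interval dt_s must be > 0")
  step_model <- match.arg(step_model,
                          c("random_walk", "wall_follow", "center_only",
                            "immobile"))
  t <- seq(0, duration_s, by = dt_s)
  n <- length(t)
  with_seed(seed, {
    if (step_model == "immobile") {
      x <- rep(arena_cm / 2, n); y <- rep(arena_cm / 2, n)
    } else if (step_model == "wall_follow") {
      side <- arena_cm - 2 * wall_margin_cm
      perim <- 4 * side
      s <- (speed_cm_s * t) %% perim
      x <- y <- numeric(n)
      seg <- floor(s / side)
      u <- s - seg * side
      m <- wall_margin_cm
      x <- ifelse(seg == 0, m + u,
           ifelse(seg == 1, m + side,
           ifelse(seg == 2, m + side - u, m)))
      y <- ifelse(seg == 0, m,
           ifelse(seg == 1, m + u,
           ifelse(seg == 2, m + side, m + side - u)))
    } else {
      lo <- if (step_model == "center_only") arena_cm / 2 - arena_cm / 4 + 0.5 else 0.5
      hi <- if (step_model == "center_only") arena_cm / 2 + arena_cm / 4 - 0.5 else arena_cm - 0.5
      x <- y <- numeric(n)
      x[1] <- runif(1, lo, hi); y[1] <- runif(1, lo, hi)
      theta <- runif(1, 0, 2 * pi)
      step <- speed_cm_s * dt_s
      for (i in 2:n) {
        theta <- theta + rnorm(1, 0, 0.6)
        xi <- x[i - 1] + step * cos(theta)
        yi <- y[i - 1] + step * sin(theta)
        # reflect at the bounds
        if (xi < lo) { xi <- 2 * lo - xi; theta <- pi - theta }
        if (xi > hi) { xi <- 2 * hi - xi; theta <- pi - theta }
        if (yi < lo) { yi <- 2 * lo - yi; theta <- -theta }
        if (yi > hi) { yi <- 2 * hi - yi; theta <- -theta }
        x[i] <- min(max(xi, lo), hi); y[i] <- min(max(yi, lo), hi)
      }
    }
    trajectory(data.frame(t_s = t, x_cm = x, y_cm = y), arena_cm = arena_cm)
  })
}

#' Generate a genotype cohort by multinomial sampling
#'
#' Draws litter genotype counts from a multinomial distribution, e.g.
#' the four expected 25% classes of a double-transgenic cross, for
#' checking Mendelian ratios with [chi_square_gof()].
#'
#' @param n number of animals.
#' @param proportions named vector of class probabilities (sums to 1).
#' @param seed integer seed.
#' @return named integer vector of counts (sums to `n`).
#' @export
generate_genotype_cohort <- function(n,
                                     proportions = c(control = 0.25,
                                                     APP_PS1 = 0.25,
                                                     Tau = 0.25,
                                                     APP_PS1_Tau = 0.25),
                                     seed = 1L) {
  stopifnot(n >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (n == 0) {
    return(stats::setNames(integer(length(proportions)), names(proportions)))
  }
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n, proportions))
    stats::setNames(counts, names(proportions))
  })
}
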