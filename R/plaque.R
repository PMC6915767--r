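#' Detect plaques and build a physical edge-distance field
#'
#' Thresholds the fibrillar (ThioS) channel with the same automatic
#' machinery as synaptic segmentation, removes per-section components
#' below `min_plaque_area_um2`, and computes, for every voxel, the
#' distance in µm to the nearest plaque voxel, respecting the
#' anisotropy between xy pixel size and section thickness. Voxels
#' inside a plaque have distance 0; with no plaques the field is
#' infinite everywhere.
#'
#' @param stack a registered [channel_stack()].
#' @param core_channel fibrillar plaque channel (default `"thios"`).
#' @param pan_channel optional pan-amyloid channel; when given its
#'   thresholded mask is stored for halo analysis.
#' @param min_plaque_area_um2 minimum per-section plaque area (µm²);
#'   guards against puncta-scale debris.
#' @param methods threshold methods for the core channel, see
#'   [binarize_section()]. Default is Otsu alone: fibrillar staining is
#'   high-contrast and bimodal, and tail-sensitive methods tuned for
#'   dim puncta over-extend plaque edges.
#' @param pan_methods threshold methods for the pan-amyloid channel.
#'   Default is the lower threshold of three-class Otsu
#'   (`"multiotsu"`), which separates tissue background from all
#'   amyloid signal even though that signal is itself bimodal (dim
#'   halo, bright core).
#' @param max_foreground degenerate-split guard passed to
#'   [binarize_section()]; plaques may legitimately occupy a large
#'   field fraction, hence a laxer cap than for puncta.
#' @return object of class `plaque_map`: `core_mask`, `pan_mask` (or
#'   NULL), `edge_distance` (µm, 3D array), calibration.
#' @export
detect_plaques <- function(stack, core_channel = "thios", pan_channel = NULL,
                           min_plaque_area_um2 = 20,
                           methods = "otsu", pan_methods = "multiotsu",
                           max_foreground = 0.6) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!core_channel %in% names(stack$channels)) {
    stop(sprintf("channel '%s' not present in stack", core_channel))
  }
  px <- stack$pixel_size_xy
  min_px <- max(1L, as.integer(round(min_plaque_area_um2 / px^2)))
  core <- binarize_stack(stack, core_channel, methods = methods,
                         min_object_px = min_px,
                         max_foreground = max_foreground,
                         min_contrast_mads = 4)
  pan <- NULL
  if (!is.null(pan_channel)) {
    if (!pan_channel %in% names(stack$channels)) {
      stop(sprintf("channel '%s' not present in stack", pan_channel))
    }
    pan <- binarize_stack(stack, pan_channel, methods = pan_methods,
                          min_object_px = min_px,
                          max_foreground = max_foreground,
                          min_contrast_mads = 4)
  }
  structure(list(core_mask = core$mask,
                 pan_mask = if (is.null(pan)) NULL else pan$mask,
                 edge_distance = edge_distance_field(core$mask, px,
                                                     stack$section_thickness),
                 pixel_size_xy = px,
                 section_thickness = stack$section_thickness),
            class = "plaque_map")
}

#' @export
print.plaque_map <- function(x, ...) {
  cat(sprintf("plaque_map: %d core voxels; min edge distance %.2f um\n",
              sum(x$core_mask), suppressWarnings(min(x$edge_distance))))
  invisible(x)
}

#' Physical distance to the nearest plaque voxel
#'
#' Per-section 2D Euclidean distance maps are combined across sections
#' with the physical z offset, giving the exact anisotropic 3D distance
#' to the voxel set: `d(v) = min over sections s of
#' sqrt(d2D_s(x, y)^2 + (dz * thickness)^2)`.
#'
#' @param mask logical 3D array `[row, col, section]`.
#' @param pixel_size_xy µm/px.
#' @param section_thickness µm.
#' @return numeric 3D array of distances in µm (`Inf` without plaques,
#'   0 inside them).
#' @export
edge_distance_field <- function(mask, pixel_size_xy, section_thickness) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  d <- dim(mask)
  d2 <- vector("list", d[3])                   # NULL slot = no plaque there
  for (s in seq_len(d[3])) {
    if (any(mask[, , s])) {
      # px distance to the mask, scaled to um
      d2[[s]] <- as.numeric(EBImage::distmap(1 - mask[, , s])) * pixel_size_xy
    }
  }
  out <- array(Inf, d)
  npix <- d[1] * d[2]
  for (s in seq_len(d[3])) {
    best <- rep(Inf, npix)
    for (sp in seq_len(d[3])) {
      if (is.null(d2[[sp]])) next
      dz <- (s - sp) * section_thickness
      best <- pmin(best, sqrt(d2[[sp]]^2 + dz^2))
    }
    out[, , s] <- best
  }
  out
}

#' Classify distances as near or far from a plaque edge
#'
#' A location closer than `cutoff_um` to a plaque edge is `"near"`;
#' at or beyond the cutoff (including infinite distance in plaque-free
#' tissue) it is `"far"`.
#'
#' @param distance_um numeric vector of non-negative distances (µm);
#'   `Inf` allowed.
#' @param cutoff_um near/far boundary, default 20 µm.
#' @return character vector of `"near"` / `"far"`.
#' @export
classify_near_far <- function(distance_um, cutoff_um = 20) {
  if (any(is.na(distance_um)) || any(distance_um < 0)) {
    stop("distances must be non-negative (Inf allowed)")
  }
  ifelse(distance_um < cutoff_um, "near", "far")
}

#' Annotate puncta with plaque proximity
#'
#' @param pset a `puncta_set`.
#' @param plaque_map a [detect_plaques()] result.
#' @param cutoff_um near/far boundary (µm).
#' @return data frame `id`, `edge_distance_um`, `near_far` (one row per
#'   punctum; the distance is evaluated at the punctum centroid voxel).
#' @export
annotate_near_far <- function(pset, plaque_map, cutoff_um = 20) {
  stopifnot(inherits(pset, "puncta_set"), inherits(plaque_map, "plaque_map"))
  d <- dim(plaque_map$edge_distance)
  px <- plaque_map$pixel_size_xy; th <- plaque_map$section_thickness
  dist <- vapply(pset$puncta, function(p) {
    r <- min(max(1L, round(p$centroid_um[["y"]] / px + 0.5)), d[1])
    c <- min(max(1L, round(p$centroid_um[["x"]] / px + 0.5)), d[2])
    s <- min(max(1L, round(p$centroid_um[["z"]] / th + 0.5)), d[3])
    plaque_map$edge_distance[r, c, s]
  }, numeric(1))
  data.frame(id = vapply(pset$puncta, `[[`, numeric(1), "id"),
             edge_distance_um = dist,
             near_far = classify_near_far(dist, cutoff_um),
             stringsAsFactors = FALSE)
}

# Burden metrics over a binary mask: sections are treated as
# independent 2D images (histology convention), so components are 2D.
.burden_from_mask <- function(mask, pixel_size_xy, roi = NULL) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (!is.null(roi)) {
    stopifnot(all(dim(roi) == dim(mask)))
    total_px <- sum(roi)
    mask <- mask & roi
  } else {
    total_px <- length(mask)
  }
  lab <- label_components(mask, link_sections = FALSE)
  n_obj <- 0L
  areas <- numeric(0)
  for (s in seq_len(dim(lab)[3])) {
    ls <- lab[, , s]
    if (any(ls > 0L)) {
      sz <- tabulate(ls[ls > 0L])
      sz <- sz[sz > 0]
      n_obj <- n_obj + length(sz)
      areas <- c(areas, sz * pixel_size_xy^2)
    }
  }
  list(percent_area = 100 * sum(mask) / total_px,
       plaque_count = n_obj,
       mean_plaque_area_um2 = if (n_obj > 0L) mean(areas) else NA_real_,
       total_area_um2 = sum(mask) * pixel_size_xy^2)
}

#' Burden of the oligomeric halo (pan-amyloid minus fibrillar core)
#'
#' The halo is the thresholded pan-amyloid mask minus the thresholded
#' fibrillar (ThioS) mask: `halo = pan AND NOT core`. Burden metrics
#' (percent area, object count, mean object area) are computed on the
#' halo within the ROI.
#'
#' @param pan_mask,core_mask logical arrays of identical shape.
#' @param pixel_size_xy µm/px.
#' @param roi optional logical array restricting the analyzed region.
#' @return object of class `burden_result`: `percent_area`,
#'   `plaque_count`, `mean_plaque_area_um2` (NA when count is 0),
#'   `total_area_um2`, plus `halo_mask`.
#' @export
halo_burden <- function(pan_mask, core_mask, pixel_size_xy, roi = NULL) {
  if (is.matrix(pan_mask)) dim(pan_mask) <- c(dim(pan_mask), 1L)
  if (is.matrix(core_mask)) dim(core_mask) <- c(dim(core_mask), 1L)
  if (!all(dim(pan_mask) == dim(core_mask))) {
    stop("pan and core masks must have identical shape")
  }
  halo <- pan_mask & !core_mask
  res <- .burden_from_mask(halo, pixel_size_xy, roi)
  structure(c(res, list(halo_mask = halo)), class = "burden_result")
}

#' Plaque burden of a single thresholded mask
#'
#' @inheritParams halo_burden
#' @param mask logical array (2D or 3D).
#' @return a `burden_result` (without halo mask).
#' @export
plaque_burden <- function(mask, pixel_size_xy, roi = NULL) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  structure(.burden_from_mask(mask, pixel_size_xy, roi),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("burden: %.3f%% area, %d objects, mean area %s um^2\n",
              x$percent_area, x$plaque_count,
              ifelse(is.na(x$mean_plaque_area_um2), "NA",
                     sprintf("%.1f", x$mean_plaque_area_um2))))
  invisible(x)
}

#' Estimate a region volume from serial histological sections
#'
#' Volume = sum over sections of (area x spacing), times a hemisphere
#' factor when only one hemisphere was measured.
#'
#' @param section_areas_mm2 per-section areas (mm², non-negative).
#' @param section_spacing_um distance between measured sections (µm);
#'   1000 for every 20th of 50 µm sections.
#' @param hemisphere_factor multiply by 2 when one hemisphere stands in
#'   for the whole brain.
#' @return volume in mm³.
#' @export
estimate_region_volume <- function(section_areas_mm2,
                                   section_spacing_um = 1000,
                                   hemisphere_factor = 2) {
  if (length(section_areas_mm2) == 0) return(0)
  if (any(section_areas_mm2 < 0)) stop("section areas must be non-negative")
  stopifnot(section_spacing_um > 0, hemisphere_factor > 0)
  sum(section_areas_mm2) * (section_spacing_um / 1000) * hemisphere_factor
}

#' Sample non-overlapping analysis ROIs, stratified near/far
#'
#' Lays a grid of square ROIs over the field, labels each by the edge
#' distance of its centre voxel, and samples the requested number of
#' near and far ROIs reproducibly.
#'
#' @param stack a [channel_stack()] (defines the field).
#' @param plaque_map a [detect_plaques()] result.
#' @param roi_size_um ROI side length (µm).
#' @param n_near,n_far requested counts.
#' @param cutoff_um near/far boundary (µm).
#' @param seed integer seed.
#' @return data frame: roi_id, row0, col0, size_px, center_x/y_um,
#'   edge_distance_um, near_far. Fewer rows than requested (with a
#'   warning) when the field cannot supply them.
#' @export
sample_rois <- function(stack, plaque_map, roi_size_um = 10,
                        n_near = 0L, n_far = 0L, cutoff_um = 20, seed = 1L) {
  stopifnot(inherits(stack, "channel_stack"), inherits(plaque_map, "plaque_map"))
  if (n_near == 0L && n_far == 0L) {
    return(data.frame(roi_id = integer(0), row0 = integer(0),
                      col0 = integer(0), size_px = integer(0),
                      center_x_um = numeric(0), center_y_um = numeric(0),
                      edge_distance_um = numeric(0),
                      near_far = character(0)))
  }
  px <- stack$pixel_size_xy
  d <- dim(stack$channels[[1]])
  size_px <- max(2L, as.integer(round(roi_size_um / px)))
  if (size_px > min(d[1:2])) stop("field smaller than one ROI")
  r0 <- seq(1L, d[1] - size_px + 1L, by = size_px)
  c0 <- seq(1L, d[2] - size_px + 1L, by = size_px)
  grid <- expand.grid(row0 = r0, col0 = c0)
  mid_s <- ceiling(d[3] / 2)
  ctr_r <- grid$row0 + size_px %/% 2L
  ctr_c <- grid$col0 + size_px %/% 2L
  dist <- plaque_map$edge_distance[cbind(ctr_r, ctr_c, mid_s)]
  lab <- classify_near_far(dist, cutoff_um)
  take <- function(want, which_lab) {
    pool <- which(lab == which_lab)
    if (length(pool) < want) {
      warning(sprintf("only %d '%s' ROIs available (%d requested)",
                      length(pool), which_lab, want))
      want <- length(pool)
    }
    if (want == 0L) return(integer(0))
    pool[sample.int(length(pool), want)]
  }
  with_seed(seed, {
    sel <- c(take(n_near, "near"), take(n_far, "far"))
    if (length(sel) == 0L) {
      return(data.frame(roi_id = integer(0), row0 = integer(0),
                        col0 = integer(0), size_px = integer(0),
                        center_x_um = numeric(0), center_y_um = numeric(0),
                        edge_distance_um = numeric(0),
                        near_far = character(0)))
    }
    data.frame(roi_id = seq_along(sel),
               row0 = grid$row0[sel], col0 = grid$col0[sel],
               size_px = size_px,
               center_x_um = (ctr_c[sel] - 0.5) * px,
               center_y_um = (ctr_r[sel] - 0.5) * px,
               edge_distance_um = dist[sel],
               near_far = lab[sel],
               stringsAsFactors = FALSE)
  })
}
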