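#' Reconstruct 3D puncta from a binarized stack
#'
#' Links foreground voxels into 3D objects: 8-connectivity within a
#' section, and linkage across consecutive sections wherever the 2D
#' footprints share at least one xy pixel. Every foreground voxel
#' belongs to exactly one punctum.
#'
#' @param bstack a registered [binary_stack()].
#' @param gap_tolerance sections that may be skipped when linking
#'   (default 0 = strictly consecutive).
#' @return object of class `puncta_set`: a list with `puncta` (list of
#'   punctum records), `channel`, calibration, and `n_foreground`.
#'   Each punctum holds `id`, `channel`, `voxels` (matrix row/col/sec),
#'   `volume_um3`, `centroid_um` (x, y, z), `section_span`,
#'   `sec_start`, `sec_end`.
#' @export
link_3d <- function(bstack, gap_tolerance = 0L) {
  stopifnot(inherits(bstack, "binary_stack"))
  lab <- label_components(bstack$mask, link_sections = TRUE,
                          gap_tolerance = gap_tolerance)
  idx <- which(lab > 0L)
  voxel_vol <- bstack$pixel_size_xy^2 * bstack$section_thickness
  puncta <- list()
  if (length(idx)) {
    coords <- arrayInd(idx, dim(lab))
    labs <- lab[idx]
    ord <- order(labs)
    coords <- coords[ord, , drop = FALSE]
    labs <- labs[ord]
    split_at <- c(0L, which(diff(labs) != 0L), length(labs))
    px <- bstack$pixel_size_xy; th <- bstack$section_thickness
    puncta <- vector("list", length(split_at) - 1L)
    for (k in seq_len(length(split_at) - 1L)) {
      vox <- coords[(split_at[k] + 1L):split_at[k + 1L], , drop = FALSE]
      colnames(vox) <- c("row", "col", "section")
      secs <- range(vox[, "section"])
      puncta[[k]] <- list(
        id = k,
        channel = bstack$channel,
        voxels = vox,
        volume_um3 = nrow(vox) * voxel_vol,
        centroid_um = c(x = (mean(vox[, "col"]) - 0.5) * px,
                        y = (mean(vox[, "row"]) - 0.5) * px,
                        z = (mean(vox[, "section"]) - 0.5) * th),
        section_span = secs[2] - secs[1] + 1L,
        sec_start = secs[1], sec_end = secs[2])
    }
  }
  structure(list(puncta = puncta, channel = bstack$channel,
                 pixel_size_xy = bstack$pixel_size_xy,
                 section_thickness = bstack$section_thickness,
                 dim = dim(bstack$mask),
                 n_foreground = length(idx)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set '%s': %d puncta, %d foreground voxels\n",
              x$channel, length(x$puncta), x$n_foreground))
  invisible(x)
}

#' @export
length.puncta_set <- function(x) length(x$puncta)

#' Remove single-section objects (background noise)
#'
#' Retains exactly the puncta spanning at least 2 sections; objects
#' present in only a single section are removed as noise. Order is
#' preserved and the operation is idempotent.
#'
#' @param pset a `puncta_set` from [link_3d()].
#' @return a filtered `puncta_set`.
#' @export
filter_single_section <- function(pset) {
  stopifnot(inherits(pset, "puncta_set"))
  keep <- vapply(pset$puncta, function(p) p$section_span >= 2L, logical(1))
  pset$puncta <- pset$puncta[keep]
  pset$n_foreground <- sum(vapply(pset$puncta, function(p) nrow(p$voxels),
                                  numeric(1)))
  pset
}

#' Punctum density per unit volume
#'
#' @param pset a `puncta_set` (or anything with a length).
#' @param roi_volume_um3 analyzed volume in µm³ (> 0).
#' @return density in puncta/µm³.
#' @export
punctum_density <- function(pset, roi_volume_um3) {
  if (!is.numeric(roi_volume_um3) || roi_volume_um3 <= 0) {
    stop("roi_volume_um3 must be > 0")
  }
  length(pset) / roi_volume_um3
}

#' Rebuild a binary mask from 3D-filtered objects
#'
#' Rasterizes the voxels of a puncta set back into a [binary_stack()].
#' Applied to a marker channel after [link_3d()] +
#' [filter_single_section()], this gives the denoised marker mask that
#' colocalization scoring uses by default: single-section marker
#' specks no longer count toward synapse positivity.
#'
#' @param pset a `puncta_set`.
#' @return a [binary_stack()] containing exactly the voxels of the
#'   retained objects.
#' @export
mask_from_puncta <- function(pset) {
  stopifnot(inherits(pset, "puncta_set"))
  mask <- array(FALSE, pset$dim)
  for (p in pset$puncta) mask[p$voxels] <- TRUE
  binary_stack(mask, pset$channel, pset$pixel_size_xy,
               pset$section_thickness)
}

#' Tabulate a puncta set
#'
#' @param pset a `puncta_set`.
#' @param near_far optional character vector (one entry per punctum)
#'   of plaque-proximity labels; see [annotate_near_far()].
#' @return data frame: id, channel, centroid_x/y/z_um, volume_um3,
#'   section_span, near_far.
#' @export
puncta_table <- function(pset, near_far = NULL) {
  stopifnot(inherits(pset, "puncta_set"))
  n <- length(pset$puncta)
  if (is.null(near_far)) near_far <- rep(NA_character_, n)
  stopifnot(length(near_far) == n)
  data.frame(
    id = vapply(pset$puncta, `[[`, numeric(1), "id"),
    channel = rep(pset$channel, n),
    centroid_x_um = vapply(pset$puncta, function(p) p$centroid_um[["x"]], numeric(1)),
    centroid_y_um = vapply(pset$puncta, function(p) p$centroid_um[["y"]], numeric(1)),
    centroid_z_um = vapply(pset$puncta, function(p) p$centroid_um[["z"]], numeric(1)),
    volume_um3 = vapply(pset$puncta, `[[`, numeric(1), "volume_um3"),
    section_span = vapply(pset$puncta, function(p) as.numeric(p$section_span), numeric(1)),
    near_far = near_far,
    stringsAsFactors = FALSE)
}
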