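#' Fraction of a punctum's volume overlapped by a marker mask
#'
#' @param punctum one punctum record from [link_3d()].
#' @param marker_mask a [binary_stack()] (or logical array) of the
#'   marker channel, in the same registered frame as the punctum.
#' @return overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(punctum, marker_mask) {
  vox <- punctum$voxels
  if (is.null(vox) || nrow(vox) == 0L) stop("empty punctum")
  m <- if (inherits(marker_mask, "binary_stack")) marker_mask$mask else marker_mask
  if (is.matrix(m)) dim(m) <- c(dim(m), 1L)
  if (any(vox[, "row"] > dim(m)[1] | vox[, "col"] > dim(m)[2] |
          vox[, "section"] > dim(m)[3])) {
    stop("punctum voxels outside marker mask bounds")
  }
  mean(m[vox])
}

#' Volumetric positivity call
#'
#' A synaptic object is positive for a pathological marker when at
#' least `threshold` (default 50%) of its voxel volume overlaps the
#' marker's binary mask; the minimum is inclusive, so exactly 50%
#' qualifies.
#'
#' @param fraction overlap fraction(s) in \[0, 1\].
#' @param threshold minimum qualifying overlap, default 0.5.
#' @return logical vector.
#' @export
classify_positive <- function(fraction, threshold = 0.5) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("overlap fraction must be in [0, 1]")
  }
  fraction >= threshold
}

#' Colocalization rates of synaptic puncta with pathological markers
#'
#' Scores every punctum against each marker mask with the volumetric
#' overlap rule, then summarizes positive counts and fractions per
#' stratum. Each marker is scored independently; the `"double"` row
#' counts puncta positive for every marker simultaneously (conjunction
#' of the independent calls). Strata with no puncta report `n = 0` and
#' an absent (NA) fraction, never 0.
#'
#' @param pset a `puncta_set` of synaptic puncta.
#' @param marker_masks named list of [binary_stack()]s (or logical
#'   arrays), one per marker.
#' @param strata optional data frame with one row per punctum (e.g.
#'   columns `animal_id`, `near_far`); rates are reported per unique
#'   stratum combination. Omit for a single overall stratum.
#' @param threshold overlap threshold, see [classify_positive()].
#' @return data frame of class `coloc_result`: stratum columns,
#'   `marker`, `n_puncta`, `n_positive`, `fraction`.
#' @export
coloc_rates <- function(pset, marker_masks, strata = NULL, threshold = 0.5) {
  stopifnot(inherits(pset, "puncta_set"), is.list(marker_masks))
  if (is.null(names(marker_masks)) || any(names(marker_masks) == "")) {
    stop("marker_masks must be a named list")
  }
  n <- length(pset$puncta)
  markers <- names(marker_masks)
  if (is.null(strata)) {
    strata <- data.frame(stratum = rep("all", n))
  }
  if (!is.data.frame(strata) || nrow(strata) != n) {
    stop("strata must be a data frame with one row per punctum")
  }
  pos <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  for (m in markers) {
    if (n > 0L) {
      frac <- vapply(pset$puncta, overlap_fraction, numeric(1),
                     marker_mask = marker_masks[[m]])
      pos[, m] <- classify_positive(frac, threshold)
    }
  }
  double <- if (length(markers) > 1L) rowSums(pos) == length(markers) else NULL

  combos <- unique(strata)
  if (nrow(combos) == 0L) {
    # no puncta at all: still report the (empty) overall stratum
    combos <- strata[NA_integer_, , drop = FALSE][1, , drop = FALSE]
    combos[1, ] <- "all"
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- rep(TRUE, n)
    for (cn in names(combos)) sel <- sel & strata[[cn]] == combos[i, cn]
    n_i <- sum(sel)
    for (m in c(markers, if (!is.null(double)) "double")) {
      npos <- if (n_i == 0L) 0L else {
        if (m == "double") sum(double[sel]) else sum(pos[sel, m])
      }
      rows[[length(rows) + 1L]] <- cbind(
        combos[i, , drop = FALSE],
        data.frame(marker = m, n_puncta = n_i, n_positive = npos,
                   fraction = if (n_i > 0L) npos / n_i else NA_real_,
                   stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # invariant: a double positive is positive for each marker singly
  if (!is.null(double)) {
    for (i in seq_len(nrow(combos))) {
      sub <- out
      for (cn in names(combos)) sub <- sub[sub[[cn]] == combos[i, cn], ]
      dbl <- sub$n_positive[sub$marker == "double"]
      stopifnot(all(dbl <= sub$n_positive[sub$marker != "double"]))
    }
  }
  class(out) <- c("coloc_result", class(out))
  out
}
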