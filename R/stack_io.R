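#' Calibrated multi-channel serial-section stack
#'
#' Container for an array-tomography acquisition: one 3D intensity array
#' per channel, all of identical dimensions, plus the physical
#' calibration needed to convert voxels to micrometres. Arrays are
#' indexed `[row, col, section]`; physical anisotropy (xy pixel size vs
#' 70 nm section thickness) is carried in the calibration, never by
#' resampling.
#'
#' @param channels named list of numeric 3D arrays `[row, col, section]`
#'   (2D matrices are promoted to single-section arrays).
#' @param pixel_size_xy xy pixel size in µm/px (> 0).
#' @param section_thickness section thickness in µm (> 0); array ribbons
#'   are conventionally cut at 0.07 µm.
#' @param provenance free-text metadata carried along with the stack.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_xy, section_thickness,
                          provenance = character()) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of arrays")
  }
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
    stopifnot(is.numeric(a), length(dim(a)) == 3L)
    a
  })
  dims <- vapply(channels, function(a) dim(a), integer(3))
  if (any(dims != dims[, 1])) {
    bad <- names(channels)[which(colSums(dims != dims[, 1]) > 0)[1]]
    stop(sprintf("channel '%s' has dimensions %s, expected %s", bad,
                 paste(dims[, bad], collapse = "x"),
                 paste(dims[, 1], collapse = "x")))
  }
  if (!is.numeric(pixel_size_xy) || length(pixel_size_xy) != 1L ||
      !is.finite(pixel_size_xy) || pixel_size_xy <= 0) {
    stop("`pixel_size_xy` must be a single positive number (µm/px)")
  }
  if (!is.numeric(section_thickness) || length(section_thickness) != 1L ||
      !is.finite(section_thickness) || section_thickness <= 0) {
    stop("`section_thickness` must be a single positive number (µm)")
  }
  structure(list(channels = channels,
                 pixel_size_xy = pixel_size_xy,
                 section_thickness = section_thickness,
                 provenance = provenance),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "channel_stack: %d channel(s) [%s], %dx%d px x %d sections, %.4g um/px, %.4g um/section\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3], x$pixel_size_xy, x$section_thickness))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$channels[[1]])

n_sections <- function(stack) dim(stack$channels[[1]])[3]

# total physical volume of the imaged field in µm³
stack_volume_um3 <- function(stack) {
  d <- dim(stack$channels[[1]])
  d[1] * d[2] * stack$pixel_size_xy^2 * d[3] * stack$section_thickness
}

#' Binary (thresholded) stack for one channel
#'
#' @param mask logical 3D array `[row, col, section]`.
#' @param channel channel name the mask was derived from.
#' @param pixel_size_xy,section_thickness calibration, copied from the
#'   source [channel_stack()].
#' @return an object of class `binary_stack`.
#' @export
binary_stack <- function(mask, channel, pixel_size_xy, section_thickness) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            pixel_size_xy > 0, section_thickness > 0)
  structure(list(mask = mask, channel = channel,
                 pixel_size_xy = pixel_size_xy,
                 section_thickness = section_thickness),
            class = "binary_stack")
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_stack '%s': %dx%d px x %d sections, %d foreground voxels\n",
              x$channel, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Write a stack as one multi-page TIFF per channel
#'
#' Sections are TIFF pages. Intensities are stored as 16-bit unsigned
#' integers, so integer-valued data in \[0, 65535\] round-trip exactly.
#' A JSON sidecar records channel file names and calibration.
#'
#' @param stack a [channel_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of written file paths
#'   (one per channel plus `"sidecar"`).
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "channel_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    if (any(a < 0 | a > 65535)) {
      stop(sprintf("channel '%s': intensities outside [0, 65535] cannot be written as 16-bit", ch))
    }
    pages <- lapply(seq_len(dim(a)[3]), function(s) a[, , s] / 65535)
    f <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    paths[ch] <- f
  }
  sidecar <- file.path(dir, "stack.json")
  jsonlite::write_json(
    list(channels = as.list(paths),
         pixel_size_xy = stack$pixel_size_xy,
         section_thickness = stack$section_thickness,
         provenance = stack$provenance),
    sidecar, auto_unbox = TRUE, digits = NA)
  paths["sidecar"] <- sidecar
  invisible(paths)
}

#' Read a calibrated multi-channel stack from TIFF files
#'
#' Each channel is one multi-page TIFF (pages = sections). All channels
#' must agree in page count and page shape. Bit depths may differ
#' between channels; stored integer counts are preserved as-is.
#'
#' @param paths named character vector `channel name -> file path`.
#' @param calibration list with `pixel_size_xy` (µm/px) and
#'   `section_thickness` (µm). Required: calibration is never assumed.
#' @param provenance optional free-text metadata.
#' @return a [channel_stack()].
#' @export
read_stack <- function(paths, calibration, provenance = character()) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("`paths` must be a named vector: channel name -> TIFF path")
  }
  if (missing(calibration) || is.null(calibration) ||
      is.null(calibration$pixel_size_xy) ||
      is.null(calibration$section_thickness)) {
    stop("calibration (pixel_size_xy, section_thickness) is required and is never assumed")
  }
  chans <- list()
  ref_dim <- NULL
  for (ch in names(paths)) {
    if (!file.exists(paths[[ch]])) {
      stop(sprintf("channel '%s': file not found: %s", ch, paths[[ch]]))
    }
    pages <- tiff::readTIFF(paths[[ch]], all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]])[1:2], length(pages))
    if (is.null(ref_dim)) {
      ref_dim <- d
    } else if (!all(d == ref_dim)) {
      stop(sprintf("channel '%s' has dimensions %s, expected %s", ch,
                   paste(d, collapse = "x"), paste(ref_dim, collapse = "x")))
    }
    a <- array(0, d)
    for (s in seq_len(d[3])) a[, , s] <- pages[[s]]
    chans[[ch]] <- a
  }
  channel_stack(chans, calibration$pixel_size_xy,
                calibration$section_thickness, provenance = provenance)
}

#' Write result tables with a provenance manifest
#'
#' Writes one CSV per table plus a JSON manifest recording the file
#' list, a hash of the run configuration, the seed, and the package
#' version. Reruns with identical tables and config produce
#' byte-identical CSVs and manifest.
#'
#' @param tables named list of data frames, keyed by stage name.
#' @param out_dir output directory (created if needed).
#' @param config the run configuration (any JSON-serializable list);
#'   hashed into the manifest.
#' @param seed the run seed recorded in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables = list(), out_dir, config = list(),
                          seed = NA_integer_) {
  stopifnot(is.list(tables))
  if (length(tables) && (is.null(names(tables)) || any(names(tables) == ""))) {
    stop("`tables` must be keyed by stage name")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory: %s", out_dir))
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    files[nm] <- basename(f)
  }
  manifest <- list(files = as.list(files),
                   config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(packageVersion("arraytomo")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a pipeline configuration file
#'
#' YAML configuration with sections `channels`, `calibration`,
#' `segmentation`, `coloc`, `plaque`, `stats` (and optionally
#' `simulate`). See [run_pipeline()] for the schema.
#'
#' @param path path to a YAML file.
#' @return the configuration as a nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  yaml::read_yaml(path)
}

#' Write a binary mask as an 8-bit multi-page TIFF (0/255)
#'
#' @param bstack a [binary_stack()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_mask <- function(bstack, path) {
  stopifnot(inherits(bstack, "binary_stack"))
  pages <- lapply(seq_len(dim(bstack$mask)[3]),
                  function(s) (bstack$mask[, , s]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
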