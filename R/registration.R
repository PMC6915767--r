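#' Per-section rigid translations
#'
#' Ordered list of (dx, dy) pixel translations, one per section, with
#' the first section as the fixed reference (shift (0, 0)). x is the
#' column direction, y the row direction; positive values move content
#' toward larger indices.
#'
#' @param shifts numeric matrix `n_sections x 2` (columns dx, dy) or a
#'   2-column data frame.
#' @return an object of class `section_transforms`.
#' @export
section_transforms <- function(shifts) {
  shifts <- as.matrix(shifts)
  stopifnot(ncol(shifts) == 2L, nrow(shifts) >= 1L, all(is.finite(shifts)))
  if (any(abs(shifts[1, ]) > 1e-9)) {
    stop("first section is the reference and must have shift (0, 0)")
  }
  colnames(shifts) <- c("dx", "dy")
  structure(list(shifts = shifts), class = "section_transforms")
}

#' @export
print.section_transforms <- function(x, ...) {
  cat(sprintf("section_transforms: %d sections, max |shift| %.3f px\n",
              nrow(x$shifts), max(abs(x$shifts))))
  invisible(x)
}

#' Serialize transforms to CSV (section, dx, dy)
#' @param transforms a [section_transforms()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_transforms <- function(transforms, path) {
  df <- data.frame(section = seq_len(nrow(transforms$shifts)),
                   dx = transforms$shifts[, "dx"],
                   dy = transforms$shifts[, "dy"])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read transforms from CSV
#' @param path CSV with columns section, dx, dy.
#' @return a [section_transforms()].
#' @export
read_transforms <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[order(df$section), c("dx", "dy")])
  dimnames(m) <- list(NULL, c("dx", "dy"))
  section_transforms(m)
}

# Translate a 2D image by (dx, dy); integer shifts are pure index
# rolls (lossless); subpixel shifts use bilinear interpolation or an
# exact Fourier phase ramp (self-inverse, but rings at hard edges and
# wraps at the borders — the wrap band is marked invalid).
# Returns list(img, valid) where valid marks in-field pixels.
translate_image <- function(img, dx, dy, interpolation = "bilinear") {
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  if (abs(dx - round(dx)) < 1e-9 && abs(dy - round(dy)) < 1e-9) {
    dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
    src_r <- seq_len(d[1]) - dy
    src_c <- seq_len(d[2]) - dx
    ok_r <- src_r >= 1L & src_r <= d[1]
    ok_c <- src_c >= 1L & src_c <= d[2]
    if (any(ok_r) && any(ok_c)) {
      out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
      valid[which(ok_r), which(ok_c)] <- TRUE
    }
  } else if (interpolation == "fourier") {
    fr <- c(0:(ceiling(d[1] / 2) - 1), (-floor(d[1] / 2)):-1) / d[1]
    fc <- c(0:(ceiling(d[2] / 2) - 1), (-floor(d[2] / 2)):-1) / d[2]
    ramp <- exp(-2i * pi * (outer(fr * dy, fc * dx, "+")))
    out <- Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / length(img)
    valid[] <- TRUE
    mr <- ceiling(abs(dy)); mc <- ceiling(abs(dx))
    if (mr > 0) {
      band <- if (dy > 0) seq_len(mr) else d[1] - seq_len(mr) + 1L
      valid[band, ] <- FALSE
    }
    if (mc > 0) {
      band <- if (dx > 0) seq_len(mc) else d[2] - seq_len(mc) + 1L
      valid[, band] <- FALSE
    }
  } else {
    # inverse mapping with bilinear interpolation
    src_r <- seq_len(d[1]) - dy
    src_c <- seq_len(d[2]) - dx
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    ok_r <- r0 >= 1L & r0 + 1L <= d[1]
    ok_c <- c0 >= 1L & c0 + 1L <= d[2]
    ir <- which(ok_r); ic <- which(ok_c)
    if (length(ir) && length(ic)) {
      A <- img[r0[ir], c0[ic], drop = FALSE]
      B <- img[r0[ir], c0[ic] + 1L, drop = FALSE]
      C <- img[r0[ir] + 1L, c0[ic], drop = FALSE]
      D <- img[r0[ir] + 1L, c0[ic] + 1L, drop = FALSE]
      wr <- fr[ir]; wc <- fc[ic]
      out[ir, ic] <- (1 - wr) * ((1 - wc[col(A)]) * A + wc[col(A)] * B) +
        wr * ((1 - wc[col(A)]) * C + wc[col(A)] * D)
      valid[ir, ic] <- TRUE
    }
  }
  list(img = out, valid = valid)
}

# Upsampled cross-correlation refinement around an initial integer
# shift (matrix-multiply DFT); returns the refined (row, col)
# displacement of b relative to a.
.dftups <- function(inp, nor, noc, usfac, roff, coff) {
  nr <- nrow(inp); nc <- ncol(inp)
  fc <- c(0:(ceiling(nc / 2) - 1), (-floor(nc / 2)):-1)
  fr <- c(0:(ceiling(nr / 2) - 1), (-floor(nr / 2)):-1)
  kernc <- exp((-2i * pi / (nc * usfac)) * outer(fc, (0:(noc - 1)) - coff))
  kernr <- exp((-2i * pi / (nr * usfac)) * outer((0:(nor - 1)) - roff, fr))
  kernr %*% inp %*% kernc
}

# Displacement (drow, dcol) of image b relative to image a, i.e. b is a
# translated by (+drow, +dcol). Whitened phase correlation locates the
# integer peak robustly; the subpixel part refines the raw (unwhitened)
# cross-correlation on a locally upsampled grid, which is less
# noise-sensitive than refining the whitened surface.
phase_corr_shift <- function(a, b, upsample = 50) {
  d <- dim(a)
  FA <- stats::fft(a - mean(a))
  FB <- stats::fft(b - mean(b))
  R <- FA * Conj(FB)
  Rn <- R / (Mod(R) + 1e-12)
  cc <- Re(stats::fft(Rn, inverse = TRUE))
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- p - 1L
  sh <- ifelse(sh > d / 2, sh - d, sh)       # (row, col), wrap-corrected
  if (upsample > 1) {
    # refine in a 1.5 px neighborhood at 1/upsample resolution
    nw <- ceiling(1.5 * upsample)
    off <- floor(nw / 2)
    cc2 <- Mod(.dftups(Conj(R), nw, nw, upsample,
                       roff = off - sh[1] * upsample,
                       coff = off - sh[2] * upsample))
    p2 <- which(cc2 == max(cc2), arr.ind = TRUE)[1, ]
    sh <- sh + ((p2 - 1) - off) / upsample
  }
  # peak at +k means b = a shifted by -k; displacement of b is -sh
  -sh
}

#' Estimate per-section alignment shifts for a serial-section stack
#'
#' Pairwise displacements between nearby sections (lags 1 to
#' `max_lag`) are measured by phase correlation with subpixel
#' refinement, then composed into per-section shifts relative to the
#' first (reference) section by least squares over the chain. The
#' redundant longer-lag measurements cancel the drift that plain
#' predecessor chaining accumulates. The returned transforms are
#' *corrective*: applying them with [apply_transforms()] aligns the
#' stack.
#'
#' @param stack a [channel_stack()] with at least 2 sections.
#' @param reference_channel channel that drives alignment. Default: the
#'   nuclear stain (`"dapi"`) when present, else the presynaptic
#'   channel (`"synaptophysin"`), else the first channel.
#' @param upsample subpixel refinement factor. 1 = integer mode: shifts
#'   are whole pixels and, applied, are lossless; the right choice when
#'   misalignments are known to be whole-pixel.
#' @param max_lag largest section lag used for redundant pairwise
#'   measurements (capped at `n_sections - 1`).
#' @return a [section_transforms()] of corrective shifts.
#' @export
estimate_shifts <- function(stack, reference_channel = NULL, upsample = 50,
                            max_lag = 3L) {
  stopifnot(inherits(stack, "channel_stack"), max_lag >= 1L)
  if (is.null(reference_channel)) {
    cand <- c("dapi", "synaptophysin")
    reference_channel <- c(cand[cand %in% names(stack$channels)],
                           names(stack$channels)[1])[1]
  }
  if (!reference_channel %in% names(stack$channels)) {
    stop(sprintf("reference channel '%s' not present", reference_channel))
  }
  a <- stack$channels[[reference_channel]]
  ns <- dim(a)[3]
  if (ns < 2L) stop("need at least 2 sections to register")
  blank <- vapply(seq_len(ns), function(s) stats::sd(a[, , s]) == 0,
                  logical(1))
  if (any(blank)) {
    warning(sprintf("blank reference section(s) at %s: inheriting the predecessor's shift",
                    paste(which(blank), collapse = ", ")))
  }
  rows <- list(); rhs <- list()
  add_eq <- function(coef, d) {
    rows[[length(rows) + 1L]] <<- coef
    rhs[[length(rhs) + 1L]] <<- d
  }
  for (k in seq_len(min(max_lag, ns - 1L))) {
    for (s in (1L + k):ns) {
      coef <- rep(0, ns - 1L)
      coef[s - 1L] <- 1
      if (s - k > 1L) coef[s - k - 1L] <- -1
      if (blank[s]) {
        # a blank section carries its predecessor's shift
        if (k == 1L) add_eq(coef, c(0, 0))
        next
      }
      if (blank[s - k]) next                 # no signal to measure against
      add_eq(coef, phase_corr_shift(a[, , s - k], a[, , s],
                                    upsample = upsample))
    }
  }
  A <- do.call(rbind, rows)
  B <- do.call(rbind, rhs)
  cum <- rbind(c(0, 0), qr.solve(A, B))      # displacement vs section 1
  if (upsample <= 1) cum <- round(cum)       # integer mode stays integer
  corr <- -cum                               # corrective shift
  # (drow, dcol) -> (dx, dy)
  section_transforms(cbind(dx = corr[, 2], dy = corr[, 1]))
}

#' Apply per-section translations to every channel of a stack
#'
#' All channels are shifted identically. Integer shifts are lossless
#' index rolls; non-integer shifts use bilinear interpolation.
#' Out-of-field pixels are zero-filled and recorded in a valid-region
#' mask.
#'
#' @param stack a [channel_stack()].
#' @param transforms a [section_transforms()] with one row per section.
#' @param interpolation `"bilinear"` (default; local, no ringing) or
#'   `"fourier"` (exact phase-ramp shift, perfectly self-inverse).
#'   Whole-pixel shifts always use lossless index rolls.
#' @return `list(stack = shifted channel_stack, valid = logical array
#'   [row, col, section] marking in-field voxels)`.
#' @export
apply_transforms <- function(stack, transforms,
                             interpolation = c("bilinear", "fourier")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(stack, "channel_stack"),
            inherits(transforms, "section_transforms"))
  sh <- transforms$shifts
  d <- dim(stack$channels[[1]])
  if (nrow(sh) != d[3]) {
    stop(sprintf("transforms have %d rows but stack has %d sections",
                 nrow(sh), d[3]))
  }
  valid <- array(TRUE, d)
  out <- stack$channels
  for (s in seq_len(d[3])) {
    if (all(abs(sh[s, ]) < 1e-12)) next
    for (ch in names(out)) {
      tr <- translate_image(out[[ch]][, , s], sh[s, "dx"], sh[s, "dy"],
                            interpolation = interpolation)
      out[[ch]][, , s] <- tr$img
      valid[, , s] <- valid[, , s] & tr$valid
    }
  }
  list(stack = channel_stack(out, stack$pixel_size_xy,
                             stack$section_thickness,
                             provenance = stack$provenance),
       valid = valid)
}

#' Invert a set of section transforms
#' @param transforms a [section_transforms()].
#' @return a [section_transforms()] with negated shifts.
#' @export
invert_transforms <- function(transforms) {
  section_transforms(-transforms$shifts)
}
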