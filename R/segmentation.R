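# Automatic threshold algorithms. Each works on a 256-bin histogram of
# the min-max normalized image, so linear intensity gain leaves the
# selected foreground unchanged.

.threshold_otsu <- function(img) {
  rng <- range(img)
  x01 <- (img - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1), levels = 256)
  rng[1] + thr01 * (rng[2] - rng[1])
}

# Triangle method (Zack): line from the histogram peak to the far end of
# the bright tail; threshold at the bin of maximum perpendicular
# distance below the line. Suited to skewed histograms where the
# foreground is a small bright tail.
.threshold_triangle <- function(img) {
  rng <- range(img)
  br <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(img, br, rightmost.closed = TRUE), nbins = 256L)
  pk <- which.max(h)
  tail_end <- max(which(h > 0))
  if (tail_end <= pk) return(rng[2])          # no bright tail
  i <- pk:tail_end
  # distance of the histogram below the line from (peak, h[peak]) to
  # (tail end, 0), in normalized coordinates
  hx <- (i - pk) / (tail_end - pk)
  hy <- h[i] / h[pk]
  dist <- (1 - hx) - hy
  t_bin <- i[which.max(dist)]
  (br[t_bin] + br[t_bin + 1L]) / 2
}

# Lower threshold of three-class (two-threshold) Otsu: separates tissue
# background from all signal when the signal itself is bimodal (e.g. a
# pan-amyloid channel whose plaques have a dim oligomeric halo and a
# bright fibrillar core, which defeats single-threshold Otsu).
.threshold_multiotsu <- function(img) {
  rng <- range(img)
  br <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(img, br, rightmost.closed = TRUE), nbins = 256L)
  h <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  W <- cumsum(h); M <- cumsum(h * mids); mt <- M[256]
  best <- -Inf; t1 <- rng[2]
  for (i in 1:254) {
    w1 <- W[i]
    if (w1 <= 0) next
    j <- (i + 1):255
    w2 <- W[j] - W[i]; w3 <- 1 - W[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m1 <- M[i] / w1
    m2 <- (M[j] - M[i]) / w2; m3 <- (mt - M[j]) / w3
    v <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
    v[!ok] <- -Inf
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; t1 <- mids[i] }
  }
  t1
}

.threshold_methods <- list(otsu = .threshold_otsu,
                           triangle = .threshold_triangle,
                           multiotsu = .threshold_multiotsu)

#' Compute an automatic threshold for one image
#'
#' @param img numeric matrix.
#' @param method `"otsu"` or `"triangle"`.
#' @return threshold value (foreground is `img > threshold`).
#' @export
auto_threshold <- function(img, method = "otsu") {
  if (!method %in% names(.threshold_methods)) {
    stop(sprintf("unknown threshold method '%s'; supported: %s", method,
                 paste(names(.threshold_methods), collapse = ", ")))
  }
  if (diff(range(img)) == 0) return(Inf)      # constant image: nothing above
  .threshold_methods[[method]](img)
}

#' Binarize one section with a union of auto-threshold algorithms
#'
#' The mask is the union of the foregrounds selected by each method,
#' which captures both bright puncta (global bimodal methods) and dim
#' puncta (tail-sensitive methods) in one unbiased pass. In-plane
#' connected components (8-connectivity) smaller than `min_object_px`
#' are removed.
#'
#' @param img numeric matrix (one section of one channel).
#' @param methods character vector of method names; see
#'   [auto_threshold()].
#' @param min_object_px minimum 2D component size in pixels.
#' @param max_foreground a method whose foreground would exceed this
#'   fraction of the section has degenerated (split within the
#'   background of an effectively signal-free image, as global
#'   bimodal methods do); its contribution is dropped. Puncta occupy a
#'   few percent of a section, so the default 0.25 never binds on real
#'   signal.
#' @param min_contrast_mads when > 0, the section's foreground must be
#'   separated from its background: the median foreground intensity
#'   must exceed the median background intensity by at least this many
#'   background MADs, else the section is declared signal-free and its
#'   mask emptied. Protects channels that may carry no signal at all
#'   (auto-threshold methods always split *something*).
#' @return logical matrix mask. A constant image yields an empty mask.
#' @export
binarize_section <- function(img, methods = c("otsu", "triangle"),
                             min_object_px = 2L, max_foreground = 0.25,
                             min_contrast_mads = 0) {
  stopifnot(is.matrix(img), length(methods) >= 1L)
  mask <- matrix(FALSE, nrow(img), ncol(img))
  for (m in methods) {
    thr <- auto_threshold(img, m)
    fg <- img > thr
    if (mean(fg) > max_foreground) {
      at_log("method '%s' degenerate on this section (%.0f%% foreground), dropped",
             m, 100 * mean(fg), level = "debug")
      next
    }
    mask <- mask | fg
  }
  if (min_contrast_mads > 0 && any(mask)) {
    bg <- img[!mask]
    scale <- max(stats::mad(bg), 1e-9)
    if (stats::median(img[mask]) - stats::median(bg) <
        min_contrast_mads * scale) {
      at_log("section foreground indistinct from background, emptied",
             level = "debug")
      mask[] <- FALSE
    }
  }
  if (min_object_px > 1L && any(mask)) {
    lab <- label_components(mask, link_sections = FALSE)[, , 1]
    sz <- tabulate(lab[lab > 0L])
    mask <- mask & array(sz[pmax(lab, 1L)] >= min_object_px &
                           lab > 0L, dim(lab))
  }
  mask
}

#' Binarize one channel of a stack, section by section
#'
#' Thresholds are computed independently per section, which makes the
#' segmentation robust to section-to-section staining variation, and
#' means permuting sections permutes the masks identically.
#'
#' @param stack a registered [channel_stack()].
#' @param channel channel name to binarize.
#' @param methods,min_object_px,max_foreground passed to
#'   [binarize_section()].
#' @return a [binary_stack()].
#' @export
binarize_stack <- function(stack, channel, methods = c("otsu", "triangle"),
                           min_object_px = 2L, max_foreground = 0.25,
                           min_contrast_mads = 0) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!channel %in% names(stack$channels)) {
    stop(sprintf("channel '%s' not present in stack", channel))
  }
  a <- stack$channels[[channel]]
  d <- dim(a)
  mask <- array(FALSE, d)
  for (s in seq_len(d[3])) {
    mask[, , s] <- binarize_section(a[, , s], methods = methods,
                                    min_object_px = min_object_px,
                                    max_foreground = max_foreground,
                                    min_contrast_mads = min_contrast_mads)
  }
  binary_stack(mask, channel, stack$pixel_size_xy, stack$section_thickness)
}
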