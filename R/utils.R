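#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois rbinom median aggregate complete.cases
#' @importFrom utils write.csv packageVersion head tail
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Simple leveled logger; level set via options(arraytomo.log_level=).
.log_levels <- c(debug = 1L, info = 2L, warning = 3L, quiet = 4L)

at_log <- function(msg, ..., level = "info") {
  thr <- getOption("arraytomo.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]]) {
    message(sprintf("[arraytomo %s] %s", level, sprintf(msg, ...)))
  }
  invisible(NULL)
}

# Stable hash of an R object (config provenance): canonical JSON -> md5.
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Label connected voxel components in a binary stack
#'
#' Foreground voxels are connected with 8-connectivity within a section
#' (in-plane) and, optionally, to the voxel at the same (row, col) in the
#' next section(s). This is the linkage rule used for 3D puncta
#' reconstruction: two in-plane components in consecutive sections belong
#' to the same 3D object iff their xy footprints share at least one pixel.
#'
#' @param mask logical 3D array `[row, col, section]` (a 2D matrix is
#'   treated as a single section).
#' @param link_sections link voxels across consecutive sections
#'   (same xy position)? `FALSE` gives independent 2D labeling per section.
#' @param gap_tolerance number of missing sections tolerated when linking
#'   across sections (0 = strictly consecutive).
#' @return integer array of the same shape; 0 = background, objects
#'   labeled 1..n in first-voxel order.
#' @export
label_components <- function(mask, link_sections = TRUE, gap_tolerance = 0L) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  stopifnot(length(dim(mask)) == 3L, gap_tolerance >= 0L)
  mask <- mask != 0
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  id <- array(0L, d)
  id[idx] <- seq_along(idx)

  offsets <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L))
  if (link_sections && d[3] > 1L) {
    for (ds in seq_len(min(gap_tolerance + 1L, d[3] - 1L))) {
      offsets <- c(offsets, list(c(0L, 0L, ds)))
    }
  }
  edges <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    o <- offsets[[k]]
    r1 <- max(1L, 1L - o[1]):min(d[1], d[1] - o[1])
    c1 <- max(1L, 1L - o[2]):min(d[2], d[2] - o[2])
    s1 <- max(1L, 1L - o[3]):min(d[3], d[3] - o[3])
    a <- id[r1, c1, s1, drop = FALSE]
    b <- id[r1 + o[1], c1 + o[2], s1 + o[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    edges[[k]] <- rbind(a[keep], b[keep])
  }
  ee <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(ee), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel so components are numbered by first occurrence
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  lab[idx] <- remap[memb]
  lab
}
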