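#' Open-field trajectory
#'
#' An ordered series of (time, x, y) samples inside a square arena.
#' Times must be strictly increasing; positions outside the arena are
#' clipped to its bounds with a warning.
#'
#' @param samples data frame with columns `t_s`, `x_cm`, `y_cm`.
#' @param arena_cm arena side length (cm); the standard box is 40 cm
#'   with a centred 20 x 20 cm inner zone.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(samples, arena_cm = 40) {
  stopifnot(is.data.frame(samples),
            all(c("t_s", "x_cm", "y_cm") %in% names(samples)),
            arena_cm > 0)
  if (nrow(samples) >= 2L && any(diff(samples$t_s) <= 0)) {
    stop("sample times must be strictly increasing")
  }
  out_of_bounds <- samples$x_cm < 0 | samples$x_cm > arena_cm |
    samples$y_cm < 0 | samples$y_cm > arena_cm
  if (any(out_of_bounds)) {
    warning(sprintf("%d sample(s) outside the arena were clipped",
                    sum(out_of_bounds)))
    samples$x_cm <- pmin(pmax(samples$x_cm, 0), arena_cm)
    samples$y_cm <- pmin(pmax(samples$y_cm, 0), arena_cm)
  }
  structure(list(samples = samples[, c("t_s", "x_cm", "y_cm")],
                 arena_cm = arena_cm),
            class = "trajectory")
}

#' Read a trajectory from CSV (t_s, x_cm, y_cm)
#' @param path CSV file path.
#' @param arena_cm arena side length (cm).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, arena_cm = 40) {
  trajectory(utils::read.csv(path), arena_cm = arena_cm)
}

#' Write a trajectory to CSV
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  write.csv(traj$samples, path, row.names = FALSE)
  invisible(path)
}

#' Total distance traveled
#'
#' Sum of Euclidean distances between consecutive samples.
#'
#' @param traj a [trajectory()].
#' @return distance in cm (0, with a warning, for fewer than 2 samples).
#' @export
total_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  s <- traj$samples
  if (nrow(s) < 2L) {
    warning("fewer than 2 samples: distance is 0")
    return(0)
  }
  sum(sqrt(diff(s$x_cm)^2 + diff(s$y_cm)^2))
}

# TRUE when a point lies in the centred inner zone (square of side
# `inner_cm`). Points exactly on the zone boundary count as inner.
.in_inner_zone <- function(x, y, arena_cm, inner_cm) {
  half <- inner_cm / 2; ctr <- arena_cm / 2
  pmax(abs(x - ctr), abs(y - ctr)) <= half
}

#' Inner/outer zone metrics of an open-field trajectory
#'
#' The arena is split into a centred inner square (default 20 x 20 cm
#' in the 40 cm box) and the surrounding outer segment. Each step is
#' assigned to the zone of its starting sample, so inner and outer
#' distances sum exactly to the total distance; likewise occupancy time
#' fractions sum to 1.
#'
#' @param traj a [trajectory()].
#' @param inner_zone_cm inner zone side length (cm).
#' @return list: `total_cm`, `inner_dist_cm`, `outer_dist_cm`,
#'   `inner_time_frac`, `outer_time_frac`.
#' @export
zone_metrics <- function(traj, inner_zone_cm = 20) {
  stopifnot(inherits(traj, "trajectory"), inner_zone_cm < traj$arena_cm)
  s <- traj$samples
  if (nrow(s) < 2L) {
    warning("fewer than 2 samples: zone metrics are 0")
    return(list(total_cm = 0, inner_dist_cm = 0, outer_dist_cm = 0,
                inner_time_frac = NA_real_, outer_time_frac = NA_real_))
  }
  step <- sqrt(diff(s$x_cm)^2 + diff(s$y_cm)^2)
  dt <- diff(s$t_s)
  inner_start <- .in_inner_zone(s$x_cm, s$y_cm, traj$arena_cm,
                                inner_zone_cm)[-nrow(s)]
  inner_d <- sum(step[inner_start])
  outer_d <- sum(step[!inner_start])
  inner_t <- sum(dt[inner_start]) / sum(dt)
  list(total_cm = inner_d + outer_d,
       inner_dist_cm = inner_d,
       outer_dist_cm = outer_d,
       inner_time_frac = inner_t,
       outer_time_frac = 1 - inner_t)
}
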