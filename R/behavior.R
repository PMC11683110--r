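# Open-field behavior metrics: total ambulation, percentage of ambulation
# in the central zone, rearing count, and their post-minus-pre changes.

#' Construct a trajectory object
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param x,y Positions in cm, within `[0, arena_side]`.
#' @param rearing_times Rearing event timestamps in seconds.
#' @param arena_side Arena side length in cm (default 40).
#' @return A `trajectory` object.
#' @export
as_trajectory <- function(times, x, y, rearing_times = numeric(0),
                          arena_side = 40) {
  stopifnot(length(times) == length(x), length(x) == length(y),
            arena_side > 0)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(x < 0 | x > arena_side | y < 0 | y > arena_side))
    stop("positions outside the arena bounds")
  structure(list(times = times, x = x, y = y,
                 rearing_times = sort(rearing_times),
                 arena_side = arena_side),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Open-field trajectory: %d positions over %.1f s, %d rearing event(s), %g cm arena\n",
              length(x$times), diff(range(x$times)),
              length(x$rearing_times), x$arena_side))
  invisible(x)
}

#' The central analysis zone of the arena
#'
#' Default convention: a centred square with half the arena's linear
#' dimension (20 x 20 cm in a 40 x 40 cm arena).
#'
#' @param arena_side Arena side length in cm.
#' @param fraction Linear fraction of the arena covered by the zone.
#' @return List with `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
central_zone <- function(arena_side = 40, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  half <- arena_side * fraction / 2
  c0 <- arena_side / 2
  list(xmin = c0 - half, xmax = c0 + half, ymin = c0 - half, ymax = c0 + half)
}

#' Total ambulation (path length)
#'
#' Sum of Euclidean distances between consecutive trajectory samples.
#'
#' @param traj A `trajectory`.
#' @return Path length in cm (0 for a single point).
#' @export
path_length <- function(traj) {
  n <- length(traj$x)
  if (n < 2) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Percentage of ambulation inside the central zone
#'
#' Each step is assigned to the zone containing its midpoint; the metric is
#' 100 times the zone path length over the total path length (0 when the
#' animal never moves).
#'
#' @param traj A `trajectory`.
#' @param zone Zone rectangle (default [central_zone()] of the trajectory's
#'   arena).
#' @return Percentage in \[0, 100\].
#' @export
central_ambulation_pct <- function(traj, zone = central_zone(traj$arena_side)) {
  n <- length(traj$x)
  if (n < 2) return(0)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  total <- sum(steps)
  if (total == 0) return(0)
  mx <- (traj$x[-1] + traj$x[-n]) / 2
  my <- (traj$y[-1] + traj$y[-n]) / 2
  inside <- mx >= zone$xmin & mx <= zone$xmax &
    my >= zone$ymin & my <= zone$ymax
  100 * sum(steps[inside]) / total
}

#' Number of rearing events within the recording
#'
#' Events outside `[0, duration]` (trailing annotation spill-over) are
#' excluded.
#'
#' @param traj A `trajectory`.
#' @param duration Recording duration in s (default: last sample time).
#' @return Integer count.
#' @export
rearing_count <- function(traj, duration = max(traj$times)) {
  sum(traj$rearing_times >= 0 & traj$rearing_times <= duration)
}

#' All three open-field indices of one trajectory
#'
#' @param traj A `trajectory`.
#' @param zone Central zone rectangle.
#' @return A `behavior_metrics` list: `total_ambulation` (cm),
#'   `central_pct` (%), `rearing_count`.
#' @export
behavior_metrics <- function(traj, zone = central_zone(traj$arena_side)) {
  structure(list(total_ambulation = path_length(traj),
                 central_pct = central_ambulation_pct(traj, zone),
                 rearing_count = rearing_count(traj)),
            class = "behavior_metrics")
}

#' Post-minus-pre behavioral changes
#'
#' @param post,pre `behavior_metrics` objects.
#' @return Named numeric vector of componentwise differences.
#' @export
behavior_change <- function(post, pre) {
  c(total_ambulation = post$total_ambulation - pre$total_ambulation,
    central_pct = post$central_pct - pre$central_pct,
    rearing_count = post$rearing_count - pre$rearing_count)
}
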