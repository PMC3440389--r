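#' Agent behavioural states
#'
#' The six states of the forager state machine, in update order: `idle`
#' (inside the nest, leaves with probability `leave_prob` per step),
#' `searching` (random walk, or trail following when above-threshold
#' pheromone lies in the forward cone), `feeding` (stationary on a patch for
#' `drinking_time` steps), `dissatisfied` (reached a patch already at its
#' crowding threshold; random-walks ignoring and not laying pheromone, until
#' it enters any open patch with free capacity), `recruiting` (crop full,
#' homing on the nest-scent gradient while depositing pheromone on every cell
#' entered) and `unloading` (stationary in the nest for `unloading_time`
#' steps, then idle again).
#'
#' @format character vector of the six state names.
#' @export
AGENT_STATES <- c("idle", "searching", "feeding", "dissatisfied",
                  "recruiting", "unloading")

#' Forward gradient sensing
#'
#' An agent samples the three cells one step ahead at 0 and +/-45 degrees of
#' its heading and turns toward the walkable cell with the greatest field
#' value, provided that value exceeds `threshold`; ties among maxima are
#' broken uniformly at random. Used by searching agents on the pheromone
#' field (threshold = detection threshold) and by recruiters on the
#' nest-scent field (no threshold). This calls the same compiled routine the
#' simulation engine runs.
#'
#' @param world an `ant_world`.
#' @param field matrix of field values with the world's dimensions (e.g.
#'   `world$pheromone` or `world$nest_scent`).
#' @param position numeric `c(x, y)` continuous coordinates; the occupied
#'   cell is the integer floor of each coordinate.
#' @param heading direction index 0..7 (multiples of 45 degrees,
#'   0 = +x, 2 = +y).
#' @param threshold minimum detectable field value (`-Inf` for none).
#' @return the chosen absolute direction 0..7, or `NA` if no forward cell
#'   qualifies.
#' @export
sense_forward <- function(world, field, position, heading,
                          threshold = -Inf) {
  stopifnot(inherits(world, "ant_world"), heading %in% 0:7)
  if (!is_walkable(world, floor(position)))
    stop("position is outside the walkable region", call. = FALSE)
  f <- field
  f[is.na(f)] <- -1e18
  d <- cpp_sense_forward(world$region, f, world$x0, world$y0,
                         position[1], position[2], as.integer(heading),
                         threshold)
  if (d < 0) NA_integer_ else d
}

#' Admissible movement directions
#'
#' The subset of the 8 compass directions whose one-cell-length destination
#' stays on the walkable region from a given continuous position. Random
#' walks draw uniformly from this set; an agent boxed in on all sides (never
#' the case on the default maze) reverses its heading instead.
#'
#' @inheritParams sense_forward
#' @return integer vector of direction indices 0..7.
#' @export
admissible_directions <- function(world, position) {
  stopifnot(inherits(world, "ant_world"))
  cpp_admissible_dirs(world$region, world$x0, world$y0,
                      position[1], position[2])
}

#' Unit step vector of a compass direction
#'
#' Direction `k` is `k * 45` degrees from the +x axis; every step has length
#' exactly 1 cell independent of direction (movement is off-lattice).
#'
#' @param direction integer 0..7.
#' @return numeric `c(dx, dy)` of unit length.
#' @export
direction_vector <- function(direction) {
  stopifnot(all(direction %in% 0:7))
  ang <- direction * pi / 4
  c(dx = cos(ang), dy = sin(ang))
}
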