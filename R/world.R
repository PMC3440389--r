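#' T-maze geometry
#'
#' Describes the discrete T-maze arena: a nest block at the base of a vertical
#' stem that ends in a horizontal crossbar carrying one arm on each side, with
#' a square food patch at the distal end of each arm. All dimensions are in
#' cell lengths (one cell ~ one ant body length; one simulated step crosses
#' one cell). The default dimensions put each patch centre roughly 40 walked
#' cells from the nest centre, so a direct return trip takes about 40 steps
#' at speed 1.
#'
#' @param stem_length stem length in cells (default 24).
#' @param stem_width stem width in cells (default 5).
#' @param arm_length length of each arm in cells (default 11).
#' @param arm_width arm (crossbar) width in cells (default 4).
#' @param nest_width,nest_depth nest block dimensions (default 5 x 4).
#' @param patch_size side of the square food patch (default 4).
#' @param stem_multiplier,arm_multiplier integer length multipliers in 1..10
#'   used by the geometry sensitivity sweeps (stem x10 or arm x6 correspond
#'   to roughly 2 m in the real arena).
#' @return an object of class `maze_geometry`.
#' @examples
#' g <- maze_geometry()
#' w <- build_world(g)
#' table(world_df(w)$region)
#' @export
maze_geometry <- function(stem_length = 24, stem_width = 5,
                          arm_length = 11, arm_width = 4,
                          nest_width = 5, nest_depth = 4,
                          patch_size = 4,
                          stem_multiplier = 1, arm_multiplier = 1) {
  g <- list(
    stem_length = as.integer(stem_length), stem_width = as.integer(stem_width),
    arm_length = as.integer(arm_length), arm_width = as.integer(arm_width),
    nest_width = as.integer(nest_width), nest_depth = as.integer(nest_depth),
    patch_size = as.integer(patch_size),
    stem_multiplier = as.integer(stem_multiplier),
    arm_multiplier = as.integer(arm_multiplier)
  )
  dims <- unlist(g[c("stem_length", "stem_width", "arm_length", "arm_width",
                     "nest_width", "nest_depth", "patch_size")])
  if (any(is.na(dims)) || any(dims < 1L))
    stop("all maze dimensions must be >= 1 cell", call. = FALSE)
  mult <- c(g$stem_multiplier, g$arm_multiplier)
  if (any(is.na(mult)) || any(mult < 1L) || any(mult > 10L))
    stop("stem/arm multipliers must be integers in 1..10", call. = FALSE)
  class(g) <- "maze_geometry"
  g
}

# region codes shared with the C++ engine (0 = not walkable)
REGION_CODES <- c(nest = 1L, stem = 2L, left_arm = 3L, right_arm = 4L,
                  patch_1 = 5L, patch_2 = 6L)

#' Pheromone field parameters
#'
#' @param deposit_amount pheromone units laid per cell crossing by a returning
#'   recruiter (default 60).
#' @param decay_rate evaporation rate r in percent per time step; each step
#'   every cell's amount is multiplied by `(100 - r)/100` (default 0.4, an
#'   exponential decay that takes an established trail below the detection
#'   threshold in roughly 45 simulated minutes).
#' @param detection_threshold minimum per-cell amount a searching agent can
#'   sense (default 0.05).
#' @param diffusion_rate fraction of each cell's pheromone spread equally
#'   toward its 8 neighbours per step (shares toward non-walkable cells are
#'   lost at the walls). A modest lateral spread lets the field carry a
#'   cross-trail gradient, which is what allows a trail follower's 3-cell
#'   forward cone to resolve the left/right fork at the maze junction by
#'   relative trail strength; see the package vignette for the rationale and
#'   calibration.
#' @return an object of class `pheromone_params`.
#' @export
pheromone_params <- function(deposit_amount = 60, decay_rate = 0.4,
                             detection_threshold = 0.05,
                             diffusion_rate = 0.05) {
  if (!is.finite(deposit_amount) || deposit_amount <= 0)
    stop("deposit_amount must be > 0", call. = FALSE)
  if (!is.finite(decay_rate) || decay_rate < 0 || decay_rate > 100)
    stop("decay_rate must lie in [0, 100] percent per step", call. = FALSE)
  if (!is.finite(detection_threshold) || detection_threshold <= 0)
    stop("detection_threshold must be > 0", call. = FALSE)
  if (!is.finite(diffusion_rate) || diffusion_rate < 0 || diffusion_rate > 1)
    stop("diffusion_rate must lie in [0, 1]", call. = FALSE)
  structure(list(deposit_amount = deposit_amount, decay_rate = decay_rate,
                 detection_threshold = detection_threshold,
                 diffusion_rate = diffusion_rate),
            class = "pheromone_params")
}

#' Build the T-maze world
#'
#' Lays out the walkable region on an integer cell grid (origin at the nest
#' centre cell, x increasing to the right, y increasing up the stem), assigns
#' each cell to exactly one region (nest, stem, left/right arm, patch 1 left,
#' patch 2 right), initialises the static nest-scent field
#' `scent(X) = 100 - d(X_nest, X)` (Euclidean distance between cell centres)
#' and a zero pheromone field. Junction cells where the stem meets the
#' crossbar belong to the stem region, so the two arms are mirror images and
#' per-arm pheromone sums are symmetric by construction.
#'
#' @param geometry a [maze_geometry()].
#' @return an object of class `ant_world`: matrices `region`, `nest_scent`,
#'   `pheromone` indexed as `[x - x0 + 1, y - y0 + 1]`, offsets `x0`, `y0`,
#'   the nest/patch centre coordinates, and `patch_available_from` (time step
#'   from which each patch offers food; both 0 until an experiment sets a
#'   delay).
#' @export
build_world <- function(geometry = maze_geometry()) {
  stopifnot(inherits(geometry, "maze_geometry"))
  g <- geometry
  Ls <- g$stem_length * g$stem_multiplier
  La <- g$arm_length * g$arm_multiplier
  half_sw <- (g$stem_width - 1L) %/% 2L
  stem_x <- seq(-half_sw, -half_sw + g$stem_width - 1L)
  half_nw <- (g$nest_width - 1L) %/% 2L
  nest_x <- seq(-half_nw, -half_nw + g$nest_width - 1L)

  x_min <- min(-max(half_sw, half_nw) - La - g$patch_size, min(nest_x))
  x_max <- max(max(stem_x) + La + g$patch_size, max(nest_x))
  y_min <- -g$nest_depth
  y_max <- Ls - 1L
  x0 <- x_min; y0 <- y_min
  nx <- x_max - x_min + 1L
  ny <- y_max - y_min + 1L

  region <- matrix(0L, nx, ny)
  idx <- function(x, y) cbind(x - x0 + 1L, y - y0 + 1L)
  fill <- function(xs, ys, code) {
    cells <- expand.grid(x = xs, y = ys)
    region[idx(cells$x, cells$y)] <<- code
  }

  fill(nest_x, seq(-g$nest_depth, -1L), REGION_CODES[["nest"]])
  fill(stem_x, seq(0L, Ls - 1L), REGION_CODES[["stem"]])
  # the crossbar overlaps the top arm_width rows of the stem: the arms attach
  # to the sides of the stem head (the junction cells belong to the stem), so
  # the two return lanes cross the stem's climb column with lateral
  # separation and a trail-following searcher's forward cone can compare them
  bar_y <- seq(Ls - g$arm_width, Ls - 1L)
  left_arm_x <- seq(min(stem_x) - La, min(stem_x) - 1L)
  right_arm_x <- seq(max(stem_x) + 1L, max(stem_x) + La)
  fill(left_arm_x, bar_y, REGION_CODES[["left_arm"]])
  fill(right_arm_x, bar_y, REGION_CODES[["right_arm"]])
  patch_y <- seq(Ls - g$patch_size, Ls - 1L)
  p1_x <- seq(min(left_arm_x) - g$patch_size, min(left_arm_x) - 1L)
  p2_x <- seq(max(right_arm_x) + 1L, max(right_arm_x) + g$patch_size)
  fill(p1_x, patch_y, REGION_CODES[["patch_1"]])
  fill(p2_x, patch_y, REGION_CODES[["patch_2"]])

  nest_centre <- c(x = nest_x[ceiling(length(nest_x) / 2)],
                   y = -ceiling(g$nest_depth / 2))
  centre_of <- function(xs, ys) c(x = mean(xs) + 0.5, y = mean(ys) + 0.5)
  patch_centres <- rbind(centre_of(p1_x, patch_y), centre_of(p2_x, patch_y))

  # nest scent: 100 - Euclidean distance between cell centres; NA off-maze
  xs <- (x_min:x_max) + 0.5
  ys <- (y_min:y_max) + 0.5
  ncx <- nest_centre[["x"]] + 0.5
  ncy <- nest_centre[["y"]] + 0.5
  dist <- sqrt(outer((xs - ncx)^2, (ys - ncy)^2, `+`))
  nest_scent <- 100 - dist
  nest_scent[region == 0L] <- NA_real_

  structure(list(
    region = region, nest_scent = nest_scent,
    pheromone = matrix(0, nx, ny),
    x0 = x0, y0 = y0,
    nest_centre = nest_centre,
    patch_centres = patch_centres,
    patch_available_from = c(0L, 0L),
    geometry = g
  ), class = "ant_world")
}

#' @export
print.ant_world <- function(x, ...) {
  cat("<ant_world> ", sum(x$region > 0L), " walkable cells, grid ",
      nrow(x$region), "x", ncol(x$region), "\n", sep = "")
  cat("  regions:",
      paste(names(REGION_CODES),
            tabulate(x$region[x$region > 0L], 6L), collapse = " "), "\n")
  invisible(x)
}

cell_index <- function(world, cell) {
  cbind(cell[1] - world$x0 + 1L, cell[2] - world$y0 + 1L)
}

#' Is a cell walkable?
#'
#' @param world an `ant_world`.
#' @param cell integer `c(x, y)` cell coordinates.
#' @return logical.
#' @export
is_walkable <- function(world, cell) {
  i <- cell[1] - world$x0 + 1L; j <- cell[2] - world$y0 + 1L
  if (i < 1L || j < 1L || i > nrow(world$region) || j > ncol(world$region))
    return(FALSE)
  world$region[i, j] > 0L
}

#' Region label of a cell
#'
#' @inheritParams is_walkable
#' @return one of `"nest"`, `"stem"`, `"left_arm"`, `"right_arm"`,
#'   `"patch_1"`, `"patch_2"`, or `NA` off the maze.
#' @export
region_of_cell <- function(world, cell) {
  if (!is_walkable(world, cell)) return(NA_character_)
  names(REGION_CODES)[world$region[cell_index(world, cell)]]
}

#' Deposit pheromone on one cell
#'
#' Adds the full per-crossing amount to a single cell; deposits are purely
#' additive (no per-step cap).
#'
#' @param world an `ant_world`.
#' @param cell integer `c(x, y)`; must be walkable.
#' @param params a [pheromone_params()].
#' @return the world with the updated pheromone field.
#' @export
deposit <- function(world, cell, params = pheromone_params()) {
  if (!is_walkable(world, cell))
    stop("cannot deposit pheromone on a non-walkable cell", call. = FALSE)
  world$pheromone[cell_index(world, cell)] <-
    world$pheromone[cell_index(world, cell)] + params$deposit_amount
  world
}

#' Apply one global evaporation step
#'
#' Multiplies every cell's pheromone by `(100 - r)/100` simultaneously, the
#' per-step exponential decay with rate `r` percent.
#'
#' @inheritParams deposit
#' @return the world with the decayed field.
#' @export
decay_step <- function(world, params = pheromone_params()) {
  r <- params$decay_rate
  if (r < 0 || r > 100)
    stop("decay_rate must lie in [0, 100]", call. = FALSE)
  world$pheromone <- world$pheromone * (100 - r) / 100
  world
}

#' Is a food patch open at time t?
#'
#' A patch offers food from its availability step onward; before that a
#' searching agent walks straight through it (no feeding, no dissatisfaction).
#'
#' @param world an `ant_world`.
#' @param patch_id 1 or 2.
#' @param t time step (>= 0).
#' @return logical.
#' @export
patch_is_open <- function(world, patch_id, t) {
  stopifnot(patch_id %in% c(1L, 2L))
  t >= world$patch_available_from[patch_id]
}

#' World snapshot as a data frame
#'
#' One row per walkable cell with columns `x`, `y`, `region`, `pheromone`,
#' `nest_scent`; suitable for writing to CSV.
#'
#' @param world an `ant_world`.
#' @return a data.frame.
#' @export
world_df <- function(world) {
  walk <- which(world$region > 0L, arr.ind = TRUE)
  data.frame(
    x = walk[, 1] + world$x0 - 1L,
    y = walk[, 2] + world$y0 - 1L,
    region = names(REGION_CODES)[world$region[walk]],
    pheromone = world$pheromone[walk],
    nest_scent = world$nest_scent[walk]
  )
}
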