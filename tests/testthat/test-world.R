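test_that("default maze has the documented region sizes", {
  w <- build_world()
  df <- world_df(w)
  counts <- table(df$region)
  # stem proper is 24 x 5; the 4 x 5 junction block where the crossbar
  # overlaps the stem head is assigned to the stem region
  expect_equal(unname(counts[["stem"]]), 24 * 5)
  expect_equal(unname(counts[["left_arm"]]), 11 * 4)
  expect_equal(unname(counts[["right_arm"]]), 11 * 4)
  expect_equal(unname(counts[["patch_1"]]), 16)
  expect_equal(unname(counts[["patch_2"]]), 16)
  expect_equal(unname(counts[["nest"]]), 20)
  # every walkable cell has exactly one region
  expect_false(any(is.na(df$region)))
})

test_that("nest scent peaks at the nest centre and decreases with distance", {
  w <- build_world()
  nc <- w$nest_centre
  expect_equal(w$nest_scent[nc[["x"]] - w$x0 + 1, nc[["y"]] - w$y0 + 1], 100)
  df <- world_df(w)
  d <- sqrt((df$x + 0.5 - (nc[["x"]] + 0.5))^2 +
            (df$y + 0.5 - (nc[["y"]] + 0.5))^2)
  expect_equal(df$nest_scent, 100 - d)
  # monotone: strictly farther cells always carry strictly less scent
  o <- order(d)
  expect_true(all(diff(df$nest_scent[o]) <= 1e-12))
})

test_that("walkable region is connected from nest to both patch centres", {
  w <- build_world()
  reach <- bfs_reachable(w, w$nest_centre)
  for (p in 1:2) {
    pc <- floor(w$patch_centres[p, ])
    expect_true(reach[pc[["x"]] - w$x0 + 1, pc[["y"]] - w$y0 + 1])
  }
  # and all walkable cells are reachable (no disconnected islands)
  expect_true(all(reach[w$region > 0L]))
})

test_that("patch centres lie roughly 40 walked cells from the nest centre", {
  w <- build_world()
  # corridor walk length: up the stem then along the crossbar (diagonals
  # cannot shorten it because the lateral offsets exceed the corridor width)
  nc <- w$nest_centre
  pc <- w$patch_centres[1, ]
  manhattan_ish <- abs(pc[["y"]] - nc[["y"]]) + abs(pc[["x"]] - nc[["x"]]) -
    w$geometry$arm_width # diagonal saving inside the crossbar
  expect_gt(manhattan_ish, 30)
  expect_lt(manhattan_ish, 50)
})

test_that("deposit is additive and rejects non-walkable cells", {
  w <- build_world()
  p <- pheromone_params()
  cell <- c(0, 5) # stem
  w1 <- deposit(w, cell, p)
  expect_equal(w1$pheromone[cell[1] - w$x0 + 1, cell[2] - w$y0 + 1], 60)
  w2 <- deposit(w1, cell, p)
  expect_equal(w2$pheromone[cell[1] - w$x0 + 1, cell[2] - w$y0 + 1], 120)
  # only the target cell changed
  delta <- w2$pheromone - w$pheromone
  expect_equal(sum(delta != 0), 1)
  expect_error(deposit(w, c(100, 100), p), "non-walkable")
})

test_that("decay follows the printed exponential formula", {
  w <- build_world()
  p <- pheromone_params(decay_rate = 0.4)
  cell <- c(0, 5)
  w <- deposit(w, cell, pheromone_params(deposit_amount = 100))
  w1 <- decay_step(w, p)
  expect_equal(w1$pheromone[cell[1] - w$x0 + 1, cell[2] - w$y0 + 1], 99.6)
  # zero decay is the identity
  w0 <- decay_step(w, pheromone_params(decay_rate = 0))
  expect_equal(w0$pheromone, w$pheromone)
  # closed form after k steps, within floating tolerance
  wk <- w
  for (k in 1:50) wk <- decay_step(wk, p)
  expect_equal(max(wk$pheromone), 100 * (0.996)^50, tolerance = 1e-9)
})

test_that("a 60-unit deposit at r = 0.4 stays detectable for ~1769 steps", {
  # independent oracle: iterate the decay formula until below threshold
  C <- 60; k <- 0
  while (C >= 0.05) { C <- C * 0.996; k <- k + 1 }
  expect_equal(k, ceiling(log(0.05 / 60) / log(0.996)))
  expect_true(abs(k - 1769.1) < 1.5)
})

test_that("patch availability respects the opening delay strictly", {
  w <- build_world()
  w$patch_available_from <- c(0L, 900L)
  expect_true(patch_is_open(w, 1, 0))
  expect_false(patch_is_open(w, 2, 899))
  expect_true(patch_is_open(w, 2, 900))
  # simultaneous offering: both open from the start
  w$patch_available_from <- c(0L, 0L)
  expect_true(all(sapply(0:10, function(t) patch_is_open(w, 1, t) &&
                                           patch_is_open(w, 2, t))))
})

test_that("geometry validation rejects degenerate arenas", {
  expect_error(maze_geometry(arm_width = 0), "dimensions")
  expect_error(maze_geometry(stem_length = -3), "dimensions")
  expect_error(maze_geometry(stem_multiplier = 11), "multipliers")
  expect_error(pheromone_params(decay_rate = -1), "decay_rate")
  expect_error(pheromone_params(decay_rate = 101), "decay_rate")
})

test_that("geometry multipliers scale the patch-to-nest distance linearly", {
  d_of <- function(m) {
    w <- build_world(maze_geometry(stem_multiplier = m))
    unname(abs(w$patch_centres[1, "y"] - (w$nest_centre[["y"]] + 0.5)))
  }
  d1 <- d_of(1); d2 <- d_of(2); d4 <- d_of(4)
  expect_equal((d4 - d2) / (d2 - d1), 2, tolerance = 0.15)
})
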