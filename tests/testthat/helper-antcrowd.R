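# small configs used across tests: short runs keep the suite fast while the
# acceptance tests run the full-length reference settings
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(colony_size = 200, total_steps = 1200, thresholds = c(8, 8),
                   seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# breadth-first search over walkable cells (8-connected): independent oracle
# for connectivity of the maze
bfs_reachable <- function(world, start) {
  reach <- matrix(FALSE, nrow(world$region), ncol(world$region))
  queue <- list(start)
  reach[start[1] - world$x0 + 1, start[2] - world$y0 + 1] <- TRUE
  moves <- expand.grid(dx = -1:1, dy = -1:1)
  moves <- moves[!(moves$dx == 0 & moves$dy == 0), ]
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(moves))) {
      nxt <- c(cur[1] + moves$dx[k], cur[2] + moves$dy[k])
      i <- nxt[1] - world$x0 + 1; j <- nxt[2] - world$y0 + 1
      if (i < 1 || j < 1 || i > nrow(reach) || j > ncol(reach)) next
      if (reach[i, j] || world$region[i, j] == 0L) next
      reach[i, j] <- TRUE
      queue[[length(queue) + 1]] <- nxt
    }
  }
  reach
}

# sample of n values with mean m and sd s exactly (for t-statistic oracles)
sample_with_moments <- function(n, m, s) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}
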