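test_that("a run conserves agents across states at every step", {
  r <- run_simulation(quick_config(seed = 1))
  s <- r$series
  totals <- s$idle + s$searching + s$feeding + s$dissatisfied +
    s$recruiting + s$unloading
  expect_true(all(totals == 200))
  expect_equal(s$feeding, s$n1 + s$n2)
  expect_equal(nrow(s), 1200)
})

test_that("feeding counts never exceed the crowding thresholds", {
  r <- run_simulation(quick_config(thresholds = c(8, 24), seed = 2,
                                   colony_size = 400))
  expect_true(r$ceiling_ok)
  expect_lte(max(r$series$n1), 8)
  expect_lte(max(r$series$n2), 24)
})

test_that("identical config and seed give bit-identical results", {
  cfg <- quick_config(seed = 7)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$pheromone, r2$pheromone)
})

test_that("a delayed patch hosts no feeding before it opens", {
  cfg <- quick_config(thresholds = c(8, 24), patch2_delay = 900,
                      total_steps = 1100, colony_size = 400, seed = 3)
  s <- run_simulation(cfg)$series
  expect_true(all(s$n2[s$step < 900] == 0))
  expect_gt(sum(s$n2[s$step >= 950]), 0)
})

test_that("replicates use distinct seeds and reproduce deterministically", {
  cfg <- quick_config(total_steps = 400)
  reps <- run_replicates(cfg, n_runs = 4, seed_base = 100)
  expect_length(unique(reps$seeds), 4)
  again <- run_replicates(cfg, n_runs = 4, seed_base = 100)
  for (i in 1:4) expect_identical(reps$runs[[i]]$series, again$runs[[i]]$series)
  one <- run_replicates(cfg, n_runs = 1, seed_base = 1)
  expect_length(one$runs, 1)
})

test_that("replicate means are stable across different seed bases", {
  cfg <- quick_config(colony_size = 300, total_steps = 1000)
  m1 <- sapply(run_replicates(cfg, 8, 1000)$runs,
               function(r) r$series$n1[1000] + r$series$n2[1000])
  m2 <- sapply(run_replicates(cfg, 8, 9000)$runs,
               function(r) r$series$n1[1000] + r$series$n2[1000])
  se <- sqrt(stats::var(m1) / 8 + stats::var(m2) / 8)
  expect_lt(abs(mean(m1) - mean(m2)), 3 * max(se, 0.5))
})

test_that("mean_series averages replicate series", {
  cfg <- quick_config(total_steps = 300)
  reps <- run_replicates(cfg, 3, 1)
  m <- mean_series(reps)
  manual <- rowMeans(sapply(reps$runs, function(r) r$series$n1))
  expect_equal(m$n1, manual)
})

test_that("switch summary reports sustained crossings of the mean series", {
  cfg <- quick_config(thresholds = c(8, 24), patch2_delay = 300,
                      colony_size = 400, total_steps = 1500)
  reps <- run_replicates(cfg, 6, 42)
  sw <- switch_summary(reps)
  expect_type(sw$switched, "logical")
  if (sw$switched) {
    expect_gte(sw$crossing_time_agents, 300)
  } else {
    expect_true(is.na(sw$crossing_time_agents))
  }
})

test_that("config validation catches invalid parameterisations", {
  expect_error(sim_config(colony_size = 0), "colony_size")
  expect_error(sim_config(thresholds = c(0, 8)), "thresholds")
  expect_error(sim_config(patch2_delay = -1), "patch2_delay")
  expect_error(sim_config(leave_prob = 2), "leave_prob")
  expect_error(sim_config(decay_rate = 120), "decay_rate")
})

test_that("sweep tables carry one row per grid point and replicate", {
  sw <- sensitivity_sweep("colony_size", values = c(100, 200),
                          thresholds = c(8, 24), delay = 300, n_runs = 3,
                          seed_base = 1,
                          config_args = list(total_steps = 800))
  expect_equal(nrow(sw$table), 6)
  expect_equal(nrow(sw$summary), 2)
  expect_setequal(unique(sw$table$value), c(100, 200))
  expect_true(all(c("crossing_agents", "switched") %in% names(sw$table)))
  expect_length(unique(sw$table$seed), 6)
})
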