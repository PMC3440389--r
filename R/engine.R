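#' Simulation configuration
#'
#' Bundles every model parameter for one run: colony size, run length,
#' per-patch crowding thresholds, the delay before the second patch opens,
#' pheromone deposition/decay parameters, the behavioural timings, maze
#' geometry, the state-group update order and the RNG seed. Defaults are the
#' model's reference parameterisation: 500 agents, 5400 steps (one step ~ one
#' second, so ~90 min), leave probability 0.002 per idle agent per step,
#' drinking and unloading 60 steps each, deposit 60 units per cell crossing,
#' decay 0.4 percent per step, detection threshold 0.05 units.
#'
#' @param colony_size number of agents (default 500).
#' @param total_steps run length in time steps (default 5400).
#' @param thresholds length-2 integer vector: crowding thresholds of patch 1
#'   and patch 2 (agents feeding simultaneously; reference levels 8, 24, 72,
#'   216).
#' @param patch2_delay time step from which patch 2 offers food (0 = both
#'   patches open from the start; 900 for the changing-environment setup).
#' @param deposit_amount,decay_rate,detection_threshold,diffusion_rate see
#'   [pheromone_params()].
#' @param leave_prob per-step probability that an idle agent starts searching
#'   (default 2/1000, i.e. on average 0.002 x (agents in nest) leavers per
#'   step).
#' @param drinking_time,unloading_time timed-state durations in steps.
#' @param routing_mode `"random_walk"` (default): dissatisfied agents wander
#'   uniformly, ignoring pheromone; `"routed"`: on becoming dissatisfied an
#'   agent commits to walking directly to the nest (probability
#'   `p_nest_when_dissatisfied`) or to the other patch, and to the nest when
#'   both patches are full.
#' @param p_nest_when_dissatisfied commitment probability for `"routed"` mode.
#' @param diss_off_patch if TRUE, a dissatisfied agent reverts to ordinary
#'   searching as soon as its random walk leaves the patch region (the
#'   dissatisfied episode is tied to being at the crowded patch); if FALSE
#'   (default) it stays trail-blind until it feeds or re-enters the nest.
#' @param nest_resets if TRUE, a searching or dissatisfied agent
#'   that re-enters the nest region joins the idle pool again (it must win
#'   the leaving lottery to resume foraging); if FALSE such agents keep
#'   wandering indefinitely.
#' @param geometry a [maze_geometry()].
#' @param update_order `"forward"` (idle, searching, feeding, dissatisfied,
#'   recruiting, unloading) or `"reversed"`.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(colony_size = 500, total_steps = 5400,
                       thresholds = c(8, 8), patch2_delay = 0,
                       deposit_amount = 60, decay_rate = 0.4,
                       detection_threshold = 0.05, diffusion_rate = 0.05,
                       leave_prob = 2 / 1000,
                       drinking_time = 60, unloading_time = 60,
                       routing_mode = c("random_walk", "routed"),
                       p_nest_when_dissatisfied = NULL,
                       nest_resets = FALSE, diss_off_patch = FALSE,
                       geometry = maze_geometry(),
                       update_order = c("forward", "reversed"),
                       seed = NULL) {
  routing_mode <- match.arg(routing_mode)
  update_order <- match.arg(update_order)
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, 2L)
  if (colony_size < 1L) stop("colony_size must be >= 1", call. = FALSE)
  if (total_steps < 1L) stop("total_steps must be >= 1", call. = FALSE)
  if (length(thresholds) != 2L || any(thresholds < 1L))
    stop("thresholds must be two positive integers", call. = FALSE)
  if (patch2_delay < 0L) stop("patch2_delay must be >= 0", call. = FALSE)
  if (leave_prob < 0 || leave_prob > 1)
    stop("leave_prob must lie in [0, 1]", call. = FALSE)
  if (drinking_time < 1L || unloading_time < 1L)
    stop("drinking_time and unloading_time must be >= 1 step", call. = FALSE)
  if (routing_mode == "routed") {
    if (is.null(p_nest_when_dissatisfied) ||
        !is.finite(p_nest_when_dissatisfied) ||
        p_nest_when_dissatisfied < 0 || p_nest_when_dissatisfied > 1)
      stop("routed mode requires p_nest_when_dissatisfied in [0, 1]",
           call. = FALSE)
  } else {
    p_nest_when_dissatisfied <- NULL
  }
  stopifnot(inherits(geometry, "maze_geometry"))
  structure(list(
    colony_size = as.integer(colony_size),
    total_steps = as.integer(total_steps),
    thresholds = as.integer(thresholds),
    patch2_delay = as.integer(patch2_delay),
    pheromone = pheromone_params(deposit_amount, decay_rate,
                                 detection_threshold, diffusion_rate),
    behaviour = list(leave_prob = leave_prob,
                     drinking_time = as.integer(drinking_time),
                     unloading_time = as.integer(unloading_time),
                     routing_mode = routing_mode,
                     p_nest_when_dissatisfied = p_nest_when_dissatisfied,
                     nest_resets = isTRUE(nest_resets),
                     diss_off_patch = isTRUE(diss_off_patch)),
    geometry = geometry,
    update_order = update_order,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> colony", x$colony_size, "| steps", x$total_steps,
      "| thresholds", paste(x$thresholds, collapse = "/"),
      "| patch2 delay", x$patch2_delay,
      "| decay", x$pheromone$decay_rate,
      "| order", x$update_order, "| routing", x$behaviour$routing_mode, "\n")
  invisible(x)
}

#' Run one seeded simulation
#'
#' Initialises the maze (zero pheromone, all agents idle at the nest centre),
#' then advances `total_steps` steps. Within a step the state groups are
#' updated asynchronously in the configured order, each agent acting at most
#' once per step; recruiters' deposits land before the single global
#' evaporation of the step, after which the per-step summaries are recorded.
#'
#' @param config a [sim_config()].
#' @param trace_ids optional integer agent ids whose per-step position and
#'   state are logged (debugging aid; one row per traced agent per step).
#' @return an object of class `ant_run` with elements `series` (data.frame:
#'   `step`, feeding counts `n1`, `n2`, per-arm pheromone sums `pher1`,
#'   `pher2` (junction excluded), and the six per-state totals), `pheromone`
#'   (final field matrix), `world`, `config`, `seed`, `ceiling_ok` (TRUE iff
#'   the per-patch feeding count never exceeded its threshold on any recorded
#'   step) and, if requested, `trace`.
#' @export
run_simulation <- function(config = sim_config(), trace_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  world <- build_world(config$geometry)
  world$patch_available_from <- c(0L, config$patch2_delay)
  scent <- world$nest_scent
  scent[is.na(scent)] <- -1e18
  b <- config$behaviour
  p <- config$pheromone
  res <- cpp_run_sim(
    world$region, scent, world$x0, world$y0,
    config$colony_size, config$total_steps,
    config$thresholds, world$patch_available_from,
    p$deposit_amount, p$decay_rate, p$diffusion_rate, p$detection_threshold,
    b$leave_prob, b$drinking_time, b$unloading_time,
    world$nest_centre[["x"]] + 0.5, world$nest_centre[["y"]] + 0.5,
    world$patch_centres[, "x"], world$patch_centres[, "y"],
    config$update_order == "reversed",
    b$routing_mode == "routed",
    if (is.null(b$p_nest_when_dissatisfied)) 0 else b$p_nest_when_dissatisfied,
    b$nest_resets, b$diss_off_patch,
    if (is.null(trace_ids)) integer(0) else as.integer(trace_ids)
  )
  s <- res$series
  series <- data.frame(
    step = seq_len(config$total_steps),
    n1 = s[, 1], n2 = s[, 2], pher1 = s[, 3], pher2 = s[, 4],
    idle = s[, 5], searching = s[, 6], feeding = s[, 7],
    dissatisfied = s[, 8], recruiting = s[, 9], unloading = s[, 10]
  )
  world$pheromone <- res$pheromone
  out <- list(series = series, pheromone = res$pheromone, world = world,
              config = config, seed = config$seed,
              ceiling_ok = res$ceiling_ok,
              routed_commits = res$routed_commits)
  if (!is.null(trace_ids)) {
    tr <- as.data.frame(res$trace)
    names(tr) <- c("step", "id", "x", "y", "state")
    tr$state <- c("idle", "searching", "feeding", "dissatisfied",
                  "recruiting", "unloading")[tr$state + 1]
    out$trace <- tr
  }
  structure(out, class = "ant_run")
}

#' @export
print.ant_run <- function(x, ...) {
  n <- nrow(x$series)
  cat("<ant_run> ", n, " steps, colony ", x$config$colony_size,
      "; final feeding ", x$series$n1[n], "/", x$series$n2[n],
      ", final arm pheromone ", round(x$series$pher1[n]), "/",
      round(x$series$pher2[n]), "\n", sep = "")
  invisible(x)
}

#' Run independent replicates of one configuration
#'
#' Each replicate uses a distinct seed derived as `seed_base + replicate`
#' (the reference analyses use 30 replicates per parameter combination; the
#' sensitivity sweeps use 10).
#'
#' @param config a [sim_config()] (its own `seed` field is ignored).
#' @param n_runs number of replicates.
#' @param seed_base integer; replicate i runs with seed `seed_base + i`.
#' @param keep_fields keep each run's final pheromone field matrix (set FALSE
#'   in large sweeps to save memory).
#' @return an object of class `replicate_set`: list of `ant_run`s plus the
#'   shared config and the seed vector.
#' @export
run_replicates <- function(config, n_runs = 30, seed_base = 1,
                           keep_fields = TRUE) {
  stopifnot(n_runs >= 1)
  seeds <- seed_base + seq_len(n_runs)
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    r <- run_simulation(cfg)
    if (!keep_fields) {
      r$pheromone <- NULL
      r$world <- NULL
    }
    r
  })
  structure(list(runs = runs, config = config, seeds = seeds),
            class = "replicate_set")
}

#' Across-replicate mean time series
#'
#' @param reps a `replicate_set`.
#' @return data.frame with per-step means of the feeding counts and arm
#'   pheromone sums across replicates.
#' @export
mean_series <- function(reps) {
  stopifnot(inherits(reps, "replicate_set"))
  cols <- c("n1", "n2", "pher1", "pher2", "dissatisfied")
  acc <- Reduce(`+`, lapply(reps$runs, function(r) as.matrix(r$series[cols])))
  out <- as.data.frame(acc / length(reps$runs))
  out$step <- reps$runs[[1]]$series$step
  out[c("step", cols)]
}

#' Switch summary of a replicate set
#'
#' Sustained crossing times of the across-replicate mean series: the first
#' step from which patch 2 holds more feeding agents (and, separately, more
#' branch pheromone) than patch 1 for `persistence` consecutive steps.
#'
#' @param reps a `replicate_set`.
#' @param persistence sustained-crossing window in steps (default 60, one
#'   simulated minute).
#' @return list with `crossing_time_agents`, `crossing_time_pheromone`
#'   (step or `NA`) and `switched` (TRUE iff the agent crossing exists).
#' @export
switch_summary <- function(reps, persistence = 60) {
  m <- mean_series(reps)
  ca <- crossing_time(m$n1, m$n2, persistence = persistence, times = m$step)
  cp <- crossing_time(m$pher1, m$pher2, persistence = persistence,
                      times = m$step)
  list(crossing_time_agents = ca, crossing_time_pheromone = cp,
       switched = !is.na(ca))
}

#' Stable-environment experiment (two identical patches)
#'
#' For each crowding threshold, runs replicates with both patches at that
#' threshold and no opening delay, and summarises symmetry breaking per
#' replicate: the majority patch is identified at step 600, and the run is
#' summarised by the mean proportion of feeders at that patch and by the
#' symmetry index (mean absolute difference of the two proportions over
#' defined time points).
#'
#' @param thresholds crowding levels to test (default the four reference
#'   levels).
#' @param n_runs replicates per level (default 30).
#' @param seed_base base seed; level k, replicate i uses
#'   `seed_base + 1000 k + i`.
#' @param majority_at step at which the majority patch is identified.
#' @param config_args named list of overrides passed to [sim_config()].
#' @return list with `summary` (one row per threshold: replicate means and
#'   SDs of majority-patch proportion and symmetry index), `per_run` (one row
#'   per replicate) and `mean_series` (per-threshold across-run mean series).
#' @export
experiment_stable <- function(thresholds = c(8, 24, 72, 216), n_runs = 30,
                              seed_base = 1, majority_at = 600,
                              config_args = list()) {
  per_run <- list(); msers <- list()
  for (k in seq_along(thresholds)) {
    thr <- thresholds[k]
    cfg <- do.call(sim_config, c(list(thresholds = c(thr, thr),
                                      patch2_delay = 0), config_args))
    reps <- run_replicates(cfg, n_runs, seed_base + 1000 * k,
                           keep_fields = FALSE)
    per_run[[k]] <- do.call(rbind, lapply(seq_along(reps$runs), function(i) {
      s <- reps$runs[[i]]$series
      cs <- count_series(s$step, s$n1, s$n2, source = "simulation")
      maj <- majority_patch(cs, at_time = majority_at)
      pr <- feeder_proportions(cs)
      pmaj <- if (maj == 1L) pr$p1 else pr$p2
      data.frame(threshold = thr, replicate = i, seed = reps$seeds[i],
                 majority = maj,
                 majority_prop = mean(pmaj, na.rm = TRUE),
                 symmetry_index = symmetry_index(cs))
    }))
    msers[[as.character(thr)]] <- mean_series(reps)
  }
  per_run <- do.call(rbind, per_run)
  summary <- do.call(rbind, lapply(split(per_run, per_run$threshold),
    function(d) data.frame(
      threshold = d$threshold[1], n_runs = nrow(d),
      mean_majority_prop = mean(d$majority_prop),
      sd_majority_prop = stats::sd(d$majority_prop),
      mean_symmetry_index = mean(d$symmetry_index),
      sd_symmetry_index = stats::sd(d$symmetry_index))))
  summary <- summary[order(summary$threshold), ]
  rownames(summary) <- NULL
  list(summary = summary, per_run = per_run, mean_series = msers)
}

#' Changing-environment experiment (superior patch opens later)
#'
#' For each threshold pair, patch 1 opens at step 0 with the smaller
#' threshold and patch 2 opens after `delay` steps with three times the
#' capacity; summaries are the sustained crossing times of the
#' across-replicate mean feeding counts and mean arm pheromone.
#'
#' @param pairs list of length-2 threshold vectors.
#' @param delay opening delay of patch 2 in steps (default 900).
#' @param n_runs replicates per pair (default 30).
#' @param seed_base base seed (as in [experiment_stable()]).
#' @param persistence sustained-crossing window (default 60 steps).
#' @param config_args named list of overrides passed to [sim_config()].
#' @return list with `summary` (one row per pair: crossing times, switched),
#'   `mean_series` (per pair) and `per_run` (per-replicate crossing times).
#' @export
experiment_changing <- function(pairs = list(c(8, 24), c(24, 72), c(72, 216)),
                                delay = 900, n_runs = 30, seed_base = 1,
                                persistence = 60, config_args = list()) {
  rows <- list(); msers <- list(); per_run <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    cfg <- do.call(sim_config, c(list(thresholds = pr, patch2_delay = delay),
                                 config_args))
    reps <- run_replicates(cfg, n_runs, seed_base + 1000 * k,
                           keep_fields = FALSE)
    sw <- switch_summary(reps, persistence)
    key <- paste(pr, collapse = "v")
    msers[[key]] <- mean_series(reps)
    rows[[k]] <- data.frame(threshold_1 = pr[1], threshold_2 = pr[2],
                            crossing_agents = na_or(sw$crossing_time_agents),
                            crossing_pheromone =
                              na_or(sw$crossing_time_pheromone),
                            switched = sw$switched)
    per_run[[k]] <- do.call(rbind, lapply(seq_along(reps$runs), function(i) {
      s <- reps$runs[[i]]$series
      data.frame(threshold_1 = pr[1], threshold_2 = pr[2], replicate = i,
                 crossing_agents = na_or(crossing_time(
                   s$n1, s$n2, persistence = persistence, times = s$step)))
    }))
  }
  list(summary = do.call(rbind, rows), mean_series = msers,
       per_run = do.call(rbind, per_run))
}

na_or <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NA_real_ else x

#' Sensitivity sweep over one parameter
#'
#' Runs a replicate set per grid point of one swept parameter and returns a
#' tidy table with one row per (grid point, replicate) plus per-point
#' summaries based on the across-replicate mean series (the per-run crossing
#' is also reported). Supported parameters: `"colony_size"`, `"decay_rate"`,
#' `"stem_multiplier"`, `"arm_multiplier"`, `"p_nest"` (routed
#' dissatisfied-agent mode).
#'
#' @param parameter which parameter to sweep.
#' @param values grid values.
#' @param thresholds threshold pair (default c(8, 24)).
#' @param delay patch-2 opening delay (default 900; the long-maze sweeps use
#'   14000 for stem and 1800 for arm multipliers so the first patch is
#'   reliably discovered before the second opens).
#' @param n_runs replicates per grid point (default 10, as in the sensitivity
#'   analyses; headline experiments use 30).
#' @param seed_base base seed.
#' @param persistence sustained-crossing window (default 60).
#' @param config_args named list of overrides passed to [sim_config()].
#' @return list with `table` (grid point x replicate rows: per-run crossing
#'   time and switched flag) and `summary` (per grid point: crossing time of
#'   the across-run mean series, plus a `switched` flag that additionally
#'   requires patch 2 to hold the majority of feeders at the end of the run,
#'   so that noise crossings of near-zero counts in very small colonies do
#'   not count as reallocation).
#' @export
sensitivity_sweep <- function(parameter = c("colony_size", "decay_rate",
                                "stem_multiplier", "arm_multiplier", "p_nest"),
                  values, thresholds = c(8, 24), delay = 900,
                  n_runs = 10, seed_base = 1, persistence = 60,
                  config_args = list()) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1)
  tab <- list(); summ <- list()
  for (k in seq_along(values)) {
    v <- values[k]
    args <- c(list(thresholds = thresholds, patch2_delay = delay),
              config_args)
    if (parameter == "colony_size") args$colony_size <- v
    if (parameter == "decay_rate") args$decay_rate <- v
    if (parameter == "stem_multiplier")
      args$geometry <- maze_geometry(stem_multiplier = v)
    if (parameter == "arm_multiplier")
      args$geometry <- maze_geometry(arm_multiplier = v)
    if (parameter == "p_nest") {
      args$routing_mode <- "routed"
      args$p_nest_when_dissatisfied <- v
    }
    cfg <- do.call(sim_config, args)
    reps <- run_replicates(cfg, n_runs, seed_base + 1000 * k,
                           keep_fields = FALSE)
    sw <- switch_summary(reps, persistence)
    # "switched" means the colony reallocated the majority of its foragers:
    # a sustained crossing alone can be a noise artefact when mean feeding
    # counts are tiny (very small colonies), so patch 2 must also hold the
    # majority at the end of the run
    m <- mean_series(reps)
    tail_idx <- seq(max(1L, nrow(m) - 499L), nrow(m))
    tot <- m$n1[tail_idx] + m$n2[tail_idx]
    p2_end <- mean((m$n2[tail_idx] / tot)[tot > 0], na.rm = TRUE)
    sw$switched <- isTRUE(sw$switched && is.finite(p2_end) && p2_end > 0.5)
    tab[[k]] <- do.call(rbind, lapply(seq_along(reps$runs), function(i) {
      s <- reps$runs[[i]]$series
      data.frame(parameter = parameter, value = v, replicate = i,
                 seed = reps$seeds[i],
                 crossing_agents = na_or(crossing_time(
                   s$n1, s$n2, persistence = persistence, times = s$step)))
    }))
    summ[[k]] <- data.frame(parameter = parameter, value = v,
                            crossing_agents = na_or(sw$crossing_time_agents),
                            crossing_pheromone =
                              na_or(sw$crossing_time_pheromone),
                            switched = sw$switched)
  }
  tab <- do.call(rbind, tab)
  tab$switched <- !is.na(tab$crossing_agents)
  list(table = tab, summary = do.call(rbind, summ))
}

#' Smallest colony size that switches
#'
#' Convenience reading of a colony-size [sensitivity_sweep()]: the smallest swept size
#' whose across-run mean feeding counts show a sustained crossing to patch 2
#' within the run.
#'
#' @param colony_sweep result of `sensitivity_sweep("colony_size", ...)`.
#' @return the size (same units as the sweep grid), or `NA` if none switched.
#' @export
min_switching_colony <- function(colony_sweep) {
  s <- colony_sweep$summary
  sw <- s$value[s$switched]
  if (length(sw) == 0) NA_real_ else min(sw)
}
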