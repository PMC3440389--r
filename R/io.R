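#' Load a simulation configuration from YAML or JSON
#'
#' Absent keys take the reference defaults (see [sim_config()]); unknown keys
#' are rejected by name. The optional `geometry` block mirrors the
#' [maze_geometry()] fields.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   the full default configuration.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of keys to values",
                          call. = FALSE)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  top_keys <- c("colony_size", "total_steps", "thresholds", "patch2_delay",
                "deposit_amount", "decay_rate", "detection_threshold",
                "diffusion_rate",
                "leave_prob", "drinking_time", "unloading_time",
                "routing_mode", "p_nest_when_dissatisfied",
                "update_order", "seed", "geometry")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  geo_keys <- names(formals(maze_geometry))
  args <- raw[setdiff(names(raw), "geometry")]
  if (!is.null(raw$geometry)) {
    bad <- setdiff(names(raw$geometry), geo_keys)
    if (length(bad) > 0)
      stop("unknown geometry key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    args$geometry <- do.call(maze_geometry, raw$geometry)
  }
  num_keys <- setdiff(names(args), c("routing_mode", "update_order",
                                     "geometry"))
  for (k in num_keys)
    if (!is.numeric(args[[k]]))
      stop("configuration key '", k, "' must be numeric", call. = FALSE)
  if (!is.null(args$thresholds)) args$thresholds <- unlist(args$thresholds)
  do.call(sim_config, args)
}

#' Save a simulation configuration to YAML
#'
#' The saved file round-trips: [load_config()] on it reproduces an identical
#' [sim_config()].
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- config_as_list(config)
  yaml::write_yaml(out, path)
  invisible(path)
}

config_as_list <- function(config) {
  b <- config$behaviour; p <- config$pheromone; g <- config$geometry
  out <- list(
    colony_size = config$colony_size,
    total_steps = config$total_steps,
    thresholds = config$thresholds,
    patch2_delay = config$patch2_delay,
    deposit_amount = p$deposit_amount,
    decay_rate = p$decay_rate,
    detection_threshold = p$detection_threshold,
    diffusion_rate = p$diffusion_rate,
    leave_prob = b$leave_prob,
    drinking_time = b$drinking_time,
    unloading_time = b$unloading_time,
    routing_mode = b$routing_mode,
    update_order = config$update_order,
    geometry = unclass(g)
  )
  if (!is.null(b$p_nest_when_dissatisfied))
    out$p_nest_when_dissatisfied <- b$p_nest_when_dissatisfied
  if (!is.null(config$seed)) out$seed <- config$seed
  out
}

#' Write a run's time series to CSV
#'
#' Columns `step,N1,N2,P1,P2,dissatisfied`: per-step feeding counts at each
#' patch, per-arm pheromone sums and the number of dissatisfied agents.
#'
#' @param run an `ant_run` (or its `series` data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(run, path) {
  s <- if (inherits(run, "ant_run")) run$series else run
  out <- data.frame(step = s$step, N1 = s$n1, N2 = s$n2,
                    P1 = s$pher1, P2 = s$pher2,
                    dissatisfied = s$dissatisfied)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a time-series CSV
#'
#' Accepts the schema written by [write_timeseries()]; the pheromone columns
#' `P1`/`P2` are optional. Non-numeric cells are rejected with the offending
#' row number.
#'
#' @param path input path.
#' @return list with `series` (a [count_series()] of the feeding counts),
#'   `pheromone` (data.frame `step`, `P1`, `P2`, or `NULL` if absent) and
#'   `dissatisfied` (vector or `NULL`).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE,
                        colClasses = NA, stringsAsFactors = FALSE)
  need <- c("step", "N1", "N2")
  if (!all(need %in% names(df)))
    stop("malformed time-series header: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (col in intersect(c("step", "N1", "N2", "P1", "P2", "dissatisfied"),
                        names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0)
        stop("non-numeric value in column '", col, "' at data row ", bad[1],
             call. = FALSE)
      df[[col]] <- num
    }
  }
  list(
    series = count_series(df$step, df$N1, df$N2, source = "manual"),
    pheromone = if (all(c("P1", "P2") %in% names(df)))
      df[c("step", "P1", "P2")] else NULL,
    dissatisfied = df$dissatisfied
  )
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce an experiment bit-exactly: the full
#' configuration, the seeds used, the package version, a timestamp and the
#' output file inventory.
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @param seeds seed vector used (defaults to the config's own seed).
#' @param files character vector of output files produced.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, seeds = config$seed,
                           files = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- list(
    package = "antcrowd",
    version = as.character(utils::packageVersion("antcrowd")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    files = files,
    config = config_as_list(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest back into a configuration
#'
#' @param path manifest path written by [write_manifest()].
#' @return list with `config` (a [sim_config()]), `seeds`, `files`,
#'   `version`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(config = config_from_list(as.list(m$config)), seeds = m$seeds,
       files = m$files, version = m$version)
}
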