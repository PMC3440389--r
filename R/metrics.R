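#' Two-feeder count series
#'
#' A pair of aligned, non-negative count series at strictly increasing time
#' points: the number of foragers feeding at each of two patches, either
#' observed-style data (counts every few minutes) or per-step simulation
#' output.
#'
#' @param times strictly increasing time points.
#' @param counts_1,counts_2 non-negative counts, same length as `times`.
#' @param source one of `"simulation"`, `"synthetic"`, `"manual"`.
#' @return an object of class `count_series`.
#' @export
count_series <- function(times, counts_1, counts_2,
                         source = c("manual", "simulation", "synthetic")) {
  source <- match.arg(source)
  if (length(times) != length(counts_1) || length(times) != length(counts_2))
    stop("times, counts_1 and counts_2 must have equal length", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(counts_1 < 0) || any(counts_2 < 0))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(times = times, counts_1 = counts_1, counts_2 = counts_2,
                 source = source), class = "count_series")
}

#' Per-time-point feeder proportions
#'
#' `p1(t) = counts_1 / (counts_1 + counts_2)` where the total is positive;
#' time points with zero total are undefined (`NA`), not imputed 0.5, and are
#' excluded from any downstream mean.
#'
#' @param series a [count_series()].
#' @return data.frame with columns `time`, `p1`, `p2`.
#' @export
feeder_proportions <- function(series) {
  stopifnot(inherits(series, "count_series"))
  tot <- series$counts_1 + series$counts_2
  p1 <- ifelse(tot > 0, series$counts_1 / tot, NA_real_)
  data.frame(time = series$times, p1 = p1, p2 = 1 - p1)
}

#' Majority patch at a reference time
#'
#' The patch with strictly more foragers at `at_time`; ties go to the patch
#' with the greater cumulative count up to and including `at_time`, and a
#' remaining tie to patch 1.
#'
#' @param series a [count_series()].
#' @param at_time a time point present in `series$times` (600 steps for
#'   simulation runs; the 5-minute count for experiment-style data).
#' @return 1L or 2L.
#' @export
majority_patch <- function(series, at_time) {
  stopifnot(inherits(series, "count_series"))
  i <- match(at_time, series$times)
  if (is.na(i)) stop("at_time is not a time point of the series",
                     call. = FALSE)
  c1 <- series$counts_1[i]; c2 <- series$counts_2[i]
  if (c1 > c2) return(1L)
  if (c2 > c1) return(2L)
  s1 <- sum(series$counts_1[seq_len(i)]); s2 <- sum(series$counts_2[seq_len(i)])
  if (s2 > s1) 2L else 1L
}

#' Symmetry index of a two-feeder series
#'
#' Mean absolute difference of the two feeder proportions over defined time
#' points: 0 for a perfectly even split at every point, 1 when all foragers
#' are always at one feeder.
#'
#' @param series a [count_series()].
#' @return a value in `[0, 1]`.
#' @export
symmetry_index <- function(series) {
  pr <- feeder_proportions(series)
  d <- abs(pr$p1 - pr$p2)
  if (all(is.na(d)))
    stop("symmetry index undefined: all time points have zero total",
         call. = FALSE)
  mean(d, na.rm = TRUE)
}

#' Sustained crossing time
#'
#' Earliest time from which `series_2` strictly exceeds `series_1` for
#' `persistence` consecutive points. The persistence window (default 60
#' steps, one simulated minute) suppresses single-step noise; the window must
#' fit inside the series. Typically applied to across-replicate mean feeding
#' counts (agent crossing) or mean arm-pheromone sums (pheromone crossing);
#' per-run crossings are obtained by applying it to a single run's series.
#'
#' @param series_1,series_2 aligned numeric series.
#' @param persistence required run of consecutive exceedances (>= 1).
#' @param times optional time values (defaults to indices `1..n`).
#' @return the crossing time, or `NA` if there is no sustained crossing.
#' @export
crossing_time <- function(series_1, series_2, persistence = 60, times = NULL) {
  stopifnot(length(series_1) == length(series_2), persistence >= 1)
  n <- length(series_1)
  if (is.null(times)) times <- seq_len(n)
  exceeds <- series_2 > series_1
  exceeds[is.na(exceeds)] <- FALSE
  r <- rle(exceeds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= persistence)
  if (length(ok) == 0) return(NA_real_)
  times[starts[ok[1]]]
}

#' Chi-square test of trial bias against a 50:50 split
#'
#' Pearson goodness-of-fit (df = 1, no continuity correction) of the counts
#' of trials biased vs not biased toward the early-leading feeder against
#' equal expected frequencies.
#'
#' @param n_trials total trials.
#' @param n_biased trials whose early leader stayed the majority feeder.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_equal_bias <- function(n_trials, n_biased) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (n_biased < 0 || n_biased > n_trials)
    stop("n_biased must lie in [0, n_trials]", call. = FALSE)
  ct <- stats::chisq.test(c(n_biased, n_trials - n_biased),
                          p = c(0.5, 0.5), correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' One-sample t test of proportions against a null mean
#'
#' @param values numeric sample (e.g. per-trial proportions at the
#'   early-leading feeder).
#' @param mu null mean (default 0.5, the even split).
#' @return list with `t`, `df`, `p_value`; a zero-variance sample with mean
#'   different from `mu` is flagged with `t = Inf` (sign of the difference).
#' @export
one_sample_t <- function(values, mu = 0.5) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    if (mean(values) == mu) return(list(t = 0, df = length(values) - 1,
                                        p_value = 1))
    return(list(t = sign(mean(values) - mu) * Inf, df = length(values) - 1,
                p_value = 0))
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Regression of switch time on log decay rate
#'
#' Ordinary least squares of the mean crossing time on the natural log of the
#' pheromone decay rate (zero decay is excluded: it has no log and the switch
#' still occurs without decay). A negative slope means faster decay shortens
#' the time to reallocate foragers.
#'
#' @param decay_rate positive decay rates (percent per step).
#' @param crossing_time mean crossing times at those rates.
#' @return list with `slope`, `intercept`, `t_value` (slope), `p_value`,
#'   `r_squared`.
#' @export
regress_switch_logdecay <- function(decay_rate, crossing_time) {
  keep <- is.finite(decay_rate) & is.finite(crossing_time)
  decay_rate <- decay_rate[keep]; crossing_time <- crossing_time[keep]
  if (length(decay_rate) < 3)
    stop("need at least 3 finite (decay, crossing time) points",
         call. = FALSE)
  if (any(decay_rate <= 0))
    stop("decay rates must be > 0 for the log regression", call. = FALSE)
  fit <- stats::lm(crossing_time ~ log(decay_rate))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       t_value = sm$coefficients[2, "t value"],
       p_value = sm$coefficients[2, "Pr(>|t|)"],
       r_squared = sm$r.squared)
}

#' Holm (sequential Bonferroni) step-down decisions
#'
#' @param p_values p values in `[0, 1]`.
#' @param alpha family-wise error level (default 0.05).
#' @return logical vector, TRUE where the hypothesis is rejected.
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm") <= alpha
}
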