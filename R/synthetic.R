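#' Specification of a synthetic stable-environment trial
#'
#' Emulates the structure of a two-identical-feeder trial: total forager
#' numbers fluctuating around a mean, split between the feeders with a fixed
#' ground-truth bias, counted at regular intervals (default 24 time points,
#' as in a 120-minute trial counted every 5 minutes).
#'
#' @param n_timepoints number of count time points (default 24).
#' @param mean_total expected total foragers per time point (default 40).
#' @param bias ground-truth proportion at feeder 1, in `[0, 1]`.
#' @param noise overdispersion factor >= 0; 0 gives a deterministic exact
#'   split (the per-feeder variance grows with `noise`).
#' @param seed optional RNG seed.
#' @return an object of class `stable_trial_spec`.
#' @export
stable_trial_spec <- function(n_timepoints = 24, mean_total = 40, bias = 0.5,
                              noise = 0, seed = NULL) {
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]", call. = FALSE)
  if (mean_total <= 0) stop("mean_total must be > 0", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(n_timepoints = as.integer(n_timepoints),
                 mean_total = mean_total, bias = bias, noise = noise,
                 seed = seed), class = "stable_trial_spec")
}

#' Generate a stable-environment count series
#'
#' With `noise = 0` every time point is the deterministic split
#' `(round(mean_total * bias), rest)`. With `noise > 0` the per-point total is
#' a negative-binomial draw around `mean_total` (variance
#' `mean_total * (1 + noise)`) and feeder 1's count is binomial with the
#' ground-truth bias, a two-stage draw whose expected recovered bias equals
#' the planted one. The metrics under test must not depend on this noise
#' family.
#'
#' @param spec a [stable_trial_spec()].
#' @return a [count_series()] with attribute `true_bias`.
#' @export
gen_stable <- function(spec) {
  stopifnot(inherits(spec, "stable_trial_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_timepoints
  if (spec$noise == 0) {
    c1 <- rep(round(spec$mean_total * spec$bias), n)
    tot <- rep(round(spec$mean_total), n)
  } else {
    tot <- stats::rnbinom(n, mu = spec$mean_total,
                          size = spec$mean_total / spec$noise)
    c1 <- stats::rbinom(n, size = tot, prob = spec$bias)
  }
  out <- count_series(seq_len(n), c1, tot - c1, source = "synthetic")
  attr(out, "true_bias") <- spec$bias
  out
}

#' Specification of a synthetic changing-environment trial
#'
#' Emulates a trial where feeder 2 appears mid-trial (default 45 time points,
#' as in a 90-minute trial counted every 2 minutes, with the second feeder
#' appearing around the 8th count) and, optionally, overtakes feeder 1 from a
#' planted switch point onward.
#'
#' @param n_timepoints number of count time points (default 45).
#' @param onset_index time point at which feeder 2 appears (default 8).
#' @param switch_index planted crossing time point (feeder 2 strictly exceeds
#'   feeder 1 from here to the end of the series), or `NULL` for no switch.
#' @param ramp time points from onset to plateau (>= 2 so that single-point
#'   pre-switch blips stay shorter than any persistence window >= ramp).
#' @param base_level feeder 1's plateau count (default 20).
#' @param n_blips number of isolated single-point pre-switch excursions of
#'   feeder 2 above feeder 1 (default 2 when there is room; these must not be
#'   mistaken for the switch).
#' @param noise_sd bounded integer jitter is applied to both feeders after
#'   onset; the construction margin guarantees the planted ordering survives
#'   the jitter.
#' @param seed optional RNG seed.
#' @return an object of class `changing_trial_spec`.
#' @export
changing_trial_spec <- function(n_timepoints = 45, onset_index = 8,
                                switch_index = 20, ramp = 3,
                                base_level = 20, n_blips = 2,
                                noise_sd = 1, seed = NULL) {
  if (!is.null(switch_index) && switch_index <= onset_index)
    stop("switch_index must be greater than onset_index", call. = FALSE)
  if (!is.null(switch_index) && switch_index > n_timepoints)
    stop("switch_index must lie inside the series", call. = FALSE)
  if (onset_index < 1 || onset_index > n_timepoints)
    stop("onset_index must lie inside the series", call. = FALSE)
  if (ramp < 2) stop("ramp must be >= 2", call. = FALSE)
  if (base_level < 4) stop("base_level must be >= 4", call. = FALSE)
  structure(list(n_timepoints = as.integer(n_timepoints),
                 onset_index = as.integer(onset_index),
                 switch_index = if (is.null(switch_index)) NULL
                                else as.integer(switch_index),
                 ramp = as.integer(ramp), base_level = base_level,
                 n_blips = as.integer(n_blips), noise_sd = noise_sd,
                 seed = seed), class = "changing_trial_spec")
}

#' Generate a changing-environment count series
#'
#' Feeder 2's counts are identically zero before the onset; after it they
#' ramp up but stay below feeder 1 until the planted switch point (if any),
#' from which feeder 2 strictly exceeds feeder 1 through the end of the
#' series. Isolated single-point blips above feeder 1 may occur before the
#' switch; a persistence window of at least 2 points rejects them. The
#' bounded jitter cannot flip the planted ordering, so
#' `crossing_time(..., persistence >= ramp)` recovers `switch_index` exactly.
#'
#' @param spec a [changing_trial_spec()].
#' @return a [count_series()] with attributes `true_switch` (time point or
#'   `NA`) and `onset` .
#' @export
gen_changing <- function(spec) {
  stopifnot(inherits(spec, "changing_trial_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_timepoints
  on <- spec$onset_index
  sw <- spec$switch_index
  base <- round(spec$base_level)
  margin <- max(3, round(base / 4))

  f1 <- rep(base, n)
  f2 <- numeric(n)
  rise_end <- if (is.null(sw)) n else sw - 1L
  if (rise_end >= on) {
    k <- seq(on, rise_end)
    f2[k] <- round((base - margin) * (k - on + 1) / (rise_end - on + 1))
  }
  if (!is.null(sw)) {
    k <- seq(sw, n)
    f2[k] <- base + margin + pmin(k - sw, spec$ramp)
  }

  # bounded jitter: at most floor((margin - 1)/2) per series, so the planted
  # ordering (f2 below f1 pre-switch, above from the switch on) is preserved
  amp <- (margin - 1) %/% 2
  if (spec$noise_sd > 0 && amp > 0) {
    jit <- function(m) sample(seq(-m, m), n, replace = TRUE)
    f1 <- f1 + jit(amp)
    j2 <- jit(amp)
    j2[seq_len(min(on - 1L, n))] <- 0 # feeder 2 absent before onset
    f2 <- pmax(0, f2 + j2)
  }

  # isolated one-point blips of feeder 2 above feeder 1 before the switch
  blip_hi <- if (is.null(sw)) n - 1L else sw - 2L
  blip_cand <- seq(on + 1L, length.out = max(0L, blip_hi - on))
  blip_cand <- blip_cand[seq_along(blip_cand) %% 2 == 1L] # non-adjacent
  nb <- min(spec$n_blips, length(blip_cand))
  if (nb > 0) {
    at <- sort(sample(blip_cand, nb))
    f2[at] <- f1[at] + 2
  }

  out <- count_series(seq_len(n), pmax(0, f1), pmax(0, f2),
                      source = "synthetic")
  attr(out, "true_switch") <- if (is.null(sw)) NA_integer_ else sw
  attr(out, "onset") <- on
  out
}

#' Generate a trial-level bias outcome
#'
#' Binomial draw of how many of `n_trials` two-feeder trials ended biased
#' toward the feeder that led early, given the per-trial probability of that
#' outcome; a fixture for the 50:50 bias test.
#'
#' @param n_trials number of trials.
#' @param p_bias_toward_leader per-trial probability the early leader stays
#'   the majority feeder.
#' @param seed optional RNG seed.
#' @return an object of class `trial_bias`: list with `n_trials`, `n_biased`.
#' @export
gen_trialset <- function(n_trials, p_bias_toward_leader, seed = NULL) {
  if (p_bias_toward_leader < 0 || p_bias_toward_leader > 1)
    stop("p_bias_toward_leader must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  structure(list(n_trials = as.integer(n_trials),
                 n_biased = stats::rbinom(1, n_trials, p_bias_toward_leader)),
            class = "trial_bias")
}
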