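#' Gaussian recruitment positions
#'
#' Relative peak-time positions of the cells in a moving bump, following a
#' truncated Gaussian over the produced interval (centre and SD in interval
#' units). \code{method = "quantile"} places cells at the quantiles of the
#' truncated Gaussian (the population recruitment rate then follows the
#' Gaussian exactly, emulating onset times adjusted to a Gaussian recruitment
#' profile); \code{method = "random"} samples them.
#'
#' @param n number of cells.
#' @param center,sd Gaussian centre and SD in interval units.
#' @param lo,hi truncation bounds in interval units.
#' @param method "quantile" or "random".
#' @return sorted numeric vector of relative positions in \code{[lo, hi]}.
#' @export
recruit_positions <- function(n, center = 0.5, sd = 0.25, lo = 0, hi = 1,
                              method = c("quantile", "random")) {
  method <- match.arg(method)
  ranks <- switch(method,
                  quantile = stats::ppoints(n, a = 0.5),
                  random = sort(stats::runif(n)))
  positions_from_ranks(ranks, center, sd, lo, hi)
}

#' @rdname recruit_positions
#' @param ranks recruitment quantile ranks in (0, 1); a cell keeps its rank
#'   across intervals, so relative activation order is preserved while the
#'   interval-specific recruitment width stretches the positions.
#' @export
positions_from_ranks <- function(ranks, center = 0.5, sd = 0.25, lo = 0,
                                 hi = 1) {
  plo <- stats::pnorm(lo, center, sd)
  phi <- stats::pnorm(hi, center, sd)
  stats::qnorm(plo + ranks * (phi - plo), center, sd)
}

# interval-specific relative recruitment SD
recruit_sd_rel <- function(config, interval_ms) {
  if (!is.null(config$recruitment_sd)) config$recruitment_sd
  else config$recruitment_sd_ms / interval_ms
}

#' Simulate moving-bump population activity for one target interval
#'
#' Builds a population rate matrix (1-ms resolution) in which cells are
#' recruited sequentially across each produced interval following a Gaussian
#' recruitment profile centred mid-interval, each cell firing a gamma-sum
#' activation waveform of the interval's configured duration. The cascade
#' repeats cyclically for \code{n_intervals_per_trial} intervals; cells at the
#' recruitment tails start before the interval-start tap and finish after the
#' interval-end tap.
#'
#' @param config a \code{\link{sim_config}}.
#' @param interval_ms target interval; must appear in the config maps.
#' @param positions optional relative peak positions (overrides recruitment
#'   draw; used to share cell identity across intervals).
#' @param profiles optional list of parameter draws from
#'   \code{\link{draw_profile_params}}, one per cell, re-used across intervals.
#' @param n_neurons optional override of the configured neuron count.
#' @param noise_sd additive truncated-Gaussian rate noise SD (fraction of peak
#'   rate); default taken from the config.
#' @param condition condition label stored with the activity.
#' @return object of class \code{population_activity}: fields \code{rate}
#'   (neurons x time, a.u. with unit peak waveforms), \code{time_ms} (sample
#'   times, 0 = first tap), \code{tap_times_ms}, \code{target_interval_ms},
#'   \code{condition}, \code{positions}, \code{peak_times_ms} (first cycle),
#'   \code{onset_ms}, \code{offset_ms}, \code{duration_ms}, \code{profiles},
#'   \code{active} (logical; all TRUE here).
#' @export
simulate_moving_bump <- function(config, interval_ms, positions = NULL,
                                 profiles = NULL, n_neurons = NULL,
                                 noise_sd = NULL, condition = "SC") {
  iv <- as.character(interval_ms)
  if (!iv %in% names(config$n_neurons_by_interval))
    stop("interval ", interval_ms, " not present in the config maps")
  n <- if (is.null(n_neurons)) config$n_neurons_by_interval[[iv]] else n_neurons
  if (n < 2) stop("neuron count must be at least 2")
  dur <- config$activation_ms_by_interval[[iv]]
  if (is.null(positions))
    positions <- recruit_positions(n, config$recruitment_center,
                                   recruit_sd_rel(config, interval_ms))
  if (length(positions) != n) stop("positions length must equal neuron count")
  if (is.null(profiles))
    profiles <- replicate(n, draw_profile_params(), simplify = FALSE)
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  build_bump_activity(positions, profiles, interval_ms, dur,
                      config$n_intervals_per_trial, noise_sd, condition,
                      recruit_center = config$recruitment_center,
                      recruit_sd = recruit_sd_rel(config, interval_ms))
}

# Assemble the cyclic rate matrix from per-cell waveforms and peak positions.
build_bump_activity <- function(positions, profiles, interval_ms, duration_ms,
                                n_cycles, noise_sd, condition,
                                active = NULL, recruit_center = 0.5,
                                recruit_sd = 0.25) {
  n <- length(positions)
  waves <- lapply(profiles, function(p)
    simulate_activation_profile(duration_ms, params = p))
  margin <- ceiling(duration_ms)       # room for tails crossing the end taps
  tap_times <- margin + (0:n_cycles) * interval_ms
  t1 <- n_cycles * interval_ms + 2 * margin
  time_ms <- seq(0.5, t1 - 0.5, by = 1)
  nt <- length(time_ms)
  rate <- matrix(0, n, nt)
  onset <- offset <- peak1 <- numeric(n)
  for (i in seq_len(n)) {
    w <- waves[[i]]$waveform
    peak_off <- waves[[i]]$peak_ms
    for (j in seq_len(n_cycles) - 1L) {
      pk <- margin + (j + positions[i]) * interval_ms
      start <- pk - peak_off           # waveform window start (ms)
      idx0 <- round(start)             # 0-based sample offset
      sel <- seq_along(w) + idx0
      ok <- sel >= 1 & sel <= nt
      rate[i, sel[ok]] <- rate[i, sel[ok]] + w[ok]
      if (j == 0L) {
        onset[i] <- start
        offset[i] <- start + duration_ms
        peak1[i] <- pk
      }
    }
  }
  if (noise_sd > 0)
    rate <- pmax(rate + matrix(stats::rnorm(n * nt, 0, noise_sd), n, nt), 0)
  if (is.null(active)) active <- rep(TRUE, n)
  structure(list(rate = rate, time_ms = time_ms, tap_times_ms = tap_times,
                 target_interval_ms = interval_ms, condition = condition,
                 positions = positions, peak_times_ms = peak1,
                 onset_ms = onset, offset_ms = offset,
                 duration_ms = duration_ms, profiles = profiles,
                 active = active, recruit_center = recruit_center,
                 recruit_sd = recruit_sd),
            class = "population_activity")
}

#' @export
print.population_activity <- function(x, ...) {
  cat("<population_activity>", nrow(x$rate), "neurons x", ncol(x$rate),
      "ms;", x$condition, "interval", x$target_interval_ms, "ms;",
      length(x$tap_times_ms), "taps\n")
  invisible(x)
}

#' Add cells at intermediate recruitment positions
#'
#' Extends a moving-bump population by \code{extra_n} cells whose peak
#' positions are drawn from the recruitment Gaussian restricted strictly
#' between the earliest and latest existing peaks, so the original cells keep
#' their relative order of peak times. This is the mechanism by which longer
#' target intervals recruit more cells: extra cells enter in the intermediate
#' portion of the bump.
#'
#' @param base a \code{population_activity} from
#'   \code{\link{simulate_moving_bump}}.
#' @param extra_n number of cells to insert (>= 0).
#' @param center,sd recruitment Gaussian parameters (interval units;
#'   defaults taken from the base activity).
#' @param noise_sd rate-noise SD for the rebuilt activity (default 0).
#' @return a \code{population_activity} with \code{nrow(base$rate) + extra_n}
#'   cells; the first \code{nrow(base$rate)} rows are the base cells.
#' @export
extend_bump_population <- function(base, extra_n,
                                   center = base$recruit_center,
                                   sd = base$recruit_sd, noise_sd = 0) {
  if (extra_n < 0) stop("extra_n must be >= 0")
  if (extra_n == 0) return(base)
  lo <- min(base$positions)
  hi <- max(base$positions)
  eps <- 1e-9
  u <- positions_from_ranks(eps + stats::runif(extra_n) * (1 - 2 * eps),
                            center, sd, lo, hi)
  u <- pmin(pmax(u, lo + eps), hi - eps)
  positions <- c(base$positions, u)
  profiles <- c(base$profiles, replicate(extra_n, draw_profile_params(),
                                         simplify = FALSE))
  build_bump_activity(positions, profiles, base$target_interval_ms,
                      base$duration_ms,
                      length(base$tap_times_ms) - 1L, noise_sd,
                      base$condition, recruit_center = center,
                      recruit_sd = sd)
}

#' Additive truncated-Gaussian rate noise
#' @param activity a \code{population_activity}.
#' @param sd noise SD as a fraction of the peak rate.
#' @return the activity with noisy, non-negative rates.
#' @export
add_rate_noise <- function(activity, sd) {
  if (sd <= 0) return(activity)
  dm <- dim(activity$rate)
  activity$rate <- pmax(activity$rate +
                          matrix(stats::rnorm(prod(dm), 0, sd), dm[1], dm[2]),
                        0)
  activity
}

#' Draw spike trains from a rate profile
#'
#' Samples an inhomogeneous Poisson spike train per cell from the simulated
#' rate profile scaled to a peak discharge rate. This links the rate-based
#' simulator to the spike-based analyses (binning, surprise-index detection);
#' no refractoriness is modelled.
#'
#' @param activity a \code{population_activity}.
#' @param peak_rate_hz discharge rate corresponding to rate 1 (default 50).
#' @param trial_id trial identifier for the returned table.
#' @return a \code{\link{spike_table}}.
#' @export
rates_to_spikes <- function(activity, peak_rate_hz = 50, trial_id = 1L) {
  lambda <- activity$rate * peak_rate_hz / 1000  # expected spikes per ms
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda))
  idx <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(idx))
    return(spike_table(trial_id, integer(0), numeric(0)))
  reps <- counts[idx]
  neuron <- rep(idx[, 1], reps)
  tms <- rep(activity$time_ms[idx[, 2]], reps) +
    stats::runif(sum(reps), -0.5, 0.5)
  spike_table(trial_id, neuron, tms)
}
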