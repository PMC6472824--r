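#' Generate rhythmic tapping behaviour
#'
#' Draws produced intervals with mean \code{target + constant_error} and SD
#' \code{weber_fraction * target} (the scalar property), accumulates them into
#' tap times, and places metronome stimuli at exact target spacing over the
#' synchronization phase; the continuation phase has no stimuli. A trial with
#' \code{n_taps} taps produces \code{n_taps - 1} intervals, split half
#' synchronization (condition "SC") and half continuation ("CC"); a full
#' sequence of 7 taps gives the 3 + 3 interval structure of the
#' synchronization-continuation task.
#'
#' @param bc a \code{\link{behavior_config}}.
#' @param target_interval_ms instructed interval (ms).
#' @param n_taps taps per trial (>= 2; default 7).
#' @param n_sync_intervals number of metronome-paced intervals (default half,
#'   rounded up). Stimuli are placed at taps 1..(n_sync_intervals + 1).
#' @return an \code{\link{event_table}} with \code{bc$n_trials} trials; the
#'   condition column is "SC" for trials, stimulus rows mark the metronome.
#' @export
generate_behavior <- function(bc, target_interval_ms, n_taps = 7,
                              n_sync_intervals = NULL) {
  if (n_taps < 2) stop("n_taps must be >= 2")
  n_int <- n_taps - 1
  if (is.null(n_sync_intervals)) n_sync_intervals <- ceiling(n_int / 2)
  out <- vector("list", bc$n_trials)
  for (tr in seq_len(bc$n_trials)) {
    produced <- draw_produced_intervals(n_int, target_interval_ms,
                                        bc$constant_error_ms,
                                        bc$weber_fraction)
    taps <- cumsum(c(0, produced))
    stims <- (0:n_sync_intervals) * target_interval_ms
    out[[tr]] <- event_table(tr, "SC", target_interval_ms, taps, stims)
  }
  do.call(bind_events, out)
}

# Gaussian interval draw; non-positive draws are resampled (and logged).
draw_produced_intervals <- function(n, target, constant_error, weber) {
  mu <- target + constant_error
  sdv <- weber * target
  x <- stats::rnorm(n, mu, sdv)
  bad <- which(x <= 0)
  n_res <- 0L
  while (length(bad)) {
    n_res <- n_res + length(bad)
    x[bad] <- stats::rnorm(length(bad), mu, sdv)
    bad <- which(x <= 0)
  }
  if (n_res > 0)
    message("resampled ", n_res, " non-positive produced interval(s)")
  x
}

#' Simulate a reactive (serial reaction-time) control
#'
#' Generates stimuli at random interstimulus intervals drawn from a pool,
#' taps that follow each stimulus by a jittered reaction latency, and a
#' population response that is a stimulus-locked transient: each cell fires
#' its gamma-sum waveform at a fixed latency after every stimulus, so there is
#' no periodic pre-stimulus build-up and no single tempo in the activity.
#'
#' @param intervals_pool non-empty pool of interstimulus intervals (ms).
#' @param n_stimuli number of stimuli per trial (default 6).
#' @param response_latency_ms mean reaction latency (default 381 ms).
#' @param latency_jitter_ms SD of the reaction latency (default 46 ms; 0 gives
#'   taps at exactly stimulus + latency).
#' @param n_neurons population size (default 130).
#' @param transient_ms duration of the stimulus-locked population transient
#'   over which cells are recruited (default 200 ms).
#' @param activation_ms single-cell activation duration (default 150 ms).
#' @param noise_sd additive rate-noise SD (default 0).
#' @return list with elements \code{events} (an \code{\link{event_table}},
#'   condition "SRTT") and \code{activity} (a \code{population_activity}).
#' @export
simulate_reactive_control <- function(intervals_pool, n_stimuli = 6,
                                      response_latency_ms = 381,
                                      latency_jitter_ms = 46,
                                      n_neurons = 130, transient_ms = 200,
                                      activation_ms = 150, noise_sd = 0) {
  if (!length(intervals_pool)) stop("intervals_pool must be non-empty")
  isi <- if (length(intervals_pool) == 1) rep(intervals_pool, n_stimuli - 1)
         else sample(intervals_pool, n_stimuli - 1, replace = TRUE)
  margin <- ceiling(activation_ms + transient_ms + 100)
  stims <- margin + cumsum(c(0, isi))
  taps <- stims + response_latency_ms +
    if (latency_jitter_ms > 0) stats::rnorm(n_stimuli, 0, latency_jitter_ms)
    else 0
  # stimulus-locked recruitment: cell i peaks at stimulus + lat_i
  lat <- sort(stats::runif(n_neurons, 30, 30 + transient_ms))
  profiles <- replicate(n_neurons, draw_profile_params(), simplify = FALSE)
  waves <- lapply(profiles, function(p)
    simulate_activation_profile(activation_ms, params = p))
  t1 <- max(taps) + margin
  time_ms <- seq(0.5, t1 - 0.5, by = 1)
  nt <- length(time_ms)
  rate <- matrix(0, n_neurons, nt)
  for (i in seq_len(n_neurons)) {
    w <- waves[[i]]$waveform
    for (s in stims) {
      idx0 <- round(s + lat[i] - waves[[i]]$peak_ms)
      sel <- seq_along(w) + idx0
      ok <- sel >= 1 & sel <= nt
      rate[i, sel[ok]] <- rate[i, sel[ok]] + w[ok]
    }
  }
  if (noise_sd > 0)
    rate <- pmax(rate +
                   matrix(stats::rnorm(n_neurons * nt, 0, noise_sd),
                          n_neurons, nt), 0)
  activity <- structure(list(rate = rate, time_ms = time_ms,
                             tap_times_ms = taps,
                             target_interval_ms = NA_real_,
                             condition = "SRTT", positions = lat,
                             peak_times_ms = stims[1] + lat,
                             onset_ms = stims[1] + lat - activation_ms / 2,
                             offset_ms = stims[1] + lat + activation_ms / 2,
                             duration_ms = activation_ms,
                             profiles = profiles,
                             active = rep(TRUE, n_neurons)),
                        class = "population_activity")
  events <- event_table(1L, "SRTT", NA_real_, sort(taps), stims)
  list(events = events, activity = activity)
}
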