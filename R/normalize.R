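#' Tap-based event time normalization
#'
#' Maps event times onto a tap-relative unit scale: for an event inside the
#' produced interval between taps \code{k} and \code{k+1} (0-based), the time
#' of the interval-ending tap is subtracted, the result is divided by the
#' produced interval, and the tap sequence number is added. Tap \code{k} maps
#' exactly to the integer \code{k}, so a full 7-tap trial spans [0, 6] (and
#' values below zero/above the last tap for events outside the tap span,
#' which are extrapolated with the nearest produced interval and flagged).
#'
#' @param event_times_ms numeric event times (ms).
#' @param tap_times_ms strictly increasing tap times (ms), length >= 2.
#' @return numeric vector of normalized event values, with attribute
#'   \code{"extrapolated"} marking events outside the tap span.
#' @examples
#' time_normalize_events(750, c(500, 1000))  # 0.5
#' @export
time_normalize_events <- function(event_times_ms, tap_times_ms) {
  if (length(tap_times_ms) < 2) stop("need at least 2 taps")
  if (is.unsorted(tap_times_ms, strictly = TRUE))
    stop("tap times must be strictly increasing")
  k <- findInterval(event_times_ms, tap_times_ms)      # 0 before first tap
  nseg <- length(tap_times_ms) - 1L
  seg <- pmin(pmax(k, 1L), nseg)                       # clamp to outer segments
  produced <- tap_times_ms[seg + 1L] - tap_times_ms[seg]
  out <- (event_times_ms - tap_times_ms[seg + 1L]) / produced + seg
  attr(out, "extrapolated") <- event_times_ms < tap_times_ms[1] |
    event_times_ms > tap_times_ms[length(tap_times_ms)]
  out
}

# half-up rounding (450/20 = 22.5 -> 23 bins)
round_half_up <- function(x) floor(x + 0.5)

#' Bin spike trains into tap-aligned rate windows
#'
#' Divides every inter-tap segment into consecutive windows and converts
#' spike counts to discharge rates (spikes/s, count divided by the window's
#' real-time duration). In \code{"UTND"} (unit-time-normalized) mode each
#' segment gets exactly \code{1 / bin_unit} = 50 windows regardless of tempo;
#' in \code{"TIND"} (target-interval-normalized) mode the number of windows
#' per segment is \code{round(target / 20 ms)} (23 for 450 ms, 50 for
#' 1000 ms), so window duration stays close to 20 ms of real time. Windows
#' are half-open [start, end): a spike exactly at a tap belongs to the
#' following segment. Trials with fewer than 2 taps are skipped with a
#' warning; events before the first tap are outside all segments.
#'
#' @param spikes a \code{\link{spike_table}}.
#' @param events an \code{\link{event_table}} covering the same trials.
#' @param mode "UTND", "TIND" or "raw20" (fixed 20-ms windows from first to
#'   last tap, ignoring segment boundaries).
#' @param bin_unit normalized window width (default 0.02 units = 50 per
#'   segment).
#' @param bin_ms real-time window width for TIND/raw20 (default 20 ms).
#' @param neuron_ids optional neuron universe (preserves silent neurons).
#' @return object of class \code{binned_population}: \code{X} (neurons x
#'   bins discharge-rate matrix), \code{bins} (per-column metadata: trial,
#'   condition, target interval, serial-order segment, bin index, real-time
#'   centre, normalized-time centre, real-time width), \code{mode},
#'   \code{neuron_ids}, \code{normalized = FALSE}.
#' @export
bin_rates <- function(spikes, events, mode = c("UTND", "TIND", "raw20"),
                      bin_unit = 0.02, bin_ms = 20, neuron_ids = NULL) {
  mode <- match.arg(mode)
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(spikes$neuron_id))
  trials <- unique(events$trial_id)
  Xs <- list(); metas <- list()
  for (tr in trials) {
    taps <- trial_times(events, tr, "tap")
    if (length(taps) < 2) {
      warning("trial ", tr, " has fewer than 2 taps; skipped")
      next
    }
    info <- events[events$trial_id == tr, ][1, ]
    grid <- bin_grid(taps, info$target_interval_ms, mode, bin_unit, bin_ms)
    st <- spikes[spikes$trial_id == tr, , drop = FALSE]
    nb <- length(grid$start)
    X <- matrix(0, length(neuron_ids), nb)
    for (i in seq_along(neuron_ids)) {
      tt <- st$time_ms[st$neuron_id == neuron_ids[i]]
      if (!length(tt)) next
      idx <- findInterval(tt, c(grid$start, grid$end[nb]))
      idx <- idx[idx >= 1 & idx <= nb & tt < grid$end[nb]]
      X[i, ] <- tabulate(idx, nb) / ((grid$end - grid$start) / 1000)
    }
    Xs[[length(Xs) + 1L]] <- X
    metas[[length(metas) + 1L]] <-
      data.frame(trial_id = tr, condition = info$condition,
                 target_interval_ms = info$target_interval_ms,
                 segment = grid$segment, bin = grid$bin,
                 time_ms = (grid$start + grid$end) / 2,
                 norm_time = grid$norm_time,
                 width_ms = grid$end - grid$start)
  }
  if (!length(Xs)) stop("no trial with at least 2 taps")
  new_binned(do.call(cbind, Xs), do.call(rbind, metas), mode, neuron_ids)
}

# window boundaries for one trial
bin_grid <- function(taps, target, mode, bin_unit, bin_ms) {
  nseg <- length(taps) - 1L
  if (mode == "raw20") {
    edges <- seq(taps[1], taps[length(taps)], by = bin_ms)
    if (edges[length(edges)] < taps[length(taps)])
      edges <- c(edges, taps[length(taps)])
    nb <- length(edges) - 1L
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    return(list(start = edges[-length(edges)], end = edges[-1],
                segment = findInterval(centers, taps),
                bin = seq_len(nb),
                norm_time = time_normalize_events(centers, taps)))
  }
  nb_seg <- if (mode == "UTND") round(1 / bin_unit)
            else round_half_up(target / bin_ms)
  start <- end <- norm_time <- numeric(0)
  segment <- bin <- integer(0)
  for (k in seq_len(nseg)) {
    e <- seq(taps[k], taps[k + 1], length.out = nb_seg + 1)
    start <- c(start, e[-length(e)]); end <- c(end, e[-1])
    segment <- c(segment, rep(k, nb_seg)); bin <- c(bin, seq_len(nb_seg))
    norm_time <- c(norm_time, (k - 1) + (seq_len(nb_seg) - 0.5) / nb_seg)
  }
  list(start = start, end = end, segment = segment, bin = bin,
       norm_time = norm_time)
}

new_binned <- function(X, bins, mode, neuron_ids, normalized = FALSE,
                       max_rates = NULL, silent = NULL) {
  rownames(X) <- neuron_ids
  structure(list(X = X, bins = bins, mode = mode, neuron_ids = neuron_ids,
                 normalized = normalized, max_rates = max_rates,
                 silent = silent),
            class = "binned_population")
}

#' @export
print.binned_population <- function(x, ...) {
  cat("<binned_population>", nrow(x$X), "neurons x", ncol(x$X), "bins (",
      x$mode, if (x$normalized) ", max-normalized" else "", ")\n", sep = " ")
  invisible(x)
}

#' Bin a simulated rate matrix directly
#'
#' Same windowing as \code{\link{bin_rates}} but averaging a dense rate
#' matrix (1-ms samples) instead of counting spikes; used for the noise-free
#' rate-based simulations.
#'
#' @param activity a \code{population_activity}.
#' @param mode "UTND", "TIND" or "raw20".
#' @param trial_id trial identifier stored in the metadata.
#' @inheritParams bin_rates
#' @return a \code{binned_population} (rates in the activity's arbitrary
#'   units).
#' @export
bin_population <- function(activity, mode = c("UTND", "TIND", "raw20"),
                           trial_id = 1L, bin_unit = 0.02, bin_ms = 20) {
  mode <- match.arg(mode)
  taps <- activity$tap_times_ms
  grid <- bin_grid(taps, activity$target_interval_ms, mode, bin_unit, bin_ms)
  t0 <- activity$time_ms[1] - 0.5          # sample s covers [s-1, s) + t0
  cs <- cbind(0, t(apply(activity$rate, 1, cumsum)))
  nt <- ncol(activity$rate)
  j0 <- pmin(pmax(round(grid$start - t0), 0), nt)
  j1 <- pmin(pmax(round(grid$end - t0), 0), nt)
  X <- (cs[, j1 + 1, drop = FALSE] - cs[, j0 + 1, drop = FALSE]) /
    rep(pmax(j1 - j0, 1), each = nrow(cs))
  bins <- data.frame(trial_id = trial_id, condition = activity$condition,
                     target_interval_ms = activity$target_interval_ms,
                     segment = grid$segment, bin = grid$bin,
                     time_ms = (grid$start + grid$end) / 2,
                     norm_time = grid$norm_time,
                     width_ms = grid$end - grid$start)
  new_binned(X, bins, mode, seq_len(nrow(activity$rate)))
}

#' Combine binned populations over trials
#' @param ... \code{binned_population} objects sharing mode and neurons.
#' @return one \code{binned_population} with columns concatenated.
#' @export
combine_binned <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "binned_population"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1)
  modes <- unique(vapply(parts, `[[`, "", "mode"))
  if (length(modes) != 1) stop("cannot combine different binning modes")
  ids <- parts[[1]]$neuron_ids
  for (p in parts) if (!identical(p$neuron_ids, ids))
    stop("neuron sets differ across parts")
  new_binned(do.call(cbind, lapply(parts, `[[`, "X")),
             do.call(rbind, lapply(parts, `[[`, "bins")),
             modes, ids)
}

#' Per-neuron maximum-rate normalization
#'
#' Divides each neuron's binned rates by its maximum over all columns (all
#' repetitions and target intervals present in the object). Neurons with zero
#' maximum are left at zero and flagged silent. Applying the normalization
#' twice equals applying it once.
#'
#' @param binned a \code{binned_population}.
#' @return the object with unit row maxima, \code{max_rates} and
#'   \code{silent} filled in, \code{normalized = TRUE}.
#' @export
normalize_rates <- function(binned) {
  mx <- apply(binned$X, 1, max)
  silent <- mx <= 0
  scale <- ifelse(silent, 1, mx)
  binned$X <- binned$X / scale
  binned$max_rates <- if (is.null(binned$max_rates)) mx else binned$max_rates
  binned$silent <- silent
  binned$normalized <- TRUE
  binned
}

#' Behavioural timing metrics
#'
#' Computes, per trial and per target interval: the constant error (mean of
#' produced minus target interval, a timing-accuracy measure), the temporal
#' variability (SD of the produced intervals within a trial, across its
#' serial-order elements) and tap asynchronies (tap time minus nearest
#' metronome stimulus, for trials with stimuli).
#'
#' @param events an \code{\link{event_table}} (one or more trials).
#' @return list with data frames \code{per_trial} (trial, target, constant
#'   error, variability, n intervals), \code{per_target} (aggregated means)
#'   and \code{asynchronies} (trial, tap time, asynchrony).
#' @export
behavior_metrics <- function(events) {
  trials <- unique(events$trial_id)
  pt <- list(); asy <- list()
  for (tr in trials) {
    taps <- trial_times(events, tr, "tap")
    stims <- trial_times(events, tr, "stimulus")
    target <- events$target_interval_ms[events$trial_id == tr][1]
    produced <- diff(taps)
    pt[[length(pt) + 1L]] <- data.frame(
      trial_id = tr, target_interval_ms = target,
      constant_error_ms = mean(produced - target),
      variability_ms = if (length(produced) > 1) stats::sd(produced) else 0,
      n_intervals = length(produced))
    if (length(stims))
      asy[[length(asy) + 1L]] <- data.frame(
        trial_id = tr, tap_time_ms = taps,
        asynchrony_ms = vapply(taps, function(x) x - stims[
          which.min(abs(stims - x))], 0))
  }
  per_trial <- do.call(rbind, pt)
  agg <- do.call(rbind, lapply(split(per_trial, per_trial$target_interval_ms),
    function(d) data.frame(target_interval_ms = d$target_interval_ms[1],
                           constant_error_ms = mean(d$constant_error_ms),
                           variability_ms = mean(d$variability_ms),
                           n_trials = nrow(d))))
  rownames(agg) <- NULL
  list(per_trial = per_trial, per_target = agg,
       asynchronies = if (length(asy)) do.call(rbind, asy) else NULL)
}
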