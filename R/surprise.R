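#' Poisson surprise index
#'
#' The surprise index of observing \code{n} or more spikes in a window of
#' duration \code{T} seconds given a baseline mean rate \code{r} spikes/s is
#' \code{SI = -log P} with \code{P = exp(-rT) * sum_{i>=n} (rT)^i / i!}, the
#' upper-tail Poisson probability. The tail is evaluated through the
#' regularized incomplete-gamma identity \code{P(N >= n) = P(Gamma(n) <= rT)}
#' in log space, so it is stable far into the tail. \code{n = 0} gives
#' \code{P = 1}, \code{SI = 0}; a zero baseline with spikes present gives
#' \code{SI = Inf}.
#'
#' @param n observed spike count (non-negative integer, vectorized).
#' @param r baseline mean rate (spikes/s).
#' @param T window duration (s).
#' @param base logarithm base (default natural).
#' @return surprise index (same length as \code{n}), always >= 0.
#' @examples
#' poisson_surprise(10, r = 10, T = 0.5)  # about 3.45
#' @export
poisson_surprise <- function(n, r, T, base = exp(1)) {
  if (any(n < 0) || any(n != floor(n))) stop("n must be non-negative integers")
  if (r < 0 || T <= 0) stop("need r >= 0 and T > 0")
  lambda <- r * T
  out <- numeric(length(n))
  if (lambda == 0) {
    out[n > 0] <- Inf
    return(out)
  }
  pos <- n > 0
  # log P(N >= n) = log P(Gamma(n, 1) <= lambda)
  out[pos] <- -stats::pgamma(lambda, shape = n[pos], log.p = TRUE)
  out <- pmax(out, 0)
  if (!isTRUE(all.equal(base, exp(1)))) out <- out / log(base)
  out
}

#' Detect activation periods in a spike train
#'
#' Greedy surprise-maximization: a candidate window is seeded at every run of
#' \code{min_spikes} consecutive spikes, extended forward spike-by-spike
#' while the surprise index increases, then trimmed at the start while the
#' surprise increases further. Candidates with surprise at or above the
#' threshold, at least \code{min_spikes} spikes and at least
#' \code{min_duration_ms} are kept; overlapping candidates are resolved by
#' keeping the highest-surprise window first. The baseline \code{mean_rate}
#' should be the neuron's mean discharge rate over the entire recording.
#'
#' @param spike_times_ms sorted spike times (ms) of one neuron in one
#'   analysis window (typically tap-warped time).
#' @param mean_rate baseline rate (spikes/s).
#' @param si_threshold surprise threshold (default 4.6, about p < 0.01).
#' @param min_spikes minimum spikes per period (default 3).
#' @param min_duration_ms minimum period duration (default 20 ms).
#' @param lookahead spikes examined ahead when growing a window, so a single
#'   lull inside a burst does not stop the extension (default 3).
#' @return data.frame with one row per period: \code{onset_ms},
#'   \code{offset_ms}, \code{duration_ms}, \code{n_spikes}, \code{si},
#'   \code{rate_hz} (within-period rate), \code{peak_ms} (spike centre of
#'   mass). Zero rows when nothing is significant.
#' @export
detect_activation_periods <- function(spike_times_ms, mean_rate,
                                      si_threshold = 4.6, min_spikes = 3,
                                      min_duration_ms = 20, lookahead = 3) {
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), n_spikes = integer(0),
                      si = numeric(0), rate_hz = numeric(0),
                      peak_ms = numeric(0))
  st <- sort(spike_times_ms)
  ns <- length(st)
  if (ns < min_spikes) return(empty)
  win_si <- function(i, j) {
    dur <- max(st[j] - st[i], min_duration_ms) / 1000
    poisson_surprise(j - i + 1, mean_rate, dur)
  }
  cand <- list()
  for (i in seq_len(ns - min_spikes + 1)) {
    j <- i + min_spikes - 1L
    s <- win_si(i, j)
    # extend the end while surprise increases (looking a few spikes ahead so
    # a single lull inside a burst does not stop the growth)
    repeat {
      if (j >= ns) break
      js <- seq(j + 1L, min(j + lookahead, ns))
      ss <- vapply(js, function(jj) win_si(i, jj), 0)
      if (max(ss) <= s) break
      j <- js[which.max(ss)]
      s <- max(ss)
    }
    # trim the start while surprise increases
    i2 <- i
    while (j - i2 >= min_spikes && win_si(i2 + 1, j) > s) {
      i2 <- i2 + 1L
      s <- win_si(i2, j)
    }
    if (s >= si_threshold && (st[j] - st[i2]) >= min_duration_ms)
      cand[[length(cand) + 1L]] <- c(i = i2, j = j, si = s)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "si"]), , drop = FALSE]
  keep <- list()
  taken <- rep(FALSE, ns)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    keep[[length(keep) + 1L]] <- cand[k, ]
  }
  keep <- do.call(rbind, keep)
  out <- data.frame(onset_ms = st[keep[, "i"]], offset_ms = st[keep[, "j"]],
                    n_spikes = as.integer(keep[, "j"] - keep[, "i"] + 1),
                    si = keep[, "si"])
  out$duration_ms <- out$offset_ms - out$onset_ms
  out$rate_hz <- out$n_spikes / (pmax(out$duration_ms, min_duration_ms) / 1000)
  out$peak_ms <- vapply(seq_len(nrow(out)), function(k)
    mean(st[keep[k, "i"]:keep[k, "j"]]), 0)
  out <- out[order(out$onset_ms),
             c("onset_ms", "offset_ms", "duration_ms", "n_spikes", "si",
               "rate_hz", "peak_ms")]
  rownames(out) <- NULL
  out
}

#' Detect activation periods across a population and conditions
#'
#' Runs \code{\link{detect_activation_periods}} per neuron and inter-tap
#' condition (target interval x serial order), with each neuron's baseline
#' rate taken from its mean discharge rate over the whole recording (all
#' trials supplied).
#'
#' @param spikes a \code{\link{spike_table}} (one or more trials).
#' @param events an \code{\link{event_table}} for the same trials.
#' @param total_duration_ms recording duration per trial used for the
#'   baseline rate; default: per-trial span of the event table padded by the
#'   first/last inter-tap interval.
#' @param ... passed to \code{\link{detect_activation_periods}}.
#' @return data.frame with one row per detected period: neuron, trial,
#'   target interval, serial-order segment and the per-period fields.
#' @export
population_activation_periods <- function(spikes, events,
                                          total_duration_ms = NULL, ...) {
  trials <- unique(events$trial_id)
  # whole-recording baseline per neuron
  if (is.null(total_duration_ms)) {
    total_duration_ms <- sum(vapply(trials, function(tr) {
      tt <- events$time_ms[events$trial_id == tr]
      diff(range(tt)) + 2 * mean(diff(sort(trial_times(events, tr))))
    }, 0))
  }
  counts <- table(factor(spikes$neuron_id,
                         levels = sort(unique(spikes$neuron_id))))
  base_rate <- as.numeric(counts) / (total_duration_ms / 1000)
  names(base_rate) <- names(counts)
  out <- list()
  for (tr in trials) {
    taps <- trial_times(events, tr, "tap")
    if (length(taps) < 2) next
    info <- events[events$trial_id == tr, ][1, ]
    st <- spikes[spikes$trial_id == tr, , drop = FALSE]
    for (nid in unique(st$neuron_id)) {
      tt <- st$time_ms[st$neuron_id == nid]
      for (k in seq_len(length(taps) - 1L)) {
        seg_t <- tt[tt >= taps[k] & tt < taps[k + 1]]
        per <- detect_activation_periods(seg_t, base_rate[[as.character(nid)]],
                                         ...)
        if (nrow(per)) {
          per$neuron_id <- nid
          per$trial_id <- tr
          per$target_interval_ms <- info$target_interval_ms
          per$segment <- k
          out[[length(out) + 1L]] <- per
        }
      }
    }
  }
  if (!length(out))
    return(cbind(detect_activation_periods(numeric(0), 1),
                 data.frame(neuron_id = integer(0), trial_id = integer(0),
                            target_interval_ms = numeric(0),
                            segment = integer(0))))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Moving-bump summary of detected activation periods
#'
#' Per condition (target interval): the number of distinct cells with
#' significant activation periods, the mean activation duration, the
#' recruitment lapses (differences in peak-activity time between
#' consecutively activated cells, computed on peak-time-sorted cells within
#' each trial segment) and the mean within-period discharge rate.
#'
#' @param periods data.frame from
#'   \code{\link{population_activation_periods}}.
#' @param population_size total number of cells in the population (bounds
#'   the counts).
#' @return object of class \code{bump_summary}: data.frame \code{per_target}
#'   with columns target, n_cells, mean_duration_ms, mean_lapse_ms,
#'   mean_rate_hz; list \code{lapses} of per-target lapse vectors.
#' @export
summarize_bump <- function(periods, population_size = NA_integer_) {
  targets <- sort(unique(periods$target_interval_ms))
  rows <- list(); lapses <- list()
  for (tg in targets) {
    d <- periods[periods$target_interval_ms == tg, ]
    lp <- numeric(0)
    for (key in unique(paste(d$trial_id, d$segment))) {
      dd <- d[paste(d$trial_id, d$segment) == key, ]
      peaks <- tapply(dd$peak_ms, dd$neuron_id, mean)
      if (length(peaks) > 1) lp <- c(lp, diff(sort(peaks)))
    }
    n_cells <- length(unique(d$neuron_id))
    if (!is.na(population_size)) n_cells <- min(n_cells, population_size)
    rows[[length(rows) + 1L]] <- data.frame(
      target_interval_ms = tg, n_cells = n_cells,
      mean_duration_ms = mean(d$duration_ms),
      mean_lapse_ms = if (length(lp)) mean(lp) else NA_real_,
      mean_rate_hz = mean(d$rate_hz))
    lapses[[as.character(tg)]] <- lp
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_interval_ms = numeric(0), n_cells = integer(0),
               mean_duration_ms = numeric(0), mean_lapse_ms = numeric(0),
               mean_rate_hz = numeric(0))
  structure(list(per_target = per, lapses = lapses,
                 population_size = population_size),
            class = "bump_summary")
}

#' @export
print.bump_summary <- function(x, ...) {
  cat("<bump_summary>\n")
  print(x$per_target)
  invisible(x)
}
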