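#' Simulate a full moving-bump experiment across target intervals
#'
#' Generates \code{n_repetitions} independent simulations for every target
#' interval in the config, with a nested cell population: cells participating
#' in the shortest interval keep the same relative recruitment position at all
#' intervals (their activation is time-scaled), and the extra cells required
#' by longer intervals are inserted at random intermediate positions of the
#' bump. Every returned activity has the full population's rows; cells not
#' recruited at a given interval are silent there (flagged in \code{active}),
#' so one shared loading matrix can be fitted across intervals.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed (default \code{config$seed}); \code{NULL} leaves
#'   the RNG state untouched.
#' @return object of class \code{bump_experiment}: list with \code{trials} (a
#'   list of entries \code{list(activity, interval, rep, trial_id)}),
#'   \code{config} and \code{n_neurons_total}.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  ivs <- config$target_intervals_ms
  counts <- config$n_neurons_by_interval[as.character(ivs)]
  if (is.unsorted(counts)) stop("neuron counts must be non-decreasing in ",
                                "interval for the nested population")
  n_min <- counts[[1]]
  n_max <- counts[[length(counts)]]
  trials <- list()
  tid <- 0L
  for (r in seq_len(config$n_repetitions)) {
    # base cells sit at the recruitment quantiles; extras get random ranks
    # strictly inside the base span, so added cells are intermediate and the
    # base cells keep their relative order at every interval
    ranks_base <- stats::ppoints(n_min, a = 0.5)
    ranks_extra <- if (n_max > n_min)
      min(ranks_base) + stats::runif(n_max - n_min) *
        (max(ranks_base) - min(ranks_base))
    else numeric(0)
    ranks <- c(ranks_base, ranks_extra)
    profiles <- replicate(n_max, draw_profile_params(), simplify = FALSE)
    for (k in seq_along(ivs)) {
      n_k <- counts[[k]]
      act_ids <- seq_len(n_k)            # base cells first, then extras
      iv <- ivs[k]
      sd_rel <- recruit_sd_rel(config, iv)
      positions <- positions_from_ranks(ranks[act_ids],
                                        config$recruitment_center, sd_rel)
      a <- build_bump_activity(positions, profiles[act_ids], iv,
                               config$activation_ms_by_interval[[as.character(iv)]],
                               config$n_intervals_per_trial, config$noise_sd,
                               "SC", recruit_center = config$recruitment_center,
                               recruit_sd = sd_rel)
      a <- pad_population(a, n_max, act_ids)
      tid <- tid + 1L
      trials[[tid]] <- list(activity = a, interval = iv, rep = r,
                            trial_id = tid)
    }
  }
  structure(list(trials = trials, config = config, n_neurons_total = n_max),
            class = "bump_experiment")
}

# embed an activity's rows into the full population (silent rows = 0)
pad_population <- function(activity, n_total, active_ids) {
  if (nrow(activity$rate) == n_total) {
    activity$active <- rep(TRUE, n_total)
    return(activity)
  }
  rate <- matrix(0, n_total, ncol(activity$rate))
  rate[active_ids, ] <- activity$rate
  pad <- function(x) {
    out <- rep(NA_real_, n_total); out[active_ids] <- x; out
  }
  activity$rate <- rate
  activity$positions <- pad(activity$positions)
  activity$peak_times_ms <- pad(activity$peak_times_ms)
  activity$onset_ms <- pad(activity$onset_ms)
  activity$offset_ms <- pad(activity$offset_ms)
  activity$active <- seq_len(n_total) %in% active_ids
  activity
}

#' @export
print.bump_experiment <- function(x, ...) {
  cat("<bump_experiment>", length(x$trials), "trials,", x$n_neurons_total,
      "neurons,", x$config$regime, "regime\n")
  invisible(x)
}

#' Event table of a simulated experiment
#' @param experiment a \code{bump_experiment}.
#' @return an \code{\link{event_table}} with one trial per simulated activity.
#' @export
experiment_events <- function(experiment) {
  do.call(bind_events, lapply(experiment$trials, function(tr)
    event_table(tr$trial_id, tr$activity$condition, tr$interval,
                tr$activity$tap_times_ms, tr$activity$tap_times_ms)))
}
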