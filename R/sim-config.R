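#' Simulation configuration for moving-bump population activity
#'
#' Bundles the interval-dependent parameters of the moving-bump simulator.
#' The expanding regime uses the published parameter set: target intervals of
#' 450, 550, 650, 850 and 1000 ms with 108, 120, 130, 170 and 182 neurons and
#' activation durations of 197, 205, 213, 233 and 257 ms respectively, so that
#' both the number of recruited cells and the duration of their transient
#' activation grow with tempo. The static regime keeps both parameters fixed
#' (130 neurons, 213 ms -- the mid-range values) across intervals, which is
#' the temporal-scaling control.
#'
#' @param target_intervals_ms numeric vector of produced-interval durations (ms).
#' @param n_neurons_by_interval named numeric vector mapping interval to neuron
#'   count. Defaults depend on \code{regime}.
#' @param activation_ms_by_interval named numeric vector mapping interval to
#'   activation-period duration (ms).
#' @param n_intervals_per_trial number of consecutive produced intervals per
#'   simulated trial (the cascade repeats once per interval).
#' @param n_repetitions number of independent simulation repetitions.
#' @param regime \code{"expanding"} (neuron count and activation duration grow
#'   with interval) or \code{"static"} (both constant).
#' @param recruitment_shape shape of the cell-recruitment profile; only
#'   \code{"gaussian"} is supported.
#' @param recruitment_center centre of the Gaussian recruitment profile in
#'   units of the produced interval (default mid-interval).
#' @param recruitment_sd_ms SD of the Gaussian recruitment profile in
#'   milliseconds, shared across intervals (default 150). A fixed absolute
#'   width makes the peak population activation mass proportional to
#'   \code{n_neurons * activation_ms}, which is what lets the expanding
#'   regime grow its trajectory amplitude with tempo at constant speed.
#' @param recruitment_sd optional relative SD (units of the produced
#'   interval); when set it overrides \code{recruitment_sd_ms} at every
#'   interval.
#' @param noise_sd SD of additive truncated-Gaussian rate noise, as a fraction
#'   of the peak rate (0 disables).
#' @param seed integer seed recorded in the config (used by
#'   \code{\link{simulate_experiment}}).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(target_intervals_ms = c(450, 550, 650, 850, 1000),
                       n_neurons_by_interval = NULL,
                       activation_ms_by_interval = NULL,
                       n_intervals_per_trial = 3,
                       n_repetitions = 5,
                       regime = c("expanding", "static"),
                       recruitment_shape = "gaussian",
                       recruitment_center = 0.5,
                       recruitment_sd_ms = 150,
                       recruitment_sd = NULL,
                       noise_sd = 0.05,
                       seed = 1L) {
  regime <- match.arg(regime)
  if (!identical(recruitment_shape, "gaussian"))
    stop("only gaussian recruitment is supported")
  iv <- as.character(target_intervals_ms)
  if (is.null(n_neurons_by_interval)) {
    n_neurons_by_interval <- if (regime == "expanding")
      default_neuron_counts(target_intervals_ms)
    else stats::setNames(rep(130, length(iv)), iv)
  }
  if (is.null(activation_ms_by_interval)) {
    activation_ms_by_interval <- if (regime == "expanding")
      default_activation_ms(target_intervals_ms)
    else stats::setNames(rep(213, length(iv)), iv)
  }
  miss <- setdiff(iv, intersect(names(n_neurons_by_interval),
                                names(activation_ms_by_interval)))
  if (length(miss))
    stop("missing map entries for intervals: ", paste(miss, collapse = ", "))
  if (any(target_intervals_ms <= 0) || n_intervals_per_trial <= 0 ||
      n_repetitions <= 0 ||
      any(n_neurons_by_interval[iv] <= 0) ||
      any(activation_ms_by_interval[iv] <= 0))
    stop("all counts and durations must be strictly positive")
  structure(list(
    target_intervals_ms = sort(target_intervals_ms),
    n_neurons_by_interval = n_neurons_by_interval,
    activation_ms_by_interval = activation_ms_by_interval,
    n_intervals_per_trial = as.integer(n_intervals_per_trial),
    n_repetitions = as.integer(n_repetitions),
    regime = regime,
    recruitment_shape = recruitment_shape,
    recruitment_center = recruitment_center,
    recruitment_sd_ms = recruitment_sd_ms,
    recruitment_sd = recruitment_sd,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

default_neuron_counts <- function(intervals) {
  ref <- c(`450` = 108, `550` = 120, `650` = 130, `850` = 170, `1000` = 182)
  iv <- as.character(intervals)
  if (!all(iv %in% names(ref)))
    stop("no default neuron count for intervals outside the published set; ",
         "supply n_neurons_by_interval")
  ref[iv]
}

default_activation_ms <- function(intervals) {
  ref <- c(`450` = 197, `550` = 205, `650` = 213, `850` = 233, `1000` = 257)
  iv <- as.character(intervals)
  if (!all(iv %in% names(ref)))
    stop("no default activation duration for intervals outside the published ",
         "set; supply activation_ms_by_interval")
  ref[iv]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> regime:", x$regime, "\n")
  cat("  intervals (ms):", paste(x$target_intervals_ms, collapse = ", "), "\n")
  cat("  neurons:      ",
      paste(x$n_neurons_by_interval[as.character(x$target_intervals_ms)],
            collapse = ", "), "\n")
  cat("  activation ms:",
      paste(x$activation_ms_by_interval[as.character(x$target_intervals_ms)],
            collapse = ", "), "\n")
  cat("  intervals/trial:", x$n_intervals_per_trial,
      " repetitions:", x$n_repetitions, " noise sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Behavioural generator configuration
#'
#' Parameters of the tapping-behaviour generator: produced intervals are drawn
#' with a signed constant error (timing accuracy) and an SD proportional to the
#' target interval (scalar property / Weber law). The defaults -- Weber
#' fraction 0.05 and a small negative constant error of -15 ms -- give the
#' slight tempo underestimation and the linear SD growth characteristic of
#' primate rhythmic tapping.
#'
#' @param weber_fraction SD of produced intervals divided by the target
#'   interval (dimensionless, >= 0).
#' @param constant_error_ms mean of produced minus target interval (ms).
#' @param n_trials number of trials generated per call.
#' @param seed integer seed recorded in the config.
#' @return object of class \code{behavior_config}.
#' @export
behavior_config <- function(weber_fraction = 0.05, constant_error_ms = -15,
                            n_trials = 5, seed = 1L) {
  if (weber_fraction < 0) stop("weber_fraction must be >= 0")
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(weber_fraction = weber_fraction,
                 constant_error_ms = constant_error_ms,
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "behavior_config")
}
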