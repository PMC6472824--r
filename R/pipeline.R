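#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one object
#' that round-trips losslessly through JSON (\code{\link{write_config}} /
#' \code{\link{read_config}}).
#'
#' @param regime simulation regime ("expanding" or "static").
#' @param target_intervals_ms target intervals (ms).
#' @param n_repetitions simulation repetitions per interval.
#' @param n_intervals_per_trial produced intervals per simulated trial.
#' @param noise_sd additive rate-noise SD.
#' @param seed master seed; each random stage derives its own stream from it.
#' @param smooth_span trajectory smoothing span (fraction of a segment).
#' @param n_components retained first-layer components.
#' @param dpca_bins per-segment bin count for the demixed decomposition.
#' @param dpca_components demixed components per marginalization.
#' @param si_threshold,min_spikes,min_duration_ms surprise-detector defaults.
#' @param peak_rate_hz discharge rate mapped to rate 1 when drawing spikes.
#' @param folds,repeats cross-validation settings for the classifiers.
#' @param svm_cost linear SVM cost.
#' @param tap_threshold,tap_window_ms tap-decoder threshold and correctness
#'   window.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("geometry", "dpca", "activations", "decode_interval",
#'   "decode_taps")}; simulation always runs.
#' @param out_dir optional output directory for stage artifacts.
#' @return object of class \code{pipeline_config} (a named list).
#' @export
pipeline_config <- function(regime = "expanding",
                            target_intervals_ms = c(450, 550, 650, 850, 1000),
                            n_repetitions = 5, n_intervals_per_trial = 3,
                            noise_sd = 0.05, seed = 1L, smooth_span = 0.1,
                            n_components = 8, dpca_bins = 30,
                            dpca_components = 3, si_threshold = 4.6,
                            min_spikes = 3, min_duration_ms = 20,
                            peak_rate_hz = 50, folds = 5, repeats = 10,
                            svm_cost = 1, tap_threshold = 0.12,
                            tap_window_ms = 60,
                            stages = c("geometry", "dpca", "activations",
                                       "decode_interval", "decode_taps"),
                            out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# deterministic per-stage substream of the master seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  (seed * 97L + stage * 1009L) %% 2147483647L
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates moving-bump experiments and runs the requested analysis stages:
#' rate binning and normalization, shared-loading trajectories with segment
#' geometry and regressions (radius, variability, speed versus target
#' interval), the demixed decomposition with cross-tempo distance profiles,
#' surprise-index activation periods with bump summaries, interval
#' classification with population ablation, and tap-time decoding. Results
#' are returned as a report list and, when \code{out_dir} is set, written as
#' delimited tables and JSON.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{pipeline_report}; elements per stage (see
#'   details in the vignette), always including \code{config},
#'   \code{experiment} and \code{geometry} inputs used downstream.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- config$stages
  sc <- sim_config(target_intervals_ms = config$target_intervals_ms,
                   n_intervals_per_trial = config$n_intervals_per_trial,
                   n_repetitions = config$n_repetitions,
                   regime = config$regime, noise_sd = config$noise_sd,
                   seed = stage_seed(config$seed, 1L))
  exp <- simulate_experiment(sc)
  prep <- prepare_trajectories(exp, span = config$smooth_span,
                               n_components = config$n_components)
  report <- list(config = config, sim_config = sc,
                 n_neurons = exp$n_neurons_total,
                 explained = prep$coeffs$explained[seq_len(
                   prep$coeffs$n_retained)])
  if ("geometry" %in% stages)
    report$geometry <- geometry_stage(prep)
  if ("dpca" %in% stages)
    report$dpca <- dpca_stage(prep, config)
  if ("activations" %in% stages) {
    set.seed(stage_seed(config$seed, 2L))
    report$activations <- activation_stage(exp, config)
  }
  if ("decode_interval" %in% stages) {
    set.seed(stage_seed(config$seed, 3L))
    report$decode_interval <- decode_interval_stage(prep, config)
  }
  if ("decode_taps" %in% stages) {
    set.seed(stage_seed(config$seed, 4L))
    report$decode_taps <- decode_taps_stage(prep, config)
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# binning, shared normalization, loading fit and TIND projection
prepare_trajectories <- function(exp, span = 0.1, n_components = 8) {
  utnd <- combine_binned(lapply(exp$trials, function(tr)
    bin_population(tr$activity, "UTND", trial_id = tr$trial_id)))
  tind <- combine_binned(lapply(exp$trials, function(tr)
    bin_population(tr$activity, "TIND", trial_id = tr$trial_id)))
  mx <- pmax(apply(utnd$X, 1, max), apply(tind$X, 1, max))
  scale <- ifelse(mx <= 0, 1, mx)
  utnd$X <- utnd$X / scale; utnd$normalized <- TRUE
  utnd$max_rates <- mx; utnd$silent <- mx <= 0
  tind$X <- tind$X / scale; tind$normalized <- TRUE
  tind$max_rates <- mx; tind$silent <- mx <= 0
  coeffs <- fit_coefficients(utnd, n_components = n_components)
  traj <- project_trajectory(coeffs, tind, smooth = TRUE, span = span)
  traj_utnd <- project_trajectory(coeffs, utnd, smooth = TRUE, span = span)
  list(exp = exp, utnd = utnd, tind = tind, coeffs = coeffs, traj = traj,
       traj_utnd = traj_utnd)
}

# per-(repetition, target) radius / variability / speed and their regressions
geometry_stage <- function(prep) {
  geom <- trajectory_geometry(prep$traj)
  geoms <- attr(geom, "geoms")
  rep_of <- vapply(prep$exp$trials, `[[`, 0L, "trial_id")
  rep_map <- stats::setNames(vapply(prep$exp$trials, `[[`, 0L, "rep"),
                             rep_of)
  geom$rep <- rep_map[as.character(geom$trial_id)]
  key <- unique(geom[, c("rep", "target_interval_ms")])
  per_rep <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- geom$rep == key$rep[i] &
      geom$target_interval_ms == key$target_interval_ms[i]
    data.frame(rep = key$rep[i],
               target_interval_ms = key$target_interval_ms[i],
               radius = mean(geom$radius[sel]),
               variability = radius_variability(geoms[which(sel)]),
               speed = mean(geom$speed[sel]))
  }))
  list(per_segment = geom, per_rep = per_rep,
       fit_radius = regression_summary(per_rep$radius,
                                       per_rep$target_interval_ms),
       fit_variability = regression_summary(per_rep$variability,
                                            per_rep$target_interval_ms),
       fit_speed = regression_summary(per_rep$speed,
                                      per_rep$target_interval_ms))
}

#' Linear regression summary (slope, intercept, R^2, p)
#' @param y,x numeric vectors.
#' @return named list with slope, intercept, r2, p, n.
#' @export
regression_summary <- function(y, x) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, p = p, n = length(y))
}

dpca_stage <- function(prep, config) {
  marg <- marginalize(prep$tind, n_bins = config$dpca_bins)
  model <- fit_dpca(marg, n_components = config$dpca_components)
  # distance profiles: reference = shortest interval, per condition average
  targets <- marg$targets
  nbt <- config$dpca_bins * marg$n_segments
  cols <- function(k) (k - 1) * nbt + seq_len(nbt)
  d1 <- model$components$interval$scores
  prof <- lapply(seq_along(targets)[-1], function(k) {
    dd <- sqrt(colSums((d1[1, cols(1), drop = FALSE] -
                          d1[1, cols(k), drop = FALSE])^2))
    data.frame(target_interval_ms = targets[k], mean = mean(dd),
               sd = stats::sd(dd))
  })
  list(model = model, marg = marg,
       distance_dpc1 = do.call(rbind, prof))
}

activation_stage <- function(exp, config) {
  spikes <- do.call(rbind, lapply(exp$trials, function(tr)
    rates_to_spikes(tr$activity, config$peak_rate_hz, tr$trial_id)))
  class(spikes) <- c("spike_table", "data.frame")
  events <- experiment_events(exp)
  periods <- population_activation_periods(
    spikes, events, si_threshold = config$si_threshold,
    min_spikes = config$min_spikes,
    min_duration_ms = config$min_duration_ms)
  summary <- summarize_bump(periods, exp$n_neurons_total)
  list(periods = periods, summary = summary,
       fit_n_cells = regression_summary(summary$per_target$n_cells,
                                        summary$per_target$target_interval_ms),
       fit_duration = regression_summary(
         summary$per_target$mean_duration_ms,
         summary$per_target$target_interval_ms))
}

decode_interval_stage <- function(prep, config) {
  best <- best_component(prep$traj, components = 1:3,
                         repeats = 2, folds = config$folds,
                         C = config$svm_cost)
  cloud <- build_segment_cloud(prep$traj, best$best)
  full <- classify_interval(cloud, repeats = config$repeats,
                            folds = config$folds, C = config$svm_cost)
  curve <- ablate_and_classify(prep$tind, prep$coeffs,
                               component = best$best,
                               train_binned = prep$utnd,
                               span = config$smooth_span,
                               repeats = max(2, config$repeats %/% 2),
                               folds = config$folds, C = config$svm_cost)
  list(best_component = best$best, accuracy = full, ablation = curve)
}

decode_taps_stage <- function(prep, config) {
  trials <- lapply(unique(prep$traj$bins$trial_id), function(tr) {
    rows <- which(prep$traj$bins$trial_id == tr)
    taps <- tap_times_of(prep$exp, tr)
    list(series = prep$traj$Y[rows, 1], time_ms = prep$traj$bins$time_ms[rows],
         tap_times_ms = taps)
  })
  train_tap_decoder(trials, folds = config$folds,
                    threshold = config$tap_threshold,
                    window_ms = config$tap_window_ms)
}

tap_times_of <- function(exp, trial_id) {
  for (tr in exp$trials) if (tr$trial_id == trial_id)
    return(tr$activity$tap_times_ms)
  stop("unknown trial ", trial_id)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$config$regime, "regime,", x$n_neurons,
      "neurons\n")
  if (!is.null(x$geometry)) {
    cat("  radius slope ", signif(x$geometry$fit_radius$slope, 3),
        " (R2 ", signif(x$geometry$fit_radius$r2, 3), ", p ",
        signif(x$geometry$fit_radius$p, 3), ")\n", sep = "")
    cat("  speed slope  ", signif(x$geometry$fit_speed$slope, 3),
        " (p ", signif(x$geometry$fit_speed$p, 3), ")\n", sep = "")
  }
  if (!is.null(x$decode_interval))
    cat("  interval classification ",
        round(100 * x$decode_interval$accuracy$accuracy, 1), "%\n", sep = "")
  if (!is.null(x$decode_taps))
    cat("  taps decoded within window ",
        round(100 * x$decode_taps$frac_correct, 1), "%\n", sep = "")
  invisible(x)
}

# write stage artifacts as TSV/JSON under out_dir
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(report$config, file.path(out_dir, "config.json"))
  summ <- list(n_neurons = report$n_neurons, explained = report$explained)
  if (!is.null(report$geometry)) {
    utils::write.table(report$geometry$per_rep,
                       file.path(out_dir, "geometry_per_rep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summ$fit_radius <- report$geometry$fit_radius
    summ$fit_variability <- report$geometry$fit_variability
    summ$fit_speed <- report$geometry$fit_speed
  }
  if (!is.null(report$activations)) {
    utils::write.table(report$activations$summary$per_target,
                       file.path(out_dir, "bump_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$decode_interval)) {
    utils::write.table(report$decode_interval$ablation,
                       file.path(out_dir, "ablation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summ$interval_accuracy <- report$decode_interval$accuracy$accuracy
  }
  if (!is.null(report$decode_taps))
    summ$tap_frac_correct <- report$decode_taps$frac_correct
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
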