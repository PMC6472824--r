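# shared fixtures: small configs and hand-built trajectory objects

# a small two-interval expanding-style config for cheap end-to-end tests
small_config <- function(noise_sd = 0, reps = 2, seed = 1L) {
  sim_config(target_intervals_ms = c(450, 650),
             n_neurons_by_interval = c(`450` = 24, `650` = 32),
             activation_ms_by_interval = c(`450` = 197, `650` = 213),
             n_repetitions = reps, noise_sd = noise_sd, seed = seed)
}

# build a neural_trajectory object directly from a bins x components matrix
make_traj <- function(Y, trial_id = 1L, segment = 1L, target = 650,
                      mode = "TIND", bin_ms = 20) {
  n <- nrow(Y)
  bins <- data.frame(trial_id = trial_id, condition = "SC",
                     target_interval_ms = target,
                     segment = segment, bin = seq_len(n),
                     time_ms = seq_len(n) * bin_ms - bin_ms / 2,
                     norm_time = (seq_len(n) - 0.5) / n,
                     width_ms = bin_ms)
  structure(list(Y = Y, bins = bins, n_components = ncol(Y),
                 smooth = FALSE, span = 0, mode = mode),
            class = "neural_trajectory")
}

# circle in a plane of a d-dimensional space, one full cycle over n bins
circle_points <- function(n, radius = 1, d = 3, dims = c(2, 3),
                          center = rep(0, d), phase = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n + phase
  Y <- matrix(rep(center, each = n), n, d)
  Y[, dims[1]] <- Y[, dims[1]] + radius * cos(th)
  Y[, dims[2]] <- Y[, dims[2]] + radius * sin(th)
  Y
}

# stack several trajectories (same component count) into one object
bind_traj <- function(...) {
  parts <- list(...)
  structure(list(Y = do.call(rbind, lapply(parts, `[[`, "Y")),
                 bins = do.call(rbind, lapply(parts, `[[`, "bins")),
                 n_components = parts[[1]]$n_components,
                 smooth = FALSE, span = 0, mode = parts[[1]]$mode),
            class = "neural_trajectory")
}
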