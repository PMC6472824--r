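#' Fit a shared principal-component loading matrix
#'
#' Computes the loading (coefficient) matrix of a principal-component
#' decomposition of the neurons x bins rate matrix, to be re-used as a single
#' shared transform for every trial and condition. Fitting on unit-time
#' normalized (UTND) data gives every condition the same number of columns,
#' so no tempo is over-represented in the decomposition. Per-neuron means
#' over the training matrix are subtracted before the decomposition and
#' stored for projection.
#'
#' @param binned a \code{binned_population} (UTND recommended; a warning is
#'   given otherwise).
#' @param n_components retained dimensionality (default 8).
#' @param min_var_frac warn threshold: retained components are normally those
#'   explaining at least this fraction of variance (default 0.01).
#' @return object of class \code{coeff_matrix}: \code{P} (components x
#'   neurons, orthonormal rows), \code{center}, \code{explained} (variance
#'   fractions, non-increasing), \code{n_retained}, \code{neuron_ids}.
#' @export
fit_coefficients <- function(binned, n_components = 8, min_var_frac = 0.01) {
  X <- binned$X
  if (ncol(X) < 2) stop("need at least 2 bins to fit the decomposition")
  if (binned$mode != "UTND")
    warning("loading matrix is normally fitted on UTND data; got ",
            binned$mode)
  center <- rowMeans(X)
  Xc <- X - center
  if (all(abs(Xc) < 1e-12)) stop("training matrix has zero variance")
  pca <- stats::prcomp(t(Xc), center = FALSE, scale. = FALSE)
  explained <- pca$sdev^2 / sum(pca$sdev^2)
  n_ret <- min(n_components, ncol(pca$rotation))
  if (sum(explained >= min_var_frac) < n_ret)
    warning("only ", sum(explained >= min_var_frac), " components explain >= ",
            min_var_frac * 100, "% of variance; retaining ", n_ret,
            " as requested")
  structure(list(P = t(pca$rotation), center = center, explained = explained,
                 n_retained = n_ret, neuron_ids = binned$neuron_ids),
            class = "coeff_matrix")
}

#' @export
print.coeff_matrix <- function(x, ...) {
  cat("<coeff_matrix>", nrow(x$P), "components x", ncol(x$P), "neurons;",
      "retained", x$n_retained, "(",
      paste0(round(100 * x$explained[seq_len(min(3, length(x$explained)))], 1),
             "%", collapse = ", "), "...)\n")
  invisible(x)
}

#' Project binned activity through a shared loading matrix
#'
#' Applies \code{Y = P (X - center)} with the stored loadings, optionally
#' followed by locally-weighted (lowess) smoothing of each component along
#' every trial. Using one transform for all trials makes trajectories from
#' different tempos and tasks directly comparable.
#'
#' @param coeffs a \code{\link{fit_coefficients}} result.
#' @param binned a \code{binned_population} with the same neuron set.
#' @param smooth logical; apply lowess smoothing per component and trial.
#' @param span smoothing span as a fraction of one inter-tap segment
#'   (default 0.1).
#' @param n_components number of components kept (default the fitted
#'   retention, normally 8).
#' @return object of class \code{neural_trajectory}: \code{Y} (bins x
#'   components), \code{bins} metadata (as in the binned input), \code{dims},
#'   \code{smooth}, \code{span}, \code{mode}; attribute \code{"raw"} holds
#'   the unsmoothed scores when smoothing is on.
#' @export
project_trajectory <- function(coeffs, binned, smooth = TRUE, span = 0.1,
                               n_components = coeffs$n_retained) {
  if (!identical(binned$neuron_ids, coeffs$neuron_ids)) {
    missing <- setdiff(coeffs$neuron_ids, binned$neuron_ids)
    stop("neuron set does not match the fitted loadings; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  nc <- min(n_components, nrow(coeffs$P))
  Y <- t(coeffs$P[seq_len(nc), , drop = FALSE] %*% (binned$X - coeffs$center))
  raw <- Y
  if (smooth) {
    for (tr in unique(binned$bins$trial_id)) {
      rows <- which(binned$bins$trial_id == tr)
      nseg <- length(unique(binned$bins$segment[rows]))
      f <- max(span / max(nseg, 1), 3 / length(rows))
      for (j in seq_len(nc))
        Y[rows, j] <- stats::lowess(seq_along(rows), Y[rows, j], f = f)$y
    }
  }
  out <- structure(list(Y = Y, bins = binned$bins, n_components = nc,
                        smooth = smooth, span = span, mode = binned$mode),
                   class = "neural_trajectory")
  if (smooth) attr(out, "raw") <- raw
  out
}

#' @export
print.neural_trajectory <- function(x, ...) {
  cat("<neural_trajectory>", nrow(x$Y), "bins x", x$n_components,
      "components (", x$mode, if (x$smooth) ", smoothed" else "", ")\n")
  invisible(x)
}

traj_rows <- function(traj, trial_id, segment) {
  which(traj$bins$trial_id == trial_id & traj$bins$segment == segment)
}

#' Radius of one trajectory segment
#'
#' The radius of an inter-tap trajectory segment is the mean Euclidean
#' distance between the segment's centroid and each of its points, by default
#' on the plane of components 2 and 3 (the pair showing the quarter-cycle
#' phase-shifted oscillation that traces a loop per produced interval).
#'
#' @param traj a \code{neural_trajectory}.
#' @param trial_id,segment which inter-tap segment.
#' @param dims components used (default \code{c(2, 3)}).
#' @return object of class \code{segment_geometry}: \code{radius},
#'   \code{distances} (point-to-centroid), \code{centroid},
#'   \code{target_interval_ms}, \code{segment}, \code{trial_id},
#'   \code{produced_ms} (real segment duration), \code{speed} (NA here).
#' @export
segment_radius <- function(traj, trial_id, segment, dims = c(2, 3)) {
  rows <- traj_rows(traj, trial_id, segment)
  if (length(rows) < 3) stop("segment needs at least 3 bins")
  pts <- traj$Y[rows, dims, drop = FALSE]
  centroid <- colMeans(pts)
  d <- sqrt(rowSums((pts - rep(centroid, each = nrow(pts)))^2))
  if (all(d < 1e-12))
    warning("degenerate segment: all points identical; radius 0")
  structure(list(radius = mean(d), distances = d, centroid = centroid,
                 target_interval_ms = traj$bins$target_interval_ms[rows[1]],
                 segment = segment, trial_id = trial_id,
                 produced_ms = sum(traj$bins$width_ms[rows]),
                 speed = NA_real_),
            class = "segment_geometry")
}

#' Radius variability across serial-order segments
#'
#' Pools the point-to-centroid distances of several segments (typically the
#' six serial-order elements of a trial, or all segments of one target
#' interval) and returns their standard deviation. The alternative
#' \code{method = "radii_sd"} takes the SD of the per-segment radii instead.
#'
#' @param geoms list of \code{segment_geometry} objects.
#' @param method "pooled" (default) or "radii_sd".
#' @return numeric SD.
#' @export
radius_variability <- function(geoms, method = c("pooled", "radii_sd")) {
  method <- match.arg(method)
  if (!length(geoms)) stop("no segment geometries supplied")
  if (length(geoms) < 6)
    attr(geoms, "flag") <- "fewer than six serial-order segments"
  if (method == "pooled")
    stats::sd(unlist(lapply(geoms, `[[`, "distances")))
  else
    stats::sd(vapply(geoms, `[[`, 0, "radius"))
}

#' Linear speed of a trajectory segment
#'
#' Mean over bins of the Euclidean displacement between consecutive bin
#' states (components 1-3 by default) divided by the bin duration; requires a
#' real-time (TIND or raw) trajectory.
#'
#' @inheritParams segment_radius
#' @param dims components used (default 1:3).
#' @return speed in trajectory units per second.
#' @export
linear_speed <- function(traj, trial_id, segment, dims = 1:3) {
  if (traj$mode == "UTND")
    stop("linear speed requires a real-time (TIND or raw20) trajectory")
  rows <- traj_rows(traj, trial_id, segment)
  if (length(rows) < 2) stop("segment needs at least 2 bins for a speed")
  pts <- traj$Y[rows, dims, drop = FALSE]
  step <- sqrt(rowSums(diff(pts)^2))
  dt_s <- diff(traj$bins$time_ms[rows]) / 1000
  mean(step / dt_s)
}

#' Geometry table over all segments of a trajectory
#'
#' Convenience wrapper computing radius (components 2-3), linear speed
#' (components 1-3, real-time modes only) and the produced duration for every
#' (trial, segment) pair.
#'
#' @param traj a \code{neural_trajectory}.
#' @param dims_radius,dims_speed component selections.
#' @return data.frame with one row per segment and the pooled distances as a
#'   list attribute \code{"geoms"}.
#' @export
trajectory_geometry <- function(traj, dims_radius = c(2, 3),
                                dims_speed = 1:3) {
  key <- unique(traj$bins[, c("trial_id", "segment")])
  geoms <- vector("list", nrow(key))
  rows <- lapply(seq_len(nrow(key)), function(i)
    segment_radius(traj, key$trial_id[i], key$segment[i], dims_radius))
  speed <- rep(NA_real_, nrow(key))
  if (traj$mode != "UTND")
    speed <- vapply(seq_len(nrow(key)), function(i)
      linear_speed(traj, key$trial_id[i], key$segment[i], dims_speed), 0)
  df <- data.frame(trial_id = key$trial_id, segment = key$segment,
                   target_interval_ms = vapply(rows, `[[`, 0,
                                               "target_interval_ms"),
                   produced_ms = vapply(rows, `[[`, 0, "produced_ms"),
                   radius = vapply(rows, `[[`, 0, "radius"),
                   speed = speed)
  attr(df, "geoms") <- rows
  df
}

#' Split segment radii by produced-interval percentile
#'
#' Within every target interval, groups segments whose produced inter-tap
#' duration falls at or below the \code{low}th percentile ("short") and at or
#' above the \code{high}th percentile ("long"), and summarizes the radii per
#' group. When the radius is coupled to the produced duration the short group
#' shows the smaller radius.
#'
#' @param geom_df data.frame from \code{\link{trajectory_geometry}} (needs
#'   \code{target_interval_ms}, \code{produced_ms}, \code{radius}).
#' @param low,high percentile cut points (defaults 20 and 80).
#' @param min_n minimum observations per target (default 10).
#' @return data.frame with columns target, group ("short"/"long"), mean
#'   radius, mean produced duration and n.
#' @export
percentile_split <- function(geom_df, low = 20, high = 80, min_n = 10) {
  out <- list()
  for (tg in sort(unique(geom_df$target_interval_ms))) {
    d <- geom_df[geom_df$target_interval_ms == tg, ]
    if (nrow(d) < min_n)
      stop("fewer than ", min_n, " produced intervals for target ", tg)
    qs <- stats::quantile(d$produced_ms, c(low, high) / 100)
    short <- d[d$produced_ms <= qs[1], ]
    long <- d[d$produced_ms >= qs[2], ]
    out[[length(out) + 1L]] <- data.frame(
      target_interval_ms = tg,
      group = c("short", "long"),
      radius = c(mean(short$radius), mean(long$radius)),
      produced_ms = c(mean(short$produced_ms), mean(long$produced_ms)),
      n = c(nrow(short), nrow(long)))
  }
  do.call(rbind, out)
}

#' Fixed-frequency sinusoid fit of a component segment
#'
#' Least-squares fit of \code{a * sin(2 pi t + c) + b t + d} to one inter-tap
#' component segment, after resampling to \code{n_bins} bins with time mapped
#' to [0, 1] s. The frequency is fixed at one cycle per produced interval, so
#' the fit is linear in \code{(a cos c, a sin c, b, d)} and solved in closed
#' form; the linear term plays the role of the detrending step. The amplitude
#' is canonicalized to \code{a >= 0} with phase \code{c} in [0, 2 pi).
#'
#' @param y numeric component values over one segment.
#' @param n_bins resampling length (default 30).
#' @return object of class \code{sinusoid_fit}: \code{a}, \code{c}, \code{d},
#'   \code{slope}, \code{mse}, \code{fitted}, \code{t}.
#' @export
fit_sinusoid <- function(y, n_bins = 30) {
  y <- resample_series(y, n_bins)
  t <- seq(0, 1, length.out = n_bins)
  B <- cbind(sin(2 * pi * t), cos(2 * pi * t), t, 1)
  beta <- stats::lm.fit(B, y)$coefficients
  beta[is.na(beta)] <- 0
  a <- sqrt(beta[1]^2 + beta[2]^2)
  cc <- atan2(beta[2], beta[1]) %% (2 * pi)
  fitted <- as.vector(B %*% beta)
  structure(list(a = unname(a), c = unname(cc), d = unname(beta[4]),
                 slope = unname(beta[3]),
                 mse = mean((y - fitted)^2), fitted = fitted, t = t),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat("<sinusoid_fit> a =", signif(x$a, 4), " c =", signif(x$c, 4),
      " d =", signif(x$d, 4), " MSE =", signif(x$mse, 4), "\n")
  invisible(x)
}

# linear resampling of a series to n points (endpoints preserved)
resample_series <- function(y, n) {
  if (length(y) == n) return(as.numeric(y))
  stats::approx(seq(0, 1, length.out = length(y)), y,
                xout = seq(0, 1, length.out = n))$y
}

resample_segment <- function(Y, n) {
  apply(Y, 2, resample_series, n = n)
}

#' Anchor-point distances of tap and half-interval states
#'
#' Tests the tangent-circle picture: trajectories for different tempos form
#' loops of different radii that share a common state near the tap. An anchor
#' point is placed in state space (default: centroid of all tap-time states;
#' alternative: the point minimizing the variance of the anchor-to-tap
#' distances), and for every segment the Euclidean distances from the anchor
#' to the segment's tap state (\code{d_t}) and to its half-interval state
#' (\code{d_h}) are computed, with linear regressions of each against target
#' interval.
#'
#' @param traj a \code{neural_trajectory} (shared loading matrix across
#'   targets).
#' @param dims components used (default \code{c(2, 3)}).
#' @param anchor_rule "tap_centroid" or "optimize".
#' @return object of class \code{anchor_distances}: \code{anchor},
#'   \code{per_segment} data.frame (target, trial, segment, d_t, d_h),
#'   \code{fit_dt} and \code{fit_dh} (lm objects of distance ~ target).
#' @export
anchor_distance_analysis <- function(traj, dims = c(2, 3),
                                     anchor_rule = c("tap_centroid",
                                                     "optimize")) {
  anchor_rule <- match.arg(anchor_rule)
  key <- unique(traj$bins[, c("trial_id", "segment")])
  tap_states <- half_states <- matrix(NA_real_, nrow(key), length(dims))
  tg <- numeric(nrow(key))
  for (i in seq_len(nrow(key))) {
    rows <- traj_rows(traj, key$trial_id[i], key$segment[i])
    tap_states[i, ] <- traj$Y[rows[1], dims]
    half_states[i, ] <- traj$Y[rows[ceiling(length(rows) / 2)], dims]
    tg[i] <- traj$bins$target_interval_ms[rows[1]]
  }
  anchor <- colMeans(tap_states)
  if (anchor_rule == "optimize") {
    obj <- function(a) stats::var(sqrt(colSums((t(tap_states) - a)^2)))
    anchor <- stats::optim(anchor, obj)$par
  }
  d_t <- sqrt(colSums((t(tap_states) - anchor)^2))
  d_h <- sqrt(colSums((t(half_states) - anchor)^2))
  per <- data.frame(target_interval_ms = tg, trial_id = key$trial_id,
                    segment = key$segment, d_t = d_t, d_h = d_h)
  structure(list(anchor = anchor, per_segment = per,
                 fit_dt = stats::lm(d_t ~ target_interval_ms, per),
                 fit_dh = stats::lm(d_h ~ target_interval_ms, per)),
            class = "anchor_distances")
}

#' Bin-by-bin distance between two trajectories
#'
#' Resamples every segment of both trajectories to a common bin count and
#' returns the Euclidean distance between corresponding bins (reference
#' first), together with per-segment mean and SD. Used with the shortest
#' tempo as reference, the mean distance grows with the other trajectory's
#' target interval when amplitude (not time) encodes tempo.
#'
#' @param ref_traj,other_traj \code{neural_trajectory} objects with the same
#'   number of segments per trial.
#' @param dims components used (default 1:3; use 1 for a demixed component).
#' @param n_bins common per-segment bin count (default 30).
#' @param ref_trial,other_trial trial selections (defaults: first trial of
#'   each).
#' @return list: \code{distance} (vector over bins), \code{per_segment}
#'   data.frame (segment, mean, sd).
#' @export
distance_profile <- function(ref_traj, other_traj, dims = 1:3, n_bins = 30,
                             ref_trial = NULL, other_trial = NULL) {
  if (is.null(ref_trial)) ref_trial <- ref_traj$bins$trial_id[1]
  if (is.null(other_trial)) other_trial <- other_traj$bins$trial_id[1]
  segs_r <- sort(unique(ref_traj$bins$segment[
    ref_traj$bins$trial_id == ref_trial]))
  segs_o <- sort(unique(other_traj$bins$segment[
    other_traj$bins$trial_id == other_trial]))
  if (length(segs_r) != length(segs_o))
    stop("segment counts differ between trajectories")
  dist_all <- numeric(0)
  per <- list()
  for (i in seq_along(segs_r)) {
    A <- resample_segment(ref_traj$Y[traj_rows(ref_traj, ref_trial,
                                               segs_r[i]), dims,
                                     drop = FALSE], n_bins)
    B <- resample_segment(other_traj$Y[traj_rows(other_traj, other_trial,
                                                 segs_o[i]), dims,
                                       drop = FALSE], n_bins)
    d <- sqrt(rowSums((A - B)^2))
    dist_all <- c(dist_all, d)
    per[[i]] <- data.frame(segment = segs_r[i], mean = mean(d),
                           sd = stats::sd(d))
  }
  list(distance = dist_all, per_segment = do.call(rbind, per))
}
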