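#' Second-layer PCA segment cloud
#'
#' Captures the shape of every inter-tap trajectory segment as a single
#' 3-coordinate point: each segment of one first-layer component is
#' resampled to 30 bins (removing the length bias across tempos), the
#' segments x 30 matrix gets a second-layer principal-component
#' decomposition, and the first three scores of each segment form its
#' coordinates.
#'
#' @param traj a \code{neural_trajectory}.
#' @param component which first-layer component to use (default 1).
#' @param n_bins per-segment resampling length (default 30).
#' @param keep number of second-layer coordinates (default 3).
#' @return object of class \code{segment_cloud}: \code{coords} (segments x
#'   keep), \code{labels} data.frame (target interval, trial, segment),
#'   \code{component}, \code{rotation}, \code{explained}.
#' @export
build_segment_cloud <- function(traj, component = 1, n_bins = 30, keep = 3) {
  key <- unique(traj$bins[, c("trial_id", "segment")])
  if (nrow(key) < 2) stop("need at least 2 segments")
  rows_ok <- logical(nrow(key))
  S <- matrix(NA_real_, nrow(key), n_bins)
  tg <- numeric(nrow(key))
  for (i in seq_len(nrow(key))) {
    rows <- traj_rows(traj, key$trial_id[i], key$segment[i])
    if (length(rows) < 3) {
      warning("segment with fewer than 3 bins excluded")
      next
    }
    S[i, ] <- resample_series(traj$Y[rows, component], n_bins)
    tg[i] <- traj$bins$target_interval_ms[rows[1]]
    rows_ok[i] <- TRUE
  }
  S <- S[rows_ok, , drop = FALSE]
  key <- key[rows_ok, , drop = FALSE]
  tg <- tg[rows_ok]
  pca <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  keep <- min(keep, ncol(pca$x))
  structure(list(coords = pca$x[, seq_len(keep), drop = FALSE],
                 labels = data.frame(target_interval_ms = tg,
                                     trial_id = key$trial_id,
                                     segment = key$segment),
                 component = component, rotation = pca$rotation,
                 explained = pca$sdev^2 / sum(pca$sdev^2)),
            class = "segment_cloud")
}

#' @export
print.segment_cloud <- function(x, ...) {
  cat("<segment_cloud>", nrow(x$coords), "segments x", ncol(x$coords),
      "coords from component", x$component, "\n")
  invisible(x)
}

#' Classify target interval from a segment cloud
#'
#' Repeated stratified k-fold cross-validation of a linear one-vs-one SVM on
#' the second-layer coordinates, with the target interval as the class.
#'
#' @param cloud a \code{\link{build_segment_cloud}} result (or a list with
#'   \code{coords} and \code{labels$target_interval_ms}).
#' @param repeats classifier retrainings with fresh fold splits (default 10).
#' @param folds cross-validation folds (default 5).
#' @param C SVM cost (default 1).
#' @param permute_labels if TRUE the class labels are randomly permuted
#'   before each repeat (chance-level control).
#' @return object of class \code{interval_classification}: \code{accuracy}
#'   (mean over repeats), \code{sd}, \code{per_repeat}, \code{chance}.
#' @export
classify_interval <- function(cloud, repeats = 10, folds = 5, C = 1,
                              permute_labels = FALSE) {
  X <- cloud$coords
  y <- factor(cloud$labels$target_interval_ms)
  counts <- table(y)
  if (any(counts < folds))
    stop("every class needs at least ", folds, " segments; got ",
         min(counts))
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    yy <- if (permute_labels) sample(y) else y
    fold <- stratified_folds(yy, folds)
    hits <- 0L
    for (f in seq_len(folds)) {
      te <- fold == f
      m <- linear_svm(X[!te, , drop = FALSE], yy[!te], C)
      hits <- hits + sum(predict(m, X[te, , drop = FALSE]) == yy[te])
    }
    acc[r] <- hits / length(yy)
  }
  structure(list(accuracy = mean(acc), sd = stats::sd(acc),
                 per_repeat = acc, chance = 1 / nlevels(y),
                 n = length(y)), class = "interval_classification")
}

#' @export
print.interval_classification <- function(x, ...) {
  cat("<interval_classification> accuracy", round(100 * x$accuracy, 1),
      "+/-", round(100 * x$sd, 1), "% (chance",
      round(100 * x$chance, 1), "%)\n")
  invisible(x)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Best-component selection by classification accuracy
#' @param traj a \code{neural_trajectory}.
#' @param components candidate first-layer components (default all).
#' @param ... passed to \code{\link{classify_interval}}.
#' @return list with \code{best} (component index) and \code{accuracy} per
#'   candidate.
#' @export
best_component <- function(traj, components = seq_len(traj$n_components),
                           ...) {
  acc <- vapply(components, function(pc)
    classify_interval(build_segment_cloud(traj, pc), ...)$accuracy, 0)
  list(best = components[which.max(acc)],
       accuracy = stats::setNames(acc, components))
}

#' Population ablation schedule
#'
#' Orders neurons by the magnitude of their loading on the chosen component
#' and produces retained-fraction steps of 100%, 90%, ..., 10%, 1%: at each
#' step the most strongly contributing remaining neurons have been removed.
#'
#' @param coeffs a \code{\link{fit_coefficients}} result.
#' @param component loading row used for the ordering (the best component).
#' @param fractions retained fractions (default \code{c(seq(1, 0.1, -0.1),
#'   0.01)}).
#' @param min_neurons floor on the smallest retained set (default 15, the
#'   published endpoint of the 1\% step; capped at the population size).
#' @return object of class \code{ablation_schedule}: \code{order} (neuron
#'   indices by decreasing loading magnitude), \code{fractions},
#'   \code{component}, \code{min_neurons}.
#' @export
ablation_schedule <- function(coeffs, component = 1,
                              fractions = c(seq(1, 0.1, -0.1), 0.01),
                              min_neurons = 15) {
  if (is.unsorted(rev(fractions), strictly = TRUE) ||
      any(fractions <= 0) || any(fractions > 1))
    stop("fractions must be strictly decreasing in (0, 1]")
  w <- abs(coeffs$P[component, ])
  structure(list(order = order(w, decreasing = TRUE),
                 fractions = fractions, component = component,
                 n = length(w),
                 min_neurons = max(1L, min(min_neurons, length(w)))),
            class = "ablation_schedule")
}

#' Classification accuracy under population ablation
#'
#' For every retained fraction of the schedule, removes the top-loading
#' neurons, re-projects the data with the original loadings restricted to
#' the retained set (optionally re-fits them), rebuilds the second-layer
#' segment cloud and re-runs the cross-validated classifier.
#'
#' @param binned normalized \code{binned_population} (trajectory input,
#'   typically TIND).
#' @param coeffs fitted loadings on the full population.
#' @param schedule an \code{\link{ablation_schedule}}; default built from
#'   \code{component}.
#' @param component first-layer component classified (the best component).
#' @param refit re-fit the loadings on the retained population (default
#'   TRUE, which reproduces the published above-chance robustness down to
#'   small ensembles; \code{FALSE} restricts the original loadings instead,
#'   which decays to chance at the smallest sets).
#' @param train_binned UTND \code{binned_population} used for re-fitting
#'   loadings; required when \code{refit = TRUE}.
#' @param smooth,span passed to \code{\link{project_trajectory}}.
#' @param ... passed to \code{\link{classify_interval}}.
#' @return data.frame: fraction, n_neurons, accuracy, sd.
#' @export
ablate_and_classify <- function(binned, coeffs, schedule = NULL,
                                component = 1, refit = TRUE,
                                train_binned = NULL, smooth = TRUE,
                                span = 0.1, ...) {
  if (is.null(schedule)) schedule <- ablation_schedule(coeffs, component)
  n <- schedule$n
  out <- list()
  min_keep <- if (is.null(schedule$min_neurons)) 1L else schedule$min_neurons
  for (fr in schedule$fractions) {
    n_keep <- max(min_keep, round(fr * n))
    drop_ids <- schedule$order[seq_len(n - n_keep)]
    keep <- setdiff(seq_len(n), drop_ids)
    sub <- subset_neurons(binned, keep)
    cf <- if (refit) {
      if (is.null(train_binned)) stop("refit = TRUE needs train_binned")
      fit_coefficients(subset_neurons(train_binned, keep),
                       n_components = coeffs$n_retained)
    } else {
      restrict_coeffs(coeffs, keep)
    }
    traj <- project_trajectory(cf, sub, smooth = smooth, span = span)
    cl <- classify_interval(build_segment_cloud(traj, component), ...)
    out[[length(out) + 1L]] <- data.frame(fraction = fr, n_neurons = n_keep,
                                          accuracy = cl$accuracy,
                                          sd = cl$sd)
  }
  do.call(rbind, out)
}

subset_neurons <- function(binned, keep) {
  binned$X <- binned$X[keep, , drop = FALSE]
  binned$neuron_ids <- binned$neuron_ids[keep]
  if (!is.null(binned$silent)) binned$silent <- binned$silent[keep]
  if (!is.null(binned$max_rates)) binned$max_rates <- binned$max_rates[keep]
  binned
}

restrict_coeffs <- function(coeffs, keep) {
  coeffs$P <- coeffs$P[, keep, drop = FALSE]
  coeffs$center <- coeffs$center[keep]
  coeffs$neuron_ids <- coeffs$neuron_ids[keep]
  coeffs
}
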