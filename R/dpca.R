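#' Marginalize a binned population over task parameters
#'
#' Decomposes the neurons x bins matrix into parameter-specific averages:
#' a condition-independent (time) part, a target-interval part, and a noise
#' residual, such that \code{X = mean + X_time + X_interval + X_noise}
#' exactly. Columns must carry a target-interval label and a within-segment
#' time index; trials of every target are first resampled to a common bin
#' count (30 per segment) and averaged per condition, the demixing
#' convention for tempo comparisons on the time-normalized grid.
#'
#' @param binned a \code{binned_population} (TIND input is resampled to
#'   \code{n_bins} per segment; UTND input with equal bin counts is used
#'   directly when \code{n_bins} matches).
#' @param n_bins common per-segment bin count (default 30).
#' @return object of class \code{dpca_marginalization}: \code{X}
#'   (condition-averaged, grand mean removed, neurons x (targets *
#'   n_bins * segments)), \code{X_phi} (list with \code{time} and
#'   \code{interval} matrices), \code{X_noise}, \code{grand_mean},
#'   \code{labels} (per-column target and time index), \code{n_bins}.
#' @export
marginalize <- function(binned, n_bins = 30) {
  b <- binned$bins
  if (anyNA(b$target_interval_ms))
    stop("every column needs a target-interval label")
  targets <- sort(unique(b$target_interval_ms))
  segs <- sort(unique(b$segment))
  n_seg <- length(segs)
  n_neu <- nrow(binned$X)
  # resample every (trial, segment) to n_bins, then average per target
  cond_sum <- array(0, c(n_neu, n_bins * n_seg, length(targets)))
  cond_n <- integer(length(targets))
  per_trial <- list()
  key <- unique(b[, c("trial_id", "target_interval_ms")])
  for (i in seq_len(nrow(key))) {
    tr <- key$trial_id[i]
    tg_i <- match(key$target_interval_ms[i], targets)
    M <- matrix(NA_real_, n_neu, n_bins * n_seg)
    for (s in seq_len(n_seg)) {
      rows <- which(b$trial_id == tr & b$segment == segs[s])
      if (!length(rows)) stop("trial ", tr, " lacks segment ", segs[s])
      M[, (s - 1) * n_bins + seq_len(n_bins)] <-
        t(resample_segment(t(binned$X[, rows, drop = FALSE]), n_bins))
    }
    cond_sum[, , tg_i] <- cond_sum[, , tg_i] + M
    cond_n[tg_i] <- cond_n[tg_i] + 1L
    per_trial[[i]] <- list(M = M, target = key$target_interval_ms[i])
  }
  cond_avg <- lapply(seq_along(targets), function(k) cond_sum[, , k] /
                       cond_n[k])
  Xavg <- do.call(cbind, cond_avg)
  grand_mean <- rowMeans(Xavg)
  Xc <- Xavg - grand_mean
  tvec <- rep(seq_len(n_bins * n_seg), length(targets))
  gvec <- rep(targets, each = n_bins * n_seg)
  # time marginalization: average over targets at each time index
  time_prof <- sapply(seq_len(n_bins * n_seg), function(j)
    rowMeans(Xc[, tvec == j, drop = FALSE]))
  X_time <- time_prof[, tvec, drop = FALSE]
  X_interval <- Xc - X_time
  # noise: per-trial deviation from its condition average, on the same grid
  X_noise <- do.call(cbind, lapply(per_trial, function(p)
    p$M - cond_avg[[match(p$target, targets)]]))
  structure(list(X = Xc, X_phi = list(time = X_time, interval = X_interval),
                 X_noise = X_noise, grand_mean = grand_mean,
                 labels = data.frame(target_interval_ms = gvec,
                                     time_index = tvec),
                 n_bins = n_bins, targets = targets, n_segments = n_seg),
            class = "dpca_marginalization")
}

#' Fit the demixed decomposition
#'
#' For every marginalization, finds encoder (\code{F}) and decoder (\code{D})
#' matrices minimizing \code{sum_phi ||X_phi - F_phi D_phi X||^2} by
#' ridge-regularized reduced-rank regression: with \code{A_phi = X_phi X'
#' (X X' + lambda I)^(-1)}, the rank-constrained solution takes the leading
#' left singular vectors \code{U} of \code{A_phi X}, giving \code{F_phi = U}
#' and \code{D_phi = U' A_phi}. Components are ordered by explained
#' marginalized variance.
#'
#' @param marg a \code{\link{marginalize}} result.
#' @param n_components components per marginalization (default 5).
#' @param lambda ridge parameter; default \code{1e-6} times the mean diagonal
#'   of \code{X X'}.
#' @return object of class \code{dpca_model}: per-marginalization lists with
#'   \code{F}, \code{D}, \code{scores} (components x bins of the averaged
#'   data) and \code{explained_var}; plus \code{loss} and the input
#'   \code{marg}.
#' @export
fit_dpca <- function(marg, n_components = 5, lambda = NULL) {
  if (n_components < 1) stop("n_components must be >= 1")
  X <- marg$X
  XXt <- X %*% t(X)
  if (is.null(lambda)) lambda <- 1e-6 * mean(diag(XXt))
  G <- XXt + diag(lambda, nrow(XXt))
  Ginv <- tryCatch(solve(G), error = function(e) {
    warning("rank-deficient covariance; increasing ridge")
    solve(XXt + diag(1e-3 * mean(diag(XXt)) + 1e-12, nrow(XXt)))
  })
  comps <- list()
  loss <- 0
  for (phi in names(marg$X_phi)) {
    Xp <- marg$X_phi[[phi]]
    A <- Xp %*% t(X) %*% Ginv
    sv <- svd(A %*% X, nu = n_components, nv = 0)
    U <- sv$u[, seq_len(min(n_components, ncol(sv$u))), drop = FALSE]
    Fm <- U
    Dm <- t(U) %*% A
    S <- Dm %*% X
    tot <- sum(Xp^2)
    ev <- if (tot > 0)
      vapply(seq_len(nrow(S)), function(k)
        1 - sum((Xp - Fm[, k, drop = FALSE] %*% S[k, , drop = FALSE])^2) /
          tot, 0)
    else rep(0, nrow(S))
    ord <- order(ev, decreasing = TRUE)
    comps[[phi]] <- list(F = Fm[, ord, drop = FALSE],
                         D = Dm[ord, , drop = FALSE],
                         scores = S[ord, , drop = FALSE],
                         explained_var = ev[ord],
                         marg_var = tot)
    loss <- loss + sum((Xp - Fm %*% Dm %*% X)^2)
  }
  structure(list(components = comps, loss = loss, lambda = lambda,
                 marg = marg), class = "dpca_model")
}

#' @export
print.dpca_model <- function(x, ...) {
  cat("<dpca_model> loss", signif(x$loss, 5), "\n")
  for (phi in names(x$components))
    cat("  ", phi, ": explained ",
        paste0(round(100 * x$components[[phi]]$explained_var, 1), "%",
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score new data with fitted demixed decoders
#' @param model a \code{dpca_model}.
#' @param X neurons x bins matrix (same neuron set as the fit).
#' @param phi marginalization name ("interval" or "time").
#' @return components x bins score matrix.
#' @export
dpca_scores <- function(model, X, phi = "interval") {
  model$components[[phi]]$D %*% (X - model$marg$grand_mean)
}

#' Loss of arbitrary rank-k projections (reference check)
#'
#' Evaluates the demixing loss obtained by substituting a given orthonormal
#' projection for the fitted encoder/decoder of each marginalization; used to
#' verify the fitted loss is no worse than random projections or plain
#' principal axes of the same rank.
#'
#' @param marg a \code{\link{marginalize}} result.
#' @param U neurons x k orthonormal matrix.
#' @return total loss over marginalizations.
#' @export
dpca_projection_loss <- function(marg, U) {
  X <- marg$X
  loss <- 0
  for (phi in names(marg$X_phi)) {
    Xp <- marg$X_phi[[phi]]
    # optimal D for fixed encoder U: D = argmin ||Xp - U D X||^2
    D <- t(U) %*% Xp %*% t(X) %*% solve(X %*% t(X) +
                                          diag(1e-9, nrow(X)))
    loss <- loss + sum((Xp - U %*% D %*% X)^2)
  }
  loss
}
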