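# Time-delay network for tap-time decoding: 20 input delays of the first
# trajectory component, one 10-unit sigmoid hidden layer, one sigmoid output
# trained toward 1 at tap bins and 0 elsewhere, ridge-penalized squared error
# minimized with BFGS (the ridge stands in for Bayesian-regularized
# backpropagation).

sigmoid <- function(x) 1 / (1 + exp(-x))

tdnn_unpack <- function(th, d, h) {
  i <- 0
  W1 <- matrix(th[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- th[i + seq_len(h)]; i <- i + h
  w2 <- th[i + seq_len(h)]; i <- i + h
  b2 <- th[i + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

tdnn_forward <- function(pars, X) {
  H <- sigmoid(sweep(X %*% pars$W1, 2, pars$b1, `+`))
  list(H = H, out = sigmoid(as.vector(H %*% pars$w2 + pars$b2)))
}

tdnn_fit <- function(X, y, hidden = 10, lambda = 1e-3, maxit = 300,
                     restarts = 2) {
  d <- ncol(X)
  n <- nrow(X)
  obj <- function(th) {
    p <- tdnn_unpack(th, d, hidden)
    f <- tdnn_forward(p, X)
    mean((f$out - y)^2) + lambda * (sum(p$W1^2) + sum(p$w2^2))
  }
  grad <- function(th) {
    p <- tdnn_unpack(th, d, hidden)
    f <- tdnn_forward(p, X)
    e <- 2 * (f$out - y) / n
    do <- e * f$out * (1 - f$out)               # d loss / d pre-output
    gw2 <- as.vector(t(f$H) %*% do) + 2 * lambda * p$w2
    gb2 <- sum(do)
    dh <- outer(do, p$w2) * f$H * (1 - f$H)     # n x h
    gW1 <- t(X) %*% dh + 2 * lambda * p$W1
    gb1 <- colSums(dh)
    c(as.vector(gW1), gb1, gw2, gb2)
  }
  best <- NULL
  converged <- FALSE
  for (r in seq_len(restarts)) {
    th0 <- stats::rnorm((d + 2) * hidden + 1, 0, 0.3)
    fit <- stats::optim(th0, obj, grad, method = "BFGS",
                        control = list(maxit = maxit))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) converged <- TRUE
  }
  if (!converged)
    warning("time-delay network did not converge; best of ", restarts,
            " restarts reported")
  c(tdnn_unpack(best$par, d, hidden),
    list(value = best$value, converged = converged))
}

# delay-embedded design matrix: row t holds the series at t-d+1 .. t
delay_embed <- function(x, d) {
  n <- length(x)
  if (n < d) stop("series shorter than the delay window")
  idx <- outer(seq(d, n), seq(-d + 1, 0), `+`)
  matrix(x[idx], nrow = n - d + 1)
}

#' Train a time-delay tap decoder
#'
#' Trains a small time-delay network (default 20 delays of a 20-ms binned
#' first-component series, 10 sigmoid hidden units, sigmoid output) to emit 1
#' at tap bins and 0 otherwise, under k-fold cross-validation over trials.
#' The held-out outputs of every fold are stored, decoded with the peak
#' threshold rule and scored against the produced taps; a final network
#' trained on all trials is kept for decoding new series.
#'
#' @param trials list of trials, each a list with \code{series} (component
#'   values on a regular real-time grid), \code{time_ms} (bin centres) and
#'   \code{tap_times_ms}.
#' @param folds cross-validation folds over trials (default 5).
#' @param delays input delay count (default 20).
#' @param hidden hidden units (default 10).
#' @param threshold output peak threshold (default 0.12).
#' @param window_ms correctness window: a decoded tap is correct when within
#'   this distance of a produced tap (default 60 ms).
#' @param lambda ridge penalty (default 1e-5).
#' @param maxit,restarts optimizer budget per fold.
#' @return object of class \code{tap_decoder}: \code{net} (final weights),
#'   \code{fold_nets}, \code{cv} (per-trial held-out decoding: decoded tap
#'   times, matches, errors), \code{frac_correct} (held-out fraction of
#'   produced taps decoded within the window), \code{interval_errors}
#'   (decoded minus produced interval, held-out), plus the architecture
#'   fields.
#' @export
train_tap_decoder <- function(trials, folds = 5, delays = 20, hidden = 10,
                              threshold = 0.12, window_ms = 60,
                              lambda = 1e-5, maxit = 1000, restarts = 2) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  n_tr <- length(trials)
  if (n_tr < folds) stop("need at least as many trials as folds")
  emb <- lapply(trials, function(tr) {
    X <- delay_embed(tr$series, delays)
    tms <- tr$time_ms[delays:length(tr$time_ms)]
    bw <- stats::median(diff(tr$time_ms))
    y <- as.numeric(vapply(tms, function(t)
      any(abs(tr$tap_times_ms - t) <= bw / 2), TRUE))
    list(X = X, y = y, time_ms = tms, taps = tr$tap_times_ms)
  })
  mu <- mean(unlist(lapply(emb, function(e) e$X)))
  sdv <- stats::sd(unlist(lapply(emb, function(e) e$X)))
  if (sdv == 0) sdv <- 1
  for (i in seq_along(emb)) emb[[i]]$X <- (emb[[i]]$X - mu) / sdv
  fold_of <- rep_len(seq_len(folds), n_tr)[sample.int(n_tr)]
  fold_nets <- vector("list", folds)
  cv <- list()
  for (f in seq_len(folds)) {
    tr_idx <- which(fold_of != f)
    Xtr <- do.call(rbind, lapply(emb[tr_idx], `[[`, "X"))
    ytr <- unlist(lapply(emb[tr_idx], `[[`, "y"))
    net <- tdnn_fit(Xtr, ytr, hidden, lambda, maxit, restarts)
    fold_nets[[f]] <- net
    for (i in which(fold_of == f)) {
      out <- tdnn_forward(net, emb[[i]]$X)$out
      dec <- decode_peaks(out, emb[[i]]$time_ms, threshold)
      sc <- score_taps(dec, emb[[i]]$taps, window_ms,
                       span = range(emb[[i]]$time_ms))
      cv[[length(cv) + 1L]] <- c(list(trial = i, output = out,
                                      time_ms = emb[[i]]$time_ms,
                                      decoded = dec), sc)
    }
  }
  net_all <- tdnn_fit(do.call(rbind, lapply(emb, `[[`, "X")),
                      unlist(lapply(emb, `[[`, "y")),
                      hidden, lambda, maxit, restarts)
  n_hit <- sum(vapply(cv, function(z) z$n_correct, 0L))
  n_tap <- sum(vapply(cv, function(z) z$n_taps, 0L))
  structure(list(net = net_all, fold_nets = fold_nets, cv = cv,
                 frac_correct = n_hit / n_tap,
                 interval_errors = unlist(lapply(cv, `[[`,
                                                 "interval_errors")),
                 delays = delays, hidden = hidden, threshold = threshold,
                 window_ms = window_ms, scale = c(mu = mu, sd = sdv),
                 fold_of = fold_of),
            class = "tap_decoder")
}

#' @export
print.tap_decoder <- function(x, ...) {
  cat("<tap_decoder>", x$delays, "delays,", x$hidden, "hidden units;",
      "held-out taps within", x$window_ms, "ms:",
      round(100 * x$frac_correct, 1), "%\n")
  invisible(x)
}

# peaks of the network output above threshold
decode_peaks <- function(out, time_ms, threshold) {
  n <- length(out)
  if (n < 3) return(numeric(0))
  is_peak <- out > threshold &
    out >= c(-Inf, out[-n]) & out > c(out[-1], -Inf)
  time_ms[is_peak]
}

# greedy nearest matching of decoded to produced taps, each consumable once;
# only taps inside the decodable span (plus the correctness window) count
score_taps <- function(decoded, taps, window_ms, span = NULL) {
  if (!is.null(span))
    taps <- taps[taps >= span[1] - window_ms & taps <= span[2] + window_ms]
  n_taps <- length(taps)
  if (!length(decoded))
    return(list(n_correct = 0L, n_taps = n_taps, n_decoded = 0L,
                matches = numeric(0), interval_errors = numeric(0)))
  used <- rep(FALSE, n_taps)
  match_tap <- rep(NA_real_, length(decoded))
  for (k in order(vapply(decoded, function(d) min(abs(taps - d)), 0))) {
    j <- order(abs(taps - decoded[k]))
    j <- j[!used[j]][1]
    if (is.na(j)) next
    if (abs(taps[j] - decoded[k]) < window_ms) {
      used[j] <- TRUE
      match_tap[k] <- taps[j]
    }
  }
  ok <- !is.na(match_tap)
  ie <- if (sum(ok) > 1) diff(decoded[ok]) - diff(match_tap[ok])
        else numeric(0)
  list(n_correct = sum(used), n_taps = n_taps, n_decoded = length(decoded),
       matches = match_tap, interval_errors = ie)
}

#' Decode tap times from a component series
#'
#' Runs a trained decoder on a series: output peaks above the threshold
#' become decoded taps; when produced taps are supplied each decoded tap is
#' matched greedily to the nearest unused produced tap and counted correct
#' if within the correctness window, and decoded-versus-produced interval
#' errors are returned.
#'
#' @param decoder a \code{\link{train_tap_decoder}} result.
#' @param series component values on a regular real-time grid.
#' @param time_ms bin centres of the series.
#' @param tap_times_ms optional produced taps to score against.
#' @return list: \code{decoded_ms}, \code{output}, and when taps are given
#'   \code{n_correct}, \code{n_taps}, \code{matches},
#'   \code{interval_errors}.
#' @export
decode_taps <- function(decoder, series, time_ms, tap_times_ms = NULL) {
  X <- (delay_embed(series, decoder$delays) - decoder$scale["mu"]) /
    decoder$scale["sd"]
  tms <- time_ms[decoder$delays:length(time_ms)]
  out <- tdnn_forward(decoder$net, X)$out
  dec <- decode_peaks(out, tms, decoder$threshold)
  res <- list(decoded_ms = dec, output = out, time_ms = tms)
  if (!is.null(tap_times_ms))
    res <- c(res, score_taps(dec, tap_times_ms, decoder$window_ms,
                             span = range(tms)))
  res
}
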