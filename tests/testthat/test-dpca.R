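# helper: binned object with a given per-condition pattern
# pattern_fn(target, bin) -> neuron vector; trials: reps per target
toy_binned <- function(targets, n_neurons, n_bins, pattern_fn, reps = 1,
                       noise_sd = 0) {
  Xs <- list(); metas <- list(); tid <- 0
  for (tg in targets) for (r in seq_len(reps)) {
    tid <- tid + 1
    M <- vapply(seq_len(n_bins), function(b) pattern_fn(tg, b), numeric(n_neurons))
    if (noise_sd > 0) M <- M + matrix(rnorm(length(M), 0, noise_sd),
                                      n_neurons)
    Xs[[tid]] <- M
    metas[[tid]] <- data.frame(trial_id = tid, condition = "SC",
                               target_interval_ms = tg, segment = 1,
                               bin = seq_len(n_bins),
                               time_ms = seq_len(n_bins) * 20 - 10,
                               norm_time = (seq_len(n_bins) - 0.5) / n_bins,
                               width_ms = 20)
  }
  bumptraj:::new_binned(do.call(cbind, Xs), do.call(rbind, metas), "TIND",
                        seq_len(n_neurons))
}

test_that("marginalization decomposes exactly and isolates planted effects", {
  set.seed(1)
  n <- 12; nb <- 30
  base <- matrix(rnorm(n * nb), n)                # shared time course
  # zero interval effect: identical means across intervals
  b0 <- toy_binned(c(450, 650, 850), n, nb, function(tg, b) base[, b])
  m0 <- marginalize(b0, n_bins = nb)
  expect_lt(max(abs(m0$X_phi$interval)), 1e-10)
  # planted additive interval effect with a known norm
  eff <- outer(rnorm(n), sin(2 * pi * seq_len(nb) / nb))
  shift <- c(`450` = -1, `650` = 0, `850` = 1)
  b1 <- toy_binned(c(450, 650, 850), n, nb, function(tg, b)
    base[, b] + shift[[as.character(tg)]] * eff[, b])
  m1 <- marginalize(b1, n_bins = nb)
  # conservation: marginalizations plus grand mean reconstruct the average
  recon <- m1$grand_mean + m1$X_phi$time + m1$X_phi$interval
  expect_equal(recon, m1$X + m1$grand_mean, tolerance = 1e-10)
  expect_equal(sum(m1$X_phi$interval^2), sum(shift^2) * sum(eff^2) / 1,
               tolerance = 1e-8)
  # per-trial noise residual completes the decomposition
  set.seed(2)
  b2 <- toy_binned(c(450, 650), n, nb, function(tg, b) base[, b],
                   reps = 3, noise_sd = 0.1)
  m2 <- marginalize(b2, n_bins = nb)
  expect_equal(dim(m2$X_noise), c(n, nb * 6))
  expect_gt(sd(m2$X_noise), 0.05)
})

test_that("demixing recovers a planted rank-1 interval component", {
  set.seed(3)
  n <- 15; nb <- 30
  base <- outer(rnorm(n), cos(2 * pi * seq_len(nb) / nb))
  load_vec <- rnorm(n)
  tc <- sin(2 * pi * seq_len(nb) / nb)            # planted time course
  # amplitude deviations with zero mean: the interval effect occupies its
  # own marginalization (a nonzero mean would leak into the time average)
  amp <- c(`450` = -1, `650` = 0, `850` = 1)
  b <- toy_binned(c(450, 650, 850), n, nb, function(tg, b)
    base[, b] + amp[[as.character(tg)]] * load_vec * tc[b])
  model <- fit_dpca(marginalize(b, n_bins = nb), n_components = 2)
  s1 <- model$components$interval$scores[1, ]
  planted <- as.vector(vapply(names(amp), function(a)
    amp[[a]] * tc, numeric(nb)))
  expect_gt(abs(cor(s1, planted)), 0.999)
  # pure noise: interval marginalization explains almost nothing
  set.seed(4)
  bn <- toy_binned(c(450, 650, 850), n, nb, function(tg, b) rnorm(n) * 0,
                   reps = 1, noise_sd = 1)
  mn <- marginalize(bn, n_bins = nb)
  frac <- sum(mn$X_phi$interval^2) / sum(mn$X^2)
  model_n <- fit_dpca(mn, n_components = 2)
  expect_lt(model_n$components$interval$marg_var, sum(mn$X^2))
})

test_that("fitted loss beats random orthogonal projections of the same rank", {
  set.seed(5)
  n <- 10; nb <- 20
  b <- toy_binned(c(450, 650), n, nb, function(tg, b)
    rnorm(n, mean = tg / 650), reps = 2, noise_sd = 0.3)
  marg <- marginalize(b, n_bins = nb)
  model <- fit_dpca(marg, n_components = 2)
  worse <- 0
  for (k in seq_len(200)) {
    U <- qr.Q(qr(matrix(rnorm(n * 2), n)))
    if (dpca_projection_loss(marg, U) < model$loss - 1e-8) worse <- worse + 1
  }
  expect_equal(worse, 0)
  # and beats (or matches) plain principal axes of the same rank
  pc <- prcomp(t(marg$X), center = FALSE)
  U_pca <- pc$rotation[, 1:2]
  expect_lte(model$loss, dpca_projection_loss(marg, U_pca) + 1e-8)
})

test_that("demixed and ordinary distance profiles agree in shape on simulation", {
  set.seed(6)
  cfg <- small_config()
  exp <- simulate_experiment(cfg)
  prep <- bumptraj:::prepare_trajectories(exp)
  marg <- marginalize(prep$tind, n_bins = 30)
  model <- fit_dpca(marg, n_components = 2)
  nbt <- 30 * marg$n_segments
  s1 <- model$components$interval$scores
  d_dpca <- sqrt((s1[1, seq_len(nbt)] - s1[1, nbt + seq_len(nbt)])^2)
  # ordinary components 1-3 distance on condition-averaged data
  avg_scores <- prep$coeffs$P[1:3, ] %*% (marg$X + marg$grand_mean -
                                            prep$coeffs$center)
  d_pca <- sqrt(colSums((avg_scores[, seq_len(nbt)] -
                           avg_scores[, nbt + seq_len(nbt)])^2))
  ks <- suppressWarnings(ks.test(scale(d_pca), scale(d_dpca)))
  expect_gt(ks$p.value, 0.01)
})
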