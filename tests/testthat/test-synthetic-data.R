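test_that("activation profiles have the contracted support, peak and determinism", {
  set.seed(1)
  p <- simulate_activation_profile(257)
  expect_equal(length(p$waveform), 257)
  expect_equal(max(p$waveform), 1)
  expect_true(all(p$waveform >= 0))
  # identical waveforms under an identical RNG state
  set.seed(99); p1 <- simulate_activation_profile(197)
  set.seed(99); p2 <- simulate_activation_profile(197)
  expect_identical(p1$waveform, p2$waveform)
  expect_error(simulate_activation_profile(-5), "positive")
})

test_that("a single gamma component matches the closed-form density", {
  params <- data.frame(mode_frac = 0.4, shape = 4, amp = 1)
  p <- simulate_activation_profile(257, params = params, edge_taper = 0)
  t <- seq(0.5, by = 1, length.out = 257)
  oracle <- dgamma(t, shape = 4, scale = 0.4 * 257 / 3)
  expect_equal(p$waveform, oracle / max(oracle), tolerance = 1e-12)
})

test_that("moving bump uses the published counts and durations and recruits Gaussianly", {
  cfg <- sim_config(noise_sd = 0, seed = 1)
  set.seed(2)
  a450 <- simulate_moving_bump(cfg, 450)
  expect_equal(nrow(a450$rate), 108)
  expect_equal(a450$duration_ms, 197)
  a1000 <- simulate_moving_bump(cfg, 1000)
  expect_equal(nrow(a1000$rate), 182)
  expect_equal(a1000$duration_ms, 257)
  expect_error(simulate_moving_bump(cfg, 700), "not present")
  expect_error(simulate_moving_bump(cfg, 450, n_neurons = 1), "at least 2")
  # first cells activate before the interval-start tap, last finish after the
  # interval-end tap, and the cascade repeats cyclically
  t0 <- a450$tap_times_ms[1]
  expect_lt(min(a450$onset_ms), t0)
  expect_gt(max(a450$offset_ms), t0 + 450)
  # recruitment positions follow the configured truncated Gaussian (KS check)
  set.seed(3)
  u <- recruit_positions(10000, 0.5, 150 / 450, method = "random")
  plo <- pnorm(0, 0.5, 150 / 450); phi <- pnorm(1, 0.5, 150 / 450)
  cdf <- function(x) (pnorm(x, 0.5, 150 / 450) - plo) / (phi - plo)
  ks <- suppressWarnings(ks.test(u, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("population pattern is cyclic and reproducible", {
  cfg <- small_config()
  set.seed(4)
  a <- simulate_moving_bump(cfg, 450, noise_sd = 0)
  pop <- colSums(a$rate)
  # rate pattern within consecutive produced intervals is near-identical
  taps <- a$tap_times_ms
  seg <- function(k) pop[(taps[k] + 1):(taps[k + 1])]
  expect_gt(cor(seg(1), seg(2)), 0.95)
  expect_gt(cor(seg(2), seg(3)), 0.95)
  # lag-T autocorrelation (inside the tapped span) beats non-multiple lags
  core <- pop[(taps[1] + 1):taps[4]]
  lagcor <- function(x, k) cor(x[seq_len(length(x) - k)],
                               x[(k + 1):length(x)])
  off <- c(150, 225, 300, 600, 675)
  expect_true(all(lagcor(core, 450) > vapply(off, lagcor, 0, x = core)))
  # seeded determinism of the full experiment
  e1 <- simulate_experiment(small_config(seed = 7))
  e2 <- simulate_experiment(small_config(seed = 7))
  expect_identical(e1$trials[[3]]$activity$rate, e2$trials[[3]]$activity$rate)
})

test_that("extending a bump inserts intermediate cells and preserves order", {
  cfg <- sim_config(noise_sd = 0)
  set.seed(5)
  base <- simulate_moving_bump(cfg, 450)
  expect_identical(extend_bump_population(base, 0), base)
  ext <- extend_bump_population(base, 74)
  expect_equal(nrow(ext$rate), 182)
  # original cells keep their relative order of peak times
  expect_identical(order(ext$peak_times_ms[1:108]),
                   order(base$peak_times_ms))
  # inserted peaks fall strictly between the earliest and latest base peaks
  new_peaks <- ext$peak_times_ms[109:182]
  expect_true(all(new_peaks > min(base$peak_times_ms) &
                    new_peaks < max(base$peak_times_ms)))
})

test_that("profile count conservation holds per interval and repetition", {
  cfg <- small_config(reps = 2)
  exp <- simulate_experiment(cfg)
  for (tr in exp$trials) {
    expected <- cfg$n_neurons_by_interval[[as.character(tr$interval)]]
    expect_equal(sum(tr$activity$active), expected)
    expect_equal(length(tr$activity$profiles), expected)
  }
})

test_that("behaviour generator honours constant error and Weber scaling", {
  bc0 <- behavior_config(weber_fraction = 0, constant_error_ms = 0,
                         n_trials = 2)
  ev <- generate_behavior(bc0, 650)
  expect_equal(diff(trial_times(ev, 1)), rep(650, 6))
  # sample SD close to weber * target at n = 1000 intervals
  set.seed(6)
  bc <- behavior_config(weber_fraction = 0.05, constant_error_ms = 0,
                        n_trials = 167)
  ev <- generate_behavior(bc, 1000)
  produced <- unlist(lapply(unique(ev$trial_id), function(tr)
    diff(trial_times(ev, tr))))
  se_sd <- 50 / sqrt(2 * length(produced))
  expect_lt(abs(sd(produced) - 50), 3 * se_sd)
  # default constant error is a small underestimation at every target
  set.seed(7)
  for (tg in c(450, 850)) {
    ev <- generate_behavior(behavior_config(n_trials = 50), tg)
    m <- behavior_metrics(ev)
    expect_lt(m$per_target$constant_error_ms, 0)
  }
})

test_that("scalar property: produced-interval SD regression recovers the Weber fraction", {
  set.seed(8)
  targets <- c(450, 650, 850, 1000)
  sds <- vapply(targets, function(tg) {
    ev <- generate_behavior(behavior_config(weber_fraction = 0.05,
                                            n_trials = 84), tg)
    sd(unlist(lapply(unique(ev$trial_id), function(tr)
      diff(trial_times(ev, tr)))))
  }, 0)
  slope <- regression_summary(sds, targets)$slope
  expect_lt(abs(slope - 0.05) / 0.05, 0.10)
})

test_that("reactive control is stimulus-locked and aperiodic", {
  set.seed(9)
  ctrl <- simulate_reactive_control(seq(450, 950, 100), n_neurons = 40)
  stims <- trial_times(ctrl$events, 1, "stimulus")
  expect_false(all(diff(diff(stims)) == 0))   # not an isochronous metronome
  # zero jitter puts taps exactly at stimulus + latency
  set.seed(10)
  ctrl0 <- simulate_reactive_control(c(500, 700), latency_jitter_ms = 0,
                                     n_neurons = 10)
  stims0 <- trial_times(ctrl0$events, 1, "stimulus")
  expect_equal(sort(trial_times(ctrl0$events, 1, "tap")), stims0 + 381)
  # periodic simulator has a strong autocorrelation peak at its interval;
  # the reactive control does not, at any pool interval
  set.seed(11)
  lagcor <- function(x, k) cor(x[seq_len(length(x) - k)],
                               x[(k + 1):length(x)])
  per <- simulate_moving_bump(small_config(), 450, noise_sd = 0)
  tp <- per$tap_times_ms
  pop_per <- colSums(per$rate)[(tp[1] + 1):tp[length(tp)]]
  pop_ctl <- colSums(ctrl$activity$rate)
  expect_gt(lagcor(pop_per, 450), 0.8)
  expect_true(all(vapply(seq(450, 950, 100), lagcor, 0, x = pop_ctl) < 0.6))
})
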