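# small trajectory with two amplitude families (targets) for classifier tests
two_family_traj <- function(n_per = 8, amp = c(1, 3), n_bins = 24,
                            noise = 0.02) {
  trajs <- list(); tid <- 0
  for (f in 1:2) for (k in seq_len(n_per)) {
    tid <- tid + 1
    th <- 2 * pi * seq_len(n_bins) / n_bins
    Y <- cbind(amp[f] * sin(th) + rnorm(n_bins, 0, noise),
               amp[f] * cos(th) + rnorm(n_bins, 0, noise),
               rnorm(n_bins, 0, noise))
    trajs[[tid]] <- make_traj(Y, trial_id = tid,
                              target = c(450, 1000)[f])
  }
  do.call(bind_traj, trajs)
}

test_that("segment clouds capture shape and separate amplitude families", {
  # identical segments collapse to one point
  traj <- bind_traj(make_traj(circle_points(30), trial_id = 1),
                    make_traj(circle_points(30), trial_id = 2),
                    make_traj(circle_points(30), trial_id = 3))
  cl <- build_segment_cloud(traj, component = 2)
  expect_lt(max(dist(cl$coords)), 1e-9)
  # two families differing in amplitude separate along one coordinate
  set.seed(1)
  cl2 <- build_segment_cloud(two_family_traj(), component = 1)
  sep <- abs(tapply(cl2$coords[, 1], cl2$labels$target_interval_ms, mean))
  spread <- tapply(cl2$coords[, 1], cl2$labels$target_interval_ms, sd)
  expect_gt(abs(diff(tapply(cl2$coords[, 1],
                            cl2$labels$target_interval_ms, mean))),
            10 * max(spread))
  # degenerate short segments are excluded with a warning
  traj$bins$segment[traj$bins$trial_id == 3][3:30] <- 2
  expect_warning(build_segment_cloud(traj, component = 1), "excluded")
})

test_that("interval classification is perfect on separated clouds and at chance when permuted", {
  set.seed(2)
  cl <- build_segment_cloud(two_family_traj(n_per = 10), component = 1)
  res <- classify_interval(cl, repeats = 3, folds = 5)
  expect_equal(res$accuracy, 1)
  # label permutation: accuracy within 3 binomial SDs of chance (50%)
  perm <- classify_interval(cl, repeats = 10, folds = 5,
                            permute_labels = TRUE)
  n <- nrow(cl$coords)
  expect_lt(abs(perm$accuracy - 0.5), 3 * sqrt(0.25 / (n * 10)) + 0.15)
  # class with fewer members than folds errors
  cl_small <- cl
  keep <- c(1:3, 11:20)
  cl_small$coords <- cl$coords[keep, ]
  cl_small$labels <- cl$labels[keep, ]
  expect_error(classify_interval(cl_small, folds = 5), "at least")
})

test_that("ablation schedules order by loading magnitude and keep accuracy above chance", {
  set.seed(3)
  cfg <- small_config(noise_sd = 0.02, reps = 3)
  exp <- simulate_experiment(cfg)
  prep <- bumptraj:::prepare_trajectories(exp)
  sch <- ablation_schedule(prep$coeffs, component = 1,
                           fractions = c(1, 0.5, 0.2))
  w <- abs(prep$coeffs$P[1, ])
  expect_true(all(diff(w[sch$order]) <= 1e-12))
  expect_error(ablation_schedule(prep$coeffs, fractions = c(0.5, 1)),
               "decreasing")
  curve <- ablate_and_classify(prep$tind, prep$coeffs, sch,
                               component = 1, refit = FALSE,
                               repeats = 2, folds = 3)
  # the refit route needs the UTND training matrix
  expect_error(ablate_and_classify(prep$tind, prep$coeffs, sch,
                                   component = 1, repeats = 2, folds = 3),
               "train_binned")
  refit_curve <- ablate_and_classify(prep$tind, prep$coeffs, sch,
                                     component = 1,
                                     train_binned = prep$utnd,
                                     repeats = 2, folds = 3)
  expect_true(all(refit_curve$accuracy > 0.5))
  expect_equal(curve$fraction, c(1, 0.5, 0.2))
  expect_equal(curve$n_neurons, c(32, 16, 15))
  # both-interval classification stays above the 50% chance level
  expect_true(all(curve$accuracy > 0.5))
  # full-population step agrees with a direct classification
  direct <- classify_interval(build_segment_cloud(prep$traj, 1),
                              repeats = 2, folds = 3)
  expect_lt(abs(curve$accuracy[1] - direct$accuracy), 0.15)
})

test_that("magnitude-ordered removal hurts more than random removal", {
  set.seed(4)
  cfg <- small_config(noise_sd = 0.02, reps = 3)
  exp <- simulate_experiment(cfg)
  prep <- bumptraj:::prepare_trajectories(exp)
  n <- prep$coeffs$neuron_ids
  frac <- 0.2
  top <- ablate_and_classify(prep$tind, prep$coeffs,
                             ablation_schedule(prep$coeffs, 1,
                                               fractions = c(1, frac)),
                             component = 1, refit = FALSE,
                             repeats = 3, folds = 3)
  # random schedule: same sizes, random order (averaged over draws)
  accs <- replicate(3, {
    sch <- ablation_schedule(prep$coeffs, 1, fractions = c(1, frac))
    sch$order <- sample(sch$order)
    ablate_and_classify(prep$tind, prep$coeffs, sch, component = 1,
                        refit = FALSE, repeats = 3, folds = 3)$accuracy[2]
  })
  expect_lte(top$accuracy[2], mean(accs) + 0.1)
})

test_that("tap decoder rules behave as specified", {
  # threshold rule: a single peak above 0.12 becomes one tap
  out <- c(0.05, 0.08, 0.3, 0.1, 0.05)
  expect_equal(bumptraj:::decode_peaks(out, 1:5 * 20, 0.12), 60)
  expect_equal(length(bumptraj:::decode_peaks(rep(0.05, 30), 1:30, 0.12)), 0)
  # 60-ms correctness window: 55 ms off counts, 65 ms off does not
  sc <- bumptraj:::score_taps(c(555, 1065), c(500, 1000), 60)
  expect_equal(sc$n_correct, 1L)
  sc2 <- bumptraj:::score_taps(c(555, 1055), c(500, 1000), 60)
  expect_equal(sc2$n_correct, 2L)
})

test_that("time-delay decoder recovers taps from clean periodic input", {
  set.seed(5)
  # sinusoidal component with taps at a fixed phase, several tempos
  trials <- lapply(1:10, function(k) {
    T_ms <- c(500, 800)[(k %% 2) + 1]
    t <- seq(10, 4000, by = 20)
    taps <- seq(T_ms, 3800, by = T_ms)
    list(series = sin(2 * pi * t / T_ms), time_ms = t, tap_times_ms = taps)
  })
  dec <- suppressWarnings(train_tap_decoder(trials, folds = 5, maxit = 400))
  expect_gte(dec$frac_correct, 0.99)
  # decoded-minus-produced interval errors are centred at zero
  expect_lt(abs(mean(dec$interval_errors)), 10)
  # constant input, no taps decodable -> no peaks above threshold
  flat <- decode_taps(dec, rep(0, 100), seq(10, by = 20, length.out = 100))
  expect_equal(length(flat$decoded_ms), 0)
})
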