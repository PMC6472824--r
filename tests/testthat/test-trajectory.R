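test_that("shared loading fit orders variance, is orthonormal and recovers planted planes", {
  set.seed(1)
  cfg <- small_config()
  exp <- simulate_experiment(cfg)
  utnd <- combine_binned(lapply(exp$trials, function(tr)
    bin_population(tr$activity, "UTND", trial_id = tr$trial_id)))
  cf <- fit_coefficients(normalize_rates(utnd))
  expect_true(all(diff(cf$explained) <= 1e-12))
  PPt <- cf$P[1:8, ] %*% t(cf$P[1:8, ])
  expect_lt(max(abs(PPt - diag(8))), 1e-8)
  # rank-2 planted data: two orthogonal oscillatory modes, no noise
  n <- 20; nb <- 200
  u <- qr.Q(qr(matrix(rnorm(n * 2), n)))       # orthonormal neuron modes
  ph <- 2 * pi * seq_len(nb) / 50
  X <- u[, 1] %o% sin(ph) + u[, 2] %o% cos(ph)
  b <- bumptraj:::new_binned(X, data.frame(trial_id = 1, condition = "SC",
                                           target_interval_ms = 650,
                                           segment = 1, bin = seq_len(nb),
                                           time_ms = seq_len(nb),
                                           norm_time = seq_len(nb) / nb,
                                           width_ms = 1), "UTND", 1:n)
  cf2 <- suppressWarnings(fit_coefficients(b, n_components = 2))
  # principal angle between fitted and planted planes ~ 0
  sv <- svd(cf2$P[1:2, , drop = FALSE] %*% u)$d
  expect_lt(max(abs(sv - 1)), 1e-6)
  # degenerate input
  b0 <- b; b0$X[] <- 0
  expect_error(suppressWarnings(fit_coefficients(b0)), "zero variance")
})

test_that("projection reproduces training scores, checks neurons and is deterministic", {
  set.seed(2)
  cfg <- small_config()
  exp <- simulate_experiment(cfg)
  utnd <- normalize_rates(combine_binned(lapply(exp$trials, function(tr)
    bin_population(tr$activity, "UTND", trial_id = tr$trial_id))))
  cf <- fit_coefficients(utnd)
  traj <- project_trajectory(cf, utnd, smooth = FALSE)
  # consistency with the underlying decomposition scores
  sc <- t(cf$P[1:8, ] %*% (utnd$X - cf$center))
  expect_equal(traj$Y, sc, tolerance = 1e-10)
  # identical rates give identical trajectories
  traj2 <- project_trajectory(cf, utnd, smooth = FALSE)
  expect_identical(traj$Y, traj2$Y)
  # neuron mismatch errors name missing neurons
  sub <- bumptraj:::subset_neurons(utnd, 1:10)
  expect_error(project_trajectory(cf, sub), "missing")
  # smoothing stays within the spread of the raw scores
  trs <- project_trajectory(cf, utnd, smooth = TRUE, span = 0.1)
  raw <- attr(trs, "raw")
  expect_lt(max(abs(trs$Y - raw)), max(apply(raw, 2, function(x)
    diff(range(x)))))
})

test_that("segment radius matches exact and quadrature geometry", {
  Y <- circle_points(360, radius = 2)
  g <- segment_radius(make_traj(Y), 1, 1)
  expect_equal(g$radius, 2, tolerance = 1e-12)
  # all points identical -> radius 0 with a warning
  expect_warning(g0 <- segment_radius(make_traj(matrix(1, 10, 3)), 1, 1),
                 "degenerate")
  expect_equal(g0$radius, 0)
  expect_error(segment_radius(make_traj(matrix(1, 2, 3)), 1, 1), "3 bins")
  # ellipse with semi-axes 2 and 1: mean centre distance by quadrature
  n <- 4000
  th <- 2 * pi * (seq_len(n) - 1) / n
  Y <- cbind(0, 2 * cos(th), sin(th))
  oracle <- integrate(function(t) sqrt(4 * cos(t)^2 + sin(t)^2) / (2 * pi),
                      0, 2 * pi, rel.tol = 1e-10)$value
  g <- segment_radius(make_traj(Y), 1, 1)
  expect_equal(g$radius, oracle, tolerance = 1e-5)
})

test_that("radius variability pools distances across serial-order segments", {
  trajs <- lapply(1:6, function(k)
    make_traj(circle_points(100, radius = 2), trial_id = k))
  geoms <- lapply(1:6, function(k) segment_radius(bind_traj(trajs[[k]]), k, 1))
  expect_equal(radius_variability(geoms), 0, tolerance = 1e-12)
  # circles with radii ~ N(mu, sigma): pooled SD ~ sigma
  set.seed(3)
  sigma <- 0.2
  radii <- rnorm(1e4, 3, sigma)
  geoms <- lapply(seq_along(radii), function(k)
    segment_radius(make_traj(circle_points(10, radius = radii[k]),
                             trial_id = k), k, 1))
  expect_equal(radius_variability(geoms), sigma, tolerance = 0.05)
  # alternative summary: SD of the per-segment radii
  expect_equal(radius_variability(geoms, "radii_sd"), sd(radii),
               tolerance = 1e-6)
})

test_that("linear speed matches uniform circular motion", {
  # stationary trajectory
  expect_equal(linear_speed(make_traj(matrix(1, 20, 3)), 1, 1), 0)
  # radius R, period T sampled at 20 ms: speed ~ 2 pi R / T
  R <- 3; T_ms <- 800
  nb <- T_ms / 20
  traj <- make_traj(circle_points(nb, radius = R, dims = c(1, 2)))
  v <- linear_speed(traj, 1, 1)
  v_true <- 2 * pi * R / (T_ms / 1000)
  # chord-vs-arc discretization factor sinc(pi/nb)
  expect_equal(v, v_true * sin(pi / nb) / (pi / nb), tolerance = 1e-9)
  expect_equal(v, v_true, tolerance = 0.01)
  expect_error(linear_speed(make_traj(matrix(1, 1, 3)), 1, 1), "2 bins")
  utnd_traj <- make_traj(circle_points(50), mode = "UTND")
  expect_error(linear_speed(utnd_traj, 1, 1), "real-time")
})

test_that("percentile split separates planted radius-duration coupling", {
  set.seed(4)
  s <- 0.004                              # planted radius per ms of duration
  produced <- rnorm(60, 650, 40)
  geom <- data.frame(target_interval_ms = 650, produced_ms = produced,
                     radius = 1 + s * produced)
  ps <- percentile_split(geom)
  expect_lt(ps$radius[ps$group == "short"], ps$radius[ps$group == "long"])
  gap <- diff(ps$radius)                  # long minus short
  expect_equal(gap, s * diff(ps$produced_ms), tolerance = 1e-12)
  # identical produced intervals: groups coincide by the tie rule
  geom2 <- data.frame(target_interval_ms = 650, produced_ms = rep(650, 20),
                      radius = rep(2, 20))
  ps2 <- percentile_split(geom2)
  expect_equal(ps2$radius[1], ps2$radius[2])
  expect_error(percentile_split(geom[1:5, ]), "fewer than")
})

test_that("sinusoid fits recover exact parameters and calibrated noise MSE", {
  t <- seq(0, 1, length.out = 30)
  y <- 0.5 * sin(2 * pi * t + 1) + 0.2
  f <- fit_sinusoid(y)
  expect_equal(f$a, 0.5, tolerance = 1e-9)
  expect_equal(f$c, 1, tolerance = 1e-9)
  expect_equal(f$d, 0.2, tolerance = 1e-9)
  expect_lt(f$mse, 1e-18)
  # canonical form: negative amplitude folded into the phase
  f2 <- fit_sinusoid(-0.3 * sin(2 * pi * t + 0.5))
  expect_gte(f2$a, 0)
  expect_true(f2$c >= 0 && f2$c < 2 * pi)
  expect_equal(f2$a, 0.3, tolerance = 1e-9)
  # Gaussian noise sigma = 0.1 -> MSE ~ 0.01 (Monte-Carlo)
  set.seed(5)
  mses <- replicate(200, fit_sinusoid(y + rnorm(30, 0, 0.1))$mse)
  expect_equal(mean(mses), 0.01 * (30 - 4) / 30, tolerance = 0.15)
})

test_that("anchor distances reproduce tangent-circle geometry", {
  # circles of radius r(T) = 0.2 + 0.001 T sharing the point (0, 0),
  # traversed from the shared point (the tap state)
  targets <- c(450, 550, 650, 850, 1000)
  beta <- 0.001
  trajs <- lapply(seq_along(targets), function(i) {
    r <- 0.2 + beta * targets[i]
    make_traj(circle_points(100, radius = r, dims = c(2, 3),
                            center = c(0, r, 0), phase = pi),
              trial_id = i, target = targets[i])
  })
  traj <- do.call(bind_traj, trajs)
  ad <- anchor_distance_analysis(traj)
  # anchor at the shared tap state: d_t = 0, d_h = diameter = 2 r(T)
  expect_lt(max(ad$per_segment$d_t), 1e-9)
  expect_equal(ad$per_segment$d_h, 2 * (0.2 + beta * targets),
               tolerance = 1e-3)
  expect_equal(unname(coef(ad$fit_dh)[2]), 2 * beta, tolerance = 1e-3)
  expect_lt(abs(coef(ad$fit_dt)[2]), 1e-10)
})

test_that("distance profiles match concentric-circle geometry", {
  t1 <- make_traj(circle_points(40, radius = 2, dims = c(1, 2)))
  t2 <- make_traj(circle_points(30, radius = 5, dims = c(1, 2)))
  self <- distance_profile(t1, t1)
  expect_lt(max(self$distance), 1e-12)
  t1b <- make_traj(circle_points(30, radius = 2, dims = c(1, 2)))
  dp <- distance_profile(t1b, t2)
  expect_equal(dp$distance, rep(3, 30), tolerance = 1e-9)
  expect_equal(dp$per_segment$mean, 3, tolerance = 1e-9)
  # mismatched segment counts error
  t3 <- bind_traj(t1, make_traj(circle_points(40), segment = 2))
  expect_error(distance_profile(t3, t2), "segment counts")
})

test_that("geometry is invariant to joint orthogonal rotation", {
  set.seed(6)
  Y <- cbind(circle_points(80, radius = 2, d = 2, dims = c(1, 2)),
             matrix(rnorm(80 * 2, 0, 0.1), 80))
  R <- qr.Q(qr(matrix(rnorm(16), 4)))
  t_raw <- make_traj(Y)
  t_rot <- make_traj(Y %*% R)
  g1 <- segment_radius(t_raw, 1, 1, dims = 1:4)
  g2 <- segment_radius(t_rot, 1, 1, dims = 1:4)
  expect_equal(g1$radius, g2$radius, tolerance = 1e-10)
  expect_equal(linear_speed(t_raw, 1, 1, dims = 1:4),
               linear_speed(t_rot, 1, 1, dims = 1:4), tolerance = 1e-10)
  expect_equal(distance_profile(t_raw, t_raw, dims = 1:4)$distance,
               distance_profile(t_rot, t_rot, dims = 1:4)$distance,
               tolerance = 1e-10)
})

test_that("periodic trajectories fit sinusoids better than the reactive control", {
  set.seed(9)
  seg_mses <- function(activity) {
    b <- normalize_rates(bin_population(activity, "raw20"))
    cf <- suppressWarnings(fit_coefficients(b, n_components = 3))
    traj <- project_trajectory(cf, b, smooth = FALSE, n_components = 3)
    key <- unique(traj$bins[, c("trial_id", "segment")])
    vapply(seq_len(nrow(key)), function(i) {
      rows <- bumptraj:::traj_rows(traj, key$trial_id[i], key$segment[i])
      y <- traj$Y[rows, 1]
      fit_sinusoid(as.vector(scale(y)))$mse   # normalized sinusoid fit
    }, 0)
  }
  per <- simulate_moving_bump(small_config(), 650, noise_sd = 0.02)
  ctrl <- simulate_reactive_control(seq(450, 950, 100), n_neurons = 32,
                                    noise_sd = 0.02)
  expect_lt(mean(seg_mses(per)), mean(seg_mses(ctrl$activity)))
})
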