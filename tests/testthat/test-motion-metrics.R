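make_track <- function(x, y) data.frame(x_um = x, y_um = y)

test_that("centering translates the first point to the origin and preserves steps", {
  tr <- make_track(c(1, 2), c(1, 1))
  ct <- center_trajectory(tr)
  expect_equal(ct$x_um, c(0, 1))
  expect_equal(ct$y_um, c(0, 0))
  static <- center_trajectory(make_track(rep(5, 4), rep(5, 4)))
  expect_true(all(static$x_um == 0) && all(static$y_um == 0))
  set.seed(1)
  rnd <- make_track(cumsum(rnorm(10)), cumsum(rnorm(10)))
  expect_equal(diff(center_trajectory(rnd)$x_um), diff(rnd$x_um))
})

test_that("cumulative distance over the 30-frame window matches closed forms", {
  expect_equal(cumulative_distance(make_track(rep(1, 30), rep(2, 30))), 0)
  # straight mover at 0.05 um per frame: 29 steps
  mover <- make_track(seq(0, by = 0.05, length.out = 30), rep(0, 30))
  expect_equal(cumulative_distance(mover), 29 * 0.05)
  expect_error(cumulative_distance(make_track(1:5, 1:5), window = 30),
               "window")
  # Brownian steps are Rayleigh with mean sqrt(pi * D * dt): D = 0.005,
  # dt = 20 ms gives 0.560 um per step, about 16.3 um over the window
  spec <- particle_field_spec(n_particles = 300, diffusivity = 0.005,
                              fov_px = c(3000, 3000), n_frames = 30)
  tr <- simulate_brownian_tracks(spec, seed = 12)
  dists <- vapply(split(tr, tr$track_id), cumulative_distance, numeric(1))
  expect_equal(mean(dists), 29 * sqrt(pi * 0.005 * 20), tolerance = 0.02)
})

test_that("speed classes partition and match the published thresholds", {
  dt <- 20
  speed_track <- function(v_um_s) {
    step <- v_um_s * dt / 1000
    make_track(seq(0, by = step, length.out = 30), rep(0, 30))
  }
  expect_equal(classify_speed(speed_track(4.0), dt)$label, "FAST")
  expect_equal(classify_speed(speed_track(2.0), dt)$label, "INTERMEDIATE")
  expect_equal(classify_speed(speed_track(0), dt)$label, "SLOW")
  # partition: every speed gets exactly one class, boundaries included
  for (v in c(0, 1.6, 1.61, 3.3, 3.31, 10)) {
    lab <- classify_speed(speed_track(v), dt)$label
    expect_true(lab %in% c("FAST", "INTERMEDIATE", "SLOW"))
  }
  eps <- 1e-9  # boundaries belong to the lower class (FAST is > 3.3)
  expect_equal(classify_speed(speed_track(1.6 - eps), dt)$label, "SLOW")
  expect_equal(classify_speed(speed_track(1.6 + eps), dt)$label,
               "INTERMEDIATE")
  expect_equal(classify_speed(speed_track(3.3 - eps), dt)$label,
               "INTERMEDIATE")
  expect_equal(classify_speed(speed_track(3.3 + eps), dt)$label, "FAST")
})

test_that("MSD matches closed forms and is time-reversal symmetric", {
  static <- make_track(rep(1, 20), rep(1, 20))
  expect_true(all(compute_msd(static, 20)$msd_um2 == 0))
  # ballistic track: msd(tau) = (v tau)^2 exactly
  v <- 0.07  # um/ms
  ball <- make_track(v * 20 * (0:19), rep(0, 20))
  curve <- compute_msd(ball, 20, max_lag_fraction = 0.5)
  expect_equal(curve$msd_um2, (v * curve$lag_ms)^2, tolerance = 1e-12)
  # pair counts strictly decrease with lag
  expect_true(all(diff(curve$n_pairs) < 0))
  # time reversal leaves the estimator unchanged
  set.seed(3)
  rnd <- make_track(cumsum(rnorm(25)), cumsum(rnorm(25)))
  rev_rnd <- rnd[nrow(rnd):1, ]
  expect_equal(compute_msd(rnd, 20)$msd_um2,
               compute_msd(rev_rnd, 20)$msd_um2)
})

test_that("ensemble MSD of Brownian tracks follows the 2-D Einstein relation", {
  spec <- particle_field_spec(n_particles = 200, diffusivity = 0.005,
                              fov_px = c(3000, 3000), n_frames = 40)
  tr <- simulate_brownian_tracks(spec, seed = 8)
  curves <- lapply(split(tr, tr$track_id), compute_msd, frame_interval = 20)
  ens <- ensemble_msd(curves)
  small <- ens[1:5, ]
  expect_equal(small$msd_um2, 4 * 0.005 * small$lag_ms, tolerance = 0.1)
})

test_that("diffusion fit recovers exact lines, offsets and degenerate input", {
  lag <- (1:10) * 20
  exact <- data.frame(lag_ms = lag, msd_um2 = 4 * 0.005 * lag,
                      n_pairs = 30 - (1:10))
  fit <- fit_diffusion_coefficient(exact)
  expect_equal(fit$D, 0.005, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  # free intercept absorbs a localization-noise offset exactly
  offset <- exact; offset$msd_um2 <- offset$msd_um2 + 0.03
  fit2 <- fit_diffusion_coefficient(offset)
  expect_equal(fit2$D, 0.005, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.03, tolerance = 1e-12)
  # raw-slope convention exposed via config
  expect_equal(fit_diffusion_coefficient(exact, d_from = "slope")$D,
               4 * 0.005, tolerance = 1e-12)
  degen <- data.frame(lag_ms = lag, msd_um2 = 0, n_pairs = 29:20)
  dfit <- fit_diffusion_coefficient(degen)
  expect_true(dfit$degenerate)
  expect_equal(dfit$D, 0)
})

test_that("D is recovered from simulated ground-truth tracks", {
  spec <- particle_field_spec(n_particles = 100, diffusivity = 0.005,
                              fov_px = c(3000, 3000), n_frames = 30)
  tr <- simulate_brownian_tracks(spec, seed = 77)
  curves <- lapply(split(tr, tr$track_id), compute_msd, frame_interval = 20)
  fit <- fit_diffusion_coefficient(curves)
  expect_equal(fit$D, 0.005, tolerance = 0.15)
})

test_that("speed histogram uses left-closed 0.02-wide bins and conserves counts", {
  h <- speed_histogram(c(0.01, 0.03))
  expect_equal(h$count, c(1L, 1L))
  expect_equal(h$bin_left, c(0, 0.02))
  expect_equal(nrow(speed_histogram(numeric())), 0)
  h2 <- speed_histogram(rep(0.05, 7))
  expect_equal(sum(h2$count), 7)
  expect_equal(h2$count[h2$bin_left == 0.04], 7)
  # boundary value falls in the right-open bin above it
  h3 <- speed_histogram(c(0.02))
  expect_equal(h3$count[h3$bin_left == 0.02], 1)
  expect_error(speed_histogram(c(-0.1, 0.5)), "non-negative")
  set.seed(4)
  vals <- abs(rnorm(200, 0.3, 0.2))
  expect_equal(sum(speed_histogram(vals)$count), 200)
})

test_that("per-track metrics table assigns one class per trajectory", {
  spec <- particle_field_spec(n_particles = 20, diffusivity = 0.005,
                              fov_px = c(500, 500), n_frames = 30)
  tr <- simulate_brownian_tracks(spec, seed = 15)
  met <- motion_metrics(tr, frame_interval = 20)
  expect_equal(nrow(met), 20)
  expect_true(all(met$speed_class %in% c("FAST", "INTERMEDIATE", "SLOW")))
  expect_true(all(met$cum_distance_um >= 0))
})
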