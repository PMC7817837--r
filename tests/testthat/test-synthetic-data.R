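test_that("zero diffusivity gives constant tracks and seeds reproduce bit-exactly", {
  spec <- particle_field_spec(n_particles = 5, diffusivity = 0,
                              fov_px = c(64, 64), n_frames = 10)
  tr <- simulate_brownian_tracks(spec, seed = 11)
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    expect_equal(sub$x_um, rep(sub$x_um[1], nrow(sub)))
    expect_equal(sub$y_um, rep(sub$y_um[1], nrow(sub)))
  }
  spec2 <- particle_field_spec(n_particles = 5, diffusivity = 0.005,
                               fov_px = c(64, 64), n_frames = 10)
  expect_identical(simulate_brownian_tracks(spec2, seed = 3),
                   simulate_brownian_tracks(spec2, seed = 3))
  mv1 <- render_particle_movie(simulate_brownian_tracks(spec2, seed = 3),
                               spec2, camera_model(), seed = 4)
  mv2 <- render_particle_movie(simulate_brownian_tracks(spec2, seed = 3),
                               spec2, camera_model(), seed = 4)
  expect_identical(mv1$data, mv2$data)
})

test_that("Brownian step statistics match sqrt(2 D dt) per axis", {
  # D = 0.005 um^2/ms at dt = 20 ms: per-axis step SD = 0.4472 um
  spec <- particle_field_spec(n_particles = 400, diffusivity = 0.005,
                              fov_px = c(2000, 2000), n_frames = 251)
  tr <- simulate_brownian_tracks(spec, seed = 5)
  steps <- unlist(lapply(split(tr$x_um, tr$track_id), diff))
  expect_gt(length(steps), 1e5 - 1)
  expect_equal(stats::var(steps), 2 * 0.005 * 20, tolerance = 0.05)
  expect_equal(sd(steps), sqrt(2 * 0.005 * 20), tolerance = 0.03)
})

test_that("per-region diffusivity: empirical step-variance ratio tracks the D ratio", {
  mask <- cbind(matrix(1L, 200, 100), matrix(2L, 200, 100))
  spec <- particle_field_spec(
    n_particles = 300, diffusivity = c("1" = 0.001, "2" = 0.004),
    region_mask = mask, n_frames = 120)
  tr <- simulate_brownian_tracks(spec, seed = 9)
  # attribute each step to the region at its start
  by_track <- split(tr, tr$track_id)
  step_df <- do.call(rbind, lapply(by_track, function(s) {
    data.frame(dx = diff(s$x_um), region = s$region[-nrow(s)])
  }))
  v1 <- stats::var(step_df$dx[step_df$region == "1"])
  v2 <- stats::var(step_df$dx[step_df$region == "2"])
  expect_gt(sum(step_df$region == "2"), 1e4)
  expect_equal(v2 / v1, 4, tolerance = 0.15)
})

test_that("zero-area init region errors with the region name", {
  mask <- matrix(1L, 32, 32)
  spec <- particle_field_spec(n_particles = 3,
                              diffusivity = c("1" = 0.001, "7" = 0.002),
                              region_mask = mask, n_frames = 5)
  expect_error(simulate_brownian_tracks(spec, seed = 1, init_region = "7"),
               "'7'.*zero area")
})

test_that("rendering identities: empty field and static spot", {
  spec <- particle_field_spec(n_particles = 0, diffusivity = 0,
                              fov_px = c(32, 32), n_frames = 3)
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric())
  mv <- render_particle_movie(empty, spec, noiseless_camera())
  expect_true(all(mv$data == 0))
  # one static particle, noiseless camera: per-frame argmax at the spot
  pos <- matrix(c(3.2, 2.7), 1)
  mv2 <- static_spot_movie(pos, n_frames = 5)
  for (f in 1:5) {
    am <- which(movie_frame(mv2, f) == max(movie_frame(mv2, f)),
                arr.ind = TRUE)[1, ]
    expect_lte(abs(am["row"] - (pos[2] / 0.1 + 1)), 1)
    expect_lte(abs(am["col"] - (pos[1] / 0.1 + 1)), 1)
  }
})

test_that("spot centre exceeds background mean in nearly all noisy frames", {
  pos <- matrix(c(3.2, 3.2), 1)
  spec <- particle_field_spec(n_particles = 1, diffusivity = 0,
                              fov_px = c(64, 64), n_frames = 100,
                              spot_amplitude = 500)
  tracks <- data.frame(track_id = 1L, frame = 1:100,
                       x_um = pos[1], y_um = pos[2])
  mv <- render_particle_movie(tracks, spec,
                              camera_model(background_level = 10),
                              seed = 21)
  ctr <- c(round(pos[2] / 0.1) + 1, round(pos[1] / 0.1) + 1)
  hits <- vapply(1:100, function(f) {
    img <- movie_frame(mv, f)
    img[ctr[1], ctr[2]] > mean(img[40:60, 40:60])
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("undersampled PSF triggers a warning", {
  spec <- particle_field_spec(n_particles = 1, diffusivity = 0,
                              fov_px = c(32, 32), n_frames = 2,
                              psf_sigma = 0.03, pixel_size = 0.1)
  tracks <- data.frame(track_id = 1L, frame = 1:2, x_um = 1.5, y_um = 1.5)
  expect_warning(render_particle_movie(tracks, spec, noiseless_camera()),
                 "undersampled")
})

test_that("static bleb script renders a disc with the right area and an all-STATIONARY map", {
  sc <- bleb_script(base_radius = 5, a_max = 0, v_exp = 0, v_ret = 0)
  sim <- simulate_bleb_movie(sc, n_frames = 5, pixel_size = 0.1,
                             img_px = c(160, 160),
                             camera = noiseless_camera(), seed = 2)
  expect_true(all(sim$tricolor$labels == "STATIONARY"))
  area_px <- sum(sim$mask$data[, , 1])
  r_px <- 5 / 0.1
  # disc area within one pixel-perimeter of discretization error
  expect_lt(abs(area_px - pi * r_px^2), 2 * pi * r_px + 1)
  expect_identical(sim$mask$data[, , 1], sim$mask$data[, , 5])
})

test_that("scripted expansion labels EXPAND inside the bump while it grows", {
  sc <- bleb_script(base_radius = 6, a_max = 2.4, v_exp = 0.3, v_ret = 0.06,
                    plateau_frames = 3, start_frame = 2, theta0 = 0,
                    halfwidth = pi / 4)
  sim <- simulate_bleb_movie(sc, n_frames = 40, frame_interval = 2000,
                             pixel_size = 0.1, img_px = c(224, 224),
                             camera = noiseless_camera(), seed = 3)
  prof <- sim$profile
  grow <- which(prof$phase == "expansion")
  apex_bin <- 1  # theta0 = 0 is bin 1
  expect_true(all(sim$tricolor$labels[grow, apex_bin] == "EXPAND"))
  # outside the bump nothing ever moves
  far_bin <- 181  # theta = pi
  expect_true(all(sim$tricolor$labels[, far_bin] == "STATIONARY"))
  # ground-truth contour at the apex equals R0 + A(t)
  expect_equal(sim$contour$radius[, apex_bin], 6 + prof$amplitude)
})

test_that("scripted reporter contrast is recovered from the rendered noiseless channel", {
  sc <- bleb_script(base_radius = 6, a_max = 2.4, v_exp = 0.3, v_ret = 0.06,
                    plateau_frames = 3,
                    reporter_contrasts = list(rep = c(expansion = 2,
                                                      plateau = 2,
                                                      retraction = 1)))
  sim <- simulate_bleb_movie(sc, n_frames = 30, frame_interval = 2000,
                             pixel_size = 0.1, img_px = c(224, 224),
                             camera = noiseless_camera(), body_level = 100,
                             seed = 4)
  f <- which(sim$profile$phase == "plateau")[1]
  img <- movie_frame(sim$channels$rep, f)
  mask <- sim$mask$data[, , f] > 0
  base <- sim$mask$data[, , 1] > 0
  bleb_px <- mask & !base
  body_px <- base
  # erode the body edge: boundary pixels mix with background at rounding
  expect_equal(mean(img[bleb_px]) / mean(img[body_px]), 2, tolerance = 0.05)
})

test_that("a contour scripted beyond the field of view is rejected", {
  sc <- bleb_script(base_radius = 10, a_max = 5, v_exp = 0.5, v_ret = 0.1)
  expect_error(simulate_bleb_movie(sc, n_frames = 30, pixel_size = 0.1,
                                   img_px = c(128, 128), seed = 1),
               "field of view")
})
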