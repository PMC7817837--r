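# shared scripted movie: one bleb cycle with a plateau, noiseless mask
scripted_sim <- function(a_max = 2.4, v_exp = 0.3, v_ret = 0.06,
                         plateau_frames = 3L, n_frames = 40L,
                         halfwidth = pi / 4) {
  sc <- bleb_script(base_radius = 6, a_max = a_max, v_exp = v_exp,
                    v_ret = v_ret, plateau_frames = plateau_frames,
                    start_frame = 2L, theta0 = pi / 2,
                    halfwidth = halfwidth)
  simulate_bleb_movie(sc, n_frames = n_frames, frame_interval = 2000,
                      pixel_size = 0.1, img_px = c(224, 224),
                      camera = noiseless_camera(), seed = 50)
}

test_that("contour extraction recovers a disc and a protrusion", {
  disc <- array(0, dim = c(128, 128, 1))
  ctr <- c(65, 65)
  for (i in 1:128) for (j in 1:128) {
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 50^2) disc[i, j, 1] <- 1
  }
  mv <- movie(disc, pixel_size = 0.1, frame_interval = 1000)
  cs <- extract_contour_series(mv, n_theta = 90)
  expect_true(all(abs(cs$radius - 5.0) <= 0.1))
  # add a radial protrusion at theta = 0 (pointing +x)
  disc2 <- disc
  disc2[63:67, 115:125, 1] <- 1
  cs2 <- extract_contour_series(movie(disc2, 0.1, 1000), n_theta = 90)
  expect_gt(cs2$radius[1, 1], stats::median(cs2$radius[1, ]) + 0.8)
  # empty frame errors with the frame index
  empty <- movie(array(0, c(16, 16, 2)), 0.1, 1000)
  empty$data[8, 8, 1] <- 1
  expect_error(extract_contour_series(empty), "frame 2")
})

test_that("extracted contours match the generator ground truth within a pixel", {
  sim <- scripted_sim()
  cs <- extract_contour_series(sim$mask, n_theta = 360)
  rmse <- sqrt(mean((cs$radius - sim$contour$radius)^2))
  expect_lt(rmse, 0.1)  # 1 px at 0.1 um/px
})

test_that("radial velocity matches arithmetic and scripted ground truth", {
  r <- matrix(5, 6, 8)
  static <- contour_series(r, matrix(0, 6, 2), 1000)
  expect_true(all(radial_velocity(static) == 0))
  # one bin growing 0.1 um per 1000-ms frame: +0.1 um/s
  r2 <- r; r2[, 3] <- 5 + 0.1 * (0:5)
  grow <- contour_series(r2, matrix(0, 6, 2), 1000)
  v <- radial_velocity(grow)
  expect_equal(v[2:5, 3], rep(0.1, 4))
  expect_equal(v[1, 3], 0.1)
  # scripted expansion velocity recovered at the bleb apex
  sim <- scripted_sim(v_exp = 0.3)
  cs <- extract_contour_series(sim$mask, n_theta = 360)
  vv <- radial_velocity(cs)
  apex <- 91  # theta0 = pi/2
  exp_frames <- which(sim$profile$phase == "expansion")
  mid <- exp_frames[2:(length(exp_frames) - 1)]
  expect_equal(mean(vv[mid, apex]), 0.3, tolerance = 0.1)
})

test_that("tricolor classification is threshold-consistent and matches ground truth", {
  v <- matrix(0, 4, 6)
  expect_true(all(tricolor_map(v)$labels == "STATIONARY"))
  v2 <- matrix(1, 4, 6)
  expect_true(all(tricolor_map(v2, 0.05)$labels == "EXPAND"))
  # consistency invariant: labels always agree with velocity signs
  set.seed(9)
  v3 <- matrix(rnorm(200, 0, 0.1), 20, 10)
  m3 <- tricolor_map(v3, 0.02)
  expect_true(all((m3$labels == "EXPAND") == (v3 > 0.02)))
  expect_true(all((m3$labels == "RETRACT") == (v3 < -0.02)))
})

test_that("scripted movies yield >= 95% tricolor label agreement off phase boundaries", {
  sim <- scripted_sim()
  cs <- extract_contour_series(sim$mask, n_theta = 360)
  map <- tricolor_map(radial_velocity(cs), 0.02)
  truth <- sim$tricolor$labels
  # exclude frames adjacent to phase transitions (central differences mix
  # phases there) and bins adjacent to the bump edge
  ph <- sim$profile$phase
  boundary_frames <- which(ph != c(ph[-1], ph[length(ph)]) |
                             ph != c(ph[1], ph[-length(ph)]))
  boundary_frames <- unique(pmin(pmax(
    rep(boundary_frames, each = 3) + (-1:1), 1), nrow(truth)))
  keep_frames <- setdiff(seq_len(nrow(truth)), boundary_frames)
  gt_v <- outer(sim$profile$dA_dt,
                blebkinetics:::bleb_bump(cs$theta, pi / 2, pi / 4))
  edge_bins <- which(apply(gt_v, 2, function(col)
    any(abs(col) > 0.005 & abs(col) < 0.06)))
  keep_bins <- setdiff(seq_len(ncol(truth)), edge_bins)
  agree <- mean(map$labels[keep_frames, keep_bins] ==
                  truth[keep_frames, keep_bins])
  expect_gte(agree, 0.95)
})

test_that("bleb events are detected with correct count, ordering and size", {
  # static disc: no events
  static <- contour_series(matrix(5, 10, 90), matrix(0, 10, 2), 1000)
  expect_length(detect_bleb_events(static), 0)
  # one scripted bleb: one event, amplitude within 10%
  sim <- scripted_sim(a_max = 2.4)
  cs <- extract_contour_series(sim$mask, n_theta = 360)
  ev <- detect_bleb_events(cs)
  expect_length(ev, 1)
  expect_equal(max(ev[[1]]$amplitude), 2.4, tolerance = 0.1)
  # two synthetic blebs at disjoint angles, correct angular ordering
  theta <- 2 * pi * (0:179) / 180
  r <- matrix(5, 30, 180)
  bump1 <- blebkinetics:::bleb_bump(theta, pi / 2, pi / 6)
  bump2 <- blebkinetics:::bleb_bump(theta, 3 * pi / 2, pi / 6)
  for (f in 10:20) {
    r[f, ] <- 5 + 2 * bump1 + 1.5 * bump2
  }
  two <- contour_series(r, matrix(0, 30, 2), 1000)
  ev2 <- detect_bleb_events(two)
  expect_length(ev2, 2)
  spans <- vapply(ev2, function(e) mean(range(two$theta[e$bins])),
                  numeric(1))
  expect_lt(spans[1], spans[2])
  expect_equal(max(ev2[[1]]$amplitude), 2, tolerance = 0.05)
  expect_equal(max(ev2[[2]]$amplitude), 1.5, tolerance = 0.05)
})

test_that("events wrap across the angular seam", {
  theta <- 2 * pi * (0:179) / 180
  r <- matrix(5, 20, 180)
  bump <- blebkinetics:::bleb_bump(theta, 0, pi / 6)  # straddles theta = 0
  for (f in 5:15) r[f, ] <- 5 + 2 * bump
  ev <- detect_bleb_events(contour_series(r, matrix(0, 20, 2), 1000))
  expect_length(ev, 1)
})

test_that("phase annotation applies the 80%-of-maximum rule on a constructed profile", {
  # amplitude 0 -> 1.0 um over frames 1-11, plateau 11-15, decay to 0 by 31
  A <- c(seq(0, 1, length.out = 11), rep(1, 4), seq(1, 0, length.out = 17)[-1])
  ev <- structure(
    list(event_id = 1L, onset_frame = 1L, max_frame = 11L,
         end_frame = length(A), frames = seq_along(A), amplitude = A,
         area = A, span_rad = 0.5, bins = 1:10, frame_interval = 1000),
    class = "BlebEvent")
  ann <- annotate_phases(ev)
  expect_equal(ann$retraction_onset_frame, 15L)
  # early retraction ends at the first frame with amplitude < 0.8
  first_below <- which(seq_along(A) > 15 & A < 0.8)[1]
  expect_equal(ann$early_retraction_end_frame, first_below)
  expect_equal(unique(ann$phases[1:11]), "EARLY_EXPANSION")
  expect_equal(unique(ann$phases[12:15]), "LATE_EXPANSION")
  expect_equal(unique(ann$phases[16:(first_below - 1)]), "EARLY_RETRACTION")
  expect_equal(unique(ann$phases[first_below:length(A)]), "LATE_RETRACTION")
})

test_that("symmetric triangle profile has no late expansion; monotone rise is flagged", {
  A <- c(seq(0, 1, length.out = 10), seq(1, 0, length.out = 10)[-1])
  ev <- structure(
    list(event_id = 1L, onset_frame = 1L, max_frame = 10L,
         end_frame = length(A), frames = seq_along(A), amplitude = A,
         area = A, span_rad = 0.5, bins = 1:10, frame_interval = 1000),
    class = "BlebEvent")
  ann <- annotate_phases(ev)
  expect_false(any(ann$phases == "LATE_EXPANSION", na.rm = TRUE))
  expect_equal(ann$retraction_onset_frame, 10L)
  mono <- ev
  mono$amplitude <- seq(0.1, 1, length.out = length(A))
  mono$max_frame <- length(A)
  ann2 <- annotate_phases(mono)
  expect_true(ann2$truncated)
  expect_error(retraction_velocity(ann2), "no retraction")
})

test_that("scripted plateau frames become LATE_EXPANSION", {
  sim <- scripted_sim(plateau_frames = 5L)
  cs <- extract_contour_series(sim$mask, n_theta = 360)
  ev <- annotate_phases(detect_bleb_events(cs)[[1]])
  plateau_frames <- which(sim$profile$phase == "plateau")
  got <- ev$frames[which(ev$phases == "LATE_EXPANSION")]
  # the scripted plateau is recovered within one frame at each end
  expect_lte(abs(min(got) - min(plateau_frames)), 1)
  expect_lte(abs(max(got) - (max(plateau_frames) + 1)), 1)
})

test_that("retraction velocity matches arithmetic and scripted ground truth", {
  # amplitude falling 1.0 um over 10 frames at 1000 ms: 0.1 um/s
  A <- c(seq(0, 1, length.out = 6), seq(1, 0, length.out = 11)[-1])
  ev <- structure(
    list(event_id = 1L, onset_frame = 1L, max_frame = 6L,
         end_frame = length(A), frames = seq_along(A), amplitude = A,
         area = A, span_rad = 0.5, bins = 1:10, frame_interval = 1000),
    class = "BlebEvent")
  expect_equal(retraction_velocity(ev), 0.1, tolerance = 1e-9)
  sim <- scripted_sim(v_ret = 0.06)
  cs <- extract_contour_series(sim$mask, n_theta = 360)
  ev2 <- annotate_phases(detect_bleb_events(cs)[[1]])
  expect_equal(retraction_velocity(ev2), 0.06, tolerance = 0.1)
  expect_equal(expansion_velocity(ev2), 0.3, tolerance = 0.1)
})

test_that("segmentation of a noisy fluorescence movie produces a usable mask", {
  sc <- bleb_script(base_radius = 6, a_max = 2, v_exp = 0.25, v_ret = 0.05)
  sim <- simulate_bleb_movie(sc, n_frames = 10, frame_interval = 2000,
                             pixel_size = 0.1, img_px = c(224, 224),
                             camera = camera_model(background_level = 5),
                             body_level = 100, seed = 6)
  seg <- segment_movie(sim$channels[[1]])
  overlap <- mean((seg$data > 0) == (sim$mask$data > 0))
  expect_gt(overlap, 0.98)
})
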