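#' Quantum-dot diffusion recovery experiment
#'
#' One replicate of the reference cytoplasmic-fluidity experiment:
#' simulate Brownian quantum dots at 50 Hz, render them under the camera
#' model, re-detect and re-link them with the tracking pipeline, and
#' estimate the diffusion coefficient from the ensemble MSD slope.
#' Particles are seeded away from the field edge (margin of `margin_px`)
#' so that 30-frame excursions rarely meet the reflecting boundary and
#' the free-diffusion Einstein relation applies.
#'
#' @param seed integer seed for this replicate.
#' @param d_true true diffusion coefficient, um^2/ms.
#' @param n_particles particles simulated.
#' @param n_frames frames at `frame_interval` ms.
#' @param frame_interval frame interval, ms.
#' @param fov_px square field-of-view side, px (0.1 um/px).
#' @param margin_px seeding margin, px.
#' @param fit_lags MSD lags fitted; defaults to the quarter-track rule
#'   (`floor(n_frames / 4)`), the standard guidance for short tracks,
#'   where the time-averaged MSD at higher lags grows too noisy and
#'   correlated to help the fit.
#' @return list with `d_hat` (um^2/ms), `rel_error`, `n_tracks`.
#' @export
qd_tracking_experiment <- function(seed, d_true = 0.005,
                                   n_particles = 100L, n_frames = 30L,
                                   frame_interval = 20, fov_px = 512L,
                                   margin_px = 40L,
                                   fit_lags = max(2L, n_frames %/% 4L)) {
  mask <- matrix(2L, fov_px, fov_px)
  inner <- (margin_px + 1L):(fov_px - margin_px)
  mask[inner, inner] <- 1L
  spec <- particle_field_spec(
    n_particles = n_particles,
    diffusivity = c("1" = d_true, "2" = d_true),
    region_mask = mask, n_frames = n_frames,
    frame_interval = frame_interval, pixel_size = 0.1)
  truth <- simulate_brownian_tracks(spec, seed = seed, init_region = "1")
  mv <- render_particle_movie(truth, spec, camera_model(),
                              seed = seed + 10000L)
  tracks <- track_movie(mv, sigma = 1.5,
                        gate_radius = suggested_gate(d_true,
                                                     frame_interval),
                        min_track_length = 10L)
  curves <- lapply(split(tracks, tracks$track_id), compute_msd,
                   frame_interval = frame_interval)
  fit <- fit_diffusion_coefficient(curves, fit_lags = fit_lags)
  list(d_hat = fit$D, rel_error = fit$D / d_true - 1,
       n_tracks = length(unique(tracks$track_id)))
}

#' Two-region diffusion contrast experiment
#'
#' Simulates quantum dots in a field split into a "body" half and a
#' "bleb" half with `d_bleb = ratio * d_body`, runs the full tracking
#' pipeline, assigns each recovered trajectory to the region holding its
#' mean position, and fits D per region — the synthetic analogue of
#' comparing cytoplasmic fluidity inside and outside a bleb.
#'
#' @param seed integer seed.
#' @param d_body body diffusion coefficient, um^2/ms.
#' @param ratio bleb/body diffusivity ratio.
#' @param n_particles particles simulated.
#' @param fov_px square field side, px (0.1 um/px).
#' @return list with `d_body_hat`, `d_bleb_hat`, `correct_order`.
#' @export
two_region_experiment <- function(seed, d_body = 0.00125, ratio = 4,
                                  n_particles = 80L, fov_px = 256L) {
  half <- fov_px %/% 2L
  mask <- cbind(matrix(1L, fov_px, half),
                matrix(2L, fov_px, fov_px - half))
  d_bleb <- ratio * d_body
  spec <- particle_field_spec(
    n_particles = n_particles,
    diffusivity = c("1" = d_body, "2" = d_bleb),
    region_mask = mask, n_frames = 30L, frame_interval = 20,
    pixel_size = 0.1)
  truth <- simulate_brownian_tracks(spec, seed = seed)
  mv <- render_particle_movie(truth, spec, camera_model(),
                              seed = seed + 10000L)
  tracks <- track_movie(mv, sigma = 1.5,
                        gate_radius = suggested_gate(d_bleb, 20),
                        min_track_length = 10L)
  midline <- half * 0.1
  fit_region <- function(sel) {
    ids <- names(sel)[sel]
    sub <- tracks[tracks$track_id %in% as.integer(ids), , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    curves <- lapply(split(sub, sub$track_id), compute_msd,
                     frame_interval = 20)
    fit_diffusion_coefficient(curves)$D
  }
  mean_x <- tapply(tracks$x_um, tracks$track_id, mean)
  d_body_hat <- fit_region(mean_x < midline)
  d_bleb_hat <- fit_region(mean_x >= midline)
  list(d_body_hat = d_body_hat, d_bleb_hat = d_bleb_hat,
       correct_order = isTRUE(d_bleb_hat > d_body_hat))
}

#' Scripted bleb-cycle recovery experiment
#'
#' Simulates one scripted bleb cycle (expansion at `5 * v_ret`, a short
#' plateau, retraction at `v_ret`), re-extracts the contour from the mask
#' movie and measures everything the morphometrics stage reports,
#' together with the scripted ground truth. Scripted values are chosen so
#' phase changes land on frame boundaries, as ground-truth scripts
#' should.
#'
#' @param a_max scripted maximal amplitude, um.
#' @param v_ret scripted retraction velocity, um/s.
#' @param plateau_frames frames held at `a_max`.
#' @param frame_interval frame interval, ms.
#' @return list of recovered and ground-truth quantities (`a_max_hat`,
#'   `v_exp_hat`, `v_ret_hat`, `early_retraction_end`, and `gt_*`
#'   counterparts) plus the tricolor agreement fraction off phase
#'   boundaries (`tricolor_agreement`).
#' @export
bleb_recovery_experiment <- function(a_max = 2.4, v_ret = 0.04,
                                     plateau_frames = 4L,
                                     frame_interval = 2000) {
  v_exp <- 5 * v_ret
  dt_s <- frame_interval / 1000
  n_frames <- ceiling(a_max / (v_exp * dt_s)) + plateau_frames +
    ceiling(a_max / (v_ret * dt_s)) + 6L
  sc <- bleb_script(base_radius = 6, a_max = a_max, v_exp = v_exp,
                    v_ret = v_ret, plateau_frames = plateau_frames,
                    start_frame = 2L, theta0 = pi / 2, halfwidth = pi / 4)
  sim <- simulate_bleb_movie(sc, n_frames = n_frames,
                             frame_interval = frame_interval,
                             pixel_size = 0.1, img_px = c(224L, 224L),
                             camera = noiseless_camera(), seed = 1L)
  series <- extract_contour_series(sim$mask, n_theta = 360L)
  events <- detect_bleb_events(series)
  stopifnot(length(events) >= 1)
  ev <- annotate_phases(events[[which.max(
    vapply(events, function(e) max(e$amplitude), numeric(1)))]])
  # ground truth from the amplitude schedule
  A <- sim$profile$amplitude
  gt_ret_onset <- which(sim$profile$phase == "retraction")[1]
  gt_80 <- which(seq_along(A) >= gt_ret_onset & A < 0.8 * max(A))[1]
  map <- tricolor_map(radial_velocity(series), 0.02)
  agree <- tricolor_agreement(map, sim, series)
  list(a_max_hat = max(ev$amplitude),
       v_exp_hat = expansion_velocity(ev, frame_interval),
       v_ret_hat = retraction_velocity(ev, frame_interval),
       early_retraction_end = ev$early_retraction_end_frame,
       gt_a_max = a_max, gt_v_exp = v_exp, gt_v_ret = v_ret,
       gt_early_retraction_end = gt_80,
       tricolor_agreement = agree)
}

# Fraction of (frame, bin) tricolor labels agreeing with the generator's
# ground truth, excluding frames adjacent to phase transitions (central
# time differences mix phases there) and bins near the bump edge where
# the true radial velocity sits inside the stationary band.
tricolor_agreement <- function(map, sim, series,
                               threshold = map$stationary_threshold) {
  truth <- sim$tricolor$labels
  ph <- sim$profile$phase
  change <- which(ph[-1] != ph[-length(ph)])
  bad_frames <- unique(pmin(pmax(rep(change, each = 3) + 0:2, 1),
                            nrow(truth)))
  keep_frames <- setdiff(seq_len(nrow(truth)), bad_frames)
  v_gt <- outer(sim$profile$dA_dt, bleb_bump(series$theta, pi / 2, pi / 4))
  edge_bins <- which(apply(v_gt, 2, function(col)
    any(abs(col) > threshold / 4 & abs(col) < 3 * threshold)))
  keep_bins <- setdiff(seq_len(ncol(truth)), edge_bins)
  mean(map$labels[keep_frames, keep_bins] ==
         truth[keep_frames, keep_bins])
}

#' Scripted intensity-ratio recovery experiment
#'
#' Renders a blebbing cell whose reporter carries a scripted bleb/body
#' contrast of `contrast` during expansion and plateau, then recovers the
#' ratio with [roi_ratio_series()] under the default camera noise.
#'
#' @param seed integer seed.
#' @param contrast scripted bleb/body intensity multiplier.
#' @return list with `ratio_hat` (mean recovered ratio over plateau
#'   frames) and `contrast`.
#' @export
ratio_recovery_experiment <- function(seed, contrast = 2) {
  sc <- bleb_script(base_radius = 6, a_max = 2.4, v_exp = 0.3,
                    v_ret = 0.06, plateau_frames = 5L,
                    reporter_contrasts = list(
                      rep = c(expansion = contrast, plateau = contrast,
                              retraction = 1)))
  sim <- simulate_bleb_movie(sc, n_frames = 30L, frame_interval = 2000,
                             pixel_size = 0.1, img_px = c(224L, 224L),
                             camera = camera_model(background_level = 5),
                             body_level = 100, seed = seed)
  plateau <- which(sim$profile$phase == "plateau")
  mask <- sim$mask$data[, , plateau[1]] > 0
  base <- sim$mask$data[, , 1] > 0
  bleb_roi <- as.matrix(EBImage::erode(EBImage::Image((mask & !base) + 0),
                                       EBImage::makeBrush(5, "disc")) > 0)
  body_roi <- as.matrix(EBImage::erode(EBImage::Image(base + 0),
                                       EBImage::makeBrush(9, "disc")) > 0)
  bg_roi <- matrix(FALSE, 224, 224); bg_roi[1:20, 1:20] <- TRUE
  rs <- roi_ratio_series(sim$channels$rep, bleb_roi, body_roi,
                         background_roi = bg_roi)
  list(ratio_hat = mean(rs$ratio[plateau]), contrast = contrast)
}
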