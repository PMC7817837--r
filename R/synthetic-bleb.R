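#' Scripted bleb kinematics for synthetic movies
#'
#' Defines a circular cell of base radius `R0` carrying a single membrane
#' bleb: a compact angular bump of scripted amplitude. The bump profile is
#' a raised cosine, `bump(theta) = 0.5 * (1 + cos(pi * d / halfwidth))` for
#' angular distance `d <= halfwidth` and 0 outside — smooth and compactly
#' supported, matching the rounded blebs seen in live cells. The contour is
#' `r(theta, t) = R0 + A(t) * bump(theta)`, always single-valued in theta.
#'
#' The amplitude schedule `A(t)` is piecewise linear and mirrors a bleb
#' cycle: expansion at `v_exp` (um/s) up to `a_max` (um), a plateau of
#' `plateau_frames` frames, then retraction at `v_ret` (um/s) back to zero.
#' Expansion is typically scripted faster than retraction, as in real bleb
#' cycles.
#'
#' @param base_radius cell body radius `R0` in micrometres (> 0).
#' @param centroid cell centre `c(x, y)` in micrometres.
#' @param theta0 bleb centre angle in radians.
#' @param halfwidth angular half-width of the bump in radians.
#' @param a_max maximum bleb amplitude in micrometres.
#' @param v_exp expansion velocity in um/s (>= 0).
#' @param v_ret retraction velocity in um/s (>= 0).
#' @param plateau_frames number of frames held at `a_max` between expansion
#'   and retraction.
#' @param start_frame first frame (1-based) of expansion.
#' @param reporter_contrasts named list, one entry per channel; each entry
#'   is a named numeric vector of bleb/body intensity multipliers for the
#'   phases `pre`, `expansion`, `plateau`, `retraction`, `post` (missing
#'   phases default to 1).
#' @return An object of class `BlebScript`.
#' @export
bleb_script <- function(base_radius = 8, centroid = NULL, theta0 = 0,
                        halfwidth = pi / 4, a_max = 3,
                        v_exp = 0.25, v_ret = 0.05, plateau_frames = 3L,
                        start_frame = 2L,
                        reporter_contrasts = list(
                          reporter = c(expansion = 2, plateau = 1.5,
                                       retraction = 1))) {
  stopifnot(base_radius > 0, a_max >= 0, v_exp >= 0, v_ret >= 0,
            halfwidth > 0, halfwidth <= pi)
  structure(
    list(base_radius = base_radius, centroid = centroid, theta0 = theta0,
         halfwidth = halfwidth, a_max = a_max, v_exp = v_exp,
         v_ret = v_ret, plateau_frames = as.integer(plateau_frames),
         start_frame = as.integer(start_frame),
         reporter_contrasts = reporter_contrasts),
    class = "BlebScript"
  )
}

# Raised-cosine angular bump, 1 at theta0, 0 beyond +/- halfwidth.
bleb_bump <- function(theta, theta0, halfwidth) {
  d <- (theta - theta0 + pi) %% (2 * pi) - pi
  out <- numeric(length(theta))
  inside <- abs(d) <= halfwidth
  out[inside] <- 0.5 * (1 + cos(pi * d[inside] / halfwidth))
  out
}

#' Evaluate the scripted amplitude profile
#'
#' @param script a [bleb_script()].
#' @param n_frames number of frames.
#' @param frame_interval frame interval in milliseconds.
#' @return list with `amplitude` (um per frame), `dA_dt` (um/s, the exact
#'   schedule derivative per frame), and `phase` (character per frame in
#'   `pre`, `expansion`, `plateau`, `retraction`, `post`).
#' @export
amplitude_profile <- function(script, n_frames, frame_interval) {
  stopifnot(inherits(script, "BlebScript"))
  dt_s <- frame_interval / 1000
  exp_frames <- if (script$v_exp > 0)
    ceiling(script$a_max / (script$v_exp * dt_s)) else 0L
  ret_frames <- if (script$v_ret > 0)
    ceiling(script$a_max / (script$v_ret * dt_s)) else 0L
  A <- numeric(n_frames)
  dA <- numeric(n_frames)
  phase <- rep("pre", n_frames)
  t_exp0 <- script$start_frame
  t_plat0 <- t_exp0 + exp_frames
  t_ret0 <- t_plat0 + script$plateau_frames
  t_end <- t_ret0 + ret_frames
  for (f in seq_len(n_frames)) {
    if (f < t_exp0) {
      A[f] <- 0
    } else if (f < t_plat0) {
      A[f] <- min(script$a_max, (f - t_exp0) * script$v_exp * dt_s)
      dA[f] <- script$v_exp
      phase[f] <- "expansion"
    } else if (f < t_ret0) {
      A[f] <- script$a_max
      phase[f] <- "plateau"
    } else if (f < t_end) {
      A[f] <- max(0, script$a_max - (f - t_ret0) * script$v_ret * dt_s)
      dA[f] <- -script$v_ret
      phase[f] <- "retraction"
    } else {
      A[f] <- 0
      phase[f] <- "post"
    }
  }
  # the first plateau frame reaches a_max with expansion-rate motion into it
  list(amplitude = A, dA_dt = dA, phase = phase)
}

#' Per-frame radial contour profile of a cell
#'
#' Container for `r(theta, t)`: the distance from the cell centroid to the
#' boundary along `n_theta` evenly spaced rays, per frame. Angular bin
#' `j` (1-based) corresponds to `theta_j = 2 * pi * (j - 1) / n_theta`.
#'
#' @param radius numeric matrix `[frames, n_theta]` of radii in um.
#' @param centroid numeric matrix `[frames, 2]` of centroids `(x, y)` um.
#' @param frame_interval frame interval in ms.
#' @return An object of class `ContourSeries`.
#' @export
contour_series <- function(radius, centroid, frame_interval) {
  stopifnot(is.matrix(radius), all(radius > 0),
            nrow(centroid) == nrow(radius))
  structure(
    list(radius = radius, centroid = centroid,
         n_theta = ncol(radius),
         theta = 2 * pi * (seq_len(ncol(radius)) - 1) / ncol(radius),
         frame_interval = frame_interval),
    class = "ContourSeries"
  )
}

#' @export
print.ContourSeries <- function(x, ...) {
  cat(sprintf("ContourSeries: %d frame(s) x %d angular bins, r in [%.3g, %.3g] um\n",
              nrow(x$radius), x$n_theta, min(x$radius), max(x$radius)))
  invisible(x)
}

#' Simulate a movie of a blebbing cell with full ground truth
#'
#' Renders a circular cell carrying one scripted bleb, and returns
#' everything downstream stages will try to recover: per-channel
#' fluorescence movies, the binary mask movie, the exact contour series,
#' the exact tricolor (expand/retract/stationary) map, and the scripted
#' bleb/body intensity-ratio time course.
#'
#' Ground-truth tricolor labels threshold the true radial velocity
#' `dA/dt * bump(theta)`, i.e. the sign of `dA/dt` scaled by the angular
#' profile, so bins near the bleb edge where the boundary barely moves are
#' correctly STATIONARY.
#'
#' @param script a [bleb_script()].
#' @param n_frames number of frames.
#' @param frame_interval frame interval in ms (default 2000: bleb cycles
#'   play out over seconds to minutes).
#' @param pixel_size um/px.
#' @param img_px `c(rows, cols)` of the rendered frames.
#' @param camera a [camera_model()] for the fluorescence channels.
#' @param n_theta angular bins of the ground-truth contour and map.
#' @param stationary_threshold um/s below which ground truth is STATIONARY.
#' @param body_level expected photons per pixel inside the cell body.
#' @param seed optional seed for camera noise.
#' @return list with elements `channels` (named list of [movie()]),
#'   `mask` (binary [movie()]), `contour` (ground-truth `ContourSeries`),
#'   `tricolor` (ground-truth [tricolor_map()]), `ratio` (data.frame
#'   `frame`, `time_ms`, per-channel scripted bleb/body contrast), and
#'   `profile` (the [amplitude_profile()] used).
#' @export
simulate_bleb_movie <- function(script, n_frames = 40L,
                                frame_interval = 2000,
                                pixel_size = 0.1,
                                img_px = c(256L, 256L),
                                camera = camera_model(background_level = 5),
                                n_theta = 360L,
                                stationary_threshold = 0.02,
                                body_level = 100,
                                seed = NULL) {
  stopifnot(inherits(script, "BlebScript"))
  if (!is.null(seed)) set.seed(seed)
  nr <- img_px[1]; nc <- img_px[2]
  ctr <- script$centroid
  if (is.null(ctr)) {
    ctr <- c((nc - 1) / 2 * pixel_size, (nr - 1) / 2 * pixel_size)
  }
  prof <- amplitude_profile(script, n_frames, frame_interval)
  # pixel-centre polar coordinates about the (static) scripted centroid
  xs <- (seq_len(nc) - 1) * pixel_size
  ys <- (seq_len(nr) - 1) * pixel_size
  dx <- outer(rep(1, nr), xs - ctr[1])
  dy <- outer(ys - ctr[2], rep(1, nc))
  rho <- sqrt(dx^2 + dy^2)
  theta_px <- atan2(dy, dx) %% (2 * pi)
  bump_px <- bleb_bump(theta_px, script$theta0, script$halfwidth)
  in_bleb_sector <- bump_px > 0
  max_r <- script$base_radius + max(prof$amplitude)
  lim <- min(ctr[1], ctr[2],
             (nc - 1) * pixel_size - ctr[1], (nr - 1) * pixel_size - ctr[2])
  if (max_r > lim) {
    stop("scripted contour (max radius ", signif(max_r, 4),
         " um) exceeds the field of view")
  }
  theta_bins <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  bump_bins <- bleb_bump(theta_bins, script$theta0, script$halfwidth)
  mask_arr <- array(0, dim = c(nr, nc, n_frames))
  chan_names <- names(script$reporter_contrasts)
  chan_arr <- lapply(chan_names, function(ch) array(0, c(nr, nc, n_frames)))
  names(chan_arr) <- chan_names
  radius_gt <- matrix(0, n_frames, n_theta)
  ratio <- data.frame(frame = seq_len(n_frames),
                      time_ms = (seq_len(n_frames) - 1) * frame_interval)
  for (ch in chan_names) ratio[[ch]] <- NA_real_
  for (f in seq_len(n_frames)) {
    A <- prof$amplitude[f]
    r_theta_px <- script$base_radius + A * bump_px
    inside <- rho <= r_theta_px
    mask_arr[, , f] <- inside
    radius_gt[f, ] <- script$base_radius + A * bump_bins
    for (ch in chan_names) {
      contrasts <- script$reporter_contrasts[[ch]]
      contrast <- if (prof$phase[f] %in% names(contrasts))
        contrasts[[prof$phase[f]]] else 1
      photons <- matrix(0, nr, nc)
      photons[inside] <- body_level
      bleb_px <- inside & in_bleb_sector & rho > script$base_radius
      photons[bleb_px] <- body_level * contrast
      chan_arr[[ch]][, , f] <- render_counts(photons, camera)
      ratio[[ch]][f] <- contrast
    }
  }
  v_gt <- outer(prof$dA_dt, bump_bins)  # exact radial velocity, um/s
  labels_gt <- matrix("STATIONARY", n_frames, n_theta)
  labels_gt[v_gt > stationary_threshold] <- "EXPAND"
  labels_gt[v_gt < -stationary_threshold] <- "RETRACT"
  list(
    channels = lapply(chan_arr, movie, pixel_size = pixel_size,
                      frame_interval = frame_interval),
    mask = movie(mask_arr, pixel_size = pixel_size,
                 frame_interval = frame_interval),
    contour = contour_series(radius_gt,
                             matrix(rep(ctr, each = n_frames), ncol = 2),
                             frame_interval),
    tricolor = new_tricolor_map(labels_gt, stationary_threshold),
    ratio = ratio,
    profile = prof
  )
}
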