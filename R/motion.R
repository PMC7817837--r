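#' Centre a trajectory at the origin
#'
#' Translates a track so its first position is (0, 0) — the "centered
#' trajectory map" representation used to compare motion across particles
#' irrespective of where they sit in the cell.
#'
#' @param traj track `data.frame` with `x_um`, `y_um` (one track).
#' @return The same `data.frame` with translated coordinates.
#' @export
center_trajectory <- function(traj) {
  if (!nrow(traj)) stop("empty trajectory")
  traj$x_um <- traj$x_um - traj$x_um[1]
  traj$y_um <- traj$y_um - traj$y_um[1]
  traj
}

# Euclidean step lengths of a single track, um.
step_lengths <- function(traj) {
  sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
}

#' Cumulative travelled distance over a window
#'
#' Sum of frame-to-frame Euclidean step lengths over the first `window`
#' frames of a track (`window - 1` steps) — with the 50 Hz default
#' calibration, a 30-frame window spans 600 ms.
#'
#' @param traj single-track `data.frame` with `x_um`, `y_um`.
#' @param window number of frames (default 30).
#' @return Distance in um.
#' @export
cumulative_distance <- function(traj, window = 30L) {
  if (nrow(traj) < window) {
    stop("trajectory has ", nrow(traj), " frames; window is ", window,
         " (lower the window for short tracks)")
  }
  sum(step_lengths(traj[seq_len(window), , drop = FALSE]))
}

#' Speed class of a trajectory
#'
#' Mean frame-to-frame speed (cumulative distance over the window divided
#' by the elapsed time, `(window - 1) * frame_interval`) mapped onto three
#' diffusion-velocity classes: FAST above 3.3 um/s, INTERMEDIATE in
#' (1.6, 3.3], SLOW at or below 1.6 um/s. The classes partition `[0, Inf)`.
#'
#' @param traj single-track `data.frame` with `x_um`, `y_um`.
#' @param frame_interval frame interval in ms.
#' @param window frames used (default 30; capped at the track length).
#' @return list with `label` (`"FAST"`, `"INTERMEDIATE"` or `"SLOW"`) and
#'   `speed_um_s`.
#' @export
classify_speed <- function(traj, frame_interval, window = 30L) {
  stopifnot(nrow(traj) >= 2)
  window <- min(window, nrow(traj))
  dist <- cumulative_distance(traj, window)
  speed <- dist / ((window - 1) * frame_interval / 1000)
  label <- if (speed > 3.3) "FAST" else if (speed > 1.6) "INTERMEDIATE"
           else "SLOW"
  list(label = label, speed_um_s = speed)
}

#' Time-averaged mean square displacement of a track
#'
#' `msd(n * dt) = mean_i |r(i + n) - r(i)|^2` over all overlapping pairs,
#' for lags `n = 1 .. floor(max_lag_fraction * length)`. The pair count
#' per lag (`N - n`) is returned for ensemble weighting.
#'
#' @param traj single-track `data.frame` with `x_um`, `y_um`.
#' @param frame_interval frame interval in ms.
#' @param max_lag_fraction largest lag as a fraction of track length
#'   (default 0.5, so the default 10-lag fit range is available on
#'   30-frame windows).
#' @return `data.frame` with `lag_ms`, `msd_um2`, `n_pairs`
#'   (an `MSDCurve`).
#' @export
compute_msd <- function(traj, frame_interval, max_lag_fraction = 0.5) {
  n <- nrow(traj)
  stopifnot(n >= 2, max_lag_fraction > 0)
  max_lag <- max(1L, min(n - 1L, floor(max_lag_fraction * n)))
  x <- traj$x_um; y <- traj$y_um
  msd <- vapply(seq_len(max_lag), function(lag) {
    dx <- x[(1 + lag):n] - x[1:(n - lag)]
    dy <- y[(1 + lag):n] - y[1:(n - lag)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag_ms = seq_len(max_lag) * frame_interval,
             msd_um2 = msd,
             n_pairs = n - seq_len(max_lag))
}

#' Pair-count-weighted ensemble MSD curve
#'
#' Averages per-track MSD curves, weighting each track's value at each lag
#' by its number of displacement pairs at that lag.
#'
#' @param curves list of MSD curves from [compute_msd()] sharing the same
#'   frame interval.
#' @return `data.frame` with `lag_ms`, `msd_um2`, `n_pairs` (summed).
#' @export
ensemble_msd <- function(curves) {
  stopifnot(length(curves) >= 1)
  all <- do.call(rbind, curves)
  lags <- sort(unique(all$lag_ms))
  msd <- vapply(lags, function(l) {
    sub <- all[all$lag_ms == l, ]
    stats::weighted.mean(sub$msd_um2, sub$n_pairs)
  }, numeric(1))
  npairs <- vapply(lags, function(l) sum(all$n_pairs[all$lag_ms == l]),
                   numeric(1))
  data.frame(lag_ms = lags, msd_um2 = msd, n_pairs = npairs)
}

#' Diffusion coefficient from the fitted MSD slope
#'
#' Ordinary least squares of the ensemble-averaged MSD against lag time
#' over the first `fit_lags` lags, intercept free (the intercept absorbs
#' the static localization-error offset). For free 2-D diffusion
#' `MSD(tau) = 4 * D * tau`, so by default `D = slope / 4`; set
#' `d_from = "slope"` to report the raw slope as D instead.
#'
#' @param curves a list of MSD curves (ensemble-averaged internally), or a
#'   single MSD curve `data.frame`.
#' @param fit_lags number of initial lags to fit (>= 2; default 10,
#'   capped at the available lags).
#' @param d_from `"slope4"` (2-D Einstein relation, default) or
#'   `"slope"`.
#' @return An object of class `diffusion_fit`: list with `D` (um^2/ms),
#'   `slope` (um^2/ms), `intercept` (um^2), `fit_lag_range` (ms),
#'   `r_squared`, `degenerate` (TRUE when the MSD is identically zero, in
#'   which case D = 0).
#' @export
fit_diffusion_coefficient <- function(curves, fit_lags = 10L,
                                      d_from = c("slope4", "slope")) {
  d_from <- match.arg(d_from)
  if (is.data.frame(curves)) curves <- list(curves)
  ens <- ensemble_msd(curves)
  fit_lags <- min(as.integer(fit_lags), nrow(ens))
  if (fit_lags < 2) stop("need at least 2 lag points to fit")
  sub <- ens[seq_len(fit_lags), ]
  if (all(sub$msd_um2 == 0)) {
    return(structure(list(D = 0, slope = 0, intercept = 0,
                          fit_lag_range = range(sub$lag_ms),
                          r_squared = NA_real_, degenerate = TRUE),
                     class = "diffusion_fit"))
  }
  fit <- stats::lm(msd_um2 ~ lag_ms, data = sub)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((sub$msd_um2 - mean(sub$msd_um2))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  structure(
    list(D = if (d_from == "slope4") slope / 4 else slope,
         slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         fit_lag_range = range(sub$lag_ms),
         r_squared = r2,
         degenerate = FALSE),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "diffusion_fit: D = %.4g um^2/ms (slope %.4g, intercept %.4g um^2, R^2 %.3f)\n",
    x$D, x$slope, x$intercept,
    if (is.na(x$r_squared)) NA else x$r_squared))
  if (x$degenerate) cat("  degenerate: MSD identically zero\n")
  invisible(x)
}

#' Fixed-width speed histogram
#'
#' Left-closed, right-open bins of width `bin_width` starting at 0; the
#' counts sum to the number of values.
#'
#' @param values non-negative speeds, um/s.
#' @param bin_width bin width in um/s (default 0.02).
#' @return `data.frame` with `bin_left`, `bin_right`, `count`.
#' @export
speed_histogram <- function(values, bin_width = 0.02) {
  stopifnot(bin_width > 0)
  if (any(values < 0)) stop("speeds must be non-negative")
  if (!length(values)) {
    return(data.frame(bin_left = numeric(), bin_right = numeric(),
                      count = integer()))
  }
  idx <- floor(values / bin_width)
  tab <- table(idx)
  bins <- as.integer(names(tab))
  full <- 0:max(bins)
  count <- integer(length(full))
  count[match(bins, full)] <- as.integer(tab)
  data.frame(bin_left = full * bin_width,
             bin_right = (full + 1) * bin_width,
             count = count)
}

#' Per-track motion metrics table
#'
#' Computes, for every track in a track table, the windowed cumulative
#' distance, mean speed and speed class.
#'
#' @param tracks track table (`track_id`, `frame`, `x_um`, `y_um`).
#' @param frame_interval frame interval, ms.
#' @param window window in frames for distance/speed (default 30).
#' @return `data.frame` with `track_id`, `n_frames`, `cum_distance_um`,
#'   `mean_speed_um_s`, `speed_class`.
#' @export
motion_metrics <- function(tracks, frame_interval, window = 30L) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    w <- min(window, nrow(tr))
    cls <- classify_speed(tr, frame_interval, w)
    data.frame(track_id = id, n_frames = nrow(tr),
               cum_distance_um = cumulative_distance(tr, w),
               mean_speed_um_s = cls$speed_um_s,
               speed_class = cls$label)
  })
  do.call(rbind, rows)
}
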