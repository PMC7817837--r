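#' Extract a radial contour series from a binary mask movie
#'
#' Per frame: keeps the largest foreground component, takes its centre of
#' mass as the centroid, and measures `r(theta_j)` as the distance from
#' the centroid to the farthest foreground pixel along each of `n_theta`
#' evenly spaced rays (nearest-pixel sampling at quarter-pixel ray steps).
#' This radial representation assumes a star-convex cell about its
#' centroid — the rounded morphology of blebbing cells; frames where the
#' ray crosses background before the farthest hit (non-star-convex
#' boundaries) are still measured with the farthest-intersection rule and
#' flagged.
#'
#' @param masks binary [movie()] (nonzero = foreground).
#' @param n_theta number of angular bins (default 360).
#' @param centroid `"core"` (default): all frames share one origin, the
#'   centre of mass of the pixels that are foreground in every frame (the
#'   stable cell body); a per-frame centre of mass would recoil toward a
#'   growing bleb and leak spurious motion into every angular bin.
#'   `"per_frame"`: classic per-frame centre of mass.
#' @return A `ContourSeries` (see [contour_series()]) with an extra
#'   `non_star_convex` logical vector per frame.
#' @export
extract_contour_series <- function(masks, n_theta = 360L,
                                   centroid = c("core", "per_frame")) {
  stopifnot(inherits(masks, "Movie"))
  centroid_mode <- match.arg(centroid)
  nf <- n_frames(masks)
  nr <- nrow(masks$data); nc <- ncol(masks$data)
  ps <- masks$pixel_size
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  radius <- matrix(0, nf, n_theta)
  centroid <- matrix(0, nf, 2)
  flagged <- logical(nf)
  step_px <- 0.25
  max_steps <- ceiling(sqrt(nr^2 + nc^2) / step_px)
  rho_px <- seq_len(max_steps) * step_px
  cos_t <- cos(theta); sin_t <- sin(theta)
  core_ctr <- NULL
  if (centroid_mode == "core") {
    core <- apply(masks$data != 0, c(1, 2), all)
    if (any(core)) {
      idx <- which(core, arr.ind = TRUE)
      core_ctr <- c(mean(idx[, 1]), mean(idx[, 2]))  # (row, col) px
    }
  }
  for (f in seq_len(nf)) {
    fg <- masks$data[, , f] != 0
    if (!any(fg)) stop("mask frame ", f, " is empty")
    lab <- EBImage::bwlabel(fg)
    tab <- tabulate(lab[lab > 0])
    fg <- lab == which.max(tab)
    if (!is.null(core_ctr)) {
      cy_px <- core_ctr[1]; cx_px <- core_ctr[2]
    } else {
      idx <- which(fg, arr.ind = TRUE)
      cy_px <- mean(idx[, 1]); cx_px <- mean(idx[, 2])
    }
    centroid[f, ] <- c((cx_px - 1) * ps, (cy_px - 1) * ps)
    # all sample points for all rays at once: [steps x n_theta]
    sc <- round(outer(rho_px, cos_t) + cx_px)
    sr <- round(outer(rho_px, sin_t) + cy_px)
    inb <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
    hit <- matrix(FALSE, length(rho_px), n_theta)
    hit[inb] <- fg[cbind(sr[inb], sc[inb])]
    first_miss <- apply(hit, 2, function(h) match(FALSE, h))
    last_hit <- apply(hit, 2, function(h) {
      w <- which(h); if (length(w)) max(w) else NA_integer_
    })
    if (anyNA(last_hit)) {
      # centroid pixel itself is foreground, so a hit always exists at
      # sub-pixel rho; treat missing as half a pixel
      last_hit[is.na(last_hit)] <- 1L
    }
    flagged[f] <- any(last_hit >= first_miss, na.rm = TRUE)
    radius[f, ] <- rho_px[last_hit] * ps
  }
  out <- contour_series(radius, centroid, masks$frame_interval)
  out$non_star_convex <- flagged
  out
}

#' Radial boundary velocity per angular bin
#'
#' Central time difference of `r(theta, t)` per bin (forward/backward
#' differences at the first/last frame), converted to um/s.
#'
#' @param series a `ContourSeries`.
#' @param frame_interval frame interval in ms (defaults to the series').
#' @return Numeric matrix `[frames, n_theta]` of velocities in um/s.
#' @export
radial_velocity <- function(series, frame_interval = NULL) {
  stopifnot(inherits(series, "ContourSeries"))
  if (is.null(frame_interval)) frame_interval <- series$frame_interval
  r <- series$radius
  nf <- nrow(r)
  stopifnot(nf >= 2)
  dt_s <- frame_interval / 1000
  v <- matrix(0, nf, ncol(r))
  if (nf > 2) {
    v[2:(nf - 1), ] <- (r[3:nf, ] - r[1:(nf - 2), ]) / (2 * dt_s)
  }
  v[1, ] <- (r[2, ] - r[1, ]) / dt_s
  v[nf, ] <- (r[nf, ] - r[nf - 1, ]) / dt_s
  v
}

# internal constructor shared with the simulator
new_tricolor_map <- function(labels, stationary_threshold) {
  structure(list(labels = labels,
                 stationary_threshold = stationary_threshold),
            class = "TricolorMap")
}

#' Tricolor expansion/retraction map
#'
#' Classifies every (frame, angular bin) cell of a radial-velocity matrix:
#' EXPAND where the boundary moves outward faster than the stationary
#' threshold (rendered red), RETRACT where it moves inward faster than the
#' threshold (blue), STATIONARY otherwise (white). The default threshold,
#' 0.02 um/s, is one velocity-histogram bin.
#'
#' @param velocities `[frames, n_theta]` velocity matrix from
#'   [radial_velocity()].
#' @param stationary_threshold um/s (>= 0).
#' @return An object of class `TricolorMap`: `labels` is a character
#'   matrix over EXPAND/RETRACT/STATIONARY with time along rows and angle
#'   along columns.
#' @export
tricolor_map <- function(velocities, stationary_threshold = 0.02) {
  stopifnot(is.matrix(velocities), stationary_threshold >= 0)
  labels <- matrix("STATIONARY", nrow(velocities), ncol(velocities))
  labels[velocities > stationary_threshold] <- "EXPAND"
  labels[velocities < -stationary_threshold] <- "RETRACT"
  new_tricolor_map(labels, stationary_threshold)
}

#' @export
print.TricolorMap <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("EXPAND", "RETRACT", "STATIONARY")))
  cat(sprintf("TricolorMap: %d frame(s) x %d bins (threshold %.3g um/s)\n",
              nrow(x$labels), ncol(x$labels), x$stationary_threshold))
  cat(sprintf("  EXPAND %d, RETRACT %d, STATIONARY %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Render a tricolor map as an RGB array
#'
#' Red = EXPAND, blue = RETRACT, white = STATIONARY; angle along the
#' horizontal axis, time along the vertical axis.
#'
#' @param map a `TricolorMap`.
#' @return numeric array `[frames, n_theta, 3]` in [0, 1].
#' @export
tricolor_rgb <- function(map) {
  stopifnot(inherits(map, "TricolorMap"))
  lab <- map$labels
  rgb <- array(1, dim = c(dim(lab), 3))
  rgb[, , 2][lab == "EXPAND"] <- 0
  rgb[, , 3][lab == "EXPAND"] <- 0
  rgb[, , 1][lab == "RETRACT"] <- 0
  rgb[, , 2][lab == "RETRACT"] <- 0
  rgb
}

# circular-in-theta connected component labelling of a logical
# [frames, bins] matrix (8-connectivity), by bwlabel plus seam merging.
label_circular <- function(active) {
  lab <- EBImage::bwlabel(active)
  n_bins <- ncol(active)
  if (n_bins >= 2) {
    # merge labels touching across the theta seam (first/last column)
    repeat {
      merged <- FALSE
      for (f in seq_len(nrow(active))) {
        ff <- max(1, f - 1):min(nrow(active), f + 1)
        a <- lab[f, 1]
        if (a > 0) {
          b <- setdiff(unique(lab[ff, n_bins]), c(0, a))
          if (length(b)) {
            lab[lab %in% b] <- a
            merged <- TRUE
          }
        }
      }
      if (!merged) break
    }
  }
  lab
}

#' Detect bleb events in a contour series
#'
#' The baseline radius is a low per-bin temporal quantile of `r` over the
#' movie (default the 2nd percentile — essentially the resting radius,
#' since blebs only protrude outward, while staying robust to a stray
#' frame; a median would sit inside the bleb whenever a cycle occupies
#' more than half the movie); the amplitude field is
#' `amp(t, theta) = r - baseline`. Events
#' are maximal spatiotemporal connected regions (8-connectivity, circular
#' in theta) where the amplitude exceeds `min_amplitude`, kept if their
#' angular span reaches `min_span`. Per frame, an event's amplitude is
#' the maximum over its active bins and its area is the protrusion
#' integral `sum 0.5 * (r^2 - baseline^2) * dtheta` over active bins.
#'
#' @param series a `ContourSeries`.
#' @param min_amplitude um above baseline to count as bleb (default 0.5).
#' @param min_span minimum angular span in radians (default 5 degrees).
#' @param baseline_quantile per-bin temporal quantile of `r` used as the
#'   resting radius (default 0.02).
#' @return list of `BlebEvent` objects; each is a list with `event_id`,
#'   `onset_frame`, `max_frame`, `end_frame`, `frames`, `amplitude` (um
#'   per event frame), `area` (um^2 per event frame), `span_rad` (span at
#'   the frame of maximal amplitude), `bins` (bins ever active),
#'   `frame_interval`.
#' @export
detect_bleb_events <- function(series, min_amplitude = 0.5,
                               min_span = 5 * pi / 180,
                               baseline_quantile = 0.02) {
  stopifnot(inherits(series, "ContourSeries"))
  r <- series$radius
  baseline <- apply(r, 2, stats::quantile, probs = baseline_quantile,
                    names = FALSE)
  amp <- sweep(r, 2, baseline)
  active <- amp > min_amplitude
  if (!any(active)) return(list())
  lab <- label_circular(active)
  dtheta <- 2 * pi / series$n_theta
  events <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0)) {
    cells <- lab == id
    frames <- which(rowSums(cells) > 0)
    span_per_frame <- rowSums(cells)[frames] * dtheta
    if (max(span_per_frame) < min_span) next
    amp_ev <- vapply(frames, function(f) max(amp[f, cells[f, ]]),
                     numeric(1))
    area_ev <- vapply(frames, function(f) {
      b <- cells[f, ]
      sum(pmax(r[f, b]^2 - baseline[b]^2, 0)) / 2 * dtheta
    }, numeric(1))
    max_frame <- frames[which.max(amp_ev)]
    events[[length(events) + 1L]] <- structure(
      list(event_id = length(events) + 1L,
           onset_frame = min(frames),
           max_frame = max_frame,
           end_frame = max(frames),
           frames = frames,
           amplitude = amp_ev,
           area = area_ev,
           span_rad = span_per_frame[which.max(amp_ev)],
           bins = which(colSums(cells) > 0),
           frame_interval = series$frame_interval),
      class = "BlebEvent")
  }
  # order events by the angular position of their first active bin
  if (length(events) > 1) {
    ord <- order(vapply(events, function(e) min(e$bins), numeric(1)))
    events <- events[ord]
    for (k in seq_along(events)) events[[k]]$event_id <- k
  }
  events
}

#' Annotate the expansion/retraction phases of a bleb event
#'
#' Splits the event's amplitude profile into the four canonical phases of
#' a bleb cycle: EARLY_EXPANSION from onset to the frame of maximal
#' amplitude; LATE_EXPANSION from the maximum to the retraction onset
#' (standing in for actin-cortex reassembly when no cortex channel is
#' available); EARLY_RETRACTION until the amplitude first falls below 80%
#' of the maximum; LATE_RETRACTION for the remainder. Ties for the
#' maximum take the earliest frame. A profile with no retraction is
#' truncated after expansion and flagged.
#'
#' The retraction onset is the first frame at or after the maximum whose
#' amplitude drop (by more than `decrease_tol`) is never recovered later
#' in the event. This is robust both to single-frame segmentation
#' glitches (the drop recovers, so the frame is skipped) and to the
#' sub-pixel staircase of contour radii during slow retraction (where a
#' fixed run of strictly decreasing frames either never occurs or first
#' occurs far from the true onset).
#'
#' @param event a `BlebEvent` from [detect_bleb_events()].
#' @param decrease_tol minimum amplitude drop (um) counted as a true
#'   decrease (guards against jitter; default 1e-3).
#' @return The event with `phases` (character per event frame),
#'   `retraction_onset_frame`, `early_retraction_end_frame` (first frame
#'   below 80% of maximum, NA if never reached) and `truncated` fields.
#' @export
annotate_phases <- function(event, decrease_tol = 1e-3) {
  stopifnot(inherits(event, "BlebEvent"))
  frames <- event$frames
  A <- event$amplitude
  n <- length(frames)
  i_max <- which.max(A)  # earliest on ties
  phases <- rep(NA_character_, n)
  phases[seq_len(i_max)] <- "EARLY_EXPANSION"
  i_ret <- NA_integer_
  if (i_max < n) {
    later_max <- rev(cummax(rev(A)))  # max over A[i..n]
    for (i in seq.int(i_max, n - 1L)) {
      if (A[i + 1L] < A[i] - decrease_tol &&
          later_max[i + 1L] <= A[i] - decrease_tol) {
        i_ret <- i
        break
      }
    }
  }
  if (is.na(i_ret)) {
    event$phases <- phases
    event$retraction_onset_frame <- NA_integer_
    event$early_retraction_end_frame <- NA_integer_
    event$truncated <- TRUE
    return(event)
  }
  if (i_ret > i_max) phases[seq.int(i_max + 1L, i_ret)] <- "LATE_EXPANSION"
  cutoff <- 0.8 * A[i_max]
  below <- which(seq_len(n) > i_ret & A < cutoff)
  i_80 <- if (length(below)) min(below) else NA_integer_
  if (is.na(i_80)) {
    if (i_ret < n) phases[seq.int(i_ret + 1L, n)] <- "EARLY_RETRACTION"
  } else {
    if (i_80 > i_ret + 1L) {
      phases[seq.int(i_ret + 1L, i_80 - 1L)] <- "EARLY_RETRACTION"
    }
    phases[seq.int(i_80, n)] <- "LATE_RETRACTION"
  }
  event$phases <- phases
  event$retraction_onset_frame <- frames[i_ret]
  event$early_retraction_end_frame <-
    if (is.na(i_80)) NA_integer_ else frames[i_80]
  event$truncated <- FALSE
  event
}

#' Mean retraction velocity of a bleb event
#'
#' Mean rate of amplitude decrease from the retraction onset to the event
#' end (early plus late retraction), in um/s.
#'
#' @param event an annotated `BlebEvent` (phases are computed on the fly
#'   if absent).
#' @param frame_interval frame interval in ms (defaults to the event's).
#' @return Velocity in um/s (positive).
#' @export
retraction_velocity <- function(event, frame_interval = NULL) {
  stopifnot(inherits(event, "BlebEvent"))
  if (is.null(event$phases)) event <- annotate_phases(event)
  if (is.null(frame_interval)) frame_interval <- event$frame_interval
  if (is.na(event$retraction_onset_frame) || isTRUE(event$truncated)) {
    stop("event has no retraction phase")
  }
  i0 <- match(event$retraction_onset_frame, event$frames)
  i1 <- length(event$frames)
  if (i1 <= i0) stop("event has no retraction phase")
  dt_s <- frame_interval / 1000
  (event$amplitude[i0] - event$amplitude[i1]) / ((i1 - i0) * dt_s)
}

#' Mean expansion velocity of a bleb event
#'
#' Mean rate of amplitude increase from onset to the frame of maximal
#' amplitude, in um/s.
#'
#' @inheritParams retraction_velocity
#' @return Velocity in um/s (positive).
#' @export
expansion_velocity <- function(event, frame_interval = NULL) {
  stopifnot(inherits(event, "BlebEvent"))
  if (is.null(frame_interval)) frame_interval <- event$frame_interval
  i_max <- match(event$max_frame, event$frames)
  if (i_max <= 1) stop("event has no expansion phase")
  dt_s <- frame_interval / 1000
  (event$amplitude[i_max] - event$amplitude[1]) / ((i_max - 1) * dt_s)
}

#' Morphometrics table for a list of bleb events
#'
#' @param events list of `BlebEvent`s.
#' @param frame_interval frame interval, ms.
#' @return `data.frame` with one row per event: onset/max/end frames,
#'   angular span, maximal amplitude and area, expansion and retraction
#'   velocities (NA where a phase is absent), and the early-retraction end
#'   frame from the 80%-of-maximum rule.
#' @export
summarize_bleb_events <- function(events, frame_interval = NULL) {
  rows <- lapply(events, function(e) {
    e <- annotate_phases(e)
    if (is.null(frame_interval)) frame_interval <- e$frame_interval
    v_ret <- tryCatch(retraction_velocity(e, frame_interval),
                      error = function(...) NA_real_)
    v_exp <- tryCatch(expansion_velocity(e, frame_interval),
                      error = function(...) NA_real_)
    data.frame(event_id = e$event_id, onset_frame = e$onset_frame,
               max_frame = e$max_frame, end_frame = e$end_frame,
               span_rad = e$span_rad,
               max_amplitude_um = max(e$amplitude),
               max_area_um2 = max(e$area),
               expansion_velocity_um_s = v_exp,
               retraction_velocity_um_s = v_ret,
               retraction_onset_frame = e$retraction_onset_frame,
               early_retraction_end_frame = e$early_retraction_end_frame)
  })
  if (!length(rows)) {
    return(data.frame(event_id = integer(), onset_frame = integer(),
                      max_frame = integer(), end_frame = integer(),
                      span_rad = numeric(), max_amplitude_um = numeric(),
                      max_area_um2 = numeric(),
                      expansion_velocity_um_s = numeric(),
                      retraction_velocity_um_s = numeric(),
                      retraction_onset_frame = integer(),
                      early_retraction_end_frame = integer()))
  }
  do.call(rbind, rows)
}

#' Segment a fluorescence movie into binary masks
#'
#' Standard, replaceable segmentation for when no mask channel is
#' supplied: per frame, Otsu threshold on the normalized intensities,
#' largest connected component, hole filling.
#'
#' @param m a fluorescence [movie()].
#' @return A binary [movie()] with the same calibration.
#' @export
segment_movie <- function(m) {
  stopifnot(inherits(m, "Movie"))
  nf <- n_frames(m)
  out <- array(0, dim = dim(m$data))
  rng <- range(m$data)
  for (f in seq_len(nf)) {
    img <- (m$data[, , f] - rng[1]) / max(rng[2] - rng[1], 1e-12)
    th <- EBImage::otsu(EBImage::Image(img))
    fg <- img > th
    lab <- EBImage::bwlabel(fg)
    tab <- tabulate(lab[lab > 0])
    if (!length(tab)) stop("segmentation of frame ", f, " found no foreground")
    keep <- lab == which.max(tab)
    keep <- EBImage::fillHull(EBImage::Image(keep + 0))
    out[, , f] <- as.numeric(keep > 0)
  }
  movie(out, m$pixel_size, m$frame_interval)
}
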