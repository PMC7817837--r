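#' Laplacian-of-Gaussian spot enhancement
#'
#' Convolves the image with a negated, scale-normalized (x sigma^2)
#' Laplacian-of-Gaussian kernel, so bright blobs of radius about
#' `sigma * sqrt(2)` pixels produce positive peaks. The second-derivative
#' factor of the kernel is zero-summed, so constant (and, away from
#' borders, affine) images map to zero response. Borders use replicate
#' padding. The LoG separates as `gxx (x) g + g (x) gxx`, so the
#' convolution runs as four banded sparse-matrix products — much faster
#' than a full 2-D convolution at these kernel sizes.
#'
#' @param image 2-D numeric matrix.
#' @param sigma LoG scale in pixels (> 0).
#' @return Response matrix of the same shape.
#' @export
log_filter <- function(image, sigma) {
  if (!is.matrix(image)) stop("'image' must be a 2-D matrix")
  stopifnot(sigma > 0)
  half <- ceiling(4 * sigma)
  half <- min(half, floor((min(dim(image)) - 1) / 2))
  if (half < 1) stop("image too small for the requested sigma")
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  gxx <- (ax^2 - sigma^2) / sigma^4 * g
  gxx <- gxx - mean(gxx)  # zero-sum: constants map exactly to 0
  Mr_g <- conv_band_matrix(nrow(image), g)
  Mc_g <- conv_band_matrix(ncol(image), g)
  Mr_gxx <- conv_band_matrix(nrow(image), gxx)
  Mc_gxx <- conv_band_matrix(ncol(image), gxx)
  resp <- Mr_gxx %*% image %*% Matrix::t(Mc_g) +
    Mr_g %*% image %*% Matrix::t(Mc_gxx)
  -sigma^2 * as.matrix(resp)
}

# Banded matrix applying a symmetric 1-D convolution kernel with
# replicate boundary handling (out-of-range taps clamp to the edge).
conv_band_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  i <- rep(seq_len(n), each = length(kernel))
  j <- i + rep(-half:half, times = n)
  j <- pmin(pmax(j, 1L), n)
  Matrix::sparseMatrix(i = i, j = j,
                       x = rep(kernel, times = n),
                       dims = c(n, n))
}

#' Detect spots as prominence-filtered local maxima
#'
#' Finds local maxima of a filter response over 8-connected neighborhoods
#' and keeps those whose topographic prominence — the height of the peak
#' above the highest saddle connecting it to a higher peak, computed by
#' flood descent — exceeds a threshold. Plateau maxima (exact ties over a
#' connected region) yield a single detection at the region centroid.
#' Accepted maxima are refined to sub-pixel positions by an
#' intensity-weighted centroid over the 3x3 neighborhood of the response
#' (negative response values are clamped to zero in the weighting); set
#' `subpixel = FALSE` for integer-pixel output.
#'
#' @param response 2-D response matrix, e.g. from [log_filter()].
#' @param prominence minimum prominence, in response units, or `"auto"`
#'   for 5 x the robust noise SD of the response (1.4826 x MAD).
#' @param pixel_size um/px used to compute physical coordinates.
#' @param subpixel apply sub-pixel refinement?
#' @return `data.frame` with one row per detection: `row`, `col` (1-based
#'   integer pixel of the maximum), `x_um`, `y_um` (sub-pixel physical
#'   position; `x = (col - 1) * pixel_size`), `peak_response`,
#'   `prominence`.
#' @export
find_maxima <- function(response, prominence = "auto", pixel_size = 1,
                        subpixel = TRUE) {
  if (!is.matrix(response)) stop("'response' must be a 2-D matrix")
  if (identical(prominence, "auto")) {
    prominence <- 5 * stats::mad(response)
  }
  stopifnot(prominence >= 0)
  cand <- detect_prominent_maxima(response)
  keep <- cand$prominence > prominence
  cand <- cand[keep, , drop = FALSE]
  n <- nrow(cand)
  sub_r <- as.numeric(cand$row)
  sub_c <- as.numeric(cand$col)
  nr <- nrow(response); nc <- ncol(response)
  for (k in seq_len(n)) {
    r0 <- cand$row[k]; c0 <- cand$col[k]
    plateau <- plateau_region(response, r0, c0)
    if (nrow(plateau) > 1L) {
      sub_r[k] <- mean(plateau[, 1]); sub_c[k] <- mean(plateau[, 2])
    } else if (subpixel) {
      ii <- max(1, r0 - 1):min(nr, r0 + 1)
      jj <- max(1, c0 - 1):min(nc, c0 + 1)
      w <- pmax(response[ii, jj, drop = FALSE], 0)
      if (sum(w) > 0) {
        sub_r[k] <- sum(outer(ii, rep(1, length(jj))) * w) / sum(w)
        sub_c[k] <- sum(outer(rep(1, length(ii)), jj) * w) / sum(w)
      }
    }
  }
  data.frame(row = cand$row, col = cand$col,
             x_um = (sub_c - 1) * pixel_size,
             y_um = (sub_r - 1) * pixel_size,
             peak_response = cand$value,
             prominence = cand$prominence)
}

# 8-connected flood of the exact-value plateau containing (r0, c0);
# returns a matrix of (row, col). Plateaus are tiny in practice.
plateau_region <- function(response, r0, c0) {
  v <- response[r0, c0]
  nr <- nrow(response); nc <- ncol(response)
  seen <- new.env(hash = TRUE)
  stack <- list(c(r0, c0))
  out <- list()
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    key <- paste(p, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- p
    for (dr in -1:1) for (dc in -1:1) {
      rr <- p[1] + dr; cc <- p[2] + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (response[rr, cc] == v &&
          is.null(seen[[paste(rr, cc, sep = ",")]])) {
        stack[[length(stack) + 1L]] <- c(rr, cc)
      }
    }
  }
  do.call(rbind, out)
}

#' Linking configuration for frame-to-frame correspondence
#'
#' @param gate_radius maximum per-frame displacement considered, in um.
#'   A convenient default is `5 * sqrt(2 * d_max * frame_interval)` for the
#'   largest plausible diffusivity `d_max` (um^2/ms): five per-axis step
#'   SDs, beyond which a true link is vanishingly unlikely.
#' @param min_track_length minimum trajectory duration in frames; shorter
#'   trajectories are discarded as noise (default 10).
#' @return An object of class `LinkingConfig`.
#' @export
linking_config <- function(gate_radius, min_track_length = 10L) {
  stopifnot(gate_radius > 0, min_track_length >= 1)
  structure(list(gate_radius = gate_radius,
                 min_track_length = as.integer(min_track_length)),
            class = "LinkingConfig")
}

#' Gate radius from a diffusivity estimate
#' @param d_max largest plausible diffusion coefficient, um^2/ms.
#' @param frame_interval frame interval, ms.
#' @return Gate radius in um (5 per-axis step SDs).
#' @export
suggested_gate <- function(d_max, frame_interval) {
  5 * sqrt(2 * d_max * frame_interval)
}

#' Link detections between two consecutive frames by stable marriage
#'
#' Each detection ranks the opposite frame's detections within
#' `gate_radius` by ascending Euclidean distance (ties broken by ascending
#' detection index); the proposer-optimal stable matching is returned via
#' deferred acceptance, with the earlier frame proposing. The result
#' admits no blocking pair: no detection pair, unmatched together, where
#' both prefer each other over their assigned partners. Detections with no
#' candidate within the gate stay unmatched.
#'
#' @param detections_t,detections_t1 detection tables with `x_um`, `y_um`.
#' @param config a [linking_config()].
#' @return `data.frame` with columns `i` (row in `detections_t`) and `j`
#'   (row in `detections_t1`), plus `dist_um`.
#' @export
link_frames <- function(detections_t, detections_t1, config) {
  stopifnot(inherits(config, "LinkingConfig"))
  n <- nrow(detections_t); m <- nrow(detections_t1)
  empty <- data.frame(i = integer(), j = integer(), dist_um = numeric())
  if (n == 0L || m == 0L) return(empty)
  dmat <- outer(detections_t$x_um, detections_t1$x_um, "-")^2 +
    outer(detections_t$y_um, detections_t1$y_um, "-")^2
  dmat <- sqrt(dmat)
  gated <- dmat <= config$gate_radius
  # preference lists (ascending distance, ties by index via stable order)
  prefs_t <- lapply(seq_len(n), function(i) {
    cand <- which(gated[i, ])
    cand[order(dmat[i, cand], cand)]
  })
  rank_t1 <- matrix(Inf, m, n)  # rank of proposer i in j's list
  for (j in seq_len(m)) {
    cand <- which(gated[, j])
    cand <- cand[order(dmat[cand, j], cand)]
    rank_t1[j, cand] <- seq_along(cand)
  }
  next_prop <- rep(1L, n)         # next preference index to propose to
  engaged_j <- rep(NA_integer_, m)
  free <- which(lengths(prefs_t) > 0L)
  while (length(free)) {
    i <- free[[1]]
    if (next_prop[i] > length(prefs_t[[i]])) {
      free <- free[-1]            # exhausted all candidates
      next
    }
    j <- prefs_t[[i]][next_prop[i]]
    next_prop[i] <- next_prop[i] + 1L
    cur <- engaged_j[j]
    if (is.na(cur)) {
      engaged_j[j] <- i
      free <- free[-1]
    } else if (rank_t1[j, i] < rank_t1[j, cur]) {
      engaged_j[j] <- i
      free <- c(free[-1], cur)    # displaced proposer becomes free again
    }
    # else i stays free and proposes to its next candidate
  }
  j <- which(!is.na(engaged_j))
  i <- engaged_j[j]
  data.frame(i = i, j = j, dist_um = dmat[cbind(i, j)])[order(i), ,
                                                        drop = FALSE]
}

#' Chain frame-to-frame links into trajectories
#'
#' Links every pair of consecutive frames with [link_frames()], chains the
#' pairwise matches into maximal paths (a detection unmatched backwards
#' starts a track; unmatched forwards terminates it; there is no gap
#' closing — a missed detection ends the track), then discards
#' trajectories shorter than `config$min_track_length` frames as noise.
#'
#' @param detections detection table with columns `frame`, `x_um`, `y_um`
#'   (and optionally `peak_response`), as produced by [detect_movie()].
#' @param config a [linking_config()].
#' @return Track table: `data.frame` with `track_id`, `frame`, `x_um`,
#'   `y_um` and `peak_response` (NA when absent), sorted by track and
#'   frame. Track ids are assigned in order of track start.
#' @export
build_trajectories <- function(detections, config) {
  stopifnot(inherits(config, "LinkingConfig"))
  out_empty <- data.frame(track_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric(),
                          peak_response = numeric())
  if (!nrow(detections)) return(out_empty)
  if (is.null(detections$peak_response)) detections$peak_response <- NA_real_
  frames <- sort(unique(detections$frame))
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  track_of <- rep(NA_integer_, nrow(detections))
  next_id <- 1L
  for (f in frames) {
    rows_t <- by_frame[[as.character(f)]]
    new <- rows_t[is.na(track_of[rows_t])]
    if (length(new)) {
      track_of[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    rows_t1 <- by_frame[[as.character(f + 1L)]]
    if (is.null(rows_t1)) next
    links <- link_frames(detections[rows_t, , drop = FALSE],
                         detections[rows_t1, , drop = FALSE], config)
    if (nrow(links)) {
      track_of[rows_t1[links$j]] <- track_of[rows_t[links$i]]
    }
  }
  res <- data.frame(track_id = track_of,
                    frame = detections$frame,
                    x_um = detections$x_um,
                    y_um = detections$y_um,
                    peak_response = detections$peak_response)
  len <- table(res$track_id)
  keep <- names(len)[len >= config$min_track_length]
  res <- res[res$track_id %in% as.integer(keep), , drop = FALSE]
  if (!nrow(res)) return(out_empty)
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  res$track_id <- match(res$track_id, unique(res$track_id))
  rownames(res) <- NULL
  res
}

#' Detect spots in every frame of a movie
#'
#' Applies [log_filter()] then [find_maxima()] per frame.
#'
#' @param m a [movie()].
#' @param sigma LoG scale in pixels.
#' @param prominence minimum prominence, or `"auto"`: 5 x the robust noise
#'   SD of the first frame's response, applied to the whole movie.
#' @param subpixel sub-pixel refinement flag.
#' @return Detection table with `frame`, `row`, `col`, `x_um`, `y_um`,
#'   `peak_response`, `prominence`.
#' @export
detect_movie <- function(m, sigma, prominence = "auto", subpixel = TRUE) {
  stopifnot(inherits(m, "Movie"))
  if (identical(prominence, "auto")) {
    prominence <- 5 * stats::mad(log_filter(movie_frame(m, 1), sigma))
  }
  res <- lapply(seq_len(n_frames(m)), function(f) {
    resp <- log_filter(movie_frame(m, f), sigma)
    det <- find_maxima(resp, prominence = prominence,
                       pixel_size = m$pixel_size, subpixel = subpixel)
    if (nrow(det)) cbind(frame = f, det) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), row = integer(), col = integer(),
                      x_um = numeric(), y_um = numeric(),
                      peak_response = numeric(), prominence = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Track a movie end to end
#'
#' Convenience wrapper: detect spots in every frame, link consecutive
#' frames by stable marriage, chain links into trajectories and apply the
#' minimum-length filter.
#'
#' @inheritParams detect_movie
#' @param gate_radius linking gate in um (see [suggested_gate()]).
#' @param min_track_length minimum trajectory duration in frames.
#' @return Track table as from [build_trajectories()].
#' @export
track_movie <- function(m, sigma, gate_radius, prominence = "auto",
                        min_track_length = 10L, subpixel = TRUE) {
  det <- detect_movie(m, sigma, prominence = prominence, subpixel = subpixel)
  build_trajectories(det, linking_config(gate_radius, min_track_length))
}
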