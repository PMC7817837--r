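# Independent oracles and small fixture builders used across the suite.
# These deliberately use brute force / exhaustive enumeration and share no
# code with the implementation paths they check.

# --- topographic prominence by exhaustive level-set connectivity ---------
# For each 8-connected local maximum of `img` (plateaus collapse to one
# maximum), the prominence is peak - saddle, where the saddle is the
# highest level v such that the level set {img >= v} connects the maximum
# to dominating terrain: a strictly higher pixel, or the representative
# pixel of an equal-height maximum with earlier column-major index (the
# deterministic tie order). The overall winner gets peak - min(img).
oracle_prominence <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  neighbors <- function(i, j) {
    out <- list()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        out[[length(out) + 1L]] <- c(ii, jj)
      }
    }
    out
  }
  # local maxima: pixels with no strictly higher neighbor, deduplicated by
  # equal-value connected plateau
  is_cand <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- vapply(neighbors(i, j), function(p) img[p[1], p[2]], numeric(1))
    is_cand[i, j] <- all(vals <= img[i, j])
  }
  # flood equal-value plateaus, keep one representative each
  seen <- matrix(FALSE, nr, nc)
  maxima <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is_cand[i, j] || seen[i, j]) next
    v <- img[i, j]
    comp <- list(c(i, j)); seen[i, j] <- TRUE; k <- 1
    plateau_is_max <- TRUE
    while (k <= length(comp)) {
      p <- comp[[k]]; k <- k + 1
      for (q in neighbors(p[1], p[2])) {
        if (img[q[1], q[2]] == v && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          comp[[length(comp) + 1L]] <- q
        }
        if (img[q[1], q[2]] > v) plateau_is_max <- FALSE
      }
    }
    if (plateau_is_max) {
      cm_idx <- min(vapply(comp, function(p) (p[2] - 1L) * nr + p[1],
                           numeric(1)))
      maxima[[length(maxima) + 1L]] <- list(px = comp[[1]], value = v,
                                            cm_idx = cm_idx)
    }
  }
  # saddle search per maximum over descending unique levels
  levels <- sort(unique(as.vector(img)), decreasing = TRUE)
  res <- lapply(maxima, function(m) {
    peak <- m$value
    # pixels of equal-height maxima that dominate m by the tie order
    dom_px <- matrix(FALSE, nr, nc)
    for (m2 in maxima) {
      if (m2$value == peak && m2$cm_idx < m$cm_idx) {
        dom_px[m2$px[1], m2$px[2]] <- TRUE
      }
    }
    for (v in levels) {
      if (v >= peak) next
      # connected component of {img >= v} containing the maximum
      inset <- img >= v
      comp <- matrix(FALSE, nr, nc)
      stack <- list(m$px); comp[m$px[1], m$px[2]] <- TRUE
      dominated <- FALSE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (q in neighbors(p[1], p[2])) {
          if (inset[q[1], q[2]] && !comp[q[1], q[2]]) {
            comp[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
            if (img[q[1], q[2]] > peak || dom_px[q[1], q[2]]) {
              dominated <- TRUE
            }
          }
        }
      }
      if (dominated) {
        return(list(px = m$px, value = peak, prominence = peak - v))
      }
    }
    list(px = m$px, value = peak, prominence = peak - min(img))
  })
  res
}

# --- stable matching oracle ---------------------------------------------
# Preferences: ascending distance within the gate, ties by index.
oracle_blocking_pairs <- function(dt, dt1, matches, gate) {
  n <- nrow(dt); m <- nrow(dt1)
  dmat <- sqrt(outer(dt$x_um, dt1$x_um, "-")^2 +
                 outer(dt$y_um, dt1$y_um, "-")^2)
  partner_i <- rep(NA_integer_, n)
  partner_j <- rep(NA_integer_, m)
  if (nrow(matches)) {
    partner_i[matches$i] <- matches$j
    partner_j[matches$j] <- matches$i
  }
  prefers <- function(d_new, idx_new, d_cur, idx_cur) {
    if (is.na(idx_cur)) return(TRUE)         # unmatched prefers anyone gated
    d_new < d_cur || (d_new == d_cur && idx_new < idx_cur)
  }
  blocking <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (dmat[i, j] > gate) next
    if (!is.na(partner_i[i]) && partner_i[i] == j) next
    i_pref <- prefers(dmat[i, j], j,
                      if (is.na(partner_i[i])) NA else dmat[i, partner_i[i]],
                      partner_i[i])
    j_pref <- prefers(dmat[i, j], i,
                      if (is.na(partner_j[j])) NA else dmat[partner_j[j], j],
                      partner_j[j])
    if (i_pref && j_pref) blocking[[length(blocking) + 1L]] <- c(i, j)
  }
  blocking
}

# Enumerate every matching (injective partial assignment within the gate)
# and return the stable ones, each as a data.frame(i, j). Feasible for
# up to ~4 detections per side.
oracle_all_stable_matchings <- function(dt, dt1, gate) {
  n <- nrow(dt); m <- nrow(dt1)
  dmat <- sqrt(outer(dt$x_um, dt1$x_um, "-")^2 +
                 outer(dt$y_um, dt1$y_um, "-")^2)
  stable <- list()
  assign <- rep(NA_integer_, n)
  recurse <- function(i) {
    if (i > n) {
      used <- !is.na(assign)
      matches <- data.frame(i = which(used), j = assign[used])
      if (length(oracle_blocking_pairs(dt, dt1, matches, gate)) == 0) {
        stable[[length(stable) + 1L]] <<- matches
      }
      return(invisible())
    }
    recurse(i + 1L)  # i unmatched
    for (j in seq_len(m)) {
      if (dmat[i, j] <= gate && !(j %in% assign)) {
        assign[i] <<- j
        recurse(i + 1L)
        assign[i] <<- NA_integer_
      }
    }
  }
  recurse(1L)
  stable
}

random_link_instance <- function(max_per_side = 6L, box = 10) {
  n <- sample.int(max_per_side, 1)
  m <- sample.int(max_per_side, 1)
  list(
    dt = data.frame(x_um = runif(n, 0, box), y_um = runif(n, 0, box)),
    dt1 = data.frame(x_um = runif(m, 0, box), y_um = runif(m, 0, box))
  )
}

# --- fixture builders ----------------------------------------------------
# Noiseless movie of static Gaussian spots at given physical positions.
static_spot_movie <- function(positions_um, n_frames = 30L, fov_px = 64L,
                              pixel_size = 0.1, psf_sigma = 0.15,
                              amplitude = 500, frame_interval = 20) {
  spec <- particle_field_spec(
    n_particles = nrow(positions_um), diffusivity = 0,
    fov_px = c(fov_px, fov_px), psf_sigma = psf_sigma,
    spot_amplitude = amplitude, n_frames = n_frames,
    frame_interval = frame_interval, pixel_size = pixel_size)
  tracks <- data.frame(
    track_id = rep(seq_len(nrow(positions_um)), each = n_frames),
    frame = rep(seq_len(n_frames), nrow(positions_um)),
    x_um = rep(positions_um[, 1], each = n_frames),
    y_um = rep(positions_um[, 2], each = n_frames))
  render_particle_movie(tracks, spec, noiseless_camera())
}
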