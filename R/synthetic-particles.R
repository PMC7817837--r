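#' Specification of a synthetic particle field
#'
#' Describes a field of point particles (emulating cytoplasmic quantum
#' dots) undergoing 2-D Brownian motion with region-dependent diffusivity,
#' imaged at a fixed frame rate. The field of view is defined by
#' `region_mask`: an integer label matrix whose labels index into
#' `diffusivity` (micrometres squared per millisecond per region). Physical
#' extent is `ncol(region_mask) * pixel_size` by
#' `nrow(region_mask) * pixel_size` micrometres.
#'
#' Default calibration matches quantum-dot acquisition at 50 Hz:
#' `frame_interval = 20` ms and `pixel_size = 0.1` um/px.
#'
#' @param n_particles number of particles.
#' @param diffusivity named (or single) numeric vector of diffusion
#'   coefficients in um^2/ms, one per region label. All values >= 0.
#' @param region_mask integer matrix of region labels covering the field of
#'   view; values must index `diffusivity` (by name or position). Defaults
#'   to a single uniform region of `fov_px` pixels.
#' @param fov_px `c(rows, cols)` used to build the default uniform mask.
#' @param psf_sigma point-spread-function width in micrometres (> 0).
#' @param spot_amplitude integrated spot brightness in photons.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame interval in milliseconds.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param boundary_behavior `"reflect"` (default; particles bounce off the
#'   field edge, keeping particle count constant) or `"absorb"` (particles
#'   leaving the field stop being updated and are not rendered).
#' @return An object of class `ParticleFieldSpec`.
#' @export
particle_field_spec <- function(n_particles, diffusivity,
                                region_mask = NULL,
                                fov_px = c(256L, 256L),
                                psf_sigma = 0.15,
                                spot_amplitude = 500,
                                n_frames = 30L,
                                frame_interval = 20,
                                pixel_size = 0.1,
                                boundary_behavior = c("reflect", "absorb")) {
  boundary_behavior <- match.arg(boundary_behavior)
  if (is.null(region_mask)) {
    region_mask <- matrix(1L, nrow = fov_px[1], ncol = fov_px[2])
  }
  stopifnot(is.matrix(region_mask), all(diffusivity >= 0),
            psf_sigma > 0, n_frames >= 2, frame_interval > 0,
            pixel_size > 0, n_particles >= 0)
  labs <- sort(unique(as.vector(region_mask)))
  if (is.null(names(diffusivity))) {
    if (length(diffusivity) == 1L) {
      diffusivity <- rep(diffusivity, length(labs))
    }
    if (length(diffusivity) != length(labs)) {
      stop("'diffusivity' must have one value per region label")
    }
    names(diffusivity) <- as.character(labs)
  }
  missing <- setdiff(as.character(labs), names(diffusivity))
  if (length(missing)) {
    stop("no diffusivity given for region(s): ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(n_particles = as.integer(n_particles),
         diffusivity = diffusivity,
         region_mask = region_mask,
         psf_sigma = psf_sigma,
         spot_amplitude = spot_amplitude,
         n_frames = as.integer(n_frames),
         frame_interval = frame_interval,
         pixel_size = pixel_size,
         boundary_behavior = boundary_behavior),
    class = "ParticleFieldSpec"
  )
}

# Region label at physical position (x, y) um; positions are clamped to the
# field so a particle exactly on the far edge still resolves.
region_at <- function(x, y, region_mask, pixel_size) {
  nr <- nrow(region_mask); nc <- ncol(region_mask)
  j <- pmin(pmax(floor(x / pixel_size) + 1L, 1L), nc)
  i <- pmin(pmax(floor(y / pixel_size) + 1L, 1L), nr)
  region_mask[cbind(i, j)]
}

# Reflect coordinates into [0, L] (billiard reflection, handles multiple
# bounces for large excursions).
reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate Brownian particle tracks with region-dependent diffusivity
#'
#' Each particle takes independent Gaussian steps with per-axis variance
#' `2 * D * dt`, where `D` is looked up from the region containing the
#' particle's position at the start of the step (sub-step region crossings
#' are ignored; the frame interval is short relative to region geometry).
#' Initial positions are uniform over the field of view, or over the named
#' `init_region` only.
#'
#' @param spec a [particle_field_spec()].
#' @param seed integer seed; the simulation is reproducible given the seed.
#' @param init_region optional region label (name in `spec$diffusivity`):
#'   restrict initial positions to this region. A zero-area region is an
#'   error naming the region.
#' @return A ground-truth track table: `data.frame` with columns
#'   `track_id`, `frame` (1-based), `x_um`, `y_um`, `region`.
#' @export
simulate_brownian_tracks <- function(spec, seed = NULL, init_region = NULL) {
  stopifnot(inherits(spec, "ParticleFieldSpec"))
  if (!is.null(seed)) set.seed(seed)
  ps <- spec$pixel_size
  Lx <- ncol(spec$region_mask) * ps
  Ly <- nrow(spec$region_mask) * ps
  n <- spec$n_particles
  if (n == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      region = character()))
  }
  if (is.null(init_region)) {
    x <- stats::runif(n, 0, Lx)
    y <- stats::runif(n, 0, Ly)
  } else {
    idx <- which(as.character(spec$region_mask) == as.character(init_region))
    if (!length(idx)) {
      stop("region '", init_region, "' has zero area in the region mask")
    }
    pick <- sample(idx, n, replace = TRUE)
    i <- (pick - 1L) %% nrow(spec$region_mask) + 1L
    j <- (pick - 1L) %/% nrow(spec$region_mask) + 1L
    # uniform within the chosen pixel
    x <- (j - 1 + stats::runif(n)) * ps
    y <- (i - 1 + stats::runif(n)) * ps
  }
  nf <- spec$n_frames
  dt <- spec$frame_interval
  X <- matrix(0, nf, n); Y <- matrix(0, nf, n)
  X[1, ] <- x; Y[1, ] <- y
  alive <- rep(TRUE, n)  # absorbed particles stop being updated
  for (t in seq_len(nf - 1L)) {
    reg <- region_at(X[t, ], Y[t, ], spec$region_mask, ps)
    D <- spec$diffusivity[as.character(reg)]
    sd_step <- sqrt(2 * D * dt)
    nx <- X[t, ] + stats::rnorm(n, 0, sd_step)
    ny <- Y[t, ] + stats::rnorm(n, 0, sd_step)
    if (spec$boundary_behavior == "reflect") {
      nx <- reflect_into(nx, Lx)
      ny <- reflect_into(ny, Ly)
    } else {
      out <- nx < 0 | nx > Lx | ny < 0 | ny > Ly
      alive <- alive & !out
    }
    X[t + 1L, ] <- ifelse(alive, nx, X[t, ])
    Y[t + 1L, ] <- ifelse(alive, ny, Y[t, ])
  }
  reg_all <- region_at(as.vector(X), as.vector(Y), spec$region_mask, ps)
  data.frame(
    track_id = rep(seq_len(n), each = nf),
    frame = rep(seq_len(nf), times = n),
    x_um = as.vector(X),
    y_um = as.vector(Y),
    region = as.character(reg_all)
  )
}

# Local patch of one Gaussian spot: list(ii, jj, patch) to be added to the
# frame, or NULL when fully outside. Amplitude is the integrated photon
# count (the 2-D Gaussian integrates to `amp` over the plane).
spot_patch <- function(nr, nc, row0, col0, sigma_px, amp) {
  half <- ceiling(4 * sigma_px)
  i0 <- max(1L, floor(row0) - half); i1 <- min(nr, ceiling(row0) + half)
  j0 <- max(1L, floor(col0) - half); j1 <- min(nc, ceiling(col0) + half)
  if (i0 > i1 || j0 > j1) return(NULL)
  ii <- i0:i1; jj <- j0:j1
  gi <- exp(-((ii - row0)^2) / (2 * sigma_px^2))
  gj <- exp(-((jj - col0)^2) / (2 * sigma_px^2))
  peak <- amp / (2 * pi * sigma_px^2)
  list(ii = ii, jj = jj, patch = peak * outer(gi, gj))
}

#' Render a particle track table into a synthetic movie
#'
#' Each particle is drawn as an isotropic Gaussian of physical width
#' `spec$psf_sigma`, centred at its sub-pixel position; the expected-photon
#' image is then passed through the camera model (Poisson shot noise, gain,
#' Gaussian read noise, quantization). Positions map to the pixel grid as
#' `col = x / pixel_size + 1`, `row = y / pixel_size + 1` (1-based).
#'
#' @param tracks track table (`track_id`, `frame`, `x_um`, `y_um`) as from
#'   [simulate_brownian_tracks()].
#' @param spec the [particle_field_spec()] used to generate the tracks.
#' @param camera a [camera_model()].
#' @param seed optional seed for the camera noise.
#' @return A [movie()] with the spec's calibration attached.
#' @export
render_particle_movie <- function(tracks, spec, camera = camera_model(),
                                  seed = NULL) {
  stopifnot(inherits(spec, "ParticleFieldSpec"))
  if (!is.null(seed)) set.seed(seed)
  ps <- spec$pixel_size
  sigma_px <- spec$psf_sigma / ps
  if (sigma_px < 0.5) {
    warning("psf_sigma is below 0.5 px: the point-spread function is ",
            "undersampled and localization will degrade")
  }
  nr <- nrow(spec$region_mask); nc <- ncol(spec$region_mask)
  nf <- spec$n_frames
  frames <- array(0, dim = c(nr, nc, nf))
  rows_by_frame <- split(seq_len(nrow(tracks)), tracks$frame)
  for (t in seq_len(nf)) {
    img <- matrix(0, nr, nc)
    sub <- rows_by_frame[[as.character(t)]]
    for (k in sub) {
      sp <- spot_patch(nr, nc, tracks$y_um[k] / ps + 1,
                       tracks$x_um[k] / ps + 1, sigma_px,
                       spec$spot_amplitude)
      if (!is.null(sp)) img[sp$ii, sp$jj] <- img[sp$ii, sp$jj] + sp$patch
    }
    frames[, , t] <- render_counts(img, camera)
  }
  movie(frames, pixel_size = ps, frame_interval = spec$frame_interval)
}
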