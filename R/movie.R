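#' Calibrated image stack
#'
#' A `Movie` is the universal input of the pipeline: a single-channel stack
#' of grayscale frames together with its physical calibration. Frames are
#' stored as a numeric 3-D array indexed `[row, col, frame]`; calibration is
#' carried as `pixel_size` (micrometres per pixel) and `frame_interval`
#' (milliseconds between frames). Physical coordinates follow the pixel
#' grid: a pixel at 1-based indices `(i, j)` sits at
#' `x = (j - 1) * pixel_size`, `y = (i - 1) * pixel_size`.
#'
#' @param data numeric array `[rows, cols, frames]`, or a matrix (single
#'   frame), or a list of equally sized matrices.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param frame_interval frame interval in milliseconds (> 0).
#' @return An object of class `Movie`.
#' @export
movie <- function(data, pixel_size, frame_interval) {
  if (is.list(data)) {
    data <- simplify2array(data)
  }
  if (is.matrix(data)) {
    data <- array(data, dim = c(dim(data), 1L))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a [rows, cols, frames] array")
  }
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), frame_interval > 0)
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "Movie"
  )
}

#' @export
print.Movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Movie: %d frame(s) of %d x %d px (%.4g um/px, %.4g ms/frame)\n",
    d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Number of frames in a movie
#' @param m a `Movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(m) {
  stopifnot(inherits(m, "Movie"))
  dim(m$data)[3]
}

#' Extract one frame of a movie
#' @param m a `Movie`.
#' @param i 1-based frame index.
#' @return A numeric matrix.
#' @export
movie_frame <- function(m, i) {
  stopifnot(inherits(m, "Movie"))
  if (i < 1 || i > n_frames(m)) stop("frame index out of range")
  m$data[, , i]
}

#' Camera model for synthetic rendering
#'
#' Describes the photon-to-counts conversion used when rendering synthetic
#' movies: a constant photon background, Poisson shot noise, linear gain,
#' additive Gaussian read noise, and quantization to the sensor bit depth.
#' The noise order follows the standard sCMOS model: shot noise on the
#' photon image first, then gain, then read noise, then clipping to
#' `[0, 2^bit_depth - 1]`.
#'
#' @param background_level constant photon background per pixel (>= 0).
#' @param gain counts per photon.
#' @param read_noise_sd read-noise standard deviation in counts (>= 0).
#' @param bit_depth sensor bit depth; rendered values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param shot_noise apply Poisson shot noise? Disable together with
#'   `read_noise_sd = 0` for a noiseless "ideal" camera.
#' @return An object of class `CameraModel`.
#' @export
camera_model <- function(background_level = 10, gain = 1,
                         read_noise_sd = 2, bit_depth = 16L,
                         shot_noise = TRUE) {
  stopifnot(background_level >= 0, read_noise_sd >= 0, gain > 0,
            bit_depth >= 1)
  structure(
    list(background_level = background_level, gain = gain,
         read_noise_sd = read_noise_sd, bit_depth = as.integer(bit_depth),
         shot_noise = isTRUE(shot_noise)),
    class = "CameraModel"
  )
}

#' Ideal noiseless camera (no shot noise, no read noise, no background)
#' @param bit_depth sensor bit depth.
#' @return A `CameraModel`.
#' @export
noiseless_camera <- function(bit_depth = 16L) {
  camera_model(background_level = 0, gain = 1, read_noise_sd = 0,
               bit_depth = bit_depth, shot_noise = FALSE)
}

# Convert an expected-photon image to camera counts under `camera`.
# Draws from the caller's RNG stream; callers seed once per movie.
render_counts <- function(photons, camera) {
  stopifnot(inherits(camera, "CameraModel"))
  img <- photons + camera$background_level
  if (camera$shot_noise) {
    img[] <- stats::rpois(length(img), pmax(img, 0))
  }
  img <- img * camera$gain
  if (camera$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, camera$read_noise_sd)
  }
  top <- 2^camera$bit_depth - 1
  img <- round(img)
  img[img < 0] <- 0
  img[img > top] <- top
  img
}
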