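#' Bleb vs cell-body intensity-ratio time course
#'
#' Per frame, computes the background-subtracted mean intensity inside a
#' bleb ROI and a cell-body ROI and their ratio. The background is the
#' mean of an extracellular ROI when given, else a constant (default 0).
#'
#' @param m a [movie()].
#' @param bleb_roi,body_roi logical matrices matching the frame size
#'   (disjoint, nonempty).
#' @param background_roi optional logical matrix: extracellular region
#'   whose per-frame mean is subtracted from both ROI means.
#' @param background constant background when `background_roi` is NULL.
#' @return `data.frame` with `frame`, `time_ms`, `bleb_mean`, `body_mean`,
#'   `ratio` (a `RatioSeries`).
#' @export
roi_ratio_series <- function(m, bleb_roi, body_roi, background_roi = NULL,
                             background = 0) {
  stopifnot(inherits(m, "Movie"),
            is.logical(bleb_roi), is.logical(body_roi),
            any(bleb_roi), any(body_roi))
  if (any(bleb_roi & body_roi)) stop("bleb and body ROIs must be disjoint")
  d <- dim(m$data)
  if (!all(dim(bleb_roi) == d[1:2]) || !all(dim(body_roi) == d[1:2])) {
    stop("ROI dimensions must match the movie frames")
  }
  nf <- n_frames(m)
  bleb <- body <- numeric(nf)
  for (f in seq_len(nf)) {
    img <- m$data[, , f]
    bg <- if (!is.null(background_roi)) mean(img[background_roi])
          else background
    bleb[f] <- mean(img[bleb_roi]) - bg
    body[f] <- mean(img[body_roi]) - bg
  }
  if (any(body <= 0)) {
    stop("cell-body mean is non-positive after background subtraction ",
         "(first offending frame ", which(body <= 0)[1], ")")
  }
  data.frame(frame = seq_len(nf),
             time_ms = (seq_len(nf) - 1) * m$frame_interval,
             bleb_mean = bleb, body_mean = body,
             ratio = bleb / body)
}

#' Normalize a signal series to a reference series
#'
#' Pointwise quotient of two series sharing a time base — e.g. a calcium
#' reporter normalized to a membrane marker to remove volume and
#' membrane-density confounds.
#'
#' @param signal,reference numeric vectors of equal length, or
#'   `RatioSeries` data.frames (their `ratio` columns are used).
#' @return Numeric vector `signal / reference`.
#' @export
normalize_to_reference <- function(signal, reference) {
  if (is.data.frame(signal)) signal <- signal$ratio
  if (is.data.frame(reference)) reference <- reference$ratio
  if (length(signal) != length(reference)) {
    stop("signal and reference must share a time base")
  }
  zero <- which(reference == 0)
  if (length(zero)) {
    stop("reference is zero at frame ", zero[1])
  }
  signal / reference
}

#' Intensity kymograph along a path
#'
#' Samples the movie along a polyline at one-pixel arc steps, averaging
#' across `width` pixels perpendicular to the path; each frame contributes
#' one column, so rows are positions along the path and columns are time.
#'
#' @param m a [movie()].
#' @param path numeric matrix `[k, 2]` of `(col, row)` pixel coordinates
#'   (1-based) defining the polyline.
#' @param width number of perpendicular pixels averaged (>= 1).
#' @return Numeric matrix `[positions, frames]`.
#' @export
build_kymograph <- function(m, path, width = 1L) {
  stopifnot(inherits(m, "Movie"), is.matrix(path), ncol(path) == 2,
            width >= 1)
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) == 0) stop("degenerate (zero-length) path")
  # arc-length parameterization at 1 px steps
  total <- sum(seg_len)
  s <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(0, length(s), 2)
  nrm <- matrix(0, length(s), 2)
  for (k in seq_along(s)) {
    i <- max(which(cum <= s[k] & cum < total))
    t <- (s[k] - cum[i]) / seg_len[i]
    pts[k, ] <- path[i, ] + t * seg[i, ]
    u <- seg[i, ] / seg_len[i]
    nrm[k, ] <- c(-u[2], u[1])
  }
  offs <- seq_len(width) - (width + 1) / 2
  nr <- nrow(m$data); nc <- ncol(m$data)
  nf <- n_frames(m)
  kym <- matrix(NA_real_, length(s), nf)
  samp_c <- round(outer(pts[, 1], rep(1, width)) + outer(nrm[, 1], offs))
  samp_r <- round(outer(pts[, 2], rep(1, width)) + outer(nrm[, 2], offs))
  inb <- samp_r >= 1 & samp_r <= nr & samp_c >= 1 & samp_c <= nc
  if (!any(inb)) stop("path lies outside the image")
  for (f in seq_len(nf)) {
    img <- m$data[, , f]
    vals <- matrix(NA_real_, length(s), width)
    vals[inb] <- img[cbind(samp_r[inb], samp_c[inb])]
    kym[, f] <- rowMeans(vals, na.rm = TRUE)
  }
  kym
}

#' Count puncta inside bleb ROIs and classify blebs by cortex intensity
#'
#' Detects puncta on a single image with the same spot model as the
#' particle tracker ([log_filter()] plus prominence-filtered
#' [find_maxima()]), counts detections falling inside each bleb mask, and
#' classifies each bleb as EXPANDING when its cortex-marker mean intensity
#' is below the across-bleb median and RETRACTING otherwise (an actin-low
#' bleb is an expanding one). With fewer than two blebs the classification
#' is skipped (NA) and counts are still returned.
#'
#' @param pla_image 2-D numeric matrix of the puncta channel.
#' @param bleb_masks list of disjoint logical matrices, one per bleb.
#' @param cortex_intensity numeric vector: per-bleb mean cortex-marker
#'   intensity (same order as `bleb_masks`).
#' @param sigma LoG scale in pixels for puncta detection (default 2).
#' @param prominence prominence threshold or `"auto"`.
#' @return `data.frame` with `bleb_id`, `class`, `count`,
#'   `cortex_intensity`.
#' @export
count_puncta_in_blebs <- function(pla_image, bleb_masks, cortex_intensity,
                                  sigma = 2, prominence = "auto") {
  stopifnot(is.matrix(pla_image), length(bleb_masks) >= 1,
            length(cortex_intensity) == length(bleb_masks))
  for (a in seq_along(bleb_masks)) {
    for (b in seq_along(bleb_masks)) {
      if (a < b && any(bleb_masks[[a]] & bleb_masks[[b]])) {
        stop("bleb masks must be disjoint")
      }
    }
  }
  resp <- log_filter(pla_image, sigma)
  det <- find_maxima(resp, prominence = prominence, pixel_size = 1,
                     subpixel = FALSE)
  counts <- vapply(bleb_masks, function(mask) {
    if (!nrow(det)) return(0L)
    sum(mask[cbind(det$row, det$col)])
  }, integer(1))
  cls <- rep(NA_character_, length(bleb_masks))
  if (length(bleb_masks) >= 2) {
    med <- stats::median(cortex_intensity)
    cls <- ifelse(cortex_intensity < med, "EXPANDING", "RETRACTING")
  }
  data.frame(bleb_id = seq_along(bleb_masks), class = cls,
             count = counts, cortex_intensity = cortex_intensity)
}
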