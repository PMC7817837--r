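#' Read a movie from a multi-page TIFF
#'
#' Frames are returned in acquisition order with the calibration supplied
#' by the caller attached; TIFF metadata is never trusted for calibration
#' (tag dialects vary). Multi-channel stacks are assumed
#' channel-interleaved page-wise: page `p` belongs to channel
#' `(p - 1) %% n_channels + 1`.
#'
#' @param path TIFF file path.
#' @param pixel_size um/px to attach.
#' @param frame_interval ms to attach.
#' @param channel 1-based channel index.
#' @param n_channels number of interleaved channels in the stack.
#' @return A [movie()].
#' @export
read_movie <- function(path, pixel_size, frame_interval, channel = 1L,
                       n_channels = 1L) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("not a readable TIFF: ", path, " (",
                           conditionMessage(e), ")")
                    })
  if (channel < 1 || channel > n_channels) {
    stop("channel ", channel, " out of range (stack has ", n_channels,
         " channel(s))")
  }
  idx <- seq_along(pages)
  keep <- ((idx - 1L) %% n_channels) + 1L == channel
  frames <- lapply(pages[keep], function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # grayscale written as RGB
    p
  })
  movie(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Write a movie to a multi-page TIFF
#'
#' Pixel values are written as integers at the stated bit depth;
#' [read_movie()] recovers them exactly.
#'
#' @param m a [movie()].
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path, bits = 16L) {
  stopifnot(inherits(m, "Movie"), bits %in% c(8L, 16L))
  top <- 2^bits - 1
  if (min(m$data) < 0 || max(m$data) > top) {
    stop("pixel values outside [0, ", top, "]; rescale before writing")
  }
  pages <- lapply(seq_len(n_frames(m)),
                  function(f) movie_frame(m, f) / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write / read a track table as CSV
#'
#' Columns are snake_case with units suffixed (`x_um`, `y_um`), so the
#' files are self-describing and round-trip exactly through the package's
#' own readers.
#'
#' @param tracks track table.
#' @param path CSV path.
#' @return `write_tracks`: `path` invisibly; `read_tracks`: the table.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  utils::read.csv(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with at least `pixel_size` (um/px) and
#'   `frame_interval` (ms); module parameters (`sigma`, `prominence`,
#'   `gate_radius`, `min_track_length`, `n_theta`, `stationary_threshold`,
#'   `seed`, ...) are carried through as-is.
#' @return A named list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate a run configuration list
#' @param cfg named list.
#' @return The list, classed `RunConfig`.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$pixel_size) || cfg$pixel_size <= 0) {
    stop("config needs pixel_size > 0 (um/px)")
  }
  if (is.null(cfg$frame_interval) || cfg$frame_interval <= 0) {
    stop("config needs frame_interval > 0 (ms)")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = c("RunConfig", "list"))
}

# canonical stage order; a stage may only consume outputs of earlier ones
pipeline_stage_order <- c("simulate_qd", "track", "motion",
                          "simulate_bleb", "blebs", "ratio")

#' Run an ordered set of pipeline stages reproducibly
#'
#' Executes the requested stages in order, passing state (movies, tracks,
#' events) from one to the next, writing every tabular output under
#' `out_dir`, and finishing with a `manifest.json` recording the config,
#' the seed, the package version and an MD5 checksum per written file.
#' All randomness derives from the single config seed (stage `k` uses
#' `seed + k`), so rerunning the same config reproduces the checksums.
#'
#' Supported stages: `simulate_qd` (Brownian quantum-dot movie),
#' `track` (spot detection + stable-marriage linking), `motion`
#' (per-track metrics, ensemble MSD, diffusion fit), `simulate_bleb`
#' (scripted blebbing-cell movie), `blebs` (contour series, tricolor map,
#' event morphometrics), `ratio` (bleb/body intensity ratios). A stage
#' whose inputs are missing (e.g. `motion` without `track`) raises a
#' configuration error; a failing stage aborts the run with a
#' stage-attributed error.
#'
#' @param config a `RunConfig` list (see [read_run_config()]).
#' @param stages character vector of stage names, in execution order.
#' @param out_dir output directory (created if needed).
#' @return The run directory path, invisibly; side effect: stage outputs
#'   and `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config, stages, out_dir) {
  config <- validate_run_config(unclass(config))
  bad <- setdiff(stages, pipeline_stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.unsorted(match(stages, pipeline_stage_order))) {
    stop("stages out of order; expected order: ",
         paste(pipeline_stage_order, collapse = " -> "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  written <- character()
  log_line <- function(...) message("[blebkinetics] ", ...)
  for (k in seq_along(stages)) {
    st <- stages[k]
    seed_k <- config$seed + k
    t0 <- proc.time()[["elapsed"]]
    state <- tryCatch(
      run_stage(st, state, config, out_dir, seed_k),
      error = function(e) {
        stop("stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    written <- union(written, state$written)
    log_line(sprintf("stage %-13s done in %.2fs", st,
                     proc.time()[["elapsed"]] - t0))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("blebkinetics")),
    config = unclass(config),
    stages = stages,
    checksums = as.list(tools::md5sum(file.path(out_dir, written)))
  )
  names(manifest$checksums) <- written
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

run_stage <- function(stage, state, config, out_dir, seed) {
  written <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    written <<- c(written, name)
  }
  if (stage == "simulate_qd") {
    spec <- particle_field_spec(
      n_particles = config$n_particles %||% 10L,
      diffusivity = config$diffusivity %||% 0.005,
      fov_px = config$fov_px %||% c(128L, 128L),
      n_frames = config$n_frames %||% 30L,
      frame_interval = config$frame_interval,
      pixel_size = config$pixel_size)
    truth <- simulate_brownian_tracks(spec, seed = seed)
    state$movie <- render_particle_movie(truth, spec, camera_model(),
                                         seed = seed + 1L)
    mv_name <- "qd_movie.tif"
    write_movie(state$movie, file.path(out_dir, mv_name))
    written <- c(written, mv_name)
    emit(truth, "qd_truth_tracks.csv")
    state$spec <- spec
  } else if (stage == "track") {
    if (is.null(state$movie)) {
      if (is.null(config$movie)) {
        stop("no movie available: run simulate_qd first or set config$movie")
      }
      state$movie <- read_movie(config$movie, config$pixel_size,
                                config$frame_interval)
    }
    state$tracks <- track_movie(
      state$movie,
      sigma = config$sigma %||% 1.5,
      gate_radius = config$gate_radius %||%
        suggested_gate(config$d_max %||% 0.005, config$frame_interval),
      prominence = config$prominence %||% "auto",
      min_track_length = config$min_track_length %||% 10L)
    emit(state$tracks, "tracks.csv")
  } else if (stage == "motion") {
    if (is.null(state$tracks)) stop("no tracks: run track first")
    emit(motion_metrics(state$tracks, config$frame_interval),
         "track_metrics.csv")
    curves <- lapply(split(state$tracks, state$tracks$track_id),
                     compute_msd, frame_interval = config$frame_interval)
    ens <- ensemble_msd(curves)
    emit(ens, "msd.csv")
    fit <- fit_diffusion_coefficient(curves,
                                     fit_lags = config$fit_lags %||% 10L)
    jsonlite::write_json(
      list(d_um2_per_ms = fit$D, slope = fit$slope,
           intercept_um2 = fit$intercept, r_squared = fit$r_squared),
      file.path(out_dir, "diffusion_fit.json"), auto_unbox = TRUE,
      digits = NA)
    written <- c(written, "diffusion_fit.json")
    state$fit <- fit
  } else if (stage == "simulate_bleb") {
    sim <- simulate_bleb_movie(
      bleb_script(), n_frames = config$bleb_frames %||% 40L,
      frame_interval = config$bleb_frame_interval %||% 2000,
      pixel_size = config$pixel_size,
      seed = seed)
    state$bleb_sim <- sim
    mv_name <- "bleb_mask.tif"
    write_movie(sim$mask, file.path(out_dir, mv_name), bits = 8L)
    written <- c(written, mv_name)
    emit(sim$ratio, "bleb_truth_ratio.csv")
  } else if (stage == "blebs") {
    if (is.null(state$bleb_sim)) {
      if (is.null(config$mask_movie)) {
        stop("no mask movie: run simulate_bleb first or set config$mask_movie")
      }
      masks <- read_movie(config$mask_movie, config$pixel_size,
                          config$bleb_frame_interval %||%
                            config$frame_interval)
    } else {
      masks <- state$bleb_sim$mask
    }
    series <- extract_contour_series(masks,
                                     n_theta = config$n_theta %||% 360L)
    vel <- radial_velocity(series)
    map <- tricolor_map(vel, config$stationary_threshold %||% 0.02)
    lab <- as.data.frame(map$labels)
    names(lab) <- sprintf("bin_%03d", seq_len(ncol(map$labels)))
    emit(lab, "tricolor_labels.csv")
    events <- detect_bleb_events(series)
    emit(summarize_bleb_events(events), "bleb_events.csv")
    state$contour <- series
  } else if (stage == "ratio") {
    if (is.null(state$bleb_sim)) stop("ratio stage needs simulate_bleb")
    sim <- state$bleb_sim
    ch <- sim$channels[[1]]
    rois <- default_bleb_rois(sim)
    rs <- roi_ratio_series(ch, rois$bleb, rois$body)
    emit(rs, "ratio_series.csv")
  }
  state$written <- written
  state
}

# ROIs for the scripted bleb geometry: a disc patch inside the bleb apex
# and a matched patch in the cell body, derived from the ground truth.
default_bleb_rois <- function(sim) {
  mask0 <- sim$mask$data[, , which.max(apply(sim$mask$data, 3, sum))]
  base <- sim$mask$data[, , 1]
  bleb <- mask0 > 0 & base == 0
  body <- base > 0
  # shrink the body ROI away from the boundary
  body_er <- EBImage::erode(EBImage::Image(body + 0),
                            EBImage::makeBrush(9, "disc")) > 0
  list(bleb = bleb, body = as.matrix(body_er))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
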