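#!/usr/bin/env Rscript
# Generates the synthetic quantum-dot movies that stand in for the
# live-cell acquisitions: 100 cytoplasmic probes diffusing at
# D = 0.005 um^2/ms, imaged at 50 Hz under the Poisson-Gaussian camera
# model, plus a two-region field in which "bleb" cytoplasm is 4x more
# fluid than "body" cytoplasm. Writes the movies, the ground-truth track
# tables and the generation config under results/qd/.

suppressPackageStartupMessages(library(blebkinetics))

out_dir <- "results/qd"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260919L

# uniform field, margin-seeded so tracks stay clear of the reflecting edge
mask <- matrix(2L, 512, 512); mask[41:472, 41:472] <- 1L
spec <- particle_field_spec(n_particles = 100,
                            diffusivity = c("1" = 0.005, "2" = 0.005),
                            region_mask = mask, n_frames = 30,
                            frame_interval = 20, pixel_size = 0.1)
truth <- simulate_brownian_tracks(spec, seed = seed, init_region = "1")
mv <- render_particle_movie(truth, spec, camera_model(), seed = seed + 1L)
write_movie(mv, file.path(out_dir, "qd_uniform.tif"))
write_tracks(truth, file.path(out_dir, "qd_uniform_truth.csv"))

# two-region field: left half body, right half bleb with 4x diffusivity
mask2 <- cbind(matrix(1L, 256, 128), matrix(2L, 256, 128))
spec2 <- particle_field_spec(n_particles = 80,
                             diffusivity = c("1" = 0.00125, "2" = 0.005),
                             region_mask = mask2, n_frames = 30,
                             frame_interval = 20, pixel_size = 0.1)
truth2 <- simulate_brownian_tracks(spec2, seed = seed + 2L)
mv2 <- render_particle_movie(truth2, spec2, camera_model(), seed = seed + 3L)
write_movie(mv2, file.path(out_dir, "qd_two_region.tif"))
write_tracks(truth2, file.path(out_dir, "qd_two_region_truth.csv"))

yaml::write_yaml(list(
  seed = seed, pixel_size = 0.1, frame_interval = 20,
  d_uniform = 0.005, d_body = 0.00125, d_bleb = 0.005,
  n_particles = c(uniform = 100, two_region = 80), n_frames = 30
), file.path(out_dir, "config.yaml"))

cat("Wrote", length(list.files(out_dir)), "files to", out_dir, "\n")
cat(sprintf("Uniform movie: %d frames, truth tracks: %d\n",
            n_frames(mv), length(unique(truth$track_id))))
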