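#!/usr/bin/env Rscript
# Quantifies reporter fluorescence on a two-channel scripted bleb movie:
# a calcium-reporter-like channel whose bleb/body contrast rises to 2
# during expansion, and a flat membrane-marker-like reference channel.
# Computes the bleb vs cell-body ratio time course, the
# reference-normalized series, a kymograph through the bleb axis, and a
# puncta-count comparison between an actin-low (expanding) and an
# actin-high (retracting) bleb. Writes under results/intensity/.

suppressPackageStartupMessages(library(blebkinetics))

out_dir <- "results/intensity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260919L

script <- bleb_script(
  base_radius = 6, a_max = 2.4, v_exp = 0.3, v_ret = 0.06,
  plateau_frames = 5, start_frame = 2, theta0 = pi / 2,
  halfwidth = pi / 4,
  reporter_contrasts = list(
    calcium = c(expansion = 2, plateau = 2, retraction = 1),
    membrane = c(expansion = 1, plateau = 1, retraction = 1)))
sim <- simulate_bleb_movie(script, n_frames = 30, frame_interval = 2000,
                           pixel_size = 0.1, img_px = c(224, 224),
                           camera = camera_model(background_level = 5),
                           body_level = 100, seed = seed)

plateau <- which(sim$profile$phase == "plateau")
mask <- sim$mask$data[, , plateau[1]] > 0
base <- sim$mask$data[, , 1] > 0
bleb_roi <- as.matrix(EBImage::erode(EBImage::Image((mask & !base) + 0),
                                     EBImage::makeBrush(5, "disc")) > 0)
body_roi <- as.matrix(EBImage::erode(EBImage::Image(base + 0),
                                     EBImage::makeBrush(9, "disc")) > 0)
bg_roi <- matrix(FALSE, 224, 224); bg_roi[1:20, 1:20] <- TRUE

rs_ca <- roi_ratio_series(sim$channels$calcium, bleb_roi, body_roi,
                          background_roi = bg_roi)
rs_mem <- roi_ratio_series(sim$channels$membrane, bleb_roi, body_roi,
                           background_roi = bg_roi)
rs_ca$normalized <- normalize_to_reference(rs_ca, rs_mem)
utils::write.csv(rs_ca, file.path(out_dir, "ratio_series.csv"),
                 row.names = FALSE)
cat(sprintf("Mean bleb/body calcium ratio over plateau: %.3f (scripted 2)\n",
            mean(rs_ca$ratio[plateau])))
cat(sprintf("Reference-normalized plateau ratio: %.3f\n",
            mean(rs_ca$normalized[plateau])))

# kymograph along the bleb axis (cell centre -> beyond the apex)
ctr_px <- c(112, 112)
path <- rbind(c(ctr_px[1], ctr_px[2]), c(ctr_px[1], 20))  # (col,row): +y is down
kym <- build_kymograph(sim$channels$calcium, path, width = 5)
utils::write.csv(as.data.frame(kym), file.path(out_dir, "kymograph.csv"),
                 row.names = FALSE)
png(file.path(out_dir, "kymograph.png"), 900, 600, res = 150)
image(t(kym[nrow(kym):1, ]), col = hcl.colors(64, "inferno"), axes = FALSE,
      xlab = "time", ylab = "position along bleb axis",
      main = "Calcium-reporter kymograph")
dev.off()

# puncta counting: an expanding (cortex-low) and a retracting
# (cortex-high) bleb with 5 and 2 synthetic puncta respectively
pla <- matrix(0, 128, 128)
put_punctum <- function(img, r, c, amp = 120) {
  for (i in -3:3) for (j in -3:3) {
    img[r + i, c + j] <- img[r + i, c + j] +
      amp * exp(-(i^2 + j^2) / (2 * 1.5^2))
  }
  img
}
m1 <- matrix(FALSE, 128, 128); m1[10:60, 10:60] <- TRUE
m2 <- matrix(FALSE, 128, 128); m2[70:120, 70:120] <- TRUE
set.seed(seed)
for (p in list(c(18, 20), c(30, 45), c(42, 15), c(50, 50), c(25, 33))) {
  pla <- put_punctum(pla, p[1], p[2])
}
for (p in list(c(80, 90), c(105, 78))) pla <- put_punctum(pla, p[1], p[2])
pla <- pla + matrix(rnorm(128^2, 5, 1), 128, 128)
puncta <- count_puncta_in_blebs(pla, list(m1, m2),
                                cortex_intensity = c(20, 90),
                                sigma = 1.5)
utils::write.csv(puncta, file.path(out_dir, "puncta_counts.csv"),
                 row.names = FALSE)
print(puncta)
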