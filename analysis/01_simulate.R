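#!/usr/bin/env Rscript
# Generate the synthetic study inputs: sinusoid vessel images across a range
# of tortuosities, branching vessel trees of increasing density, a Doppler
# flow phantom with known total flow, and a two-group cohort at the study's
# size. Everything downstream (02-05) reads from results/simulated/.

library(octaflow)

out <- "results/simulated"
dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "volumes"), recursive = TRUE, showWarnings = FALSE)

amplitudes <- c(0, 2, 5, 10, 20)
for (a in amplitudes) {
  sv <- make_sinusoid_vessel(a, period_px = 50, length_px = 200,
                             width_px = 3, contrast = 5, noise_sd = 8,
                             seed = 100 + a)
  png::writePNG(sv$image$pixels / max(sv$image$pixels),
                file.path(out, "images", sprintf("sinusoid_A%02d.png", a)))
  write_centerlines_csv(list(sv$centerline),
                        file.path(out, "images",
                                  sprintf("sinusoid_A%02d_truth.csv", a)))
}
cat("wrote", length(amplitudes), "sinusoid vessel images (A = ",
    paste(amplitudes, collapse = ", "), "px)\n")

for (nb in c(5, 15, 30)) {
  tr <- make_vessel_tree(nb, seed = 11)
  write_mask_png(tr$map, file.path(out, "images",
                                   sprintf("tree_%02dbranches.png", nb)))
}
cat("wrote vessel trees with 5/15/30 branches\n")

meta <- scan_meta(ascan_rate_hz = 140000)
ph <- make_doppler_phantom(
  list(list(center_mm = c(1, 1), radius_mm = 0.05,
            peak_velocity_mm_s = 20)),
  meta = meta, n_volumes = 3)
for (i in seq_along(ph$volumes))
  write_doppler_volume(ph$volumes[[i]],
                       file.path(out, "volumes", sprintf("phantom_%d", i)))
png::writePNG(ph$vein_masks[[1]] * 1, file.path(out, "volumes", "vein_mask.png"))
cat(sprintf("wrote Doppler phantom: true total flow %.3f uL/min\n",
            ph$true_total_flow))

co <- make_cohort(seed = 2026)
write.csv(co$subjects[, c("subject_id", "group", "sex", "age", "map",
                          "haematocrit")],
          file.path(out, "subjects.csv"), row.names = FALSE)
write.csv(co$eyes, file.path(out, "eyes.csv"), row.names = FALSE)
cat(sprintf("wrote cohort: %d subjects, %d eyes (%d SCR / %d NC)\n",
            nrow(co$subjects), nrow(co$eyes),
            sum(co$eyes$group == "SCR"), sum(co$eyes$group == "NC")))
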