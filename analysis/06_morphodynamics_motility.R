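#!/usr/bin/env Rscript
# Morphodynamics (fractional area/perimeter change) and the coupling between
# near-membrane activity and boundary motility, with the binned cubic fit.
source("analysis/00_common.R")

# a livelier cell for the motility stage: stronger jitter, activity-coupled
cfg <- reference_scene(seed = 5L)
cfg$n_frames <- 24L
cfg$boundary_motility_amp_px <- 1.2
cfg$motility_coupling <- -0.9
sc <- generate_scene(cfg)
frames <- sc$frames
mask <- build_mask(frames$acceptor, pixel_size_um = frames$pixel_size_um)
ft <- compute_fret_index(frames)

mo <- fractional_changes(mask)
cat(sprintf("Mean fractional area change %.4f, perimeter change %.4f over %d frames.\n",
            mo$mean_fractional_area_change, mo$mean_fractional_perimeter_change,
            length(mo$areas_px2)))

vmap <- boundary_velocity_map(mask, frames$pixel_size_um, frames$frame_interval_min)
sig <- near_membrane_signal(ft, mask, depth_um = 1.0)
co <- motility_fret_correlation(vmap, sig)
cat(sprintf("Motility vs near-membrane FRET: %d signal bins of 3 au; Spearman rho = %.3f.\n",
            nrow(co$bins), co$spearman_rho))
cat(sprintf("Cubic fit f = y0 + a x + b x^2 + c x^3: y0 = %.4g, a = %.4g, b = %.4g, c = %.4g (R^2 = %.3f)\n",
            co$cubic_coefficients[1], co$cubic_coefficients[2],
            co$cubic_coefficients[3], co$cubic_coefficients[4], co$fit_r2))
cat("High-activity membrane zones move less: the binned trend is decreasing.\n")

write.csv(data.frame(frame = seq_along(mo$areas_px2), area_px2 = mo$areas_px2,
                     perimeter_px = mo$perimeters_px),
          file.path(results_dir, "morphodynamics.csv"), row.names = FALSE)
write.csv(co$bins, file.path(results_dir, "motility_bins.csv"), row.names = FALSE)
jsonlite::write_json(c(as.list(co$cubic_coefficients),
                       list(r2 = co$fit_r2, spearman_rho = co$spearman_rho)),
                     file.path(results_dir, "motility_fit.json"),
                     auto_unbox = TRUE, digits = NA)
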