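# Shared configuration for the analysis workflow: a single "reference cell"
# emulating the target acquisition (0.2 um/px, 2 frames/min, 25-min movie,
# 3.5-min activity pulses in a membrane-proximal hotspot).
library(fretscope)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

reference_scene <- function(seed = 1L) {
  scene_config(image_shape = c(96, 96), n_frames = 50L,
               pixel_size_um = 0.2, frame_interval_min = 0.5,
               cell_radius_px = 30, pulse_period_min = 3.5,
               hotspot_angle_deg = 45, seed = seed)
}
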