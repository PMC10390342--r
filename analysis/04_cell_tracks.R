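#!/usr/bin/env Rscript
# Track directionality split by region and condensation phase: a phase-1
# tail-to-head drift cohort vs a phase-2 near-isotropic cohort, summarised
# as polar-histogram statistics and mean average velocities.

library(vncmorph)
dir.create("results", showWarnings = FALSE)

domain <- list(width_um = 200, height_um = 100)
phase1 <- generate_tracks(
  flow_spec("tail_to_head_gradient", peak_speed = 0.08, gradient_length = 150,
            axis = c(-1, 0)),
  n_tracks = 120, n_frames = 19, frame_interval_min = 10,
  jitter_sd = 0.4, seed = 6, domain = domain)
phase2 <- generate_tracks(flow_spec("zero"),
                          n_tracks = 120, n_frames = 19,
                          frame_interval_min = 10, jitter_sd = 0.4,
                          seed = 7, domain = domain)
phase2$frame <- phase2$frame + 42   # 7 h offset
tracks <- rbind(phase1, transform(phase2, track_id = track_id + 1000))

sets <- filter_and_window_tracks(tracks, min_frames = 10,
                                 windows = list(c(0, 180), c(420, 600)),
                                 region_boundary_um = 100,
                                 frame_interval_min = 10)
rows <- lapply(names(sets), function(nm) {
  s <- track_directionality(sets[[nm]])
  data.frame(set = nm, n_tracks = s$n_tracks,
             mean_velocity_um_min = s$mean_velocity_um_min,
             resultant_length = s$resultant_length,
             circular_mean_deg = if (s$n_tracks)
               atan2(mean(sin(s$angles_rad)),
                     mean(cos(s$angles_rad))) * 180 / pi else NA)
})
out <- do.call(rbind, rows)
write.csv(out, "results/track_directionality.csv", row.names = FALSE)
print(out, row.names = FALSE)
message("phase-1 sets should be directional (resultant near 1, mean near",
        " 180 deg = tail-to-head); phase-2 sets near-isotropic")
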