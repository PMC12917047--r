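#!/usr/bin/env Rscript
# Estimate the fibre drift from the landmark series of each exported scene
# (frame-to-previous Kabsch fits, accumulated to the frame-0 referential),
# correct the observed tracks, and quantify how much apparent motion the
# correction removed. Writes corrected tracks and estimated transforms next
# to each scene.

library(musctrack)

scene_dirs <- list.dirs("results/scenes", recursive = FALSE)
stopifnot(length(scene_dirs) > 0)

for (d in scene_dirs) {
  inp <- import_scene(d)
  reg <- register_landmarks(inp$landmarks)
  corrected <- correct_tracks(inp$tracks, reg$correction)
  write_tracks_csv(corrected, file.path(d, "tracks_corrected.csv"))
  write_transforms_csv(reg$correction,
                       file.path(d, "estimated_transforms.csv"))

  # apparent vs corrected total path length: the difference is fibre motion
  raw <- motility_summary(inp$tracks, threshold = default_threshold())
  fix <- motility_summary(corrected, threshold = default_threshold())
  cat(sprintf(
    "%-28s mean path raw %7.1f um -> corrected %7.1f um; worst frame residual %.2f um%s\n",
    basename(d), mean(raw$total_um), mean(fix$total_um), max(reg$rms$rms_um),
    if (reg$motility_excluded) "  [EXCLUDED from motility]" else ""))
}
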