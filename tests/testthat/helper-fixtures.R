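# shared fixtures: tiny hand-built tracks, rasterised masks, XML snippets

make_track <- function(xy, dt = 10, cell_id = "c1", z = 0) {
  n <- nrow(xy)
  track_set(tibble::tibble(
    cell_id = cell_id, frame = seq_len(n) - 1L,
    t_min = (seq_len(n) - 1L) * dt,
    x_um = xy[, 1], y_um = xy[, 2], z_um = z), dt = dt)
}

# binary ellipse mask, semi-axes (a, b) px, rotated by theta_deg, centred at
# (cx, cy) in pixel coordinates (x = column, y = row)
ellipse_mask <- function(nrow = 200, ncol = 200, cx = 100, cy = 100,
                         a = 60, b = 15, theta_deg = 0) {
  th <- theta_deg * pi / 180
  xs <- matrix(rep(seq_len(ncol), each = nrow), nrow) - cx
  ys <- matrix(rep(seq_len(nrow), ncol), nrow) - cy
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# minimal TrackMate-dialect XML: a linear 5-frame chain
xml_chain <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<TrackMate><Model spatialunits="micron">',
    "<AllSpots>",
    sprintf('<SpotsInFrame frame="%d"><Spot ID="%d" FRAME="%d" POSITION_X="%d" POSITION_Y="0" POSITION_Z="0" POSITION_T="%d" /></SpotsInFrame>',
            0:4, 1:5, 0:4, 0:4, (0:4) * 10),
    "</AllSpots>",
    "<AllTracks><Track>",
    sprintf('<Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d" />', 1:4, 2:5),
    "</Track></AllTracks>",
    "</Model>",
    '<Settings><ImageData pixelwidth="1" pixelheight="1" voxeldepth="1" timeinterval="10" /></Settings>',
    "</TrackMate>"), path)
  path
}

# one mother (frames 0..3) dividing into two daughters at frame 3
xml_division <- function(path, n_daughters = 2) {
  d_ids <- 10 + seq_len(n_daughters)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<TrackMate><Model spatialunits="micron">',
    "<AllSpots>",
    sprintf('<SpotsInFrame frame="%d"><Spot ID="%d" FRAME="%d" POSITION_X="%d" POSITION_Y="0" POSITION_Z="0" POSITION_T="%d" /></SpotsInFrame>',
            0:3, 1:4, 0:3, 0:3, (0:3) * 10),
    '<SpotsInFrame frame="4">',
    sprintf('<Spot ID="%d" FRAME="4" POSITION_X="%d" POSITION_Y="5" POSITION_Z="0" POSITION_T="40" />',
            d_ids, seq_len(n_daughters)),
    "</SpotsInFrame>",
    "</AllSpots>",
    "<AllTracks><Track>",
    sprintf('<Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d" />', 1:3, 2:4),
    sprintf('<Edge SPOT_SOURCE_ID="4" SPOT_TARGET_ID="%d" />', d_ids),
    "</Track></AllTracks>",
    "</Model>",
    "</TrackMate>"), path)
  path
}

# small fast presets for unit tests (full-size runs live in the acceptance
# suite)
wt_small <- function(...) muscle_preset("wt", duration_h = 60, ...)
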