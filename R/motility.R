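#' Per-step distances and instantaneous speeds
#'
#' For a segment of n points, returns the n-1 step distances d_i between
#' consecutive time frames and the instantaneous speeds d_i / dt.
#'
#' @param seg tibble (or data frame) with columns frame, t_min, x_um, y_um,
#'   z_um, ordered in time.
#' @param dt frame interval in minutes.
#' @return tibble with columns frame_from, frame_to, d_um, speed_um_min,
#'   speed_um_h; zero rows (with attribute `flag = "single_point"`) for a
#'   single-point segment.
#' @export
step_metrics <- function(seg, dt) {
  n <- nrow(seg)
  if (n < 2L) {
    out <- tibble::tibble(frame_from = integer(), frame_to = integer(),
                          d_um = numeric(), speed_um_min = numeric(),
                          speed_um_h = numeric())
    attr(out, "flag") <- "single_point"
    return(out)
  }
  dx <- diff(seg$x_um); dy <- diff(seg$y_um)
  dz <- if ("z_um" %in% names(seg)) diff(seg$z_um) else 0
  d <- sqrt(dx^2 + dy^2 + dz^2)
  step_dt <- diff(seg$t_min)
  tibble::tibble(frame_from = seg$frame[-n], frame_to = seg$frame[-1],
                 d_um = d, speed_um_min = d / step_dt,
                 speed_um_h = 60 * d / step_dt)
}

#' Turning angles along a trajectory
#'
#' Angle between consecutive displacement vectors, in degrees within
#' \[0, 180\]: 0 is straight ahead, 180 a full reversal. Zero-length steps
#' have no direction and are skipped; angles are computed between successive
#' non-zero displacements.
#'
#' @inheritParams step_metrics
#' @return numeric vector of angles (degrees); empty with attribute
#'   `flag = "no_motion"` when fewer than two non-zero steps exist.
#' @export
turning_angles <- function(seg) {
  n <- nrow(seg)
  if (n < 3L) {
    out <- numeric(0); attr(out, "flag") <- "too_short"; return(out)
  }
  z <- if ("z_um" %in% names(seg)) seg$z_um else rep(0, n)
  v <- cbind(diff(seg$x_um), diff(seg$y_um), diff(z))
  len <- sqrt(rowSums(v^2))
  v <- v[len > 0, , drop = FALSE]; len <- len[len > 0]
  if (nrow(v) < 2L) {
    out <- numeric(0); attr(out, "flag") <- "no_motion"; return(out)
  }
  a <- v[-nrow(v), , drop = FALSE]; b <- v[-1, , drop = FALSE]
  cosang <- rowSums(a * b) / (len[-length(len)] * len[-1])
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Path-level motility summary of one segment
#'
#' Total distance is the sum of step distances; net distance the straight-line
#' distance between first and last point; straightness their ratio (1 for a
#' perfectly straight monotone path, towards 0 for wandering paths); average
#' speed the total distance divided by the trajectory duration.
#'
#' @inheritParams step_metrics
#' @return one-row tibble: n_points, n_steps, total_um, net_um, straightness,
#'   duration_min, avg_speed_um_min, avg_speed_um_h, mean_turn_deg.
#' @export
path_summary <- function(seg, dt) {
  n <- nrow(seg)
  if (n < 2L) stop("path_summary needs a segment with at least 2 points")
  dur <- seg$t_min[n] - seg$t_min[1]
  if (dur <= 0) stop("zero-duration segment")
  st <- step_metrics(seg, dt)
  total <- sum(st$d_um)
  z <- if ("z_um" %in% names(seg)) seg$z_um else rep(0, n)
  net <- sqrt((seg$x_um[n] - seg$x_um[1])^2 + (seg$y_um[n] - seg$y_um[1])^2 +
              (z[n] - z[1])^2)
  ang <- turning_angles(seg)
  tibble::tibble(
    n_points = n, n_steps = nrow(st),
    total_um = total, net_um = net,
    straightness = if (total > 0) net / total else NA_real_,
    duration_min = dur,
    avg_speed_um_min = total / dur,
    avg_speed_um_h = 60 * total / dur,
    mean_turn_deg = if (length(ang)) mean(ang) else NA_real_)
}

#' Published default mobile/static migration-speed threshold (um/min)
#' @export
published_speed_threshold <- 0.41

#' Derive the mobile/static speed threshold from a reference population
#'
#' Pools the per-step instantaneous speeds (strictly positive steps) of the
#' reference tracks and returns the exponential of the median log speed —
#' i.e. the median speed — in um/min. In a two-population reference (mobile
#' and static cells) this median falls in the gap between the two speed
#' modes and separates them.
#'
#' @param ts a [track_set], or a numeric vector of step speeds in um/min.
#' @param max_gap gap length (frames) splitting segments, see
#'   [track_segments()].
#' @return a `mobility_threshold` list: `value` (um/min) and `provenance`.
#' @export
derive_threshold <- function(ts, max_gap = 3) {
  speeds <- if (is.numeric(ts)) ts else {
    p <- track_segments(ts, max_gap = max_gap)
    unlist(lapply(split(p, p$segment), function(s)
      step_metrics(s, ts$dt)$speed_um_min), use.names = FALSE)
  }
  speeds <- speeds[is.finite(speeds) & speeds > 0]
  if (!length(speeds)) stop("no strictly positive steps in reference tracks")
  structure(list(value = exp(stats::median(log(speeds))),
                 provenance = "derived"),
            class = "mobility_threshold")
}

#' @rdname derive_threshold
#' @export
default_threshold <- function() {
  structure(list(value = published_speed_threshold, provenance = "default_paper"),
            class = "mobility_threshold")
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "mobility_threshold")) threshold$value
  else as.numeric(threshold)
}

#' Classify a segment as mobile or static
#'
#' A segment is mobile iff its mean instantaneous step speed is at or above
#' the threshold. Registration-excluded segments are classed "excluded".
#'
#' @param mean_speed_um_min mean instantaneous speed(s), um/min.
#' @param threshold a `mobility_threshold` or numeric value in um/min.
#' @param excluded logical vector flagging registration-excluded segments.
#' @return character vector in {"mobile", "static", "excluded"}.
#' @export
classify_mobility <- function(mean_speed_um_min,
                              threshold = default_threshold(),
                              excluded = FALSE) {
  thr <- threshold_value(threshold)
  stopifnot(thr > 0)
  out <- ifelse(mean_speed_um_min >= thr, "mobile", "static")
  out[rep_len(excluded, length(out))] <- "excluded"
  out
}

#' Per-segment motility summaries for a whole track set
#'
#' Computes the motility statistics per cell-cycle segment (one cell of the
#' lineage = one cycle; gap-split into contiguous sub-segments), or, with
#' `unit = "merged"`, along each root-to-leaf lineage path pooled into a
#' single polyline.
#'
#' @param ts a [track_set] (already drift-corrected if applicable).
#' @param threshold mobile/static threshold, see [classify_mobility()].
#' @param unit "cycle" (default) or "merged".
#' @param max_gap gap length splitting segments.
#' @param excluded_cells cell ids whose registration failed; their rows are
#'   classed "excluded".
#' @return tibble with one row per (cell_id, segment): MotilitySummary fields.
#' @export
motility_summary <- function(ts, threshold = default_threshold(),
                             unit = c("cycle", "merged"), max_gap = 3,
                             excluded_cells = character()) {
  unit <- match.arg(unit)
  p <- if (unit == "cycle") track_segments(ts, max_gap = max_gap) else
    merged_paths(ts)
  if (!nrow(p)) {
    return(tibble::tibble(cell_id = character(), segment = character(),
                          total_um = numeric(), net_um = numeric(),
                          straightness = numeric(),
                          avg_speed_um_h = numeric(),
                          avg_speed_um_min = numeric(),
                          mean_turn_deg = numeric(), n_steps = integer(),
                          mobility_class = character()))
  }
  segs <- split(p, p$segment)
  rows <- lapply(names(segs), function(sn) {
    s <- segs[[sn]]
    if (nrow(s) < 2L) return(NULL)
    ps <- path_summary(s, ts$dt)
    ps$cell_id <- s$cell_id[1]
    ps$segment <- sn
    ps
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  out[] <- lapply(out, unname)
  out$mobility_class <- classify_mobility(
    out$avg_speed_um_min, threshold,
    excluded = out$cell_id %in% excluded_cells)
  out <- out[order(out$cell_id, out$segment), ]
  dplyr::select(out, "cell_id", "segment", "total_um", "net_um",
                "straightness", "avg_speed_um_h", "avg_speed_um_min",
                "mean_turn_deg", "n_steps", "mobility_class")
}

# concatenate positions along every root-to-leaf path ("merged" unit);
# a mother's steps are shared by both daughter paths
merged_paths <- function(ts) {
  li <- ts$lineage
  if (!nrow(li)) {
    p <- ts$points; p$segment <- character(0); return(p)
  }
  kids <- split(li$cell_id, factor(li$parent_id, levels = li$cell_id))
  leaves <- li$cell_id[vapply(kids[li$cell_id], length, integer(1)) == 0L]
  parent <- stats::setNames(li$parent_id, li$cell_id)
  sp <- split(ts$points, ts$points$cell_id)
  rows <- lapply(leaves, function(leaf) {
    chain <- leaf
    while (!is.na(parent[[chain[1]]])) chain <- c(parent[[chain[1]]], chain)
    path <- dplyr::bind_rows(sp[chain])
    path <- path[order(path$frame), ]
    # mother's division frame and daughter's birth frame coincide
    path <- path[!duplicated(path$frame), ]
    path$cell_id <- chain[1]            # attributed to the founder
    path$segment <- paste0(leaf, "/merged")
    path
  })
  dplyr::bind_rows(rows)
}

#' Sister-cell co-migration after mitosis
#'
#' For each division, forms the vectors from the mitosis site (the mother's
#' last position) to each daughter's position at `t_div + offset`; the
#' daughters co-migrate at that offset iff the vectors point the same way
#' (dot product strictly positive; a zero dot product counts as opposite).
#' Divisions with a daughter not tracked up to the offset are dropped from
#' that offset's denominator.
#'
#' @param ts a [track_set] (drift-corrected).
#' @param offsets_min offsets after mitosis, minutes.
#' @return tibble per offset: n_divisions (denominator), n_comigrating,
#'   fraction, n_dropped.
#' @export
sister_comigration <- function(ts, offsets_min = c(30, 40, 50, 60)) {
  li <- ts$lineage
  mothers <- li$cell_id[li$end_reason == "division"]
  sp <- split(ts$points, ts$points$cell_id)
  out <- lapply(offsets_min, function(off) {
    n_div <- 0L; n_co <- 0L; n_drop <- 0L
    for (m in mothers) {
      ds <- li$cell_id[!is.na(li$parent_id) & li$parent_id == m]
      mp <- sp[[m]]
      site <- c(mp$x_um[nrow(mp)], mp$y_um[nrow(mp)], mp$z_um[nrow(mp)])
      t_target <- li$end_t[li$cell_id == m] + off
      v <- matrix(NA_real_, 2, 3)
      ok <- TRUE
      for (k in 1:2) {
        dp <- sp[[ds[k]]]
        if (is.null(dp) || max(dp$t_min) < t_target - 1e-9) { ok <- FALSE; break }
        pos <- interp_position(dp, t_target)
        v[k, ] <- pos - site
      }
      if (!ok) { n_drop <- n_drop + 1L; next }
      n_div <- n_div + 1L
      if (sum(v[1, ] * v[2, ]) > 0) n_co <- n_co + 1L
    }
    tibble::tibble(offset_min = off, n_divisions = n_div,
                   n_comigrating = n_co,
                   fraction = if (n_div > 0) n_co / n_div else NA_real_,
                   n_dropped = n_drop)
  })
  dplyr::bind_rows(out)
}

interp_position <- function(pts, t) {
  if (t <= pts$t_min[1]) return(c(pts$x_um[1], pts$y_um[1], pts$z_um[1]))
  n <- nrow(pts)
  if (t >= pts$t_min[n]) return(c(pts$x_um[n], pts$y_um[n], pts$z_um[n]))
  i <- findInterval(t, pts$t_min)
  w <- (t - pts$t_min[i]) / (pts$t_min[i + 1] - pts$t_min[i])
  (1 - w) * c(pts$x_um[i], pts$y_um[i], pts$z_um[i]) +
    w * c(pts$x_um[i + 1], pts$y_um[i + 1], pts$z_um[i + 1])
}
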