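#' Simulate rigid fibre drift
#'
#' Cumulative random-walk rigid motion of the fibre: per-frame rotation
#' increments (SD `fibre_rot_sd_deg`, about the fibre centre) and translation
#' increments (SD `fibre_trans_sd_um` per axis). Returns, for every frame,
#' the transform mapping reference (frame-0) coordinates onto that frame's
#' observed coordinates; invert to correct. Deterministic given the seed.
#'
#' @param preset a [simulation_preset].
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return list of `n_frames` `rigid_transform` for frames 0..n_frames-1
#'   (frame 0 = identity).
#' @export
simulate_fibre_motion <- function(preset, n_frames, seed = 1) {
  stopifnot(inherits(preset, "simulation_preset"), n_frames >= 1)
  set.seed(seed)
  motion <- vector("list", n_frames)
  motion[[1]] <- rigid_transform(frame = 0L)
  if (n_frames == 1L) return(motion)
  d_rot <- stats::rnorm(n_frames - 1, 0, preset$fibre_rot_sd_deg)
  d_tx <- stats::rnorm(n_frames - 1, 0, preset$fibre_trans_sd_um)
  d_ty <- stats::rnorm(n_frames - 1, 0, preset$fibre_trans_sd_um)
  for (t in seq_len(n_frames - 1)) {
    inc <- planar_transform(d_rot[t], c(d_tx[t], d_ty[t]), centre = c(0, 0))
    m <- rt_compose(inc, motion[[t]])
    m$frame <- t
    motion[[t + 1L]] <- m
  }
  motion
}

# observed landmark series: fixed points on the fibre, rigidly co-moving,
# read out with isotropic measurement noise
make_landmarks <- function(preset, motion, seed_offset = 0) {
  n <- preset$n_landmarks
  a <- preset$fibre_length_um / 2; b <- preset$fibre_width_um / 2
  u <- stats::runif(n, 0, 2 * pi); r <- sqrt(stats::runif(n))
  ref <- cbind(x_um = a * r * cos(u), y_um = b * r * sin(u), z_um = 0)
  frames <- seq_along(motion) - 1L
  obs <- lapply(seq_along(motion), function(i) {
    p <- rt_apply(motion[[i]], ref)
    p[, 1:2] <- p[, 1:2] +
      stats::rnorm(2 * n, 0, preset$landmark_noise_sd_um)
    tibble::tibble(frame = frames[i], label = paste0("lm", seq_len(n)),
                   x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  })
  list(true = tibble::tibble(label = paste0("lm", seq_len(n)),
                             x_um = ref[, 1], y_um = ref[, 2]),
       observed = dplyr::bind_rows(obs))
}

# one persistent-random-walk / jitter trajectory in the static referential.
# Returns an (n_frames x 2) matrix of positions starting at `start`.
walk_positions <- function(preset, n_steps, start, mobile,
                           heading0 = stats::runif(1, -pi, pi),
                           dispersal_steps = 0) {
  if (n_steps == 0L) return(matrix(start, nrow = 1, ncol = 2))
  mean_um_min <- preset$mobile_speed_mean_um_h / 60
  slog <- preset$mobile_speed_sigma_log
  mulog <- log(mean_um_min) - slog^2 / 2
  if (mobile || dispersal_steps > 0) {
    n_active <- if (mobile) n_steps else min(dispersal_steps, n_steps)
    dh <- stats::rnorm(n_active, 0, preset$heading_sd_deg * pi / 180)
    if (dispersal_steps > 0)      # ballistic separation right after mitosis
      dh[seq_len(min(dispersal_steps, n_active))] <- 0
    h <- heading0 + cumsum(dh)
    v <- stats::rlnorm(n_active, mulog, slog) * preset$dt_min
    steps <- cbind(v * cos(h), v * sin(h))
    cum <- apply(steps, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    pos_active <- rbind(start, sweep(cum, 2, start, "+"))
    if (!mobile && n_active < n_steps) {
      s <- static_jitter_sd_um(preset)
      anchor <- pos_active[nrow(pos_active), ]
      n_j <- n_steps - n_active
      jit <- cbind(stats::rnorm(n_j, anchor[1], s),
                   stats::rnorm(n_j, anchor[2], s))
      return(rbind(pos_active, jit))
    }
    pos_active
  } else {
    s <- static_jitter_sd_um(preset)
    rbind(start, cbind(stats::rnorm(n_steps, start[1], s),
                       stats::rnorm(n_steps, start[2], s)))
  }
}

apply_motion_to_points <- function(points, motion) {
  frames <- vapply(motion, function(m) m$frame, integer(1))
  idx <- match(points$frame, frames)
  if (anyNA(idx)) stop("internal: point frame without fibre-motion transform")
  pts <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  out <- pts
  for (k in sort(unique(idx))) {
    sel <- idx == k
    out[sel, ] <- rt_apply(motion[[k]], pts[sel, , drop = FALSE])
  }
  points$x_um <- out[, 1]; points$y_um <- out[, 2]; points$z_um <- out[, 3]
  points
}

new_scene <- function(kind, preset, points_true, lineage, motion, landmarks,
                      truth) {
  tracks_true <- track_set(points_true, lineage, dt = preset$dt_min)
  observed <- tracks_true
  observed$points <- apply_motion_to_points(tracks_true$points, motion)
  structure(list(
    kind = kind,
    preset = preset,
    tracks_true = tracks_true,
    tracks_observed = observed,
    motion = motion,
    correction_true = lapply(motion, function(m) {
      inv <- rt_invert(m); inv$frame <- m$frame; inv
    }),
    landmarks = landmarks$observed,
    landmarks_true = landmarks$true,
    truth = truth), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene '", x$kind, "', preset '", x$preset$name, "'>\n",
      sep = "")
  print(x$tracks_observed)
  invisible(x)
}

#' Simulate a division-free motility scene
#'
#' Each cell is mobile with probability `f_mobile`. Mobile cells perform a
#' persistent random walk with lognormal step speeds; static cells jitter
#' (independent Gaussian positions) around an anchor. The fibre drifts
#' rigidly; observed tracks and landmarks are the ground truth carried
#' through the drift, so every pipeline stage can be validated against truth.
#'
#' @param preset a [simulation_preset].
#' @param n_cells number of cells (> 0).
#' @param seed integer seed.
#' @param duration_h movie duration, hours.
#' @param fibre_motion set FALSE for a drift-free scene.
#' @return a `synthetic_scene`: `tracks_true`, `tracks_observed`, `motion`,
#'   `correction_true`, `landmarks`, and `truth$mobility` (per-cell class).
#' @export
simulate_tracks <- function(preset, n_cells, seed = 1,
                            duration_h = preset$track_duration_h,
                            fibre_motion = TRUE) {
  stopifnot(inherits(preset, "simulation_preset"))
  if (n_cells <= 0) stop("n_cells must be > 0")
  n_frames <- as.integer(round(duration_h * 60 / preset$dt_min)) + 1L
  motion <- if (fibre_motion) simulate_fibre_motion(preset, n_frames, seed)
    else lapply(seq_len(n_frames) - 1L, function(f) rigid_transform(frame = f))
  set.seed(seed + 1L)
  mobile <- stats::runif(n_cells) < preset$f_mobile
  ids <- sprintf("cell_%04d", seq_len(n_cells))
  a <- preset$fibre_length_um / 2; b <- preset$fibre_width_um / 2
  rows <- lapply(seq_len(n_cells), function(i) {
    start <- c(stats::runif(1, -0.9 * a, 0.9 * a),
               stats::runif(1, -0.6 * b, 0.6 * b))
    pos <- walk_positions(preset, n_frames - 1L, start, mobile[i])
    tibble::tibble(cell_id = ids[i], frame = seq_len(n_frames) - 1L,
                   t_min = (seq_len(n_frames) - 1L) * preset$dt_min,
                   x_um = pos[, 1], y_um = pos[, 2], z_um = 0,
                   myog = "unknown", fibre_contact = "contact")
  })
  points_true <- dplyr::bind_rows(rows)
  landmarks <- make_landmarks(preset, motion)
  truth <- list(mobility = tibble::tibble(
    cell_id = ids, mobile = mobile,
    class = ifelse(mobile, "mobile", "static")))
  new_scene("tracks", preset, points_true, lineage = NULL, motion, landmarks,
            truth)
}

# one stochastic branching pass: timing, modes, fates, orientations.
# `q_modes` is the multinomial used for negative mothers (positive mothers
# divide SCDd only). Deterministic given the seed.
build_tree <- function(preset, n_founders, q_modes, end_min, seed) {
  set.seed(seed)
  dt <- preset$dt_min
  to_frame_min <- function(t) round(t / dt) * dt
  rgamma_ms <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  }
  cells <- list()
  divisions <- list()
  queue <- lapply(seq_len(n_founders), function(i)
    list(id = sprintf("cell_%04d", i), parent = NA_character_,
         birth = 0, gen = 1L, fate = "negative",
         heading = stats::runif(1, -pi, pi), disperse = FALSE,
         orientation_flag = "contact"))
  next_id <- n_founders
  while (length(queue)) {
    c0 <- queue[[1]]; queue <- queue[-1]
    divides <- FALSE; t_div <- NA_real_
    if (c0$gen < preset$max_generation) {
      wants <- c0$fate == "negative" ||
        stats::runif(1) < preset$p_redivide_positive
      if (wants) {
        cyc_mean <- if (c0$gen == 1L) preset$activation_mean_h else
          preset$cycle_mean_h * preset$cycle_slowdown
        cyc_sd <- if (c0$gen == 1L) preset$activation_sd_h else
          preset$cycle_sd_h
        t_div <- to_frame_min(c0$birth + rgamma_ms(1, cyc_mean, cyc_sd) * 60)
        t_div <- max(t_div, c0$birth + dt)   # at least one frame of life
        divides <- t_div <= end_min
      }
    }
    if (divides) {
      mode <- if (c0$fate == "positive") "SCDd" else
        sample(c("ACD", "SCDd", "SCDp"), 1, prob = q_modes)
      orientation <- sample(names(preset$p_orientation), 1,
                            prob = preset$p_orientation)
      fates <- switch(mode,
                      SCDp = c("negative", "negative"),
                      SCDd = c("positive", "positive"),
                      ACD = sample(c("positive", "negative")))
      # daughter fibre-contact flags in the post-mitotic window encode the
      # division orientation; drawn independently of the mode
      flags <- switch(orientation,
                      planar = c("contact", "contact"),
                      perpendicular = sample(c("no_contact", "contact")),
                      undetermined = sample(c("unknown", "contact")))
      same_dir <- stats::runif(1) < preset$p_comigrate
      theta <- stats::runif(1, -pi, pi)
      jitter <- stats::rnorm(2, 0, 10 * pi / 180)
      headings <- c(theta + jitter[1],
                    theta + (if (same_dir) 0 else pi) + jitter[2])
      d_ids <- sprintf("cell_%04d", next_id + 1:2)
      next_id <- next_id + 2L
      for (k in 1:2)
        queue <- c(queue, list(list(
          id = d_ids[k], parent = c0$id, birth = t_div, gen = c0$gen + 1L,
          fate = fates[k], heading = headings[k], disperse = TRUE,
          orientation_flag = flags[k])))
      divisions[[length(divisions) + 1L]] <- list(
        mother_id = c0$id, daughter_a = d_ids[1], daughter_b = d_ids[2],
        t_div_min = t_div, generation = c0$gen, mode = mode,
        orientation = orientation, comigrating = same_dir,
        mother_fate = c0$fate)
      end_t <- t_div; end_reason <- "division"
    } else {
      end_t <- end_min; end_reason <- "censored"
    }
    cells[[length(cells) + 1L]] <- list(
      id = c0$id, parent = c0$parent, birth = c0$birth, gen = c0$gen,
      fate = c0$fate, heading = c0$heading, disperse = c0$disperse,
      orientation_flag = c0$orientation_flag,
      end_t = end_t, end_reason = end_reason)
  }
  list(cells = cells, divisions = divisions)
}

#' Simulate stochastic lineages with division modes, fates and positions
#'
#' Founders divide after an activation-time draw, then every cell-cycle draw;
#' each division is assigned a mode from the preset multinomial (a
#' MYOG-positive mother can only divide differentiatively) and an orientation
#' drawn independently; daughter MYOG fates follow the mode, with live
#' reporter onset delayed by the preset onset kinetics. Positive cells divide
#' again with probability `p_redivide_positive`. Sisters disperse
#' ballistically from the mitosis site, in opposite directions except for a
#' `p_comigrate` fraction of pairs. To reproduce the calibrated terminal
#' differentiation index, excess MYOG-positive survivors fuse into myotubes
#' (end reason "fusion") with a retention probability computed from the
#' realized positive/negative survivor counts, so the expected index over
#' surviving cells equals `diff_index_target`.
#'
#' @param preset a [simulation_preset].
#' @param n_founders number of founder cells (0 gives an empty scene).
#' @param seed integer seed.
#' @param duration_h movie duration, hours.
#' @return a `synthetic_scene` whose `truth` holds the divisions table
#'   (mother, mode, orientation), per-cell fates and mobility classes.
#' @export
simulate_lineages <- function(preset, n_founders, seed = 1,
                              duration_h = preset$duration_h) {
  stopifnot(inherits(preset, "simulation_preset"), n_founders >= 0)
  dt <- preset$dt_min
  n_frames <- as.integer(round(duration_h * 60 / dt)) + 1L
  end_min <- (n_frames - 1L) * dt
  motion <- simulate_fibre_motion(preset, n_frames, seed)
  to_frame_min <- function(t) round(t / dt) * dt

  # a MYOG-positive mother can only divide differentiatively, so her
  # (re)divisions consume part of the SCDd quota: the multinomial used for
  # negative mothers is adjusted by the share r of positive-mother divisions
  # so that the pooled mode fractions over all classified divisions match the
  # preset. r is emergent; two pilot passes estimate it.
  adjust_modes <- function(p, r) {
    if (r <= 0) return(p)
    q <- c(ACD = p[["ACD"]] / (1 - r),
           SCDd = max(0, (p[["SCDd"]] - r)) / (1 - r),
           SCDp = p[["SCDp"]] / (1 - r))
    q / sum(q)
  }
  p_modes <- preset$p_modes[c("ACD", "SCDd", "SCDp")]
  q_modes <- p_modes
  for (pass in 1:2) {
    pilot <- build_tree(preset, n_founders, q_modes, end_min,
                        seed = seed + 10L + pass)
    if (!length(pilot$divisions)) break
    mf <- vapply(pilot$divisions, function(d) d$mother_fate, character(1))
    q_modes <- adjust_modes(p_modes, mean(mf == "positive"))
  }
  tree <- build_tree(preset, n_founders, q_modes, end_min, seed = seed + 1L)
  cells <- tree$cells
  divisions <- lapply(tree$divisions, function(d)
    tibble::tibble(mother_id = d$mother_id, daughter_a = d$daughter_a,
                   daughter_b = d$daughter_b, t_div_min = d$t_div_min,
                   generation = d$generation, mode = d$mode,
                   orientation = d$orientation, comigrating = d$comigrating))
  rgamma_ms <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  }

  # terminal-fate calibration: excess MYOG-positive survivors fuse into
  # myotubes, so the expected differentiation index over surviving
  # mononucleated cells equals the preset target
  if (length(cells)) {
    surv <- vapply(cells, function(cc) cc$end_reason == "censored", logical(1))
    fate <- vapply(cells, function(cc) cc$fate, character(1))
    n_pos <- sum(surv & fate == "positive")
    n_neg <- sum(surv & fate == "negative")
    d <- preset$diff_index_target
    p_retain <- if (n_pos == 0 || d >= 1) 1 else
      min(1, d * n_neg / ((1 - d) * n_pos))
    for (i in which(surv & fate == "positive")) {
      if (stats::runif(1) < p_retain) next
      birth <- cells[[i]]$birth
      # fused cells must have been observable for at least one frame and be
      # gone before the endpoint read-out
      lo <- min(birth + 2 * 60, end_min - dt)      # visible for ~2 h
      hi <- end_min - dt
      if (lo < birth + dt || hi < lo) next         # born too late to fuse
      cells[[i]]$end_t <- to_frame_min(stats::runif(1, lo, hi))
      cells[[i]]$end_reason <- "fusion"
    }
  }

  # positions and annotations
  mean_jit <- static_jitter_sd_um(preset)
  a <- preset$fibre_length_um / 2; b <- preset$fibre_width_um / 2
  last_pos <- list()
  mobile_draw <- list()
  point_rows <- vector("list", length(cells))
  disp_steps_total <- max(1L, round(preset$dispersal_min / dt))
  # process mothers before daughters so the mitosis site is known
  ord <- order(vapply(cells, function(cc) cc$birth, numeric(1)))
  for (i in ord) {
    cc <- cells[[i]]
    f0 <- as.integer(round(cc$birth / dt))
    f1 <- as.integer(round(cc$end_t / dt))
    n_steps <- f1 - f0
    mobile <- stats::runif(1) < preset$f_mobile
    mobile_draw[[cc$id]] <- mobile
    start <- if (is.na(cc$parent)) c(stats::runif(1, -0.9 * a, 0.9 * a),
                                     stats::runif(1, -0.6 * b, 0.6 * b))
             else last_pos[[cc$parent]]
    pos <- walk_positions(preset, n_steps, start, mobile,
                          heading0 = cc$heading,
                          dispersal_steps = if (cc$disperse)
                            disp_steps_total else 0)
    last_pos[[cc$id]] <- pos[nrow(pos), ]
    frames <- f0:f1
    t_min <- frames * dt
    myog <- rep("negative", length(frames))
    if (cc$fate == "positive") {
      onset <- cc$birth + rgamma_ms(1, preset$myog_onset_mean_h,
                                    preset$myog_onset_sd_h) * 60
      myog[t_min >= onset] <- "positive"
    }
    contact <- rep("contact", length(frames))
    if (cc$disperse && cc$orientation_flag != "contact")
      contact[seq_len(min(2L, length(frames)))] <- cc$orientation_flag
    point_rows[[i]] <- tibble::tibble(
      cell_id = cc$id, frame = frames, t_min = t_min,
      x_um = pos[, 1], y_um = pos[, 2], z_um = 0,
      myog = myog, fibre_contact = contact)
  }

  if (!length(cells)) {
    points_true <- tibble::tibble(cell_id = character(), frame = integer(),
                                  t_min = numeric(), x_um = numeric(),
                                  y_um = numeric(), z_um = numeric(),
                                  myog = character(),
                                  fibre_contact = character())
    lineage <- NULL
  } else {
    points_true <- dplyr::bind_rows(point_rows)
    lineage <- tibble::tibble(
      cell_id = vapply(cells, `[[`, character(1), "id"),
      parent_id = vapply(cells, `[[`, character(1), "parent"),
      birth_t = vapply(cells, `[[`, numeric(1), "birth"),
      end_t = vapply(cells, `[[`, numeric(1), "end_t"),
      end_reason = vapply(cells, `[[`, character(1), "end_reason"),
      fate = vapply(cells, `[[`, character(1), "fate"))
  }
  landmarks <- make_landmarks(preset, motion)
  div_tbl <- if (length(divisions)) dplyr::bind_rows(divisions) else
    tibble::tibble(mother_id = character(), daughter_a = character(),
                   daughter_b = character(), t_div_min = numeric(),
                   generation = integer(), mode = character(),
                   orientation = character(), comigrating = logical())
  truth <- list(
    divisions = div_tbl,
    fates = if (length(cells)) tibble::tibble(
      cell_id = vapply(cells, `[[`, character(1), "id"),
      fate = vapply(cells, `[[`, character(1), "fate")) else
        tibble::tibble(cell_id = character(), fate = character()),
    mobility = tibble::tibble(
      cell_id = names(mobile_draw),
      mobile = unlist(mobile_draw, use.names = FALSE)))
  new_scene("lineages", preset, points_true, lineage, motion, landmarks,
            truth)
}

#' Export a synthetic scene to plain-text files
#'
#' Writes the observed tracks (CSV and TrackMate-dialect XML), the
#' ground-truth tracks, the landmark series, the true frame-to-reference
#' correction transforms, and a YAML sidecar with the preset and per-cell
#' truth. All files are re-readable by the pipeline readers.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
export_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks_csv(scene$tracks_observed, file.path(dir, "tracks.csv"))
  write_tracks_xml(scene$tracks_observed, file.path(dir, "tracks.xml"))
  write_tracks_csv(scene$tracks_true, file.path(dir, "tracks_true.csv"))
  lm <- scene$landmarks
  lm_df <- data.frame(frame = lm$frame, label = lm$label,
                      x_um = sprintf("%.6f", lm$x_um),
                      y_um = sprintf("%.6f", lm$y_um),
                      z_um = sprintf("%.6f", lm$z_um))
  utils::write.csv(lm_df, file.path(dir, "landmarks.csv"),
                   row.names = FALSE, quote = FALSE)
  write_transforms_csv(scene$correction_true,
                       file.path(dir, "true_transforms.csv"))
  truth <- list(
    kind = scene$kind,
    preset = scene$preset[!vapply(scene$preset, is.null, logical(1))],
    n_cells = nrow(scene$tracks_true$lineage),
    mode_counts = as.list(table(scene$truth$divisions$mode)),
    cells = if (nrow(scene$truth$mobility)) lapply(
      seq_len(nrow(scene$truth$mobility)), function(i) {
        id <- scene$truth$mobility$cell_id[i]
        f <- scene$truth$fates$fate[scene$truth$fates$cell_id == id]
        list(cell_id = id,
             mobile = scene$truth$mobility$mobile[i],
             fate = if (length(f)) f else "unknown")
      }) else list())
  truth$preset$p_modes <- as.list(scene$preset$p_modes)
  truth$preset$p_orientation <- as.list(scene$preset$p_orientation)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Import an exported scene directory
#'
#' Reads the observed tracks and landmark series written by [export_scene()]
#' (the pipeline-facing subset; truth sidecars are read with
#' [yaml::read_yaml()] if needed).
#'
#' @param dir directory written by [export_scene()].
#' @return list with `tracks` (a [track_set]) and `landmarks` (tibble).
#' @export
import_scene <- function(dir) {
  list(tracks = read_tracks_csv(file.path(dir, "tracks.csv")),
       landmarks = utils::read.csv(file.path(dir, "landmarks.csv"),
                                   colClasses = c(label = "character")))
}
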