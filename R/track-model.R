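#' Track set: timed cell trajectories plus lineage
#'
#' The central container of the pipeline. `points` holds one row per observed
#' cell position; `lineage` holds one row per cell with its parent link, birth
#' and end times and fate label. Coordinates are micrometres in a common
#' (right-handed, image-corner-origin) referential; frames are 0-based; time
#' is minutes internally (hours only at reporting).
#'
#' @param points tibble with columns cell_id, frame, t_min, x_um, y_um, z_um,
#'   myog (one of "negative", "positive", "unknown"), fibre_contact (one of
#'   "contact", "no_contact", "unknown"). z may be omitted (treated as 0);
#'   myog/fibre_contact may be omitted (treated as "unknown").
#' @param lineage tibble with columns cell_id, parent_id (NA for roots),
#'   birth_t (min), end_t (min), end_reason (one of "division", "censored",
#'   "fusion"), fate (one of "negative", "positive", "unknown"). Derived from
#'   `points` when NULL: a cell with daughters ends in "division", others are
#'   "censored"; fate defaults to the last myog observation.
#' @param dt frame interval in minutes; inferred from `points` when NULL.
#' @return object of class `track_set`.
#' @export
track_set <- function(points, lineage = NULL, dt = NULL) {
  points <- tibble::as_tibble(points)
  req <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  miss <- setdiff(req, names(points))
  if (length(miss))
    stop("points is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"z_um" %in% names(points)) points$z_um <- 0
  points$z_um[is.na(points$z_um)] <- 0
  for (col in c("myog", "fibre_contact")) {
    if (!col %in% names(points)) points[[col]] <- "unknown"
    v <- as.character(points[[col]])
    ok <- if (col == "myog") c("negative", "positive") else
      c("contact", "no_contact")
    v[is.na(v) | !(v %in% ok)] <- "unknown"
    points[[col]] <- v
  }
  points$cell_id <- as.character(points$cell_id)
  points$frame <- as.integer(points$frame)
  points <- points[order(points$cell_id, points$frame), ]
  coords <- as.matrix(points[, c("x_um", "y_um", "z_um")])
  if (nrow(points) && !all(is.finite(coords)))
    stop("non-finite coordinates in points")
  # frames strictly increasing within a cell
  bad <- unlist(lapply(split(points$frame, points$cell_id), function(f)
    any(diff(f) <= 0)))
  if (any(bad))
    stop("non-monotone frames within cell(s): ",
         paste(names(bad)[bad], collapse = ", "))
  if (is.null(dt)) dt <- infer_dt(points)
  if (nrow(points)) {
    resid <- points$t_min - points$frame * dt
    if (max(abs(resid - resid[1])) > 1e-6 + 1e-9 * max(abs(points$t_min), 1))
      warning("t_min is not consistent with frame * dt for all points")
  }
  if (is.null(lineage)) lineage <- derive_lineage(points)
  lineage <- tibble::as_tibble(lineage)
  lineage[] <- lapply(lineage, unname)
  lineage$cell_id <- as.character(lineage$cell_id)
  lineage$parent_id <- as.character(lineage$parent_id)
  validate_lineage(lineage)
  ts <- structure(list(points = points, lineage = lineage, dt = dt),
                  class = "track_set")
  ts
}

infer_dt <- function(points) {
  d <- unlist(lapply(split(points, points$cell_id), function(p)
    diff(p$t_min) / diff(p$frame)))
  if (!length(d)) return(1)
  stats::median(d)
}

derive_lineage <- function(points, parent_map = NULL) {
  if (!nrow(points))
    return(tibble::tibble(cell_id = character(), parent_id = character(),
                          birth_t = numeric(), end_t = numeric(),
                          end_reason = character(), fate = character()))
  sp <- split(points, points$cell_id)
  ids <- names(sp)
  parent <- if (is.null(parent_map)) rep(NA_character_, length(ids)) else
    unname(parent_map[ids])
  n_kids <- table(factor(parent, levels = ids))
  tibble::tibble(
    cell_id = ids,
    parent_id = parent,
    birth_t = vapply(sp, function(p) p$t_min[1], numeric(1)),
    end_t = vapply(sp, function(p) p$t_min[nrow(p)], numeric(1)),
    end_reason = ifelse(as.integer(n_kids) > 0, "division", "censored"),
    fate = vapply(sp, function(p) {
      m <- p$myog[p$myog != "unknown"]
      if (length(m)) m[length(m)] else "unknown"
    }, character(1))
  )
}

validate_lineage <- function(lineage) {
  if (!nrow(lineage)) return(invisible(TRUE))
  req <- c("cell_id", "parent_id", "birth_t", "end_t", "end_reason", "fate")
  miss <- setdiff(req, names(lineage))
  if (length(miss))
    stop("lineage is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(lineage$cell_id))
    stop("duplicated cell_id in lineage")
  known_parent <- !is.na(lineage$parent_id)
  if (any(known_parent & !(lineage$parent_id %in% lineage$cell_id)))
    stop("parent_id refers to unknown cell(s): ",
         paste(setdiff(lineage$parent_id[known_parent], lineage$cell_id),
               collapse = ", "))
  # acyclicity: walk each cell to a root, bounded by the number of cells
  parent <- stats::setNames(lineage$parent_id, lineage$cell_id)
  n <- length(parent)
  for (id in lineage$cell_id) {
    cur <- id; steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]; steps <- steps + 1L
      if (steps > n) stop("cycle detected in parent links (at cell ", id, ")")
    }
  }
  kids <- table(factor(lineage$parent_id, levels = lineage$cell_id))
  div <- lineage$end_reason == "division"
  bad2 <- lineage$cell_id[div & as.integer(kids) != 2L]
  if (length(bad2))
    stop("division node(s) without exactly 2 daughters: ",
         paste(bad2, collapse = ", "))
  bad_nd <- lineage$cell_id[!div & as.integer(kids) > 0L]
  if (length(bad_nd))
    stop("cell(s) with daughters but end_reason not 'division': ",
         paste(bad_nd, collapse = ", "))
  # daughters born at the mother's division time
  m <- match(lineage$parent_id, lineage$cell_id)
  has_p <- which(!is.na(m))
  if (length(has_p)) {
    dt_birth <- abs(lineage$birth_t[has_p] - lineage$end_t[m[has_p]])
    if (any(dt_birth > 1e-6))
      stop("daughter birth time != mother division time for: ",
           paste(lineage$cell_id[has_p][dt_birth > 1e-6], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.track_set <- function(x, ...) {
  nd <- sum(x$lineage$end_reason == "division")
  cat("<track_set> ", nrow(x$lineage), " cells, ", nrow(x$points),
      " points, ", nd, " divisions, dt = ", x$dt, " min\n", sep = "")
  invisible(x)
}

csv_columns <- c("cell_id", "parent_id", "frame", "t_min", "x_um", "y_um",
                 "z_um", "myog", "fibre_contact")

#' Read tracks from CSV
#'
#' Expects the tabular track format: header columns cell_id, parent_id,
#' frame, t_min, x_um, y_um, z_um, myog, fibre_contact (extra columns
#' `end_reason` and `fate` are honoured when present). Unknown annotation
#' values map to "unknown".
#'
#' @param path CSV file path.
#' @return a [track_set].
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  miss <- setdiff(csv_columns, names(df))
  if (length(miss))
    stop("CSV is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    return(track_set(tibble::tibble(cell_id = character(), frame = integer(),
                                    t_min = numeric(), x_um = numeric(),
                                    y_um = numeric()), dt = 1))
  }
  pts <- tibble::tibble(
    cell_id = df$cell_id,
    frame = as.integer(df$frame),
    t_min = as.numeric(df$t_min),
    x_um = as.numeric(df$x_um),
    y_um = as.numeric(df$y_um),
    z_um = as.numeric(df$z_um),
    myog = df$myog,
    fibre_contact = df$fibre_contact
  )
  parent <- df$parent_id
  parent[parent %in% c("", "NA")] <- NA_character_
  pm <- tapply(parent, df$cell_id, function(v) v[1])
  lineage <- derive_lineage(track_points_clean(pts), parent_map = pm)
  for (col in c("end_reason", "fate")) {
    if (col %in% names(df)) {
      v <- tapply(df[[col]], df$cell_id, function(x) x[1])
      vv <- unname(v[lineage$cell_id])
      keep <- !is.na(vv) & vv != ""
      # a stated end_reason never overrides a structural division
      if (col == "end_reason")
        keep <- keep & lineage$end_reason != "division"
      lineage[[col]][keep] <- vv[keep]
    }
  }
  track_set(pts, lineage)
}

track_points_clean <- function(pts) {
  pts$cell_id <- as.character(pts$cell_id)
  for (col in c("myog", "fibre_contact")) {
    v <- as.character(pts[[col]])
    ok <- if (col == "myog") c("negative", "positive") else
      c("contact", "no_contact")
    v[is.na(v) | !(v %in% ok)] <- "unknown"
    pts[[col]] <- v
  }
  pts[order(pts$cell_id, pts$frame), ]
}

#' Write tracks to CSV
#'
#' Fixed column order (cell_id, parent_id, frame, t_min, x_um, y_um, z_um,
#' myog, fibre_contact, end_reason, fate); all floats with 6 decimal digits,
#' so write/read/write is byte-stable.
#'
#' @param ts a [track_set].
#' @param path output file path.
#' @export
write_tracks_csv <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  p <- ts$points
  li <- ts$lineage
  m <- match(p$cell_id, li$cell_id)
  df <- data.frame(
    cell_id = p$cell_id,
    parent_id = ifelse(is.na(li$parent_id[m]), "", li$parent_id[m]),
    frame = p$frame,
    t_min = sprintf("%.6f", p$t_min),
    x_um = sprintf("%.6f", p$x_um),
    y_um = sprintf("%.6f", p$y_um),
    z_um = sprintf("%.6f", p$z_um),
    myog = p$myog,
    fibre_contact = p$fibre_contact,
    end_reason = li$end_reason[m],
    fate = li$fate[m],
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  invisible(path)
}

#' Read tracks from a TrackMate-dialect XML file
#'
#' Supports the spots + edges subset of the TrackMate model: `Spot` elements
#' with ID, FRAME and POSITION_X/Y/Z(/T) attributes under
#' `Model/AllSpots/SpotsInFrame`, and `Edge` elements with
#' SPOT_SOURCE_ID/SPOT_TARGET_ID under `Model/AllTracks/Track`. A spot with
#' two outgoing edges at one frame is a division; more than two is a
#' structural error. Positions are converted to um using the file's spatial
#' calibration when `spatialunits` is "pixel".
#'
#' @param path XML file path.
#' @return a [track_set]; each branch between divisions becomes one cell.
#' @export
read_tracks_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e)))
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing"))
    stop("malformed XML: no <Model> element found")
  units <- xml2::xml_attr(model, "spatialunits")
  scale <- c(1, 1, 1)
  dt <- NA_real_
  img <- xml2::xml_find_first(doc, ".//ImageData")
  if (!inherits(img, "xml_missing")) {
    pw <- as.numeric(xml2::xml_attr(img, "pixelwidth"))
    ph <- as.numeric(xml2::xml_attr(img, "pixelheight"))
    vd <- as.numeric(xml2::xml_attr(img, "voxeldepth"))
    ti <- as.numeric(xml2::xml_attr(img, "timeinterval"))
    if (!is.na(ti)) dt <- ti
    if (identical(units, "pixel"))
      scale <- c(ifelse(is.na(pw), 1, pw), ifelse(is.na(ph), 1, ph),
                 ifelse(is.na(vd), 1, vd))
  }
  spots <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (!length(spots)) stop("malformed XML: no <Spot> elements under <AllSpots>")
  sid <- xml2::xml_attr(spots, "ID")
  if (anyNA(sid)) stop("malformed XML: <Spot> without ID attribute")
  frame <- as.integer(xml2::xml_attr(spots, "FRAME"))
  px <- as.numeric(xml2::xml_attr(spots, "POSITION_X")) * scale[1]
  py <- as.numeric(xml2::xml_attr(spots, "POSITION_Y")) * scale[2]
  pz0 <- xml2::xml_attr(spots, "POSITION_Z")
  pz <- ifelse(is.na(pz0), 0, as.numeric(pz0)) * scale[3]
  myog <- xml2::xml_attr(spots, "MYOG")
  contact <- xml2::xml_attr(spots, "FIBRE_CONTACT")
  if (anyNA(frame) || anyNA(px) || anyNA(py))
    stop("malformed XML: <Spot> missing FRAME/POSITION attributes")
  if (is.na(dt)) {
    pt0 <- as.numeric(xml2::xml_attr(spots, "POSITION_T"))
    dt <- if (all(is.na(pt0)) || max(frame) == 0) 1 else
      stats::median(pt0[frame > 0] / frame[frame > 0], na.rm = TRUE)
  }
  edges <- xml2::xml_find_all(doc, ".//AllTracks//Edge")
  src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
  tgt <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
  if (length(src) && (anyNA(src) || anyNA(tgt)))
    stop("malformed XML: <Edge> missing SPOT_SOURCE_ID/SPOT_TARGET_ID")
  unknown <- setdiff(c(src, tgt), sid)
  if (length(unknown))
    stop("malformed XML: edge references unknown spot id(s): ",
         paste(unknown, collapse = ", "))
  n_out <- table(factor(src, levels = sid))
  over <- names(n_out)[n_out > 2]
  if (length(over))
    stop("spot(s) with more than 2 daughters: ", paste(over, collapse = ", "))
  n_in <- table(factor(tgt, levels = sid))
  if (any(n_in > 1))
    stop("spot(s) with more than one incoming edge: ",
         paste(names(n_in)[n_in > 1], collapse = ", "))
  succ <- split(tgt, factor(src, levels = sid))
  # walk branches: a new cell starts at a root spot or just after a division
  roots <- sid[as.integer(n_in) == 0L]
  pos <- stats::setNames(seq_along(sid), sid)
  rows <- list(); lin <- list()
  queue <- lapply(roots, function(r) list(spot = r, parent = NA_character_))
  cell_n <- 0L
  while (length(queue)) {
    job <- queue[[1]]; queue <- queue[-1]
    cell_n <- cell_n + 1L
    cid <- sprintf("cell_%04d", cell_n)
    chain <- character(0)
    cur <- job$spot
    repeat {
      chain <- c(chain, cur)
      nxt <- succ[[cur]]
      if (length(nxt) == 1L) cur <- nxt else break
    }
    i <- unname(pos[chain])
    fr <- frame[i]
    rows[[cell_n]] <- tibble::tibble(
      cell_id = cid, frame = fr, t_min = fr * dt,
      x_um = px[i], y_um = py[i], z_um = pz[i],
      myog = ifelse(is.na(myog[i]), "unknown", myog[i]),
      fibre_contact = ifelse(is.na(contact[i]), "unknown", contact[i]))
    nxt <- succ[[cur]]
    lin[[cell_n]] <- tibble::tibble(cell_id = cid, parent_id = job$parent,
      divides = length(nxt) == 2L)
    if (length(nxt) == 2L)
      queue <- c(queue, lapply(nxt, function(s) list(spot = s, parent = cid)))
  }
  pts <- dplyr::bind_rows(rows)
  linfo <- dplyr::bind_rows(lin)
  pm <- stats::setNames(linfo$parent_id, linfo$cell_id)
  lineage <- derive_lineage(track_points_clean(pts), parent_map = pm)
  # daughters in TrackMate carry their first spot one frame after the
  # division; anchor their birth at the mother's division time
  m <- match(lineage$parent_id, lineage$cell_id)
  has_p <- !is.na(m)
  lineage$birth_t[has_p] <- lineage$end_t[m[has_p]]
  track_set(pts, lineage, dt = dt)
}

#' Write tracks to the TrackMate-dialect XML format
#'
#' Inverse of [read_tracks_xml()]: spots in um (`spatialunits="micron"`),
#' edges chaining each cell and linking mothers to daughter branches.
#'
#' @param ts a [track_set].
#' @param path output file path.
#' @export
write_tracks_xml <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  p <- ts$points
  sid <- sprintf("%d", seq_len(nrow(p)))
  fmt <- function(v) sprintf("%.6f", v)
  spot_attrs <- sprintf(
    '<Spot ID="%s" name="%s" FRAME="%d" POSITION_X="%s" POSITION_Y="%s" POSITION_Z="%s" POSITION_T="%s" MYOG="%s" FIBRE_CONTACT="%s" />',
    sid, p$cell_id, p$frame, fmt(p$x_um), fmt(p$y_um), fmt(p$z_um),
    fmt(p$t_min), p$myog, p$fibre_contact)
  frames <- sort(unique(p$frame))
  spots_block <- unlist(lapply(frames, function(f) {
    c(sprintf('<SpotsInFrame frame="%d">', f), spot_attrs[p$frame == f],
      "</SpotsInFrame>")
  }))
  # edges: within-cell chains, then mother-last-spot -> daughter-first-spot
  first_idx <- tapply(seq_len(nrow(p)), p$cell_id, function(i) i[1])
  last_idx <- tapply(seq_len(nrow(p)), p$cell_id, function(i) i[length(i)])
  edges <- character(0)
  for (cid in unique(p$cell_id)) {
    i <- which(p$cell_id == cid)
    if (length(i) > 1)
      edges <- c(edges, sprintf(
        '<Edge SPOT_SOURCE_ID="%s" SPOT_TARGET_ID="%s" />',
        sid[i[-length(i)]], sid[i[-1]]))
  }
  li <- ts$lineage
  kid <- li[!is.na(li$parent_id), ]
  if (nrow(kid))
    edges <- c(edges, sprintf(
      '<Edge SPOT_SOURCE_ID="%s" SPOT_TARGET_ID="%s" />',
      sid[last_idx[kid$parent_id]], sid[first_idx[kid$cell_id]]))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<TrackMate version="7">',
    '<Model spatialunits="micron" timeunits="min">',
    "<AllSpots>", spots_block, "</AllSpots>",
    "<AllTracks>", '<Track TRACK_ID="0">', edges, "</Track>", "</AllTracks>",
    "</Model>",
    "<Settings>",
    sprintf('<ImageData pixelwidth="1" pixelheight="1" voxeldepth="1" timeinterval="%s" />',
            fmt(ts$dt)),
    "</Settings>",
    "</TrackMate>")
  writeLines(lines, path)
  invisible(path)
}

#' Split tracks into contiguous segments
#'
#' Motility metrics are computed per contiguous segment: a gap of more than
#' `max_gap` missing frames splits a cell's track, since long gaps corrupt
#' step statistics.
#'
#' @param ts a [track_set].
#' @param max_gap maximum tolerated number of consecutive missing frames.
#' @return the `points` tibble with an extra `segment` column
#'   ("cell_id/s<k>") and a `has_gap` flag.
#' @export
track_segments <- function(ts, max_gap = 3) {
  p <- ts$points
  if (!nrow(p)) {
    p$segment <- character(0); p$has_gap <- logical(0)
    return(p)
  }
  p <- p[order(p$cell_id, p$frame), ]
  new_cell <- c(TRUE, p$cell_id[-1] != p$cell_id[-nrow(p)])
  gap <- c(0L, diff(p$frame)) - 1L
  gap[new_cell] <- 0L
  brk <- new_cell | gap > max_gap
  seg_k <- stats::ave(as.integer(brk), p$cell_id, FUN = cumsum)
  p$segment <- paste0(p$cell_id, "/s", seg_k)
  p$has_gap <- stats::ave(gap, p$segment, FUN = function(g) any(g > 0)) > 0
  p
}
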