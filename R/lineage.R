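#' Cell-cycle durations per generation
#'
#' Generation 1 is the time from observation start (or grafting) to the first
#' division of a founder; generation k >= 2 is the inter-division interval of
#' a daughter cell. Censored cells (no division before movie end) are flagged
#' and excluded from duration means; [mean_cycle_durations()] additionally
#' applies a minimum observation-window filter so that completed intervals
#' squeezed against the end of the movie do not bias means downwards.
#'
#' @param ts a [track_set].
#' @param t_start observation start time, minutes (default 0).
#' @param t_end end of observation, minutes; defaults to the latest point.
#' @return tibble: cell_id, generation, birth_min, duration_h, censored,
#'   window_h (available observation window of the cell, h).
#' @export
cell_cycle_durations <- function(ts, t_start = 0, t_end = NULL) {
  li <- ts$lineage
  if (!nrow(li))
    return(tibble::tibble(cell_id = character(), generation = integer(),
                          birth_min = numeric(), duration_h = numeric(),
                          censored = logical(), window_h = numeric()))
  if (is.null(t_end)) t_end <- max(ts$points$t_min, li$end_t)
  gen <- lineage_generation(li)
  birth <- ifelse(is.na(li$parent_id), t_start, li$birth_t)
  if (any(li$end_t < birth - 1e-9))
    stop("division/end before birth for cell(s): ",
         paste(li$cell_id[li$end_t < birth - 1e-9], collapse = ", "))
  divided <- li$end_reason == "division"
  tibble::tibble(
    cell_id = li$cell_id,
    generation = unname(gen[li$cell_id]),
    birth_min = birth,
    duration_h = ifelse(divided, (li$end_t - birth) / 60, NA_real_),
    censored = !divided,
    window_h = (t_end - birth) / 60)
}

lineage_generation <- function(li) {
  parent <- stats::setNames(li$parent_id, li$cell_id)
  gen <- stats::setNames(rep(NA_integer_, nrow(li)), li$cell_id)
  for (id in li$cell_id) {
    g <- 1L; cur <- id
    while (!is.na(parent[[cur]])) { cur <- parent[[cur]]; g <- g + 1L }
    gen[[id]] <- g
  }
  gen
}

#' Mean cycle duration by generation group
#'
#' @param durations output of [cell_cycle_durations()].
#' @param min_window_h cells whose observation window is shorter than this
#'   are dropped before averaging (administrative-censoring guard; only
#'   applied to generations >= 2, whose windows start mid-movie). Default 16 h.
#' @return tibble per generation group ("1", ">=2"): n, mean_h, sd_h, se_h,
#'   n_censored.
#' @export
mean_cycle_durations <- function(durations, min_window_h = 16) {
  d <- durations
  d$group <- ifelse(d$generation == 1L, "1", ">=2")
  d <- d[d$group == "1" | d$window_h >= min_window_h, ]
  done <- d[!d$censored, ]
  out <- lapply(split(done, done$group), function(g)
    tibble::tibble(generation_group = g$group[1], n = nrow(g),
                   mean_h = mean(g$duration_h), sd_h = stats::sd(g$duration_h),
                   se_h = stats::sd(g$duration_h) / sqrt(nrow(g))))
  res <- dplyr::bind_rows(out)
  cens <- table(d$group[d$censored])
  res$n_censored <- as.integer(cens[res$generation_group])
  res$n_censored[is.na(res$n_censored)] <- 0L
  res
}

#' Classify a division from its daughters' MYOG fates
#'
#' Both daughters negative: symmetric proliferative (SCDp); both positive:
#' symmetric differentiative (SCDd); one of each: asymmetric (ACD); any
#' unknown fate: unclassified.
#'
#' @param fate_a,fate_b daughter fates in {"negative", "positive", "unknown"}
#'   (vectorized).
#' @return character vector in {"SCDp", "SCDd", "ACD", "unclassified"}.
#' @export
classify_division <- function(fate_a, fate_b) {
  out <- rep("unclassified", length(fate_a))
  known <- fate_a %in% c("negative", "positive") &
    fate_b %in% c("negative", "positive")
  both_neg <- known & fate_a == "negative" & fate_b == "negative"
  both_pos <- known & fate_a == "positive" & fate_b == "positive"
  out[both_neg] <- "SCDp"
  out[both_pos] <- "SCDd"
  out[known & !both_neg & !both_pos] <- "ACD"
  out
}

#' Read a daughter's fate at classification time
#'
#' Two reading modes mirror the two experimental designs: `endpoint`
#' (immunostaining at the end of the movie; the recorded fate label, falling
#' back to the last annotated observation) and `live` (knock-in fluorescent
#' reporter; the cell is positive if any observation between its birth and
#' its own division/end is positive — reporter onset lags mitosis by several
#' hours, so only the post-mitotic window counts).
#'
#' @param ts a [track_set].
#' @param cell_id the daughter cell.
#' @param mode "endpoint" or "live".
#' @return one of "negative", "positive", "unknown".
#' @export
fate_at_classification <- function(ts, cell_id, mode = c("endpoint", "live")) {
  mode <- match.arg(mode)
  li <- ts$lineage
  row <- li[li$cell_id == cell_id, ]
  if (!nrow(row)) stop("unknown cell_id: ", cell_id)
  fate_from_obs(ts$points$myog[ts$points$cell_id == cell_id], row$fate, mode)
}

fate_from_obs <- function(obs, recorded_fate, mode) {
  obs <- obs[obs != "unknown"]
  if (mode == "endpoint") {
    if (recorded_fate %in% c("negative", "positive")) return(recorded_fate)
    if (length(obs)) return(obs[length(obs)])
    return("unknown")
  }
  if (!length(obs)) return("unknown")
  if (any(obs == "positive")) "positive" else "negative"
}

# per-cell fates for many cells at once (points split only once)
fates_for <- function(ts, ids, mode) {
  myog_by_cell <- split(ts$points$myog, ts$points$cell_id)
  rec <- stats::setNames(ts$lineage$fate, ts$lineage$cell_id)
  vapply(ids, function(id)
    fate_from_obs(myog_by_cell[[id]], rec[[id]], mode), character(1))
}

#' Division orientation relative to the myofibre
#'
#' Planar if both sisters are in contact with the fibre at mitosis,
#' perpendicular if exactly one sister has no contact; any unknown contact
#' flag gives "undetermined".
#'
#' @param contact_a,contact_b daughter fibre-contact flags within the first
#'   post-mitotic frames, in {"contact", "no_contact", "unknown"} (vectorized).
#' @return character in {"planar", "perpendicular", "undetermined"}.
#' @export
division_orientation <- function(contact_a, contact_b) {
  out <- rep("undetermined", length(contact_a))
  known <- contact_a %in% c("contact", "no_contact") &
    contact_b %in% c("contact", "no_contact")
  both <- known & contact_a == "contact" & contact_b == "contact"
  one <- known & xor(contact_a == "no_contact", contact_b == "no_contact")
  out[both] <- "planar"
  out[one] <- "perpendicular"
  out[known & !both & !one] <- "undetermined"  # both detached
  out
}

#' Build division records from a track set
#'
#' One row per division with mode (from daughter fates, see
#' [classify_division()]) and orientation (from daughter contact flags within
#' the first `contact_window_frames` post-mitotic frames).
#'
#' @param ts a [track_set].
#' @param fate_mode "endpoint" or "live", see [fate_at_classification()].
#' @param contact_window_frames frames after mitosis in which the daughters'
#'   fibre-contact status is read.
#' @return tibble: mother_id, daughter_a, daughter_b, t_div_h, generation,
#'   mother_fate, mode, orientation.
#' @export
division_records <- function(ts, fate_mode = c("endpoint", "live"),
                             contact_window_frames = 2) {
  fate_mode <- match.arg(fate_mode)
  li <- ts$lineage
  mothers <- li$cell_id[li$end_reason == "division"]
  if (!length(mothers))
    return(tibble::tibble(mother_id = character(), daughter_a = character(),
                          daughter_b = character(), t_div_h = numeric(),
                          generation = integer(), mother_fate = character(),
                          mode = character(), orientation = character()))
  gen <- lineage_generation(li)
  contact_by_cell <- split(ts$points$fibre_contact, ts$points$cell_id)
  contact_at_mitosis <- function(cid) {
    # first post-mitotic frames of the daughter carry the mitotic contact
    w <- utils::head(contact_by_cell[[cid]], contact_window_frames)
    w <- w[w != "unknown"]
    if (!length(w)) return("unknown")
    w[length(w)]
  }
  fate <- fates_for(ts, li$cell_id, fate_mode)
  names(fate) <- li$cell_id
  kids <- split(li$cell_id[!is.na(li$parent_id)],
                factor(li$parent_id[!is.na(li$parent_id)], levels = mothers))
  da <- vapply(kids, `[`, character(1), 1)
  db <- vapply(kids, `[`, character(1), 2)
  mi <- match(mothers, li$cell_id)
  tibble::tibble(
    mother_id = mothers, daughter_a = unname(da), daughter_b = unname(db),
    t_div_h = li$end_t[mi] / 60,
    generation = unname(gen[mothers]),
    mother_fate = li$fate[mi],
    mode = classify_division(unname(fate[da]), unname(fate[db])),
    orientation = division_orientation(
      vapply(da, contact_at_mitosis, character(1)),
      vapply(db, contact_at_mitosis, character(1))))
}

#' Division-mode fractions over classified divisions
#'
#' @param divisions output of [division_records()].
#' @return tibble: mode, n, fraction (over classified divisions only),
#'   plus an `n_unclassified` attribute.
#' @export
division_mode_fractions <- function(divisions) {
  cl <- divisions$mode[divisions$mode != "unclassified"]
  out <- tibble::tibble(mode = c("ACD", "SCDd", "SCDp"))
  out$n <- vapply(out$mode, function(m) sum(cl == m), integer(1))
  out$fraction <- if (length(cl)) out$n / length(cl) else NA_real_
  attr(out, "n_unclassified") <- sum(divisions$mode == "unclassified")
  out
}

#' Differentiation index of a population
#'
#' Fraction of fate-known cells that are MYOG-positive among cells alive at
#' time `at_min` (cells lost to fusion or censored before that time are
#' excluded from the denominator).
#'
#' @param ts a [track_set].
#' @param at_min analysis time in minutes; defaults to the end of observation.
#' @param fate_mode fate-reading mode, see [fate_at_classification()].
#' @return list: index, n_positive, n_known, n_unknown, at_min. `index` is NA
#'   with `flag = "no_fate_known"` when no cell has a known fate.
#' @export
differentiation_index <- function(ts, at_min = NULL,
                                  fate_mode = c("endpoint", "live")) {
  fate_mode <- match.arg(fate_mode)
  li <- ts$lineage
  if (is.null(at_min)) at_min <- max(ts$points$t_min, li$end_t)
  # alive at t: born by t and not yet ended (a cell whose record stops
  # exactly at t without dividing counts; one that divided at or before t is
  # represented by its daughters; cells fused/lost before t are excluded)
  alive <- li$birth_t <= at_min + 1e-9 &
    (li$end_t > at_min + 1e-9 |
       (abs(li$end_t - at_min) <= 1e-9 & li$end_reason != "division"))
  ids <- li$cell_id[alive]
  fates <- fates_for(ts, ids, fate_mode)
  n_pos <- sum(fates == "positive"); n_known <- sum(fates != "unknown")
  out <- list(index = if (n_known > 0) n_pos / n_known else NA_real_,
              n_positive = n_pos, n_known = n_known,
              n_unknown = sum(fates == "unknown"), at_min = at_min)
  if (n_known == 0) attr(out, "flag") <- "no_fate_known"
  out
}

#' Proliferation index
#'
#' Ratio of live cell counts between the analysis endpoint and a reference
#' time, N(t_end) / N(t_ref); for fibre or graft experiments the reference is
#' the initial labelled-cell count.
#'
#' @param ts a [track_set].
#' @param t_ref_min,t_end_min reference and end times, minutes; defaults:
#'   observation start and end.
#' @return list: index, n_ref, n_end.
#' @export
proliferation_index <- function(ts, t_ref_min = NULL, t_end_min = NULL) {
  li <- ts$lineage
  if (is.null(t_ref_min)) t_ref_min <- min(li$birth_t)
  if (is.null(t_end_min)) t_end_min <- max(ts$points$t_min, li$end_t)
  alive_at <- function(t)
    sum(li$birth_t <= t + 1e-9 & li$end_t >= t - 1e-9 &
          !(li$end_reason == "division" & li$end_t <= t + 1e-9))
  n_ref <- alive_at(t_ref_min); n_end <- alive_at(t_end_min)
  if (n_ref == 0) stop("no cells alive at the reference time")
  list(index = n_end / n_ref, n_ref = n_ref, n_end = n_end)
}

#' MYOG onset kinetics and re-division of positive cells
#'
#' From live-reporter annotations: (i) the delay between a cell's birth
#' (mitosis) and its first positive observation, (ii) the fraction of
#' MYOG-positive cells that divide once more, and (iii) the fraction of
#' symmetric-differentiative divisions whose mother was MYOG-negative.
#'
#' @param ts a [track_set] with live-reporter annotations.
#' @return list: onset_delays_h (numeric), redivision (list fraction/n),
#'   scdd_from_negative_mother (list fraction/n).
#' @export
myog_onset_and_redivision <- function(ts) {
  li <- ts$lineage
  sp <- split(ts$points, ts$points$cell_id)
  onset <- vapply(li$cell_id, function(id) {
    p <- sp[[id]]
    i <- which(p$myog == "positive")
    if (!length(i)) return(NA_real_)
    (p$t_min[i[1]] - li$birth_t[li$cell_id == id]) / 60
  }, numeric(1))
  pos <- !is.na(onset)
  n_pos <- sum(pos)
  redivide <- li$end_reason[pos] == "division"
  div <- division_records(ts, fate_mode = "live")
  scdd <- div[div$mode == "SCDd" & div$mother_fate != "unknown", ]
  list(
    onset_delays_h = unname(onset[pos & !is.na(li$parent_id)]),
    redivision = list(
      fraction = if (n_pos > 0) sum(redivide) / n_pos else NA_real_,
      n_positive = n_pos, n_redivided = sum(redivide)),
    scdd_from_negative_mother = list(
      fraction = if (nrow(scdd) > 0)
        mean(scdd$mother_fate == "negative") else NA_real_,
      n_scdd = nrow(scdd)))
}

#' Shape metrics for in vitro morphology calls
#'
#' Circularity = 4 pi area / perimeter^2, clipped to \[0, 1\] (1 = round,
#' towards 0 = elongated/irregular); aspect ratio = max/min diameter; a cell
#' is called a myotube when its aspect ratio exceeds 2.
#'
#' @param area_um2,perimeter_um,max_diameter_um,min_diameter_um positive
#'   shape descriptors (vectorized).
#' @return tibble: circularity, aspect_ratio, is_myotube.
#' @export
shape_metrics <- function(area_um2, perimeter_um, max_diameter_um,
                          min_diameter_um) {
  if (any(c(area_um2, perimeter_um, max_diameter_um, min_diameter_um) <= 0))
    stop("shape descriptors must be strictly positive")
  if (any(max_diameter_um < min_diameter_um))
    stop("max_diameter must be >= min_diameter")
  circ <- pmin(1, pmax(0, 4 * pi * area_um2 / perimeter_um^2))
  ar <- max_diameter_um / min_diameter_um
  tibble::tibble(circularity = circ, aspect_ratio = ar, is_myotube = ar > 2)
}
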