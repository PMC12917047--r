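#' Pipeline configuration
#'
#' Exactly one input source: a preset name (simulated scene) or an input
#' directory holding `tracks.csv` (+ `landmarks.csv` for landmark
#' registration).
#'
#' @param preset a [simulation_preset], or "wt"/"mdx" for the named presets;
#'   NULL when `input_dir` is given.
#' @param input_dir directory with exported tracks/landmarks; NULL when
#'   simulating.
#' @param scene_kind "lineages" (default) or "tracks" for a division-free
#'   motility scene (simulated input only).
#' @param n_cells founders (lineage scenes) or cells (track scenes) to
#'   simulate.
#' @param registration "landmarks", "none".
#' @param fate_mode "endpoint" or "live".
#' @param threshold_mode "published_default" or "derived".
#' @param offsets_min sister co-migration offsets, minutes.
#' @param out_dir output directory.
#' @param seed integer seed for stochastic stages.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "wt", input_dir = NULL,
                            scene_kind = c("lineages", "tracks"),
                            n_cells = 100,
                            registration = c("landmarks", "none"),
                            fate_mode = c("endpoint", "live"),
                            threshold_mode = c("published_default", "derived"),
                            offsets_min = c(30, 40, 50, 60),
                            out_dir = tempfile("musctrack_run_"),
                            seed = 1) {
  if (!is.null(preset) && !is.null(input_dir))
    stop("exactly one input source: give either a preset or an input_dir")
  if (is.null(preset) && is.null(input_dir))
    stop("no input source: give a preset or an input_dir")
  if (!is.null(input_dir) && !file.exists(file.path(input_dir, "tracks.csv")))
    stop("input_dir has no tracks.csv: ", input_dir)
  if (is.character(preset)) preset <- muscle_preset(preset)
  structure(list(preset = preset, input_dir = input_dir,
                 scene_kind = match.arg(scene_kind),
                 n_cells = n_cells,
                 registration = match.arg(registration),
                 fate_mode = match.arg(fate_mode),
                 threshold_mode = match.arg(threshold_mode),
                 offsets_min = offsets_min, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> register and drift-correct -> motility metrics and
#' mobile/static stratification -> lineage, division modes and fate indexes
#' -> sister co-migration -> tidy CSV tables plus a YAML run manifest. Runs
#' with the same config and seed are bit-reproducible.
#'
#' @param config a [pipeline_config].
#' @return (invisibly) list with the tables: metrics, divisions, indexes,
#'   comigration, and the manifest; all are also written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  landmarks <- NULL
  if (!is.null(config$input_dir)) {
    inp <- stage("load", import_scene(config$input_dir))
    tracks <- inp$tracks
    landmarks <- inp$landmarks
    source_desc <- config$input_dir
  } else {
    scene <- stage("simulate", if (config$scene_kind == "lineages")
      simulate_lineages(config$preset, config$n_cells, seed = config$seed)
      else simulate_tracks(config$preset, config$n_cells, seed = config$seed))
    tracks <- scene$tracks_observed
    landmarks <- scene$landmarks
    source_desc <- paste0("simulated:", config$preset$name, ":",
                          config$scene_kind)
  }

  excluded <- character(0)
  flagged_frames <- integer(0)
  if (config$registration == "landmarks") {
    reg <- stage("register", register_landmarks(landmarks))
    corrected <- stage("correct", correct_tracks(tracks, reg$correction))
    flagged_frames <- reg$flagged_frames
    if (reg$motility_excluded) excluded <- unique(tracks$points$cell_id)
  } else {
    corrected <- tracks
  }

  threshold <- stage("threshold", if (config$threshold_mode == "derived")
    derive_threshold(corrected) else default_threshold())

  metrics <- stage("metrics", motility_summary(
    corrected, threshold = threshold, excluded_cells = excluded))
  divisions <- stage("lineage", division_records(
    corrected, fate_mode = config$fate_mode))
  modes <- division_mode_fractions(divisions)
  di <- stage("indexes", differentiation_index(
    corrected, fate_mode = config$fate_mode))
  pi_ <- stage("indexes", tryCatch(proliferation_index(corrected),
                                   error = function(e) list(
                                     index = NA_real_, n_ref = 0L,
                                     n_end = 0L)))
  dur <- stage("indexes", cell_cycle_durations(corrected))
  dur_means <- mean_cycle_durations(dur)
  indexes <- tibble::tibble(
    quantity = c("differentiation_index", "proliferation_index",
                 paste0("mode_fraction_", modes$mode),
                 paste0("mean_cycle_h_gen", dur_means$generation_group)),
    value = c(di$index, pi_$index, modes$fraction, dur_means$mean_h),
    n = c(di$n_known, pi_$n_end, modes$n, dur_means$n))
  comig <- stage("comigration", sister_comigration(
    corrected, offsets_min = config$offsets_min))

  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(divisions, file.path(config$out_dir, "divisions.csv"),
                   row.names = FALSE)
  utils::write.csv(indexes, file.path(config$out_dir, "indexes.csv"),
                   row.names = FALSE)
  utils::write.csv(comig, file.path(config$out_dir, "comigration.csv"),
                   row.names = FALSE)
  gap_segments <- sum(!duplicated(metrics$segment) &
                        grepl("/s[2-9]", metrics$segment))
  manifest <- list(
    package_version = as.character(utils::packageVersion("musctrack")),
    seed = config$seed,
    source = source_desc,
    registration = config$registration,
    fate_mode = config$fate_mode,
    threshold_um_min = threshold_value(threshold),
    threshold_provenance = if (inherits(threshold, "mobility_threshold"))
      threshold$provenance else "explicit",
    n_cells = length(unique(corrected$points$cell_id)),
    n_divisions = nrow(divisions),
    n_unclassified_divisions = attr(modes, "n_unclassified"),
    n_undetermined_orientation = sum(divisions$orientation == "undetermined"),
    n_excluded_cells = length(excluded),
    n_flagged_frames = length(flagged_frames),
    n_gap_split_segments = gap_segments)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(metrics = metrics, divisions = divisions, indexes = indexes,
                 comigration = comig, manifest = manifest,
                 tracks = corrected))
}

#' Hierarchical group summaries
#'
#' Averages bottom-up through the experimental hierarchy (cell -> unit ->
#' experiment -> group) so that units with many cells do not dominate the
#' group mean (unit-level pseudoreplication is not collapsed). Empty groups
#' are excluded with a warning.
#'
#' @param df tidy table with one row per cell(-segment).
#' @param value name of the numeric value column.
#' @param unit,experiment,group names of the nesting columns (innermost
#'   first); `experiment` and `group` may be NULL to stop the hierarchy
#'   early.
#' @return tibble per group: mean, sd (across the top-level units), n_units,
#'   n_cells.
#' @export
summarize_groups <- function(df, value, unit, experiment = NULL,
                             group = NULL) {
  for (col in c(value, unit, experiment, group))
    if (!col %in% names(df))
      stop("missing grouping column: ", col)
  df <- df[!is.na(df[[value]]), ]
  if (!nrow(df)) {
    warning("no non-missing values to summarise")
    return(tibble::tibble(group = character(), mean = numeric(),
                          sd = numeric(), n_units = integer(),
                          n_cells = integer()))
  }
  if (is.null(group)) { df$.group <- "all"; group <- ".group" }
  # cell -> unit means
  lvl <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(
      c(group, experiment, unit)))),
    .value = mean(.data[[value]]), .n_cells = dplyr::n(), .groups = "drop")
  n_units <- dplyr::summarise(
    dplyr::group_by(lvl, dplyr::across(dplyr::all_of(group))),
    n_units = dplyr::n(), n_cells = sum(.data$.n_cells), .groups = "drop")
  # unit -> experiment means (when an experiment level exists)
  if (!is.null(experiment))
    lvl <- dplyr::summarise(
      dplyr::group_by(lvl, dplyr::across(dplyr::all_of(c(group, experiment)))),
      .value = mean(.data$.value), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(lvl, dplyr::across(dplyr::all_of(group))),
    mean = mean(.data$.value), sd = stats::sd(.data$.value),
    .groups = "drop")
  tibble::as_tibble(dplyr::left_join(out, n_units, by = group))
}

#' @importFrom dplyr .data
NULL
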