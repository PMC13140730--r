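ANGLE_COLS <- c("clip_id", "frame", "side", "whisker_index", "angle",
                "nose_x", "nose_y", "centroid_x", "centroid_y")
META_COLS <- c("clip_id", "mouse_id", "genotype", "sex", "age_group",
               "line", "task", "session", "contact_frame", "px_per_mm")

#' Write clips as a tracker-style angle table
#'
#' One CSV row per tracked whisker per frame, with the nose and centroid
#' pixel positions repeated on each row of a frame. Column set:
#' `clip_id, frame, side, whisker_index, angle, nose_x, nose_y,
#' centroid_x, centroid_y`; frames 0-based, angles in degrees.
#'
#' @param clips a `whisker_cohort`, a list of [clip_data()], or one clip
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_angle_table <- function(clips, path) {
  if (inherits(clips, "whisker_cohort")) clips <- clips$clips
  if (inherits(clips, "clip_data")) clips <- list(clips)
  rows <- lapply(clips, function(cl) {
    a <- cl$angles
    data.table::data.table(
      clip_id = cl$clip_id, frame = a$frame, side = a$side,
      whisker_index = a$whisker_index, angle = a$angle,
      nose_x = cl$nose[a$frame + 1L, 1], nose_y = cl$nose[a$frame + 1L, 2],
      centroid_x = cl$centroid[a$frame + 1L, 1],
      centroid_y = cl$centroid[a$frame + 1L, 2])
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Read a tracker-style angle table
#'
#' Parses and validates the CSV dialect written by [write_angle_table()]:
#' side labels must be left/right, angles numeric and finite, no duplicate
#' (clip, frame, side, whisker) rows, and every frame present in the table
#' must carry 2-12 whisker rows (the tracker's detection band). Whiskers —
#' or whole sides — may be missing in individual frames.
#'
#' @param path CSV path
#' @param metadata optional clip metadata data.frame (see
#'   [read_clip_metadata()]); attaches contact frame, session, task and
#'   calibration to each clip
#' @param fps frames per second of the recordings (not stored in the table)
#' @param n_frames optional expected frame count per clip; defaults to the
#'   highest frame index seen in that clip + 1
#' @return named list of [clip_data()], keyed by clip_id
#' @export
read_angle_table <- function(path, metadata = NULL, fps = 500,
                             n_frames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "side"))
  if (!identical(names(dt), ANGLE_COLS))
    stop("unexpected angle-table header; need exactly: ",
         paste(ANGLE_COLS, collapse = ", "))
  if (nrow(dt) == 0L) return(structure(list(), names = character()))

  bad_side <- which(!dt$side %in% c("left", "right"))
  if (length(bad_side))
    stop("unknown side label '", dt$side[bad_side[1]], "' at data row ",
         bad_side[1])
  if (!is.numeric(dt$angle))
    stop("non-numeric angle at data row ",
         which(is.na(suppressWarnings(as.numeric(dt$angle))))[1])
  bad_ang <- which(!is.finite(dt$angle))
  if (length(bad_ang))
    stop("non-finite angle at data row ", bad_ang[1])
  dup <- which(duplicated(dt[, c("clip_id", "frame", "side",
                                 "whisker_index")]))
  if (length(dup))
    stop("duplicate (clip, frame, side, whisker) at data row ", dup[1])
  cnt <- dt[, .N, by = c("clip_id", "frame")]
  bad <- cnt[cnt$N < 2L | cnt$N > 12L, ]
  if (nrow(bad))
    stop("frame ", bad$frame[1], " of clip ", bad$clip_id[1], " has ",
         bad$N[1], " whisker rows; the tracker band is 2-12 per frame")

  md <- if (!is.null(metadata)) {
    metadata[match(unique(dt$clip_id), metadata$clip_id), , drop = FALSE]
  }
  out <- lapply(split(dt, by = "clip_id", sorted = FALSE), function(g) {
    id <- g$clip_id[1]
    nf <- n_frames %||% (max(g$frame) + 1L)
    nose <- centroid <- matrix(NA_real_, nf, 2)
    i <- g$frame + 1L
    nose[i, 1] <- g$nose_x; nose[i, 2] <- g$nose_y
    centroid[i, 1] <- g$centroid_x; centroid[i, 2] <- g$centroid_y
    m <- if (!is.null(md)) md[md$clip_id == id, , drop = FALSE]
    has_meta <- !is.null(m) && nrow(m) == 1L
    cf <- if (has_meta && !is.na(m$contact_frame)) m$contact_frame
    clip_data(clip_id = id, fps = fps,
              angles = as.data.frame(g[, c("frame", "side", "whisker_index",
                                           "angle")]),
              nose = nose, centroid = centroid, contact_frame = cf,
              session = if (has_meta) m$session else NA_character_,
              task = if (has_meta) m$task else NA_character_,
              px_per_mm = if (has_meta) m$px_per_mm else NA_real_)
  })
  names(out) <- vapply(out, `[[`, "", "clip_id")
  out
}

#' Write / read the clip metadata table
#'
#' Columns: `clip_id, mouse_id, genotype, sex, age_group, line, task,
#' session, contact_frame, px_per_mm`; `contact_frame` is empty except for
#' object-task clips.
#'
#' @param metadata data.frame (e.g. `cohort$metadata`)
#' @param path CSV path
#' @return `path` invisibly, or the metadata data.frame
#' @export
write_clip_metadata <- function(metadata, path) {
  stopifnot(all(META_COLS %in% names(metadata)))
  if (anyDuplicated(metadata$clip_id))
    stop("duplicate clip_id in metadata")
  if (any(!is.na(metadata$contact_frame) & metadata$task != "object"))
    stop("contact_frame present for a non-object task clip")
  data.table::fwrite(metadata[, META_COLS], path)
  invisible(path)
}

#' @rdname write_clip_metadata
#' @export
read_clip_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- as.data.frame(data.table::fread(path, na.strings = c("NA", "")))
  if (!identical(names(md), META_COLS))
    stop("unexpected metadata header; need exactly: ",
         paste(META_COLS, collapse = ", "))
  md
}

#' Write the per-clip metrics table
#'
#' Tidy CSV, one row per clip: identifiers and design columns, the seven
#' metrics, and logical QC flag columns. Units are documented in `#` header
#' comments (angles in degrees, speeds in degrees/s, locomotion in mm/s).
#' Missing metrics are written as empty cells, never as zero.
#'
#' @param metrics data.frame with one row per clip (must contain `clip_id`)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_metrics_table <- function(metrics, path) {
  stopifnot(is.data.frame(metrics), "clip_id" %in% names(metrics))
  if (anyDuplicated(metrics$clip_id))
    stop("duplicate clip_id: ",
         metrics$clip_id[duplicated(metrics$clip_id)][1])
  writeLines(c(
    "# whiskerkin metrics table v1",
    "# units: angular metrics in degrees; protraction/retraction in degrees/s; locomotion_speed in mm/s"),
    path)
  suppressWarnings(
    data.table::fwrite(metrics, path, append = TRUE, col.names = TRUE,
                       na = ""))
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "#")))
  as.data.frame(data.table::fread(path, skip = skip, na.strings = ""))
}

#' Load and validate a YAML run configuration
#'
#' Recognised top-level sections: `seed`, `simulation`, `arena`, `qc`,
#' `cohort`, `analysis`. Absent keys take the documented defaults; unknown
#' keys at any level are an error (anti-typo contract). The fully resolved
#' configuration is echoed via `message()` unless `quiet = TRUE`.
#'
#' @param path YAML file path; `NULL` gives the all-defaults configuration
#' @param quiet suppress the resolved-config echo
#' @return a `whisker_config` list with elements `seed`, `simulation`,
#'   `arena`, `qc`, `cohort`, `analysis`
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "simulation", "arena", "qc", "cohort", "analysis")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))

  build <- function(section, ctor, nested = character()) {
    given <- raw[[section]] %||% list()
    bad <- setdiff(names(given), names(formals(ctor)))
    if (length(bad))
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    for (k in setdiff(names(given), nested))
      if (is.list(given[[k]])) given[[k]] <- unlist(given[[k]])
    do.call(ctor, given)
  }

  sim <- build("simulation", simulation_params,
               nested = c("contact", "habituation"))
  if (!is.null(raw$simulation$contact)) {
    ck <- raw$simulation$contact
    bad <- setdiff(names(ck), names(formals(contact_modulation)))
    if (length(bad))
      stop("unknown key(s) in 'simulation$contact': ",
           paste(bad, collapse = ", "))
    sim$contact <- do.call(contact_modulation, ck)
  }
  if (!is.null(raw$simulation$habituation)) {
    hb <- raw$simulation$habituation
    bad <- setdiff(names(hb), names(formals(habituation_deltas)))
    if (length(bad))
      stop("unknown key(s) in 'simulation$habituation': ",
           paste(bad, collapse = ", "))
    hb[setdiff(names(hb), "reeler_extra")] <-
      lapply(hb[setdiff(names(hb), "reeler_extra")], unlist)
    if (!is.null(hb$reeler_extra))
      hb$reeler_extra <- lapply(hb$reeler_extra, unlist)
    sim$habituation <- do.call(habituation_deltas, hb)
  }

  ana_defaults <- list(posthoc_adjust = "tukey", manova_aggregate = "clip",
                       responses = metric_names())
  ana <- raw$analysis %||% list()
  bad <- setdiff(names(ana), names(ana_defaults))
  if (length(bad))
    stop("unknown key(s) in 'analysis': ", paste(bad, collapse = ", "))
  ana <- modifyList(ana_defaults, ana)

  cfg <- structure(list(seed = raw$seed %||% 1L,
                        simulation = sim,
                        arena = build("arena", arena_spec),
                        qc = build("qc", qc_thresholds),
                        cohort = build("cohort", cohort_spec),
                        analysis = ana),
                   class = "whisker_config")
  if (!quiet)
    message("resolved configuration:\n",
            yaml::as.yaml(config_as_list(cfg)))
  cfg
}

config_as_list <- function(cfg) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v)) strip(v) else v)
  }
  strip(cfg)
}

#' Print the CSV and config schemas
#'
#' Returns (and prints) the column sets of the angle, metadata and metrics
#' tables, and the recognised configuration keys.
#'
#' @return character vector of schema lines, invisibly
#' @export
io_schemas <- function() {
  txt <- c(
    "angle table (CSV, one row per tracked whisker per frame):",
    paste(" ", paste(ANGLE_COLS, collapse = ", ")),
    "  frame: 0-based; time of frame k = k/fps s; angle: degrees;",
    "  nose/centroid: pixels",
    "clip metadata (CSV, one row per clip):",
    paste(" ", paste(META_COLS, collapse = ", ")),
    "metrics table (CSV, one row per clip, '#' comment header):",
    paste(" ", paste(c("clip_id", "...design columns...", metric_names(),
                       "flag_*"), collapse = ", ")),
    "config (YAML): sections seed, simulation, arena, qc, cohort, analysis;",
    "  keys follow the arguments of simulation_params(), arena_spec(),",
    "  qc_thresholds(), cohort_spec()")
  cat(txt, sep = "\n")
  invisible(txt)
}
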