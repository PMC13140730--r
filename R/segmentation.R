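#' Clip inclusion check
#'
#' Applies the automatable clip inclusion criteria: both whisker sides must
#' be visible (at least one tracked whisker on each side) in at least
#' `min_fraction_frames_both_sides` of frames, and the total tracked whisker
#' count in every frame must stay within the tracker's 2-12 band. The
#' head-level criterion requires manual 3D review and is honoured only as a
#' pass-through flag when supplied in metadata.
#'
#' @param clip a [clip_data()] object
#' @param thresholds a [qc_thresholds()] object
#' @return list with `pass` (logical) and `reasons` (character, empty when
#'   passing), plus the measured `fraction_both_sides`
#' @export
qc_clip <- function(clip, thresholds = qc_thresholds()) {
  stopifnot(inherits(clip, "clip_data"), inherits(thresholds, "qc_thresholds"))
  reasons <- character()
  a <- clip$angles
  has_l <- tabulate(a$frame[a$side == "left"] + 1L, clip$n_frames) > 0L
  has_r <- tabulate(a$frame[a$side == "right"] + 1L, clip$n_frames) > 0L
  frac <- mean(has_l & has_r)
  if (frac < thresholds$min_fraction_frames_both_sides)
    reasons <- c(reasons, sprintf(
      "both sides visible in only %.1f%% of frames (minimum %.1f%%)",
      100 * frac, 100 * thresholds$min_fraction_frames_both_sides))
  counts <- tabulate(a$frame + 1L, clip$n_frames)
  if (any(counts < thresholds$min_whiskers_per_frame) ||
      any(counts > thresholds$max_whiskers_per_frame))
    reasons <- c(reasons, sprintf(
      "whisker count per frame outside %d-%d band (observed %d-%d)",
      thresholds$min_whiskers_per_frame, thresholds$max_whiskers_per_frame,
      min(counts), max(counts)))
  list(pass = length(reasons) == 0L, reasons = reasons,
       fraction_both_sides = frac)
}

#' Section an object clip into pre-contact and during-contact frames
#'
#' PC is frames `[0, contact_frame)`; DC is `[contact_frame, contact_end)`
#' (or the clip end). Both segments must strictly exceed
#' `min_segment_duration` seconds — at 500 fps and the 0.2 s default this
#' means at least 101 frames each — otherwise the clip is rejected with a
#' reason.
#'
#' @param clip a [clip_data()] object with a `contact_frame`
#' @param thresholds a [qc_thresholds()] object
#' @return list with `accepted`; when accepted, 0-based frame vectors `pc`
#'   and `dc`; otherwise a `reason`
#' @export
split_pc_dc <- function(clip, thresholds = qc_thresholds()) {
  stopifnot(inherits(clip, "clip_data"))
  if (is.null(clip$contact_frame))
    stop("clip has no contact_frame; only object clips can be sectioned")
  cf <- clip$contact_frame
  dc_end <- clip$contact_end %||% clip$n_frames
  pc <- seq.int(0L, cf - 1L)
  dc <- seq.int(cf, dc_end - 1L)
  min_dur <- thresholds$min_segment_duration
  if (!(length(pc) / clip$fps > min_dur))
    return(list(accepted = FALSE, reason = sprintf(
      "pre-contact segment %.3f s not > %.3f s", length(pc) / clip$fps,
      min_dur)))
  if (!(length(dc) / clip$fps > min_dur))
    return(list(accepted = FALSE, reason = sprintf(
      "during-contact segment %.3f s not > %.3f s", length(dc) / clip$fps,
      min_dur)))
  list(accepted = TRUE, pc = pc, dc = dc)
}

#' Pre-contact minus during-contact metric differences
#'
#' Computes [clip_metrics()] separately on the PC and DC segments and their
#' componentwise difference `pc - dc`, the convention under which a metric
#' that is higher before contact gives a positive delta. Missing metrics
#' propagate to the delta.
#'
#' @param clip a [clip_data()] object with a contact annotation
#' @param thresholds a [qc_thresholds()] object
#' @return a `pcdc_metrics` list with elements `pc`, `dc` (both
#'   `whisker_metrics`) and `delta` (named numeric), or a rejection with
#'   `accepted = FALSE`
#' @export
pc_dc_delta <- function(clip, thresholds = qc_thresholds()) {
  sp <- split_pc_dc(clip, thresholds)
  if (!sp$accepted) return(c(sp, list(pc = NULL, dc = NULL, delta = NULL)))
  pc <- clip_metrics(clip, sp$pc)
  dc <- clip_metrics(clip, sp$dc)
  delta <- unlist(pc[metric_names()]) - unlist(dc[metric_names()])
  structure(list(accepted = TRUE, pc = pc, dc = dc, delta = delta),
            class = "pcdc_metrics")
}

#' Minimum nose-to-object distance
#'
#' Shortest distance over frames from the nose tip to the object surface
#' (Euclidean distance to the object centre minus the object radius, floored
#' at zero), in millimetres.
#'
#' @param clip a [clip_data()] object with a nose track and calibration
#' @param arena an [arena_spec()]
#' @return distance in mm
#' @export
min_nose_object_distance <- function(clip, arena) {
  stopifnot(inherits(clip, "clip_data"), inherits(arena, "arena_spec"))
  if (is.na(clip$px_per_mm) || clip$px_per_mm <= 0)
    stop("missing px_per_mm calibration")
  nose_mm <- clip$nose / clip$px_per_mm
  ctr <- arena$object_center * 10
  d <- sqrt((nose_mm[, 1] - ctr[1])^2 + (nose_mm[, 2] - ctr[2])^2) -
    arena$object_radius * 10
  max(min(d), 0)
}

#' Arena zone occupancy
#'
#' Classifies every frame of a centroid track into mutually exclusive zones
#' (around the object, if present, takes precedence; then within
#' `wall_margin` of any wall; else middle) and returns the percentage of
#' frames in each. Frames outside the arena bounds raise a warning and are
#' clamped to the nearest wall.
#'
#' @param centroid n x 2 matrix of pixel positions
#' @param arena an [arena_spec()]
#' @param px_per_mm calibration; defaults to the arena's
#' @param include_object whether an object is present this session
#' @return a `zone_occupancy` list with `pct_middle`, `pct_edge`,
#'   `pct_object` (percentages summing to 100)
#' @export
zone_occupancy <- function(centroid, arena, px_per_mm = arena$px_per_mm,
                           include_object = TRUE) {
  stopifnot(inherits(arena, "arena_spec"), px_per_mm > 0)
  pos_cm <- as.matrix(centroid) / px_per_mm / 10
  w <- arena$width; l <- arena$length
  if (any(pos_cm[, 1] < 0 | pos_cm[, 1] > w |
          pos_cm[, 2] < 0 | pos_cm[, 2] > l)) {
    warning("centroid track leaves arena bounds; clamping to the walls")
    pos_cm[, 1] <- pmin(pmax(pos_cm[, 1], 0), w)
    pos_cm[, 2] <- pmin(pmax(pos_cm[, 2], 0), l)
  }
  in_object <- if (include_object) {
    sqrt((pos_cm[, 1] - arena$object_center[1])^2 +
         (pos_cm[, 2] - arena$object_center[2])^2) <= arena$object_zone_radius
  } else rep(FALSE, nrow(pos_cm))
  near_wall <- pos_cm[, 1] <= arena$wall_margin |
    pos_cm[, 1] >= w - arena$wall_margin |
    pos_cm[, 2] <= arena$wall_margin |
    pos_cm[, 2] >= l - arena$wall_margin
  in_edge <- near_wall & !in_object
  n <- nrow(pos_cm)
  structure(list(pct_object = 100 * sum(in_object) / n,
                 pct_edge = 100 * sum(in_edge) / n,
                 pct_middle = 100 * sum(!in_object & !in_edge) / n),
            class = "zone_occupancy")
}
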