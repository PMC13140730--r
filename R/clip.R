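#' Per-clip tracked data
#'
#' The atomic unit of analysis: per-frame, per-whisker angles for both sides
#' of the face, plus nose and body-centroid pixel tracks and an optional
#' contact annotation. Frames are 0-based throughout the package; the time of
#' frame `k` is `k / fps` seconds. Angles are in degrees, higher = more
#' protracted (forward).
#'
#' @param clip_id character clip identifier
#' @param fps frames per second
#' @param angles data.frame with columns `frame` (0-based integer), `side`
#'   ("left"/"right"), `whisker_index` (integer), `angle` (degrees); whiskers
#'   may be missing in individual frames
#' @param nose,centroid numeric matrices, one row per frame, columns x and y
#'   in pixels
#' @param contact_frame optional 0-based frame of first whisker-object touch
#' @param contact_end optional 0-based frame at which contact ends (exclusive)
#' @param session session label (e.g. "OF", "H1", "H5")
#' @param task task label ("object", "open_field" or "habituation")
#' @param px_per_mm calibration scalar, pixels per millimetre
#' @return a `clip_data` object
#' @export
clip_data <- function(clip_id, fps, angles, nose, centroid,
                      contact_frame = NULL, contact_end = NULL,
                      session = NA_character_, task = NA_character_,
                      px_per_mm = NA_real_) {
  nose <- as.matrix(nose); centroid <- as.matrix(centroid)
  stopifnot(is.character(clip_id), length(clip_id) == 1L, fps > 0,
            is.data.frame(angles),
            all(c("frame", "side", "whisker_index", "angle") %in%
                  names(angles)),
            ncol(nose) == 2L, ncol(centroid) == 2L,
            nrow(nose) == nrow(centroid))
  n_frames <- nrow(nose)
  if (n_frames < 1L) stop("clip must contain at least one frame")
  if (nrow(angles) == 0L) stop("clip has zero tracked whiskers")
  if (!all(angles$side %in% c("left", "right")))
    stop("unknown side label: ",
         paste(unique(setdiff(angles$side, c("left", "right"))),
               collapse = ", "))
  if (!all(is.finite(angles$angle))) stop("non-finite whisker angle")
  if (any(angles$frame < 0L) || any(angles$frame >= n_frames))
    stop("angle rows reference frames outside the clip")
  for (s in c("left", "right"))
    if (!any(angles$side == s))
      stop("no tracked whiskers on the ", s, " side")
  if (!is.null(contact_frame)) {
    stopifnot(contact_frame >= 0, contact_frame < n_frames)
    if (!is.null(contact_end))
      stopifnot(contact_end > contact_frame, contact_end <= n_frames)
  } else if (!is.null(contact_end)) {
    stop("contact_end given without contact_frame")
  }
  structure(list(clip_id = clip_id, fps = fps,
                 n_frames = as.integer(n_frames),
                 angles = angles[, c("frame", "side", "whisker_index",
                                     "angle")],
                 nose = unname(nose), centroid = unname(centroid),
                 contact_frame = if (is.null(contact_frame)) NULL
                                 else as.integer(contact_frame),
                 contact_end = if (is.null(contact_end)) NULL
                               else as.integer(contact_end),
                 session = session, task = task, px_per_mm = px_per_mm),
            class = "clip_data")
}

#' @export
print.clip_data <- function(x, ...) {
  cat("<clip_data> ", x$clip_id, ": ", x$n_frames, " frames @ ", x$fps,
      " fps (", signif(x$n_frames / x$fps, 3), " s), ",
      nrow(x$angles), " whisker samples", sep = "")
  if (!is.null(x$contact_frame))
    cat(", contact at frame ", x$contact_frame, sep = "")
  cat("\n  task=", x$task, " session=", x$session,
      " px_per_mm=", x$px_per_mm, "\n", sep = "")
  invisible(x)
}

# frames x whiskers matrix of angles for one side; NA where untracked.
# Column order is by whisker_index, but every metric is invariant to it.
side_angle_matrix <- function(clip, side, frames = NULL) {
  a <- clip$angles[clip$angles$side == side, ]
  if (!is.null(frames)) a <- a[a$frame %in% frames, ]
  idx <- sort(unique(a$whisker_index))
  rows <- if (is.null(frames)) 0:(clip$n_frames - 1L) else sort(frames)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(idx),
              dimnames = list(NULL, idx))
  m[cbind(match(a$frame, rows), match(a$whisker_index, idx))] <- a$angle
  attr(m, "frames") <- rows
  m
}
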