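#' Per-frame side-mean whisker angles
#'
#' For each frame and side, the arithmetic mean of that side's tracked
#' whisker angles. Frames with no tracked whisker on a side are `NA` for
#' that side; the other side is unaffected.
#'
#' @param clip a [clip_data()] object
#' @param frames optional 0-based frame indices to restrict to
#' @return data.frame with columns `frame`, `left`, `right` (degrees)
#' @export
frame_mean_angles <- function(clip, frames = NULL) {
  stopifnot(inherits(clip, "clip_data"))
  l <- side_angle_matrix(clip, "left", frames)
  r <- side_angle_matrix(clip, "right", frames)
  data.frame(frame = attr(l, "frames"),
             left = rowMeans(l, na.rm = TRUE),
             right = rowMeans(r, na.rm = TRUE))
}

#' Angular velocity of a whisker-angle series
#'
#' First difference scaled to degrees per second. Positive velocity is
#' protraction (forward movement, increasing angle); negative is retraction.
#'
#' @param series per-frame angles, degrees
#' @param fps frames per second
#' @return numeric vector of length `length(series) - 1`, degrees/s
#' @export
angular_velocity <- function(series, fps) {
  stopifnot(fps > 0)
  if (length(series) < 2L) stop("need at least 2 frames for a velocity")
  diff(series) * fps
}

#' Per-clip whisker kinematic metrics
#'
#' Computes the seven per-clip outcome variables from the tracked angles:
#' \describe{
#'   \item{mean_angular_position}{mean over frames of the side-mean angle,
#'     averaged over the two sides (degrees).}
#'   \item{amplitude}{`2*sqrt(2)` times the SD of the per-frame side-mean
#'     angles pooled from both sides (degrees); for a pure sinusoid of
#'     peak-to-peak `A` this returns exactly `A`. Amplitude is the one
#'     metric not averaged side-by-side.}
#'   \item{asymmetry}{absolute difference between the left and right
#'     time-mean side-mean angles (degrees).}
#'   \item{spread}{per-frame SD of the individual whisker angles within a
#'     side (needs >= 2 whiskers in the frame), averaged over frames and
#'     then sides (degrees).}
#'   \item{protraction_speed}{mean of the positive side-mean angular
#'     velocities, per side then averaged over sides (degrees/s).}
#'   \item{retraction_speed}{mean magnitude of the negative velocities,
#'     same averaging (degrees/s, reported positive).}
#'   \item{locomotion_speed}{mean centroid step length scaled to mm/s.}
#' }
#' A side with no positive (or no negative) velocities yields a missing
#' speed and sets the corresponding flag. All SDs use the n-1 denominator.
#'
#' @param clip a [clip_data()] object
#' @param frames optional 0-based frame indices (e.g. a PC or DC segment)
#' @return a `whisker_metrics` list with the seven metrics and QC `flags`
#' @export
clip_metrics <- function(clip, frames = NULL) {
  stopifnot(inherits(clip, "clip_data"))
  if (!is.null(frames)) {
    if (any(frames < 0L) || any(frames >= clip$n_frames))
      stop("frame range outside clip")
    frames <- sort(unique(as.integer(frames)))
  }
  n_sel <- if (is.null(frames)) clip$n_frames else length(frames)
  if (n_sel < 2L) stop("need at least 2 frames")

  lmat <- side_angle_matrix(clip, "left", frames)
  rmat <- side_angle_matrix(clip, "right", frames)
  lmean <- rowMeans(lmat, na.rm = TRUE)
  rmean <- rowMeans(rmat, na.rm = TRUE)
  lmean[is.nan(lmean)] <- NA_real_
  rmean[is.nan(rmean)] <- NA_real_

  mean_pos <- mean(c(mean(lmean, na.rm = TRUE), mean(rmean, na.rm = TRUE)))
  amplitude <- 2 * sqrt(2) * sd(c(lmean, rmean), na.rm = TRUE)
  asymmetry <- abs(mean(lmean, na.rm = TRUE) - mean(rmean, na.rm = TRUE))

  frame_sd <- function(m) {
    k <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    s <- sqrt(rowSums((m - mu)^2, na.rm = TRUE) / (k - 1L))
    s[k < 2L] <- NA_real_
    s
  }
  spread <- mean(c(mean(frame_sd(lmat), na.rm = TRUE),
                   mean(frame_sd(rmat), na.rm = TRUE)), na.rm = TRUE)
  if (is.nan(spread)) spread <- NA_real_

  side_speeds <- function(sm) {
    v <- angular_velocity(sm, clip$fps)
    v <- v[!is.na(v)]
    c(pro = if (any(v > 0)) mean(v[v > 0]) else NA_real_,
      ret = if (any(v < 0)) mean(-v[v < 0]) else NA_real_)
  }
  sl <- side_speeds(lmean); sr <- side_speeds(rmean)
  pro <- mean(c(sl["pro"], sr["pro"]), na.rm = TRUE)
  ret <- mean(c(sl["ret"], sr["ret"]), na.rm = TRUE)
  if (is.nan(pro)) pro <- NA_real_
  if (is.nan(ret)) ret <- NA_real_

  loco <- if (is.na(clip$px_per_mm)) NA_real_ else {
    idx <- if (is.null(frames)) seq_len(clip$n_frames) else frames + 1L
    locomotion_speed(clip$centroid[idx, , drop = FALSE],
                     clip$px_per_mm, clip$fps)
  }

  counts <- tabulate(clip$angles$frame + 1L, nbins = clip$n_frames)
  sel <- if (is.null(frames)) seq_len(clip$n_frames) else frames + 1L
  structure(list(
    mean_angular_position = mean_pos, amplitude = amplitude,
    asymmetry = asymmetry, spread = spread,
    protraction_speed = pro, retraction_speed = ret,
    locomotion_speed = loco,
    flags = list(missing_protraction = is.na(pro),
                 missing_retraction = is.na(ret),
                 low_whisker_count = any(counts[sel] < 2L))),
    class = "whisker_metrics")
}

#' @export
print.whisker_metrics <- function(x, ...) {
  v <- unlist(x[metric_names()])
  cat("<whisker_metrics>\n")
  print(round(v, 3))
  fl <- unlist(x$flags)
  if (any(fl)) cat("flags:", paste(names(fl)[fl], collapse = ", "), "\n")
  invisible(x)
}

metric_names <- function() {
  c("mean_angular_position", "amplitude", "asymmetry", "spread",
    "protraction_speed", "retraction_speed", "locomotion_speed")
}

#' @export
as.data.frame.whisker_metrics <- function(x, ...) {
  d <- as.data.frame(x[metric_names()])
  for (f in names(x$flags)) d[[paste0("flag_", f)]] <- x$flags[[f]]
  d
}

#' Mean locomotion speed from a centroid track
#'
#' Mean per-frame Euclidean step length, scaled by the frame rate and the
#' pixel calibration.
#'
#' @param centroid n x 2 matrix of pixel positions
#' @param px_per_mm calibration, pixels per millimetre (> 0)
#' @param fps frames per second
#' @return speed in mm/s
#' @export
locomotion_speed <- function(centroid, px_per_mm, fps) {
  centroid <- as.matrix(centroid)
  if (!is.numeric(px_per_mm) || is.na(px_per_mm) || px_per_mm <= 0)
    stop("px_per_mm calibration must be positive")
  stopifnot(fps > 0, ncol(centroid) == 2L)
  if (nrow(centroid) < 2L) stop("need at least 2 frames")
  steps <- sqrt(diff(centroid[, 1])^2 + diff(centroid[, 2])^2)
  mean(steps) * fps / px_per_mm
}

#' Dominant whisking frequency of an angle series
#'
#' Removes the mean, takes the periodogram, and returns the frequency of the
#' dominant peak, refined by quadratic interpolation of log-power around the
#' peak bin (sub-bin resolution for near-sinusoidal traces). Peak prominence
#' is the ratio of peak power to the median power across bins; series whose
#' prominence falls below `min_prominence` (e.g. white noise) are flagged
#' unreliable, and a flat series returns a missing frequency.
#'
#' @param series per-frame angles, degrees
#' @param fps frames per second
#' @param min_prominence reliability threshold on peak/median power
#' @return list with `frequency` (Hz, `NA` if flat), `prominence`, and
#'   `reliable`
#' @export
estimate_whisk_frequency <- function(series, fps, min_prominence = 15) {
  series <- series[!is.na(series)]
  n <- length(series)
  if (n < fps) stop("need at least 1 s of data")
  x <- series - mean(series)
  if (all(abs(x) < 1e-12))
    return(list(frequency = NA_real_, prominence = NA_real_,
                reliable = FALSE))
  pw <- Mod(fft(x))^2
  half <- 2:floor(n / 2)        # drop DC and the redundant half
  freqs <- (half - 1) * fps / n
  k <- which.max(pw[half])
  prominence <- pw[half][k] / median(pw[half])
  f_hat <- freqs[k]
  if (k > 1L && k < length(half)) {
    lp <- log(pw[half][(k - 1):(k + 1)] + .Machine$double.xmin)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / denom
      f_hat <- f_hat + max(-0.5, min(0.5, delta)) * fps / n
    }
  }
  list(frequency = f_hat, prominence = prominence,
       reliable = prominence >= min_prominence)
}
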