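# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# A clip built directly from closed-form side traces, bypassing the
# simulator, so kinematics tests are independent of the generative model.
# left_fun / right_fun map a time vector (s) to the side-mean angle; each
# whisker on a side is that trace plus its fixed offset.
make_trace_clip <- function(left_fun, right_fun = left_fun,
                            n_frames = 800, fps = 500,
                            offsets_left = 0, offsets_right = 0,
                            centroid = NULL, nose = NULL,
                            contact_frame = NULL, px_per_mm = 2,
                            clip_id = "fix") {
  t <- (0:(n_frames - 1)) / fps
  mk <- function(fun, offsets, side, base_idx) {
    base <- fun(t)
    do.call(rbind, lapply(seq_along(offsets), function(w)
      data.frame(frame = 0:(n_frames - 1), side = side,
                 whisker_index = base_idx + w,
                 angle = base + offsets[w])))
  }
  angles <- rbind(mk(left_fun, offsets_left, "left", 0L),
                  mk(right_fun, offsets_right, "right", 100L))
  if (is.null(centroid)) centroid <- matrix(100, n_frames, 2)
  if (is.null(nose)) nose <- centroid
  clip_data(clip_id = clip_id, fps = fps, angles = angles,
            nose = nose, centroid = centroid,
            contact_frame = contact_frame, px_per_mm = px_per_mm)
}

# pure-tone clip: peak-to-peak A around setpoint S, frequency f Hz
make_sine_clip <- function(A = 40, S = 100, f = 18, delta = 0, ...,
                           n_frames = 800, fps = 500) {
  make_trace_clip(
    left_fun = function(t) S + delta / 2 + (A / 2) * sin(2 * pi * f * t),
    right_fun = function(t) S - delta / 2 + (A / 2) * sin(2 * pi * f * t),
    n_frames = n_frames, fps = fps, ...)
}

default_mouse <- function(id = "m1", intercept = 0)
  list(mouse_id = id, genotype = "wildtype", random_intercept = intercept)

# independent spectral oracle: raw periodogram argmax (no interpolation)
fft_peak_hz <- function(x, fps) {
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(fft(x))^2
  half <- 2:floor(n / 2)
  ((half - 1) * fps / n)[which.max(pw[half])]
}
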