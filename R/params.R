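#' Contact modulation multipliers
#'
#' Parameter switch applied to the whisking generator from the contact frame
#' onwards, reproducing the stereotyped object-contact response: amplitude and
#' asymmetry go up while spread and whisk frequency (hence angular speeds) go
#' down. Because the mean absolute angular velocity of a sinusoid is `2*A*f`,
#' speeds decrease only when `k_amplitude * k_frequency < 1`; the defaults
#' (1.3 * 0.6 = 0.78) satisfy this.
#'
#' @param k_amplitude multiplier (>= 1) on peak-to-peak amplitude during contact
#' @param d_asymmetry additive increase (degrees, >= 0) on the left-right
#'   setpoint offset during contact
#' @param k_spread multiplier in (0, 1] on the per-whisker offset SD
#' @param k_frequency multiplier in (0, 1] on whisk frequency
#' @param k_locomotion multiplier in (0, 1] on locomotion speed
#' @return a `contact_modulation` list
#' @export
contact_modulation <- function(k_amplitude = 1.3, d_asymmetry = 4,
                               k_spread = 0.5, k_frequency = 0.6,
                               k_locomotion = 0.5) {
  stopifnot(k_amplitude >= 1, d_asymmetry >= 0,
            k_spread > 0, k_spread <= 1,
            k_frequency > 0, k_frequency <= 1,
            k_locomotion > 0, k_locomotion <= 1)
  structure(list(k_amplitude = k_amplitude, d_asymmetry = d_asymmetry,
                 k_spread = k_spread, k_frequency = k_frequency,
                 k_locomotion = k_locomotion),
            class = "contact_modulation")
}

#' Habituation session shifts
#'
#' Additive session-level shifts, relative to the first open-field session
#' (OF), applied by the cohort generator. Values are per-session vectors named
#' by session label; `reeler_extra` holds additional shifts applied to reeler
#' animals only (the genotype-by-habituation interaction). Defaults give the
#' qualitative habituation signature: whiskers held further back (setpoint
#' down), bunched (spread down), and slower locomotion, with the reeler
#' decrement continuing into the fifth session.
#'
#' @param setpoint degrees, named by session
#' @param spread degrees (shift on the per-whisker offset SD), named by session
#' @param locomotion mm/s, named by session
#' @param reeler_extra list with the same three elements, added for reeler mice
#' @return a `habituation_deltas` list
#' @export
habituation_deltas <- function(setpoint = c(H1 = -1.5, H5 = -2.0),
                               spread = c(H1 = -1.0, H5 = -1.5),
                               locomotion = c(H1 = -30, H5 = -50),
                               reeler_extra = list(setpoint = c(H5 = -1.0),
                                                   spread = c(H5 = -0.5),
                                                   locomotion = c(H5 = -10))) {
  structure(list(setpoint = setpoint, spread = spread,
                 locomotion = locomotion, reeler_extra = reeler_extra),
            class = "habituation_deltas")
}

#' Whisking simulation parameters
#'
#' Generative parameters for the phase-jittered sinusoid model of whisking.
#' Each per-clip metric maps to one closed-form parameter: mean angular
#' position to `setpoint`, amplitude to `amplitude` (peak-to-peak), asymmetry
#' to `asymmetry_offset`, spread to `whisker_spread`, and the angular speeds to
#' `2 * amplitude * frequency`.
#'
#' @param fps frames per second of the simulated high-speed video
#' @param clip_duration clip length in seconds
#' @param whisk_frequency Hz; a scalar fixes the frequency, a length-2 vector
#'   gives the range of a per-clip uniform draw (default the murine whisking
#'   band, 12-25 Hz)
#' @param setpoint mean whisker angle in degrees (higher = more protracted)
#' @param amplitude peak-to-peak whisk excursion, degrees
#' @param asymmetry_offset left-minus-right setpoint difference, degrees
#' @param whisker_spread SD of fixed per-whisker offsets around the side mean,
#'   degrees
#' @param n_whiskers_per_side tracked whiskers per side (1-6)
#' @param phase_jitter_sd Brownian phase-drift scale (cycle-to-cycle
#'   frequency wander), radians per sqrt-second; 0 gives a pure tone
#' @param angle_noise_sd per-frame, per-whisker measurement noise, degrees
#' @param mouse_intercept_sd SD of the mouse-level random intercept on the
#'   setpoint, degrees
#' @param contact contact modulation, see [contact_modulation()]
#' @param habituation session shifts, see [habituation_deltas()]
#' @param locomotion_speed mean locomotion speed, mm/s
#' @param body_length_mm nose-to-centroid offset used for the nose track, mm
#' @param seed optional integer seed
#' @return a `simulation_params` list
#' @export
simulation_params <- function(fps = 500, clip_duration = 1.6,
                              whisk_frequency = c(12, 25),
                              setpoint = 100, amplitude = 40,
                              asymmetry_offset = 2, whisker_spread = 5,
                              n_whiskers_per_side = 6,
                              phase_jitter_sd = 0.1, angle_noise_sd = 1,
                              mouse_intercept_sd = 3,
                              contact = contact_modulation(),
                              habituation = habituation_deltas(),
                              locomotion_speed = 150,
                              body_length_mm = 35,
                              seed = NULL) {
  stopifnot(fps > 0, clip_duration > 0,
            length(whisk_frequency) %in% c(1L, 2L), all(whisk_frequency > 0),
            amplitude >= 0, whisker_spread >= 0,
            n_whiskers_per_side >= 1, n_whiskers_per_side <= 6,
            phase_jitter_sd >= 0, angle_noise_sd >= 0,
            mouse_intercept_sd >= 0, locomotion_speed >= 0)
  if (length(whisk_frequency) == 2L && whisk_frequency[1] > whisk_frequency[2])
    stop("whisk_frequency range must be increasing")
  if (!inherits(contact, "contact_modulation"))
    contact <- do.call(contact_modulation, as.list(contact))
  if (!inherits(habituation, "habituation_deltas"))
    habituation <- do.call(habituation_deltas, as.list(habituation))
  structure(list(fps = fps, clip_duration = clip_duration,
                 whisk_frequency = whisk_frequency, setpoint = setpoint,
                 amplitude = amplitude, asymmetry_offset = asymmetry_offset,
                 whisker_spread = whisker_spread,
                 n_whiskers_per_side = as.integer(n_whiskers_per_side),
                 phase_jitter_sd = phase_jitter_sd,
                 angle_noise_sd = angle_noise_sd,
                 mouse_intercept_sd = mouse_intercept_sd,
                 contact = contact, habituation = habituation,
                 locomotion_speed = locomotion_speed,
                 body_length_mm = body_length_mm, seed = seed),
            class = "simulation_params")
}

#' Arena geometry and calibration
#'
#' Rectangular Perspex arena with an optional central object. Coordinates are
#' in centimetres with the origin at one corner; pixel tracks are related to
#' physical distance through `px_per_mm`.
#'
#' @param width,length,height arena dimensions in cm (default 30 x 50 x 15)
#' @param object_center xy position of the object centre, cm
#' @param object_radius physical object radius, cm
#' @param wall_margin width of the "around the walls" zone, cm
#' @param object_zone_radius radius of the "around the object" zone, cm
#' @param px_per_mm camera calibration, pixels per millimetre
#' @return an `arena_spec` list
#' @export
arena_spec <- function(width = 30, length = 50, height = 15,
                       object_center = c(15, 25), object_radius = 1.5,
                       wall_margin = 5, object_zone_radius = 5,
                       px_per_mm = 2) {
  stopifnot(width > 0, length > 0, height > 0, object_radius > 0,
            wall_margin > 0, object_zone_radius > 0, px_per_mm > 0,
            length(object_center) == 2L)
  if (wall_margin >= min(width, length) / 2)
    stop("wall_margin must be smaller than half the smallest arena dimension")
  if (object_center[1] - object_radius < 0 ||
      object_center[1] + object_radius > width ||
      object_center[2] - object_radius < 0 ||
      object_center[2] + object_radius > length)
    stop("object must lie inside the arena")
  structure(list(width = width, length = length, height = height,
                 object_center = as.numeric(object_center),
                 object_radius = object_radius, wall_margin = wall_margin,
                 object_zone_radius = object_zone_radius,
                 px_per_mm = px_per_mm),
            class = "arena_spec")
}

#' Cohort design for the synthetic study
#'
#' @param n_per_genotype mice per genotype (study default 9 + 9)
#' @param genotypes genotype labels; first level is the control
#' @param sexes sex labels
#' @param age_groups exactly four ordered age bins spanning 2-8 months
#' @param lines transgenic background lines cycled over mice
#' @param sessions ordered open-field session labels
#' @param clips_per_mouse length-2 integer range of clips per mouse per
#'   session (study range 1-9)
#' @param object_clips_per_mouse length-2 range of object-task clips per mouse
#' @param seed optional integer seed
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_per_genotype = 9,
                        genotypes = c("wildtype", "reeler"),
                        sexes = c("F", "M"),
                        age_groups = c("2-3mo", "3-5mo", "5-7mo", "7-8mo"),
                        lines = c("PV", "VIP", "SOM"),
                        sessions = c("OF", "H1", "H5"),
                        clips_per_mouse = c(1, 9),
                        object_clips_per_mouse = c(1, 9),
                        seed = NULL) {
  stopifnot(n_per_genotype >= 1, length(genotypes) == 2L,
            length(age_groups) == 4L,
            length(clips_per_mouse) == 2L,
            length(object_clips_per_mouse) == 2L)
  if (clips_per_mouse[1] < 1 || clips_per_mouse[2] > 9 ||
      clips_per_mouse[1] > clips_per_mouse[2])
    stop("clips_per_mouse must be an increasing range within [1, 9]")
  if (object_clips_per_mouse[1] > object_clips_per_mouse[2] ||
      object_clips_per_mouse[1] < 0)
    stop("object_clips_per_mouse must be a non-negative increasing range")
  structure(list(n_per_genotype = as.integer(n_per_genotype),
                 genotypes = genotypes, sexes = sexes,
                 age_groups = age_groups, lines = lines, sessions = sessions,
                 clips_per_mouse = as.integer(clips_per_mouse),
                 object_clips_per_mouse = as.integer(object_clips_per_mouse),
                 seed = seed),
            class = "cohort_spec")
}

#' Clip quality-control thresholds
#'
#' @param min_segment_duration minimum strict duration (s) of both the
#'   pre-contact and during-contact segment of an object clip
#' @param min_whiskers_per_frame,max_whiskers_per_frame allowed band of total
#'   tracked whiskers per frame (tracker band 2-12)
#' @param min_fraction_frames_both_sides minimum fraction of frames with at
#'   least one tracked whisker on each side ("both whisker sides visible")
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(min_segment_duration = 0.2,
                          min_whiskers_per_frame = 2,
                          max_whiskers_per_frame = 12,
                          min_fraction_frames_both_sides = 0.9) {
  stopifnot(min_segment_duration > 0,
            min_whiskers_per_frame >= 2,
            max_whiskers_per_frame <= 12,
            min_whiskers_per_frame <= max_whiskers_per_frame,
            min_fraction_frames_both_sides > 0,
            min_fraction_frames_both_sides <= 1)
  structure(list(min_segment_duration = min_segment_duration,
                 min_whiskers_per_frame = as.integer(min_whiskers_per_frame),
                 max_whiskers_per_frame = as.integer(max_whiskers_per_frame),
                 min_fraction_frames_both_sides =
                   min_fraction_frames_both_sides),
            class = "qc_thresholds")
}

#' Partial eta-squared size bands
#'
#' Conventional effect-size bands for partial eta-squared: 0.01 small,
#' 0.06 medium, 0.14 large (lower-inclusive).
#'
#' @param small,medium,large strictly increasing band edges
#' @return an `effect_size_bands` list
#' @export
effect_size_bands <- function(small = 0.01, medium = 0.06, large = 0.14) {
  stopifnot(small < medium, medium < large, small > 0, large < 1)
  structure(list(small = small, medium = medium, large = large),
            class = "effect_size_bands")
}
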