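#' Sinusoidal whisking waveform
#'
#' The generative model for a side's mean whisker angle: a phase-jittered
#' sinusoid around a setpoint,
#' `S +/- delta/2 + (A/2) * sin(2*pi*f*t + phi0 + jitter) + noise`,
#' where the left side carries `+delta/2` and the right `-delta/2`. With zero
#' jitter and noise the trace is a pure tone at the whisk frequency, so every
#' clip metric has a closed form in the parameters.
#'
#' @param t time vector in seconds, uniformly sampled at `1/fps`
#' @param params a [simulation_params()] object
#' @param side "left" or "right"
#' @param frequency optional fixed whisk frequency (Hz); if `NULL`, resolved
#'   from `params$whisk_frequency` (drawn uniformly when that is a range)
#' @param phase0 initial phase, radians
#' @param seed optional seed for the jitter/noise/frequency draws
#' @return numeric vector of whisker angles, degrees
#' @examples
#' p <- simulation_params(amplitude = 30, phase_jitter_sd = 0,
#'                        angle_noise_sd = 0)
#' th <- whisk_waveform(seq(0, 1.6, by = 1/500), p, "left", frequency = 18)
#' @export
whisk_waveform <- function(t, params, side = c("left", "right"),
                           frequency = NULL, phase0 = 0, seed = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(frequency) && (!is.numeric(frequency) || frequency <= 0))
    stop("whisk frequency must be a positive number")
  with_seed(seed, {
    f <- frequency %||% resolve_frequency(params$whisk_frequency)
    sgn <- if (side == "left") 1 else -1
    dt <- if (length(t) > 1L) t[2] - t[1] else 1
    jitter <- if (params$phase_jitter_sd > 0)
      cumsum(rnorm(length(t), 0, params$phase_jitter_sd * sqrt(dt))) else 0
    noise <- if (params$angle_noise_sd > 0)
      rnorm(length(t), 0, params$angle_noise_sd) else 0
    params$setpoint + sgn * params$asymmetry_offset / 2 +
      (params$amplitude / 2) * sin(2 * pi * f * t + phase0 + jitter) + noise
  })
}

resolve_frequency <- function(wf) {
  if (length(wf) == 2L) runif(1, wf[1], wf[2]) else wf
}

#' Simulate one tracked clip
#'
#' Generates a [clip_data()] object from the sinusoidal whisking model:
#' per-whisker angles are the side waveform plus fixed per-clip whisker
#' offsets (SD `whisker_spread`) plus frame noise; the body centroid follows
#' a smoothed-heading random walk at the configured locomotion speed with
#' wall reflection, and the nose sits one body-offset ahead of the centroid.
#' From `contact_frame` onwards the generator switches to contact parameters:
#' amplitude x `k_amplitude`, asymmetry + `d_asymmetry`, whisker offsets
#' x `k_spread`, frequency x `k_frequency` (phase-continuous), locomotion
#' x `k_locomotion`; for contact clips the path is shifted so the nose grazes
#' the object boundary at the contact frame.
#'
#' @param mouse list with at least `mouse_id`; optional `random_intercept`
#'   (degrees, added to the setpoint)
#' @param params a [simulation_params()] object
#' @param arena an [arena_spec()] object
#' @param contact `NULL` for no contact; `TRUE` to auto-place the contact
#'   frame so both segments comfortably exceed the QC minimum; or a list
#'   `list(frame = , end = NULL)` with an explicit 0-based contact frame
#' @param clip_id,session,task labels stored on the clip
#' @param seed optional seed; identical seeds give bit-identical clips
#' @return a `clip_data` object; the generative ground truth is attached as
#'   `attr(, "truth")`
#' @export
simulate_clip <- function(mouse, params, arena, contact = NULL,
                          clip_id = paste0(mouse$mouse_id, "_clip"),
                          session = NA_character_, task = NA_character_,
                          seed = NULL) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(arena, "arena_spec"))
  n <- round(params$fps * params$clip_duration)
  fps <- params$fps
  cm <- params$contact

  contact_frame <- contact_end <- NULL
  if (isTRUE(contact)) {
    margin <- ceiling(0.25 * fps)  # both segments >= 0.25 s, above QC 0.2 s
    if (2 * margin >= n)
      stop("contact placement impossible: clip too short for both segments")
  } else if (is.list(contact)) {
    contact_frame <- as.integer(contact$frame)
    if (contact_frame < 1L || contact_frame >= n)
      stop("contact placement impossible within clip")
    if (!is.null(contact$end)) contact_end <- as.integer(contact$end)
  } else if (!is.null(contact) && !isFALSE(contact)) {
    stop("contact must be NULL, TRUE, or list(frame=, end=)")
  }

  with_seed(seed, {
    if (isTRUE(contact))
      contact_frame <- sample(seq.int(margin, n - margin), 1L)
    f <- resolve_frequency(params$whisk_frequency)
    phase0 <- runif(1, 0, 2 * pi)
    in_dc <- if (is.null(contact_frame)) rep(FALSE, n) else
      (seq_len(n) - 1L) >= contact_frame &
      (if (is.null(contact_end)) TRUE else (seq_len(n) - 1L) < contact_end)

    f_vec <- ifelse(in_dc, f * cm$k_frequency, f)
    a_vec <- ifelse(in_dc, params$amplitude * cm$k_amplitude,
                    params$amplitude)
    d_vec <- ifelse(in_dc, params$asymmetry_offset + cm$d_asymmetry,
                    params$asymmetry_offset)
    s_vec <- ifelse(in_dc, cm$k_spread, 1)

    # phase-continuous frequency switch; jitter is a Brownian phase drift
    # (smooth frequency wander), so it does not inject velocity noise
    phase <- phase0 + 2 * pi * cumsum(c(0, f_vec[-n])) / fps
    jitter <- if (params$phase_jitter_sd > 0)
      cumsum(rnorm(n, 0, params$phase_jitter_sd / sqrt(fps))) else 0
    carrier <- (a_vec / 2) * sin(phase + jitter)
    s0 <- params$setpoint + (mouse$random_intercept %||% 0)

    nw <- params$n_whiskers_per_side
    rows <- vector("list", 2)
    for (k in 1:2) {
      side <- c("left", "right")[k]
      sgn <- if (side == "left") 1 else -1
      base <- s0 + sgn * d_vec / 2 + carrier
      # offsets are centred within the side so that the side mean is exactly
      # the setpoint +/- delta/2: asymmetry is controlled by delta alone and
      # spread by whisker_spread alone (sample SD is centring-invariant)
      offsets <- rnorm(nw, 0, params$whisker_spread)
      if (nw > 1L) offsets <- offsets - mean(offsets)
      ang <- outer(base, rep(1, nw)) + outer(s_vec, offsets)
      if (params$angle_noise_sd > 0)
        ang <- ang + matrix(rnorm(n * nw, 0, params$angle_noise_sd), n, nw)
      rows[[k]] <- data.frame(
        frame = rep(0:(n - 1L), times = nw),
        side = side,
        whisker_index = rep(seq_len(nw) + (k - 1L) * nw, each = n),
        angle = as.vector(ang))
    }
    angles <- rbind(rows[[1]], rows[[2]])

    # locomotion: smoothed-heading walk in mm, reflected at the walls
    wmm <- arena$width * 10; lmm <- arena$length * 10
    speed_vec <- params$locomotion_speed * ifelse(in_dc, cm$k_locomotion, 1)
    heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1L, 0, 0.01)))
    step <- speed_vec / fps
    pos <- matrix(0, n, 2)
    pos[1, ] <- c(runif(1, 0.1 * wmm, 0.9 * wmm),
                  runif(1, 0.1 * lmm, 0.9 * lmm))
    dx <- step * cos(heading); dy <- step * sin(heading)
    pos[, 1] <- reflect_path(pos[1, 1] + cumsum(c(0, dx[-n])), wmm)
    pos[, 2] <- reflect_path(pos[1, 2] + cumsum(c(0, dy[-n])), lmm)
    nose <- pos + params$body_length_mm * cbind(cos(heading), sin(heading))

    if (!is.null(contact_frame)) {
      obj_mm <- arena$object_center * 10
      dir <- c(cos(heading[contact_frame + 1L]),
               sin(heading[contact_frame + 1L]))
      target <- obj_mm - (arena$object_radius * 10 + 1) * dir
      shift <- target - nose[contact_frame + 1L, ]
      pos <- sweep(pos, 2, shift, `+`)
      nose <- sweep(nose, 2, shift, `+`)
      pos[, 1] <- pmin(pmax(pos[, 1], 0), wmm)
      pos[, 2] <- pmin(pmax(pos[, 2], 0), lmm)
      nose[, 1] <- pmin(pmax(nose[, 1], 0), wmm)
      nose[, 2] <- pmin(pmax(nose[, 2], 0), lmm)
    }

    clip <- clip_data(clip_id = clip_id, fps = fps, angles = angles,
                      nose = nose * arena$px_per_mm,
                      centroid = pos * arena$px_per_mm,
                      contact_frame = contact_frame,
                      contact_end = contact_end,
                      session = session, task = task,
                      px_per_mm = arena$px_per_mm)
    attr(clip, "truth") <- list(
      frequency = f, setpoint = s0, amplitude = params$amplitude,
      asymmetry = params$asymmetry_offset,
      whisker_spread = params$whisker_spread,
      locomotion_speed = params$locomotion_speed,
      contact = if (is.null(contact_frame)) NULL else cm)
    clip
  })
}

# fold an unbounded 1-d path back into [0, limit] (billiard reflection)
reflect_path <- function(x, limit) {
  y <- x %% (2 * limit)
  ifelse(y > limit, 2 * limit - y, y)
}

#' Simulate a full study cohort
#'
#' Builds the mouse roster (genotype, sex, age group, line cycled to balance
#' the design cells; one random intercept per mouse, shared across all of its
#' clips), then simulates tracker clips for every open-field session and,
#' when requested, an object-exploration task with contact clips. Sessions
#' after the first open-field exposure receive the additive habituation
#' shifts from [habituation_deltas()], with reeler mice receiving the extra
#' decrements (the genotype-by-habituation interaction).
#'
#' @param cohort a [cohort_spec()]
#' @param params a [simulation_params()]
#' @param arena an [arena_spec()]
#' @param seed master seed; defaults to `cohort$seed`, then `params$seed`
#' @return a `whisker_cohort` list with elements `mice` (data.frame),
#'   `metadata` (one row per clip), `clips` (named list of [clip_data()]),
#'   and `truth` (per-clip generative parameters)
#' @export
simulate_cohort <- function(cohort, params, arena,
                            seed = cohort$seed %||% params$seed) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(params, "simulation_params"),
            inherits(arena, "arena_spec"))
  if (cohort$n_per_genotype < 1) stop("empty cohort")

  cells <- expand.grid(sex = cohort$sexes, age_group = cohort$age_groups,
                       line = cohort$lines, stringsAsFactors = FALSE)
  mk_mice <- function(genotype, gi) {
    i <- seq_len(cohort$n_per_genotype)
    data.frame(mouse_id = sprintf("%s%02d", substr(genotype, 1, 2), i),
               genotype = genotype,
               sex = cells$sex[(i - 1L) %% nrow(cells) + 1L],
               age_group = cells$age_group[(i - 1L) %% nrow(cells) + 1L],
               line = cells$line[(i - 1L) %% nrow(cells) + 1L],
               stringsAsFactors = FALSE)
  }
  mice <- rbind(mk_mice(cohort$genotypes[1], 1), mk_mice(cohort$genotypes[2], 2))

  with_seed(seed, {
    mice$random_intercept <- rnorm(nrow(mice), 0, params$mouse_intercept_sd)
    clips <- list(); meta <- list(); truth <- list()

    add_clip <- function(cl, m, task, session) {
      clips[[cl$clip_id]] <<- cl
      meta[[length(meta) + 1L]] <<- data.frame(
        clip_id = cl$clip_id, mouse_id = m$mouse_id, genotype = m$genotype,
        sex = m$sex, age_group = m$age_group, line = m$line,
        task = task, session = session,
        contact_frame = if (is.null(cl$contact_frame)) NA_integer_
                        else cl$contact_frame,
        px_per_mm = arena$px_per_mm, stringsAsFactors = FALSE)
      tr <- attr(cl, "truth")
      truth[[length(truth) + 1L]] <<- data.frame(
        clip_id = cl$clip_id, setpoint = tr$setpoint,
        amplitude = tr$amplitude, asymmetry = tr$asymmetry,
        whisker_spread = tr$whisker_spread, frequency = tr$frequency,
        locomotion_speed = tr$locomotion_speed, stringsAsFactors = FALSE)
    }

    for (mi in seq_len(nrow(mice))) {
      m <- as.list(mice[mi, ])
      is_reeler <- m$genotype == cohort$genotypes[2]
      # object-exploration task (contact clips), before open field
      n_obj <- sample_range(cohort$object_clips_per_mouse)
      for (ci in seq_len(n_obj)) {
        cl <- simulate_clip(m, params, arena, contact = TRUE,
                            clip_id = sprintf("%s_OBJ_%02d", m$mouse_id, ci),
                            session = "OF", task = "object")
        add_clip(cl, m, "object", "OF")
      }
      for (session in cohort$sessions) {
        ps <- session_params(params, session, is_reeler)
        n_cl <- sample_range(cohort$clips_per_mouse)
        for (ci in seq_len(n_cl)) {
          task <- if (session == "OF") "open_field" else "habituation"
          cl <- simulate_clip(m, ps, arena,
                              clip_id = sprintf("%s_%s_%02d", m$mouse_id,
                                                session, ci),
                              session = session, task = task)
          add_clip(cl, m, task, session)
        }
      }
    }
    structure(list(mice = mice, metadata = do.call(rbind, meta),
                   clips = clips, truth = do.call(rbind, truth),
                   params = params, arena = arena, cohort = cohort,
                   seed = seed),
              class = "whisker_cohort")
  })
}

sample_range <- function(rng) {
  if (rng[2] < 1L) return(0L)
  if (rng[1] == rng[2]) rng[1] else sample(seq.int(rng[1], rng[2]), 1L)
}

# apply cumulative habituation shifts for one session/genotype
session_params <- function(params, session, is_reeler) {
  hb <- params$habituation
  get0n <- function(v, s) if (s %in% names(v)) unname(v[s]) else 0
  dS <- get0n(hb$setpoint, session)
  dW <- get0n(hb$spread, session)
  dL <- get0n(hb$locomotion, session)
  if (is_reeler) {
    dS <- dS + get0n(hb$reeler_extra$setpoint, session)
    dW <- dW + get0n(hb$reeler_extra$spread, session)
    dL <- dL + get0n(hb$reeler_extra$locomotion, session)
  }
  params$setpoint <- params$setpoint + dS
  params$whisker_spread <- max(params$whisker_spread + dW, 0.1)
  params$locomotion_speed <- max(params$locomotion_speed + dL, 10)
  params
}

#' @export
print.whisker_cohort <- function(x, ...) {
  cat("<whisker_cohort> ", nrow(x$mice), " mice, ", length(x$clips),
      " clips\n", sep = "")
  print(table(x$metadata$genotype, x$metadata$session))
  invisible(x)
}

#' Simulate clip-level metric responses from the mixed model
#'
#' Draws per-clip values of a single outcome directly from the
#' random-intercept model `y = intercept + fixed effects + mouse + residual`,
#' bypassing trace synthesis. This is the generator used for statistical
#' calibration at scale (type-I error, coverage), where hundreds of model
#' fits are needed and the kinematic layer is not under test.
#'
#' @param n_per_genotype mice per genotype
#' @param clips_per_mouse clips per mouse (per session if sessions given)
#' @param sessions optional session labels; first is the reference
#' @param genotype_effect additive shift for the second genotype
#' @param session_effects named numeric, shifts per non-reference session
#' @param interaction_effects named numeric, extra per-session shifts applied
#'   to the second genotype only
#' @param intercept grand mean
#' @param mouse_sd SD of the mouse random intercept
#' @param resid_sd residual SD
#' @param seed optional seed
#' @return data.frame with columns mouse_id, genotype, (session,) y
#' @export
simulate_lmm_dataset <- function(n_per_genotype = 9, clips_per_mouse = 5,
                                 sessions = NULL, genotype_effect = 0,
                                 session_effects = NULL,
                                 interaction_effects = NULL,
                                 intercept = 100, mouse_sd = 1.5,
                                 resid_sd = 1, seed = NULL) {
  with_seed(seed, {
    genos <- c("wildtype", "reeler")
    mouse_id <- sprintf("m%02d", seq_len(2 * n_per_genotype))
    genotype <- rep(genos, each = n_per_genotype)
    u <- rnorm(2 * n_per_genotype, 0, mouse_sd)
    ses <- sessions %||% "all"
    d <- expand.grid(clip = seq_len(clips_per_mouse),
                     session = ses, mouse = seq_along(mouse_id),
                     stringsAsFactors = FALSE)
    y <- intercept + u[d$mouse] +
      ifelse(genotype[d$mouse] == genos[2], genotype_effect, 0) +
      rnorm(nrow(d), 0, resid_sd)
    if (!is.null(session_effects)) {
      idx <- match(d$session, names(session_effects))
      y <- y + ifelse(is.na(idx), 0, session_effects[idx])
    }
    if (!is.null(interaction_effects)) {
      idx <- match(d$session, names(interaction_effects))
      y <- y + ifelse(!is.na(idx) & genotype[d$mouse] == genos[2],
                      interaction_effects[idx], 0)
    }
    out <- data.frame(mouse_id = mouse_id[d$mouse],
                      genotype = factor(genotype[d$mouse], levels = genos),
                      y = y, stringsAsFactors = FALSE)
    if (!is.null(sessions))
      out$session <- factor(d$session, levels = sessions)
    out
  })
}
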