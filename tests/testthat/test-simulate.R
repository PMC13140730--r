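test_that("waveform reduces to the setpoint when amplitude is zero", {
  p <- simulation_params(amplitude = 0, phase_jitter_sd = 0,
                         angle_noise_sd = 0, setpoint = 100,
                         asymmetry_offset = 0)
  t <- seq(0, 1.6, by = 1 / 500)
  expect_equal(whisk_waveform(t, p, "left", frequency = 18),
               rep(100, length(t)))
})

test_that("waveform spectral peak sits at the configured frequency", {
  p <- simulation_params(amplitude = 30, phase_jitter_sd = 0,
                         angle_noise_sd = 0)
  t <- (0:799) / 500
  w <- whisk_waveform(t, p, "left", frequency = 18)
  expect_equal(fft_peak_hz(w, 500), 18, tolerance = 0.5 / 1.6)
})

test_that("asymmetry offset splits evenly between the sides", {
  p <- simulation_params(asymmetry_offset = 10, phase_jitter_sd = 0,
                         angle_noise_sd = 0, amplitude = 30)
  t <- (0:799) / 500   # 800 frames = integer cycles at 12.5 Hz
  l <- whisk_waveform(t, p, "left", frequency = 12.5)
  r <- whisk_waveform(t, p, "right", frequency = 12.5)
  expect_equal(mean(l) - mean(r), 10, tolerance = 1e-10)
})

test_that("invalid waveform parameters are rejected", {
  expect_error(simulation_params(amplitude = -5))
  expect_error(simulation_params(whisk_frequency = c(25, 12)))
  p <- simulation_params()
  expect_error(whisk_waveform((0:10) / 500, p, "left", frequency = -3),
               "positive")
})

test_that("clip simulation is deterministic given a seed", {
  ar <- arena_spec()
  m <- default_mouse()
  c1 <- simulate_clip(m, simulation_params(), ar, contact = TRUE, seed = 11)
  c2 <- simulate_clip(m, simulation_params(), ar, contact = TRUE, seed = 11)
  attr(c1, "truth") <- attr(c2, "truth") <- NULL
  expect_identical(c1, c2)
  c3 <- simulate_clip(m, simulation_params(), ar, contact = TRUE, seed = 12)
  expect_false(identical(c1$angles, c3$angles))
})

test_that("a clip without contact has stationary parameters", {
  cl <- simulate_clip(default_mouse(), simulation_params(), arena_spec(),
                      seed = 1)
  expect_null(cl$contact_frame)
  expect_equal(cl$n_frames, 800L)
})

test_that("contact scales the within-side whisker spread by k_spread", {
  p <- simulation_params(angle_noise_sd = 0,
                         contact = contact_modulation(k_spread = 0.5))
  ratios <- vapply(1:20, function(s) {
    cl <- simulate_clip(default_mouse(), p, arena_spec(),
                        contact = list(frame = 400), seed = s)
    pc <- clip_metrics(cl, 0:399)
    dc <- clip_metrics(cl, 400:799)
    dc$spread / pc$spread
  }, 0)
  expect_equal(mean(ratios), 0.5, tolerance = 0.02)
})

test_that("contact placement must leave room for both segments", {
  p <- simulation_params(clip_duration = 0.4)
  expect_error(simulate_clip(default_mouse(), p, arena_spec(),
                             contact = TRUE), "impossible")
  expect_error(simulate_clip(default_mouse(), simulation_params(),
                             arena_spec(), contact = list(frame = 900)),
               "impossible")
})

test_that("cohort bookkeeping: cells, clip counts, shared intercepts", {
  co <- cohort_spec(n_per_genotype = 9, clips_per_mouse = c(5, 5),
                    object_clips_per_mouse = c(0, 0), seed = 4)
  p <- simulation_params(clip_duration = 0.2)
  ch <- simulate_cohort(co, p, arena_spec())
  expect_equal(nrow(ch$mice), 18L)
  expect_equal(length(ch$clips), 18L * 3L * 5L)
  expect_setequal(unique(ch$metadata$session), c("OF", "H1", "H5"))
  expect_equal(as.vector(table(ch$metadata$genotype)), c(135L, 135L))
  # all clips of one mouse in one session share the generative setpoint
  # (one random intercept per mouse)
  tr <- merge(ch$truth, ch$metadata[c("clip_id", "mouse_id", "session")])
  spread_within <- tapply(tr$setpoint,
                          paste(tr$mouse_id, tr$session), sd)
  expect_true(all(spread_within < 1e-12))
})

test_that("session setpoint shift is recovered by clip-mean positions", {
  hb <- habituation_deltas(setpoint = c(H1 = -3), spread = c(H1 = 0),
                           locomotion = c(H1 = 0),
                           reeler_extra = list(setpoint = c(H1 = 0),
                                               spread = c(H1 = 0),
                                               locomotion = c(H1 = 0)))
  co <- cohort_spec(n_per_genotype = 15, clips_per_mouse = c(2, 2),
                    object_clips_per_mouse = c(0, 0),
                    sessions = c("OF", "H1"), seed = 8)
  p <- simulation_params(habituation = hb, clip_duration = 0.4)
  ch <- simulate_cohort(co, p, arena_spec())
  pos <- vapply(ch$clips, function(cl)
    clip_metrics(cl)$mean_angular_position, 0)
  ses <- ch$metadata$session[match(names(pos), ch$metadata$clip_id)]
  expect_gte(sum(ses == "H1"), 50)
  d <- mean(pos[ses == "H1"]) - mean(pos[ses == "OF"])
  expect_equal(d, -3, tolerance = 0.1)
})

test_that("zero habituation deltas leave session means equal", {
  hb <- habituation_deltas(setpoint = c(H1 = 0, H5 = 0),
                           spread = c(H1 = 0, H5 = 0),
                           locomotion = c(H1 = 0, H5 = 0),
                           reeler_extra = list(setpoint = c(H5 = 0),
                                               spread = c(H5 = 0),
                                               locomotion = c(H5 = 0)))
  co <- cohort_spec(n_per_genotype = 10, clips_per_mouse = c(2, 2),
                    object_clips_per_mouse = c(0, 0), seed = 3)
  ch <- simulate_cohort(co, simulation_params(habituation = hb,
                                              clip_duration = 0.3),
                        arena_spec())
  tr <- merge(ch$truth, ch$metadata[c("clip_id", "session")])
  m <- tapply(tr$setpoint, tr$session, mean)
  expect_lt(max(m) - min(m), 1e-10)
})

test_that("empty cohort is rejected", {
  expect_error(cohort_spec(n_per_genotype = 0))
})

test_that("metric-level generator honours its effect structure", {
  d <- simulate_lmm_dataset(n_per_genotype = 50, clips_per_mouse = 4,
                            sessions = c("OF", "H1"),
                            genotype_effect = 2,
                            session_effects = c(H1 = -3),
                            interaction_effects = c(H1 = -1),
                            mouse_sd = 0.01, resid_sd = 0.01, seed = 2)
  m <- tapply(d$y, list(d$genotype, d$session), mean)
  expect_equal(m["reeler", "OF"] - m["wildtype", "OF"], 2, tolerance = 0.05)
  expect_equal(m["wildtype", "H1"] - m["wildtype", "OF"], -3,
               tolerance = 0.05)
  expect_equal(m["reeler", "H1"] - m["reeler", "OF"], -4, tolerance = 0.05)
})
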