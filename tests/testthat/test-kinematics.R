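test_that("frame means: identity with one whisker, mean with several", {
  cl <- make_trace_clip(function(t) 100 + t, n_frames = 10, fps = 500)
  fm <- frame_mean_angles(cl)
  expect_equal(fm$left, 100 + (0:9) / 500)

  cl2 <- make_trace_clip(function(t) 100, n_frames = 5,
                         offsets_left = c(-10, 0, 10))
  expect_equal(frame_mean_angles(cl2)$left, rep(100, 5))
})

test_that("a side missing in a frame yields NA there, other side intact", {
  cl <- make_trace_clip(function(t) 100, n_frames = 6,
                        offsets_left = c(0, 1), offsets_right = c(0, 1))
  cl$angles <- cl$angles[!(cl$angles$side == "left" &
                             cl$angles$frame == 3L), ]
  fm <- frame_mean_angles(cl)
  expect_true(is.nan(fm$left[4]) || is.na(fm$left[4]))
  expect_equal(fm$right[4], 100.5)
})

test_that("angular velocity is the first difference scaled to deg/s", {
  expect_equal(angular_velocity(rep(5, 10), 500), rep(0, 9))
  expect_equal(angular_velocity(seq(0, by = 0.2, length.out = 11), 500),
               rep(100, 10))
  expect_error(angular_velocity(1, 500), "2 frames")
})

test_that("mean absolute velocity of a sinusoid matches the 2Af law", {
  A <- 30; f <- 15; fps <- 4000
  t <- seq(0, 1 - 1 / fps, by = 1 / fps)
  theta <- (A / 2) * sin(2 * pi * f * t)
  v <- angular_velocity(theta, fps)
  # quadrature oracle: time-average of |theta'| over one period
  oracle <- f * stats::integrate(function(s) abs(pi * A * f *
                                                   cos(2 * pi * f * s)),
                                 0, 1 / f, subdivisions = 1000L)$value
  expect_equal(oracle, 2 * A * f, tolerance = 1e-6)
  # finite differencing over a non-integer number of periods leaves an
  # O(1/n) edge effect
  expect_equal(mean(abs(v)), oracle, tolerance = 1e-3)
})

test_that("amplitude estimator returns peak-to-peak for a pure tone", {
  cl <- make_sine_clip(A = 40, f = 12.5, n_frames = 800, fps = 500)
  m <- clip_metrics(cl)
  # SD of a sinusoid over integer cycles is (A/2)/sqrt(2) (here the
  # population SD; the n-1 estimator differs by O(1/n))
  expect_equal(m$amplitude, 40, tolerance = 1e-3)
  expect_equal(m$mean_angular_position, 100, tolerance = 1e-10)
  expect_equal(m$asymmetry, 0, tolerance = 1e-10)
})

test_that("asymmetry equals the configured left-right offset", {
  cl <- make_sine_clip(A = 30, f = 12.5, delta = 7)
  expect_equal(clip_metrics(cl)$asymmetry, 7, tolerance = 1e-10)
})

test_that("spread equals the SD of the fixed per-whisker offsets", {
  off <- c(-6, -2, 0, 1, 3, 4)
  cl <- make_sine_clip(A = 20, f = 12.5, offsets_left = off,
                       offsets_right = off)
  expect_equal(clip_metrics(cl)$spread, sd(off), tolerance = 1e-10)
})

test_that("mean spread over clips recovers sigma_w shrunk by c4", {
  # Monte-Carlo oracle for the c4 bias factor itself
  set.seed(42)
  mc <- mean(replicate(4000, sd(rnorm(6))))
  expect_equal(mc, c4_factor(6), tolerance = 0.02)

  set.seed(7)
  sp <- replicate(60, {
    cl <- make_sine_clip(A = 20, f = 12.5, n_frames = 100,
                         offsets_left = rnorm(6, 0, 5),
                         offsets_right = rnorm(6, 0, 5))
    clip_metrics(cl)$spread
  })
  expect_equal(mean(sp), 5 * c4_factor(6), tolerance = 0.06)
})

test_that("protraction and retraction speeds split by velocity sign", {
  # sawtooth: rise 1 deg/frame for 9 frames, drop 9 deg once, repeated
  saw <- rep(c(0:9), 10)
  cl <- make_trace_clip(function(t) saw[seq_along(t)], n_frames = 100,
                        fps = 500)
  m <- clip_metrics(cl)
  expect_equal(m$protraction_speed, 1 * 500)
  expect_equal(m$retraction_speed, 9 * 500)
})

test_that("a monotone trace flags the absent movement direction", {
  cl <- make_trace_clip(function(t) 100 + 10 * t, n_frames = 50)
  m <- clip_metrics(cl)
  expect_true(is.na(m$retraction_speed))
  expect_true(m$flags$missing_retraction)
  expect_false(m$flags$missing_protraction)
})

test_that("metrics are invariant to whisker relabelling and common shifts", {
  off <- c(-3, 0, 3)
  cl <- make_sine_clip(A = 25, f = 12.5, offsets_left = off,
                       offsets_right = off)
  m1 <- clip_metrics(cl)
  cl2 <- cl
  cl2$angles$whisker_index <- match(cl2$angles$whisker_index,
                                    unique(cl2$angles$whisker_index)) * 7L
  m2 <- clip_metrics(cl2)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  # adding a common constant to both sides moves only the mean position
  cl3 <- cl; cl3$angles$angle <- cl3$angles$angle + 11
  m3 <- clip_metrics(cl3)
  expect_equal(m3$mean_angular_position, m1$mean_angular_position + 11)
  expect_equal(m3$amplitude, m1$amplitude)
  expect_equal(m3$asymmetry, m1$asymmetry, tolerance = 1e-9)
  # scaling angles scales the amplitude (scale equivariance)
  cl4 <- cl; cl4$angles$angle <- cl4$angles$angle * 3
  expect_equal(clip_metrics(cl4)$amplitude, m1$amplitude * 3)
})

test_that("locomotion speed handles rest, lines and circles", {
  still <- matrix(50, 100, 2)
  expect_equal(locomotion_speed(still, 2, 500), 0)
  straight <- cbind(seq(0, 99), 0)
  expect_equal(locomotion_speed(straight, 2, 500), 250)
  # circle of radius r at angular rate w: speed r*w
  r <- 100; w <- 2 * pi; fps <- 2000
  t <- seq(0, 1, by = 1 / fps)
  circ <- cbind(r * cos(w * t), r * sin(w * t))
  expect_equal(locomotion_speed(circ, 1, fps), r * w, tolerance = 1e-4)
  expect_error(locomotion_speed(straight, 0, 500), "calibration")
})

test_that("whisk-frequency estimation finds tones and rejects noise", {
  t <- (0:799) / 500
  est <- estimate_whisk_frequency(10 * sin(2 * pi * 18 * t), 500)
  expect_equal(est$frequency, 18, tolerance = 0.5 / 1.6)
  expect_true(est$reliable)

  cl <- simulate_clip(default_mouse(), simulation_params(), arena_spec(),
                      seed = 21)
  est2 <- estimate_whisk_frequency(frame_mean_angles(cl)$left, 500)
  expect_gte(est2$frequency, 12 - 0.7)
  expect_lte(est2$frequency, 25 + 0.7)
  expect_true(est2$reliable)

  set.seed(9)
  est3 <- estimate_whisk_frequency(rnorm(800), 500)
  expect_false(est3$reliable)

  est4 <- estimate_whisk_frequency(rep(3, 800), 500)
  expect_true(is.na(est4$frequency))
  expect_error(estimate_whisk_frequency(rnorm(100), 500), "1 s")
})
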