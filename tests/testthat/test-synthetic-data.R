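test_that("noiseless waveform is the exact sinusoid at quarter periods", {
  prof <- breathing_profile(rate = 0.25, amplitude = 1, noise_sd = 0)
  wf <- synthesize_waveform(prof, apnea_events(), duration = 5,
                            timestamps = 0:4, seed = 1)
  expect_equal(wf$displacement, c(0, 1, 0, -1, 0), tolerance = 1e-12)
})

test_that("a zero-attenuation central event silences the oscillation", {
  prof <- breathing_profile(rate = 0.3, amplitude = 2, noise_sd = 0)
  ev <- apnea_events(10, 20, "central", attenuation = 0)
  t <- seq(0, 60, by = 0.05)
  wf <- synthesize_waveform(prof, ev, 60, t, seed = 1)
  inside <- t >= 10 & t <= 30
  expect_true(all(wf$displacement[inside] == 0))
  expect_gt(max(abs(wf$displacement[!inside])), 1)
})

test_that("waveform sd matches the analytic sine + noise moment", {
  # oracle: sd of a*sin + iid noise over many periods = sqrt(a^2/2 + s^2)
  a <- 1; s <- 0.1
  prof <- breathing_profile(rate = 0.25, amplitude = a, noise_sd = s)
  t <- seq(0, 600, by = 0.1)
  wf <- synthesize_waveform(prof, apnea_events(), 600, t, seed = 42)
  expect_equal(sd(wf$displacement), sqrt(a^2 / 2 + s^2), tolerance = 0.05)
})

test_that("waveform generation is deterministic given the seed and validates events", {
  prof <- breathing_profile(noise_sd = 0.5, drift_sd = 0.1)
  t <- seq(0, 100, by = 0.1)
  ev <- apnea_events(30, 20, "obstructive")
  w1 <- synthesize_waveform(prof, ev, 100, t, seed = 9)
  w2 <- synthesize_waveform(prof, ev, 100, t, seed = 9)
  expect_identical(w1, w2)
  expect_error(synthesize_waveform(prof, ev, 100, numeric(0)), "non-empty")
  overlapping <- tibble::tibble(start = c(10, 20), duration = c(15, 10),
                                type = c("central", "central"),
                                attenuation = 0.1)
  expect_error(synthesize_waveform(prof, overlapping, 100, t), "overlap")
  expect_error(synthesize_waveform(prof, apnea_events(90, 20, "central"), 100, t),
               "within")
})

test_that("jitter-free timestamps form the uniform grid", {
  s <- sensor_profile("custom", mean_fps = 10, fps_jitter = "none")
  expect_equal(jitter_timestamps(s, 1), seq(0, 0.9, by = 0.1))
  expect_error(jitter_timestamps(s, 0), "positive")
})

test_that("uniform jitter keeps frame count near mean_fps and FPS in range", {
  s <- sensor_profile("custom", mean_fps = 20, fps_range = c(10, 30),
                      fps_jitter = "uniform")
  ts <- jitter_timestamps(s, 60, seed = 3)
  expect_true(length(ts) >= 0.9 * 1200 && length(ts) <= 1.1 * 1200)
  inst_fps <- 1 / diff(ts)
  expect_true(all(inst_fps >= 10 & inst_fps <= 30))
  expect_true(all(diff(ts) > 0))
})

test_that("heavy-tail Kinect profile produces FPS excursions bracketing 3-29", {
  s <- sensor_profile("kinect2")
  ts <- jitter_timestamps(s, 600, seed = 5)
  inst_fps <- 1 / diff(ts)
  expect_lt(min(inst_fps), 3)
  expect_gt(max(inst_fps), 29)
  mean_fps <- (length(ts) - 1) / diff(range(ts))
  expect_equal(mean_fps, 20, tolerance = 0.1)
})

test_that("rendering without noise reproduces the displacement exactly", {
  s <- sensor_profile("custom", rows = 6, cols = 8)
  # constant zero displacement -> constant frames at baseline
  seq0 <- render_depth_sequence(rep(0, 4), timestamps = (0:3) / 10, sensor = s,
                                roi = c(2, 5, 3, 6), baseline = 1000)
  expect_true(all(seq0$frames == 1000L))
  # displacement 0,2,4 -> ROI pixel differences all -2
  seq1 <- render_depth_sequence(c(0, 2, 4), timestamps = (0:2) / 10, sensor = s,
                                roi = c(2, 5, 3, 6), baseline = 1000)
  roi_px <- seq1$frames[2:5, 3:6, ]
  diffs <- roi_px[, , -1] - roi_px[, , -3]
  expect_true(all(diffs == -2L))
  expect_error(render_depth_sequence(c(0, 1), (0:1) / 10, s, roi = c(0, 5, 1, 20)),
               "roi")
})

test_that("frame differencing inverts rendering for integer displacements", {
  w <- c(0, 3, -2, 5, 1, -4)
  s <- sensor_profile("custom", rows = 8, cols = 8)
  seq <- render_depth_sequence(w, timestamps = (0:5) / 10, sensor = s,
                               roi = c(2, 7, 2, 7), baseline = 900)
  d <- frame_difference_signal(seq)
  expect_equal(d$value, -diff(w))
  expect_equal(d$t, (1:5) / 10)
})

test_that("simulate_recording is seed-deterministic and emits usable ground truth", {
  ev <- apnea_events(60, 15, "central")
  r1 <- simulate_recording(120, events = ev, seed = 11)
  r2 <- simulate_recording(120, events = ev, seed = 11)
  expect_identical(r1$sequence$frames, r2$sequence$frames)
  expect_identical(r1$sequence$timestamps, r2$sequence$timestamps)
  # annotations feed evaluation directly
  expect_named(r1$annotations, c("start_s", "end_s", "type"))
  sig <- make_signal(rep(0, 1200))
  expect_silent(truth_labels(sig, r1$annotations))
})

test_that("rendered recordings round-trip the breathing rate through extraction", {
  prof <- breathing_profile(rate = 0.3, amplitude = 6, noise_sd = 0.5)
  rec <- simulate_recording(120, profile = prof,
                            sensor = sensor_profile("d415"), seed = 13)
  sig <- extract_breathing_signal(rec$sequence)
  f <- dominant_frequency(amplitude_spectrum(sig))
  expect_lt(abs(f - 0.3), attr(sig, "fs") / nrow(sig))
})

test_that("apnea event schedules respect bounds and plausibility checks", {
  expect_error(apnea_events(0, 3, "central"), "5-44.5")
  expect_silent(apnea_events(0, 3, "central", check_duration = FALSE))
  expect_error(apnea_events(0, 20, "central", attenuation = 0.5), "central")
  expect_error(apnea_events(0, 20, "obstructive", attenuation = 0.7),
               "obstructive")
  sched <- sample_apnea_schedule(900, n_events = 5, seed = 4)
  expect_equal(nrow(sched), 5)
  expect_true(all(sched$duration >= 12 & sched$duration <= 37))
  gaps <- sched$start[-1] - (sched$start + sched$duration)[-5]
  expect_true(all(gaps > 25))
})
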