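#' Breathing, apnea and sensor profiles for the synthetic generator
#'
#' `breathing_profile()` describes the simulated sleeper: a sinusoidal
#' chest displacement at `rate` Hz with amplitude `amplitude` (depth units,
#' 1 unit = 1 mm) around a mean sensor distance `baseline_depth`, with
#' additive per-pixel Gaussian sensor noise of standard deviation
#' `noise_sd` and an optional slow random-walk posture drift
#' (`drift_sd`, depth units per sqrt-second).
#'
#' Defaults model an adult asleep: 0.27 Hz (about 16 breaths/min, inside
#' the 0.26--0.33 Hz adult band and the wider 0.16--0.5 Hz elderly band),
#' 6 mm chest excursion at 1 m distance, 1 mm sensor noise.
#'
#' @param rate breathing frequency in Hz, in `[0.05, 2]`.
#' @param amplitude chest displacement amplitude, depth units (> 0).
#' @param baseline_depth mean chest distance from the sensor, depth units.
#' @param noise_sd per-pixel additive Gaussian noise sd, depth units.
#' @param drift_sd random-walk drift sd in depth units per sqrt(s); 0 by
#'   default.
#' @return A list of class `breathing_profile`.
#' @export
breathing_profile <- function(rate = 0.27, amplitude = 6, baseline_depth = 1000,
                              noise_sd = 1, drift_sd = 0) {
  abort_if(rate < 0.05 || rate > 2, "rate must be within [0.05, 2] Hz")
  abort_if(amplitude <= 0, "amplitude must be positive")
  abort_if(noise_sd < 0, "noise_sd must be non-negative")
  abort_if(drift_sd < 0, "drift_sd must be non-negative")
  structure(list(rate = rate, amplitude = amplitude,
                 baseline_depth = baseline_depth,
                 noise_sd = noise_sd, drift_sd = drift_sd),
            class = "breathing_profile")
}

#' Apnea event schedules
#'
#' `apnea_events()` builds a validated event table. Each event suppresses
#' the breathing oscillation over `[start, start + duration]`: the sinusoid
#' is scaled by `attenuation` (fraction of amplitude remaining). Central
#' events are near-total cessations (default attenuation 0.1); obstructive
#' events keep attenuated effort with a slow out-of-band (0.05 Hz)
#' amplitude modulation; mixed events ramp from cessation into attenuated
#' effort. Durations default to the clinically observed 5--44.5 s range.
#'
#' @param start numeric vector of event onsets (s).
#' @param duration numeric vector of event durations (s).
#' @param type character vector: `"central"`, `"obstructive"` or `"mixed"`.
#' @param attenuation fraction of breathing amplitude remaining during the
#'   event, in `[0, 1]`; `NA` picks the per-type default (central 0.1,
#'   obstructive 0.4, mixed 0.25).
#' @param check_duration enforce the plausible 5--44.5 s duration range
#'   (set `FALSE` to override).
#' @return A tibble with columns `start`, `duration`, `type`,
#'   `attenuation`, sorted by `start`.
#' @export
apnea_events <- function(start = numeric(), duration = numeric(),
                         type = character(), attenuation = NA_real_,
                         check_duration = TRUE) {
  n <- length(start)
  if (n == 0) {
    return(tibble::tibble(start = numeric(), duration = numeric(),
                          type = character(), attenuation = numeric()))
  }
  abort_if(length(duration) != n || length(type) != n,
           "start, duration and type must have equal length")
  abort_if(!all(type %in% apnea_types),
           sprintf("type must be one of %s", paste(apnea_types, collapse = ", ")))
  abort_if(any(duration <= 0), "durations must be positive")
  if (check_duration) {
    abort_if(any(duration < 5 | duration > 44.5),
             "event durations outside the plausible 5-44.5 s range; set check_duration = FALSE to override")
  }
  attenuation <- rep_len(as.numeric(attenuation), n)
  defaults <- c(central = 0.1, obstructive = 0.4, mixed = 0.25)
  attenuation[is.na(attenuation)] <- defaults[type[is.na(attenuation)]]
  abort_if(any(attenuation < 0 | attenuation > 1),
           "attenuation must be within [0, 1]")
  abort_if(any(type == "central" & attenuation >= 0.3),
           "central events should retain < 0.3 of amplitude")
  abort_if(any(type == "obstructive" & attenuation >= 0.6),
           "obstructive events should retain < 0.6 of amplitude")
  ev <- tibble::tibble(start = as.numeric(start),
                       duration = as.numeric(duration),
                       type = as.character(type),
                       attenuation = attenuation)
  ev <- dplyr::arrange(ev, .data$start)
  ends <- ev$start + ev$duration
  abort_if(any(ev$start[-1] < ends[-n]), "apnea events must not overlap")
  ev
}

#' Depth-sensor acquisition profiles
#'
#' Named profiles reproduce the frame-rate behaviour of the consumer depth
#' sensors commonly used for contact-free breathing monitoring: mean FPS,
#' observed FPS range, and a jitter model (`none` for an exact uniform
#' grid, `uniform` for bounded gap jitter, `heavy_tail` for mostly-fast
#' frames with occasional long stalls, as a skeletal-tracking sensor
#' produces).
#'
#' @param name one of `"kinect2"`, `"sr300"`, `"r200"`, `"d415"`, `"d435"`,
#'   or `"custom"`.
#' @param mean_fps mean frame rate (frames/s), in `[3, 90]`.
#' @param fps_range numeric length-2, the declared min/max instantaneous
#'   FPS.
#' @param fps_jitter `"none"`, `"uniform"` or `"heavy_tail"`.
#' @param rows,cols rendered frame size in pixels. The default is compact:
#'   the ROI mean is the only statistic the workflow consumes, so frames
#'   need only be large enough to hold a realistic ROI.
#' @return A list of class `sensor_profile`.
#' @export
#' @examples
#' sensor_profile("kinect2")
#' sensor_profile("custom", mean_fps = 10, fps_range = c(8, 12))
sensor_profile <- function(name = c("kinect2", "sr300", "r200", "d415",
                                    "d435", "custom"),
                           mean_fps = NULL, fps_range = NULL,
                           fps_jitter = NULL, rows = 16L, cols = 16L) {
  name <- match.arg(name)
  presets <- list(
    kinect2 = list(mean_fps = 20, fps_range = c(3, 29), fps_jitter = "heavy_tail"),
    sr300   = list(mean_fps = 35, fps_range = c(25, 45), fps_jitter = "uniform"),
    r200    = list(mean_fps = 33, fps_range = c(25, 43), fps_jitter = "uniform"),
    d415    = list(mean_fps = 30, fps_range = c(27, 33), fps_jitter = "uniform"),
    d435    = list(mean_fps = 30, fps_range = c(25, 37), fps_jitter = "uniform"),
    custom  = list(mean_fps = 30, fps_range = c(25, 35), fps_jitter = "uniform")
  )
  p <- presets[[name]]
  if (!is.null(mean_fps)) p$mean_fps <- mean_fps
  if (!is.null(fps_range)) p$fps_range <- fps_range
  if (!is.null(fps_jitter)) {
    p$fps_jitter <- match.arg(fps_jitter, c("none", "uniform", "heavy_tail"))
  }
  abort_if(p$mean_fps < 3 || p$mean_fps > 90, "mean_fps must be within [3, 90]")
  abort_if(rows < 1 || cols < 1, "frame size must be at least 1x1")
  abort_if(length(p$fps_range) != 2 || p$fps_range[1] <= 0 ||
             p$fps_range[1] >= p$fps_range[2],
           "fps_range must be increasing and positive")
  structure(list(name = name, mean_fps = p$mean_fps,
                 fps_range = as.numeric(p$fps_range),
                 fps_jitter = p$fps_jitter,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "sensor_profile")
}

#' Simulate frame timestamps with jittered frame rate
#'
#' Generates strictly increasing acquisition times over `[0, duration)`.
#' With `fps_jitter = "none"` the grid is exactly uniform at `mean_fps`.
#' With `"uniform"`, frame gaps are uniform around `1/mean_fps`, bounded so
#' instantaneous FPS stays within the sensor's declared range. With
#' `"heavy_tail"`, frames are mostly faster than the mean with occasional
#' gap multipliers (x5, x10), reproducing the stalls of a sensor whose
#' depth output competes with other on-device processing; the empirical
#' mean FPS stays at `mean_fps` while instantaneous FPS excursions bracket
#' the declared range.
#'
#' @param sensor a [sensor_profile()].
#' @param duration recording length in seconds (> 0).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return Numeric vector of timestamps in seconds.
#' @export
jitter_timestamps <- function(sensor, duration, seed = 1L) {
  abort_if(!inherits(sensor, "sensor_profile"), "sensor must be a sensor_profile")
  abort_if(!is.numeric(duration) || duration <= 0, "duration must be positive")
  mfps <- sensor$mean_fps
  if (sensor$fps_jitter == "none") {
    n <- floor(duration * mfps + 1e-9)
    return((seq_len(n) - 1) / mfps)
  }
  n_max <- ceiling(duration * mfps * 3) + 10L
  gaps <- withr::with_seed(seed, {
    if (sensor$fps_jitter == "uniform") {
      g0 <- 1 / mfps
      w <- 0.9 * min(g0 - 1 / sensor$fps_range[2], 1 / sensor$fps_range[1] - g0)
      abort_if(w <= 0, "mean_fps must lie strictly inside fps_range for uniform jitter")
      runif(n_max, g0 - w, g0 + w)
    } else {
      # heavy tail: fast base gaps, occasional x5 / x10 stalls; multiplier
      # mix chosen so the expected gap stays 1/mean_fps
      p <- 0.04
      e_mult <- 1 + p * ((5 - 1) + (10 - 1)) / 2
      g0 <- 1 / (mfps * e_mult)
      base <- runif(n_max, 0.8 * g0, 1.2 * g0)
      u <- runif(n_max)
      mult <- ifelse(u < p / 2, 5, ifelse(u < p, 10, 1))
      base * mult
    }
  })
  ts <- cumsum(c(0, gaps))
  ts[ts < duration]
}

#' Synthesize a chest-displacement waveform
#'
#' Renders the displacement (depth units, positive = chest toward the
#' sensor) on the supplied timestamps:
#' `amplitude * a(t) * sin(2*pi*rate*t) + drift(t) + noise`, where the
#' attenuation factor `a(t)` is 1 outside apnea events and event-specific
#' inside: central events scale the oscillation by the event's
#' `attenuation`; obstructive events additionally modulate the residual
#' effort with a slow 0.05 Hz (out-of-band) envelope; mixed events ramp
#' from full cessation into attenuated effort.
#'
#' @param profile a [breathing_profile()]. `profile$noise_sd` is applied
#'   here as waveform-level additive noise (use 0 when the noise is to be
#'   added per pixel at render time instead).
#' @param events an [apnea_events()] table (possibly empty).
#' @param duration recording length (s); events must lie within
#'   `[0, duration]`.
#' @param timestamps strictly increasing sample times (s).
#' @param seed integer seed for noise and drift.
#' @return A tibble with columns `t`, `displacement` and attribute
#'   `attenuation` (the factor `a(t)` actually applied).
#' @export
synthesize_waveform <- function(profile, events = apnea_events(), duration,
                                timestamps, seed = 1L) {
  abort_if(!inherits(profile, "breathing_profile"),
           "profile must be a breathing_profile")
  events <- if (nrow(events) > 0) as_event_table(events) else events
  check_increasing(timestamps)
  if (nrow(events) > 0) {
    abort_if(any(events$start < 0 | events$start + events$duration > duration),
             "events must lie within [0, duration]")
    ends <- events$start + events$duration
    abort_if(any(events$start[-1] < ends[-nrow(events)]),
             "apnea events must not overlap")
  }
  t <- as.numeric(timestamps)
  a <- rep(1, length(t))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      inside <- t >= ev$start & t <= ev$start + ev$duration
      if (!any(inside)) next
      tt <- t[inside] - ev$start
      a[inside] <- switch(
        ev$type,
        central = ev$attenuation,
        obstructive = ev$attenuation *
          (1 + 0.4 * sin(2 * pi * 0.05 * tt)),
        mixed = ev$attenuation * pmin(1, 2 * tt / ev$duration)
      )
    }
  }
  disp <- profile$amplitude * a * sin(2 * pi * profile$rate * t)
  noise <- withr::with_seed(seed, {
    eps <- if (profile$noise_sd > 0) rnorm(length(t), 0, profile$noise_sd) else numeric(length(t))
    drift <- if (profile$drift_sd > 0) {
      cumsum(c(0, rnorm(length(t) - 1, 0, profile$drift_sd * sqrt(diff(t)))))
    } else numeric(length(t))
    eps + drift
  })
  out <- tibble::tibble(t = t, displacement = disp + noise)
  attr(out, "attenuation") <- a
  out
}

# accept either apnea_events() output or a bare data frame
as_event_table <- function(events) {
  abort_if(!is.data.frame(events), "events must be a data frame")
  abort_if(!all(c("start", "duration", "type") %in% names(events)),
           "events need columns start, duration, type")
  if (!"attenuation" %in% names(events)) events$attenuation <- NA_real_
  apnea_events(events$start, events$duration, events$type,
               events$attenuation, check_duration = FALSE)
}

#' Render a displacement waveform into a depth-frame sequence
#'
#' Inside the ROI every pixel's depth is `baseline - displacement` plus
#' iid per-pixel Gaussian noise; outside the ROI it is `baseline` plus
#' noise only. Values are rounded to whole depth units (1 mm quantization,
#' matching consumer-sensor depth error scale) and clipped to unsigned
#' 16-bit range.
#'
#' @param waveform numeric displacement per frame (depth units), or the
#'   tibble returned by [synthesize_waveform()].
#' @param timestamps per-frame times (s), same length as the waveform.
#' @param sensor a [sensor_profile()] giving the frame size.
#' @param roi `c(row_start, row_stop, col_start, col_stop)`, 1-based
#'   inclusive.
#' @param baseline mean chest distance (depth units).
#' @param noise_sd per-pixel additive noise sd (depth units).
#' @param seed integer seed.
#' @return A [depth_sequence()].
#' @export
render_depth_sequence <- function(waveform, timestamps = NULL, sensor,
                                  roi = NULL, baseline = 1000, noise_sd = 0,
                                  seed = 1L) {
  if (is.data.frame(waveform)) {
    if (is.null(timestamps)) timestamps <- waveform$t
    waveform <- waveform$displacement
  }
  abort_if(length(waveform) != length(timestamps),
           "waveform must be aligned to timestamps")
  check_increasing(timestamps)
  R <- sensor$rows; S <- sensor$cols
  if (is.null(roi)) {
    roi <- c(max(1L, R %/% 4L), R - R %/% 4L, max(1L, S %/% 4L), S - S %/% 4L)
  }
  roi <- as.integer(roi)
  abort_if(roi[1] < 1 || roi[2] > R || roi[3] < 1 || roi[4] > S ||
             roi[1] > roi[2] || roi[3] > roi[4],
           "roi must be a non-empty rectangle inside the frame bounds")
  nf <- length(waveform)
  frames <- array(0, dim = c(R, S, nf))
  frames[] <- baseline
  roi_rows <- roi[1]:roi[2]; roi_cols <- roi[3]:roi[4]
  disp <- array(0, dim = c(R, S, nf))
  disp[roi_rows, roi_cols, ] <- rep(waveform, each = length(roi_rows) * length(roi_cols))
  frames <- frames - disp
  if (noise_sd > 0) {
    frames <- frames + withr::with_seed(seed, rnorm(length(frames), 0, noise_sd))
  }
  frames <- round(pmin(pmax(frames, 0), 65535))
  storage.mode(frames) <- "integer"
  depth_sequence(frames, timestamps, roi)
}

#' Simulate a complete synthetic depth recording
#'
#' Convenience wrapper: draws jittered frame timestamps for the sensor,
#' synthesizes the (noiseless) chest-displacement waveform with the given
#' apnea schedule, and renders it into depth frames with per-pixel sensor
#' noise taken from `profile$noise_sd`. The returned ground truth
#' (waveform and annotations) is directly consumable by the evaluation
#' functions.
#'
#' @inheritParams synthesize_waveform
#' @param sensor a [sensor_profile()].
#' @param roi ROI rectangle; default centers it in the frame.
#' @param seed integer seed governing timestamps, drift and pixel noise.
#' @return A list with elements `sequence` ([depth_sequence()]),
#'   `waveform` (tibble `t`, `displacement`), `annotations` (tibble
#'   `start_s`, `end_s`, `type`), `profile`, `sensor`.
#' @export
#' @examples
#' rec <- simulate_recording(duration = 60, seed = 7)
#' rec$sequence
simulate_recording <- function(duration = 300,
                               profile = breathing_profile(),
                               events = apnea_events(),
                               sensor = sensor_profile("r200"),
                               roi = NULL, seed = 1L) {
  ts <- jitter_timestamps(sensor, duration, seed = seed)
  wf_profile <- profile
  wf_profile$noise_sd <- 0  # noise enters per pixel at render time
  wf <- synthesize_waveform(wf_profile, events, duration, ts, seed = seed + 1L)
  seq <- render_depth_sequence(wf$displacement, ts, sensor, roi = roi,
                               baseline = profile$baseline_depth,
                               noise_sd = profile$noise_sd, seed = seed + 2L)
  ann <- if (nrow(events) > 0) {
    ev <- as_event_table(events)
    tibble::tibble(start_s = ev$start, end_s = ev$start + ev$duration,
                   type = ev$type)
  } else {
    tibble::tibble(start_s = numeric(), end_s = numeric(), type = character())
  }
  list(sequence = seq, waveform = wf, annotations = ann,
       profile = profile, sensor = sensor)
}

#' Draw a random, non-overlapping apnea schedule
#'
#' Places `n_events` events uniformly at random subject to a minimum
#' separation, with durations uniform in `duration_range` and types drawn
#' from `types`. Separation defaults to 60 s so every event remains
#' usable for training-segment construction (25 s margins plus the 25 s
#' proximity exclusion).
#'
#' @param duration record length (s).
#' @param n_events number of events.
#' @param types candidate types to sample from.
#' @param duration_range numeric length-2, event duration bounds (s).
#' @param attenuation per-type attenuation passed to [apnea_events()];
#'   `NA` uses type defaults.
#' @param min_separation minimum gap between consecutive events and record
#'   edges (s).
#' @param seed integer seed.
#' @return An [apnea_events()] tibble.
#' @export
sample_apnea_schedule <- function(duration, n_events = 4,
                                  types = c("central", "obstructive"),
                                  duration_range = c(12, 37),
                                  attenuation = NA_real_,
                                  min_separation = 60, seed = 1L) {
  abort_if(n_events < 1, "n_events must be at least 1")
  slot <- (duration - 2 * min_separation) / n_events
  abort_if(slot < max(duration_range) + min_separation,
           "record too short for the requested schedule")
  withr::with_seed(seed, {
    durs <- runif(n_events, duration_range[1], duration_range[2])
    typ <- sample(types, n_events, replace = TRUE)
    starts <- vapply(seq_len(n_events), function(i) {
      lo <- min_separation + (i - 1) * slot
      hi <- min_separation + i * slot - durs[i] - min_separation
      runif(1, lo, max(lo, hi))
    }, numeric(1))
    apnea_events(starts, durs, typ, attenuation)
  })
}
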