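# Shared fixtures, all generated in code.

# uniform 10 Hz breathing_signal from an expression in t
make_signal <- function(values, fs = 10, t0 = 0) {
  t <- t0 + (seq_along(values) - 1) / fs
  out <- tibble::tibble(t = t, value = values)
  attr(out, "fs") <- fs
  class(out) <- c("breathing_signal", class(out))
  out
}

# a tiny random depth sequence for oracle comparisons
random_depth_sequence <- function(n_frames = 5, rows = 4, cols = 4,
                                  roi = c(1, rows, 1, cols), seed = 1) {
  frames <- withr::with_seed(seed, {
    array(sample.int(2000L, rows * cols * n_frames, replace = TRUE) + 500L,
          dim = c(rows, cols, n_frames))
  })
  depth_sequence(frames, timestamps = seq_len(n_frames) / 30, roi = roi)
}

# two well-separated Gaussian feature blobs
blob_features <- function(n_per = 100, centers = list(c(-2, -2), c(2, 2)),
                          sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(centers, function(ctr) {
      cbind(rnorm(n_per, ctr[1], sd), rnorm(n_per, ctr[2], sd))
    }))
    tibble::tibble(domfreq = pts[, 1], std = pts[, 2],
                   blob = rep(seq_along(centers), each = n_per))
  })
}

# 10 Hz waveform record with events, bypassing depth rendering
waveform_record <- function(duration = 300, rate = 0.25, amplitude = 1,
                            noise_sd = 0.02, events = NULL, seed = 1) {
  if (is.null(events)) {
    events <- apnea_events(start = c(80, 200), duration = c(20, 20),
                           type = c("central", "central"), attenuation = 0)
  }
  prof <- breathing_profile(rate = rate, amplitude = amplitude,
                            noise_sd = noise_sd)
  t <- seq(0, duration, by = 0.1)
  wf <- synthesize_waveform(prof, events, duration, t, seed = seed)
  sig <- make_signal(wf$displacement)
  ann <- tibble::tibble(start_s = events$start,
                        end_s = events$start + events$duration,
                        type = events$type)
  list(signal = sig, annotations = ann, events = events)
}
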