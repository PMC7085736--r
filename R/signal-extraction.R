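#' Mean frame-difference motion signal
#'
#' For each pair of consecutive depth frames the mean change over the ROI
#' is computed:
#' `d(n) = (1/(R*S)) * sum_ij (D[n+1](i,j) - D[n](i,j))`, n = 0..N-2,
#' giving a raw motion series of length N-1. Each difference sample
#' carries the timestamp of the later frame.
#'
#' @param seq a [depth_sequence()] with at least two frames.
#' @return A tibble with columns `t`, `value` (depth units) and attribute
#'   `n_frames`.
#' @export
frame_difference_signal <- function(seq) {
  abort_if(!inherits(seq, "depth_sequence"), "seq must be a depth_sequence")
  nf <- n_frames(seq)
  abort_if(nf < 2, "need at least two frames to form differences")
  roi <- seq$roi
  sub <- seq$frames[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  means <- colMeans(sub, dims = 2)
  out <- tibble::tibble(t = seq$timestamps[-1], value = diff(means))
  attr(out, "n_frames") <- nf
  out
}

#' Design a zero-DC windowed-sinc band-pass FIR filter
#'
#' A Hamming-windowed sinc band-pass of `m` taps is designed for the
#' breathing band (defaults 0.01--1 Hz, wide enough for adult and elderly
#' breathing rates while rejecting the signal mean and high-frequency
#' sensor noise), then the coefficients are shifted by their mean so they
#' sum exactly to zero: the filter rejects DC exactly regardless of tap
#' count.
#'
#' @param m number of taps (odd, so the filter is a linear-phase type I
#'   FIR). The default 1001 gives the low 0.01 Hz edge a usable transition
#'   at a 30 Hz design rate.
#' @param f1,f2 low and high cut-off frequencies (Hz), `f1 < f2 <
#'   design_fs/2`.
#' @param design_fs sampling rate the coefficients are designed for (Hz).
#' @return A list of class `filter_spec` with elements `coefficients`,
#'   `order` (taps), `f1`, `f2`, `design_fs`.
#' @export
#' @examples
#' spec <- design_bandpass(m = 501, f1 = 0.01, f2 = 1, design_fs = 30)
#' sum(spec$coefficients)  # exactly 0
design_bandpass <- function(m = 1001, f1 = 0.01, f2 = 1, design_fs = 30) {
  abort_if(m %% 2 == 0, "tap count m must be odd")
  abort_if(!(f1 > 0 && f1 < f2 && f2 < design_fs / 2),
           "cut-offs must satisfy 0 < f1 < f2 < design_fs/2")
  b <- signal::fir1(m - 1, c(f1, f2) / (design_fs / 2), type = "pass")
  b <- as.numeric(b)
  b <- b - mean(b)
  structure(list(coefficients = b, order = as.integer(m),
                 f1 = f1, f2 = f2, design_fs = design_fs),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %d-tap band-pass %.3g-%.3g Hz (design fs %g Hz), sum(b) = %.2e\n",
              x$order, x$f1, x$f2, x$design_fs, sum(x$coefficients)))
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' Evaluates `H(f) = sum_k b(k) exp(-2i*pi*f*k/fs)` at the requested
#' frequencies.
#'
#' @param spec a [design_bandpass()] filter, or a numeric coefficient
#'   vector.
#' @param f frequencies in Hz.
#' @param fs sampling rate (defaults to the spec's design rate).
#' @return A tibble with columns `f`, `magnitude`.
#' @export
filter_response <- function(spec, f, fs = NULL) {
  b <- if (inherits(spec, "filter_spec")) spec$coefficients else as.numeric(spec)
  if (is.null(fs)) fs <- if (inherits(spec, "filter_spec")) spec$design_fs else
    stop("fs required when spec is a bare coefficient vector", call. = FALSE)
  k <- seq_along(b) - 1
  mag <- vapply(f, function(ff) Mod(sum(b * exp(-2i * pi * ff * k / fs))),
                numeric(1))
  tibble::tibble(f = f, magnitude = mag)
}

# reflective extension: mirror about the end sample without repeating it;
# recycles the reflection if n exceeds the available signal
reflect_pad <- function(x, n, side = c("head", "tail")) {
  side <- match.arg(side)
  if (n == 0) return(numeric(0))
  body <- if (side == "head") rev(x[-1]) else rev(x[-length(x)])
  if (length(body) == 0) body <- x
  while (length(body) < n) body <- c(body, rev(body))
  if (side == "head") tail(body, n) else head(body, n)
}

#' Apply an FIR filter to a motion signal
#'
#' Convolves the signal with the filter coefficients after reflective
#' padding, so the output has the same length as the input. By default
#' the linear-phase group delay of `(m-1)/2` samples is compensated
#' (`align = "centered"`): output sample `n` is the filter centered on
#' input sample `n`, keeping event timing aligned with annotations.
#' `align = "causal"` instead pads `m-1` samples at the head only and
#' discards the warm-up, i.e. the strictly causal running convolution.
#'
#' @param signal a data frame with columns `t`, `value`, or a numeric
#'   vector.
#' @param spec a [design_bandpass()] filter spec (or bare coefficient
#'   vector).
#' @param align `"centered"` (group-delay compensated, default) or
#'   `"causal"`.
#' @return Same shape as the input: a tibble `t`, `value`, or a numeric
#'   vector.
#' @export
apply_fir <- function(signal, spec, align = c("centered", "causal")) {
  align <- match.arg(align)
  b <- if (inherits(spec, "filter_spec")) spec$coefficients else as.numeric(spec)
  vec_in <- !is.data.frame(signal)
  x <- if (vec_in) as.numeric(signal) else as_signal_df(signal)$value
  abort_if(length(x) < 1, "signal must have at least one sample")
  m <- length(b)
  y <- if (m == 1) {
    b * x
  } else if (align == "causal") {
    xp <- c(reflect_pad(x, m - 1, "head"), x)
    yy <- stats::filter(xp, b, method = "convolution", sides = 1)
    as.numeric(yy[m:length(xp)])
  } else {
    h <- (m - 1) %/% 2
    xp <- c(reflect_pad(x, h, "head"), x, reflect_pad(x, h, "tail"))
    yy <- stats::filter(xp, b, method = "convolution", sides = 1)
    as.numeric(yy[(m):(m - 1 + length(x))])
  }
  if (vec_in) y else {
    out <- tibble::tibble(t = signal$t, value = y)
    attributes(out)$fs <- attr(signal, "fs", exact = TRUE)
    out
  }
}

#' Savitzky-Golay smoothing
#'
#' Smooths the series with a second-order (by default) Savitzky-Golay
#' filter: each output sample is the centre value of a local least-squares
#' polynomial fit over `window` samples. Length is preserved; near the
#' ends the fit uses the partial startup/closing windows, so polynomials
#' up to `polyorder` are reproduced exactly everywhere.
#'
#' @param signal data frame with `t`, `value`, or numeric vector.
#' @param window odd window length in samples (> `polyorder`).
#' @param polyorder polynomial order of the local fit (default 2).
#' @return Same shape as the input.
#' @export
savgol_smooth <- function(signal, window = 11, polyorder = 2) {
  abort_if(window %% 2 == 0, "window must be odd")
  abort_if(window <= polyorder, "window must exceed polyorder")
  vec_in <- !is.data.frame(signal)
  x <- if (vec_in) as.numeric(signal) else as_signal_df(signal)$value
  abort_if(length(x) < window, "signal shorter than the smoothing window")
  y <- as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
  if (vec_in) y else {
    out <- tibble::tibble(t = signal$t, value = y)
    attributes(out)$fs <- attr(signal, "fs", exact = TRUE)
    out
  }
}

#' Resample an irregular series to a uniform rate by cubic spline
#'
#' Fits a cubic interpolating spline through the (timestamp, value) knots
#' and evaluates it on the uniform grid `t0, t0 + 1/fs, ...` up to the
#' last timestamp (no extrapolation). 10 Hz is the canonical rate,
#' matching polysomnography respiration channels.
#'
#' @param signal data frame with columns `t`, `value` (or values +
#'   `timestamps` given separately).
#' @param timestamps optional numeric vector when `signal` is a bare
#'   numeric vector.
#' @param fs target sampling rate in Hz (default 10).
#' @return A `breathing_signal`: tibble with columns `t`, `value` and
#'   attribute `fs`.
#' @export
resample_uniform <- function(signal, timestamps = NULL, fs = 10) {
  if (is.data.frame(signal)) {
    signal <- as_signal_df(signal)
    x <- signal$value; t <- signal$t
  } else {
    x <- as.numeric(signal); t <- as.numeric(timestamps)
  }
  abort_if(length(x) != length(t), "values and timestamps must align")
  abort_if(length(x) < 4, "need at least 4 points for cubic spline resampling")
  abort_if(anyDuplicated(t) > 0, "duplicate timestamps")
  check_increasing(t)
  abort_if(anyNA(x) || any(!is.finite(x)), "signal values must be finite")
  f <- splinefun(t, x, method = "fmm")
  grid <- seq(t[1], t[length(t)] + 1e-9, by = 1 / fs)
  grid <- grid[grid <= t[length(t)] + 1e-9]
  out <- tibble::tibble(t = grid, value = f(grid))
  attr(out, "fs") <- fs
  class(out) <- c("breathing_signal", class(out))
  out
}

#' Depth frames to uniformly sampled breathing signal
#'
#' Runs the full extraction chain: ROI frame differencing, band-pass FIR
#' filtering (applied at the native frame rate, treating samples as
#' uniform at the mean FPS), optional Savitzky-Golay smoothing, then cubic
#' spline resampling to a uniform rate. The filter is designed at the
#' sequence's mean FPS.
#'
#' @param seq a [depth_sequence()].
#' @param fs output sampling rate (Hz), default 10.
#' @param f1,f2 band-pass cut-offs (Hz).
#' @param taps FIR tap count (odd).
#' @param smooth apply Savitzky-Golay smoothing (default TRUE).
#' @param sg_window Savitzky-Golay window (samples, odd).
#' @param filter_first if `TRUE` (default) filter at the native rate then
#'   resample; if `FALSE`, resample first and filter on the uniform grid.
#' @return A `breathing_signal` tibble (`t`, `value`, attribute `fs`).
#' @export
#' @examples
#' rec <- simulate_recording(duration = 60, seed = 3)
#' sig <- extract_breathing_signal(rec$sequence)
#' head(sig)
extract_breathing_signal <- function(seq, fs = 10, f1 = 0.01, f2 = 1,
                                     taps = 1001, smooth = TRUE,
                                     sg_window = 11, filter_first = TRUE) {
  raw <- frame_difference_signal(seq)
  mean_fps <- (n_frames(seq) - 1) / diff(range(seq$timestamps))
  filt_once <- function(df, design_fs) {
    spec <- design_bandpass(m = taps, f1 = f1, f2 = f2, design_fs = design_fs)
    out <- apply_fir(df, spec)
    if (smooth && nrow(out) >= sg_window) out <- savgol_smooth(out, window = sg_window)
    out
  }
  if (filter_first) {
    resample_uniform(filt_once(raw, design_fs = mean_fps), fs = fs)
  } else {
    filt_once(resample_uniform(raw, fs = fs), design_fs = fs)
  }
}
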