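#' One-sided amplitude spectrum
#'
#' Magnitude of the discrete Fourier transform of the mean-removed,
#' Hann-windowed signal, zero-padded to at least 8x the signal length
#' (next power of two). Zero-padding interpolates the spectrum so peak
#' positions can be read off finely; it does not add resolution beyond
#' `fs / n`.
#'
#' @param signal a `breathing_signal` (tibble `t`, `value` with `fs`
#'   attribute) or numeric vector.
#' @param fs sampling rate in Hz (required for bare vectors).
#' @param window `"hann"` (default) or `"none"` (raw periodogram).
#' @return A tibble of class `resp_spectrum` with columns `frequency`
#'   (0 .. fs/2, ascending) and `magnitude`.
#' @export
#' @examples
#' t <- seq(0, 60, by = 0.1)
#' sp <- amplitude_spectrum(sin(2 * pi * 0.25 * t), fs = 10)
#' sp$frequency[which.max(sp$magnitude)]
amplitude_spectrum <- function(signal, fs = NULL, window = c("hann", "none")) {
  window <- match.arg(window)
  if (is.data.frame(signal)) {
    fs <- signal_fs(signal)
    x <- as_signal_df(signal)$value
  } else {
    x <- as.numeric(signal)
    abort_if(is.null(fs), "fs required for a bare numeric signal")
  }
  n <- length(x)
  abort_if(n < 16, "need at least 16 samples for a spectrum")
  x <- x - mean(x)
  if (window == "hann") {
    x <- x * hann_window(n)
  }
  nfft <- 2^ceiling(log2(8 * n))
  X <- fft(c(x, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1)
  out <- tibble::tibble(
    frequency = (half - 1) * fs / nfft,
    magnitude = Mod(X[half])
  )
  attr(out, "fs") <- fs
  attr(out, "n_signal") <- n
  class(out) <- c("resp_spectrum", class(out))
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Dominant frequency within a band
#'
#' Frequency of the maximum spectral magnitude restricted to `band`
#' (default 0.05--1 Hz: above posture drift, below the band-pass high
#' cut-off). Ties break toward the lower frequency.
#'
#' @param spectrum a [amplitude_spectrum()] tibble.
#' @param band numeric length-2 frequency band (Hz) within the spectrum
#'   range.
#' @return Dominant frequency in Hz (scalar).
#' @export
dominant_frequency <- function(spectrum, band = c(0.05, 1)) {
  abort_if(!is.data.frame(spectrum) ||
             !all(c("frequency", "magnitude") %in% names(spectrum)),
           "spectrum must have columns frequency, magnitude")
  abort_if(band[1] >= band[2], "band must be increasing")
  keep <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  abort_if(!any(keep), "band contains no spectral bins")
  f <- spectrum$frequency[keep]
  m <- spectrum$magnitude[keep]
  f[which.max(m)]  # which.max returns the first (= lowest-frequency) maximum
}

#' Overlapping analysis windows
#'
#' Divides the signal into windows of `window_s` seconds advancing by
#' `step_s` seconds. With the default 0.1 s step at 10 Hz every window
#' centre falls on a signal sample, realising a 10 Hz classification
#' grid. Window count is `floor((T - window_s)/step_s) + 1`.
#'
#' @param signal a `breathing_signal` tibble.
#' @param window_s window length in seconds (default 10 s, at least two
#'   breath cycles at the slowest adult rate).
#' @param step_s window step in seconds (default 0.1 s).
#' @return A tibble with columns `window_id`, `start_idx`, `center_idx`,
#'   `t_center`; attributes `fs`, `wlen` (window length in samples) and
#'   `signal` (the source values) let features be computed without
#'   materialising every slice.
#' @export
sliding_windows <- function(signal, window_s = 10, step_s = 0.1) {
  signal <- as_signal_df(signal)
  fs <- signal_fs(signal)
  abort_if(step_s <= 0 || window_s <= 0, "window and step must be positive")
  abort_if(step_s > window_s, "step must not exceed the window length")
  n <- nrow(signal)
  wlen <- round(window_s * fs)
  wstep <- max(1L, round(step_s * fs))
  abort_if(wlen > n, "window longer than the signal")
  starts <- seq.int(1L, n - wlen + 1L, by = wstep)
  centers <- starts + wlen %/% 2L
  centers <- pmin(centers, n)
  out <- tibble::tibble(
    window_id = seq_along(starts),
    start_idx = as.integer(starts),
    center_idx = as.integer(centers),
    t_center = signal$t[centers]
  )
  attr(out, "fs") <- fs
  attr(out, "wlen") <- as.integer(wlen)
  attr(out, "values") <- signal$value
  attr(out, "t") <- signal$t
  class(out) <- c("resp_windows", class(out))
  out
}

#' Per-window classifier features
#'
#' For every window: the dominant frequency of the window's amplitude
#' spectrum (Hann window, zero-padded, searched within `band`) and the
#' sample standard deviation (n-1 denominator). Z-scoring parameters
#' (mean, sd of each feature over the matrix) are computed and stored in
#' the `scaling` attribute but the features themselves stay in original
#' units.
#'
#' @param windows output of [sliding_windows()].
#' @param band dominant-frequency search band (Hz).
#' @param window `"hann"` or `"none"`, the spectral taper.
#' @return A tibble of class `resp_features` with columns `t_center`,
#'   `domfreq`, `std`; attribute `scaling` is a tibble (feature, mean, sd).
#' @export
#' @examples
#' rec <- simulate_recording(duration = 120, seed = 5)
#' sig <- extract_breathing_signal(rec$sequence)
#' feats <- sliding_windows(sig) |> extract_features()
#' head(feats)
extract_features <- function(windows, band = c(0.05, 1),
                             window = c("hann", "none")) {
  window <- match.arg(window)
  abort_if(!inherits(windows, "resp_windows"),
           "windows must come from sliding_windows()")
  fs <- attr(windows, "fs", exact = TRUE)
  wlen <- attr(windows, "wlen", exact = TRUE)
  x <- attr(windows, "values", exact = TRUE)
  abort_if(wlen < 16, "windows must contain at least 16 samples")
  nfft <- 2^ceiling(log2(8 * wlen))
  freqs <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  keep <- which(freqs >= band[1] & freqs <= band[2])
  abort_if(length(keep) == 0, "band contains no spectral bins")
  taper <- if (window == "hann") hann_window(wlen) else rep(1, wlen)

  starts <- windows$start_idx
  nwin <- length(starts)
  domfreq <- numeric(nwin)
  stds <- numeric(nwin)
  block <- 2000L
  for (b0 in seq.int(1L, nwin, by = block)) {
    idx <- b0:min(b0 + block - 1L, nwin)
    # wlen x nblock matrix of window slices
    M <- vapply(starts[idx], function(s) x[s:(s + wlen - 1L)], numeric(wlen))
    M <- matrix(M, nrow = wlen)
    stds[idx] <- apply(M, 2, sd)
    Mc <- sweep(M, 2, colMeans(M)) * taper
    Z <- rbind(Mc, matrix(0, nfft - wlen, ncol(Mc)))
    mag <- Mod(mvfft(Z)[keep, , drop = FALSE])
    domfreq[idx] <- freqs[keep][max.col(t(mag), ties.method = "first")]
  }
  out <- tibble::tibble(t_center = windows$t_center,
                        domfreq = domfreq, std = stds)
  attr(out, "scaling") <- feature_scaling(as.matrix(out[feature_cols]),
                                          fs = fs, wlen = wlen)
  attr(out, "wlen") <- wlen
  attr(out, "center_idx") <- windows$center_idx
  attr(out, "fs") <- fs
  class(out) <- c("resp_features", class(out))
  out
}
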