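# EMG feature chain: zero-phase high-pass, Hann-windowed framing, FFT,
# and mean band power over eight 50-Hz bands per channel.

#' Feature-extraction configuration
#'
#' @param frame_size analysis frame length in samples (power of two).
#' @param hop frame advance in samples (`0 < hop <= frame_size`).
#' @param n_bands number of equal-width frequency bands.
#' @param f_max upper edge of the banded range in Hz; bins at or above it are
#'   discarded.
#' @param highpass_cutoff digital high-pass cutoff in Hz (0 disables).
#' @param log_compress apply `log(1 + x)` to the band powers.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(frame_size = 256, hop = 128, n_bands = 8,
                           f_max = 400, highpass_cutoff = 50,
                           log_compress = FALSE) {
  frame_size <- as.integer(frame_size)
  if (frame_size < 2 || bitwAnd(frame_size, frame_size - 1L) != 0L) {
    stop("frame_size must be a power of two", call. = FALSE)
  }
  hop <- as.integer(hop)
  if (hop < 1 || hop > frame_size) {
    stop("hop must satisfy 0 < hop <= frame_size", call. = FALSE)
  }
  if (n_bands < 1 || f_max <= 0) {
    stop("n_bands and f_max must be positive", call. = FALSE)
  }
  structure(list(frame_size = frame_size, hop = hop,
                 n_bands = as.integer(n_bands), f_max = f_max,
                 highpass_cutoff = highpass_cutoff,
                 log_compress = isTRUE(log_compress)),
            class = "feature_config")
}

#' Periodic Hann window
#'
#' @param n window length in samples.
#' @return Numeric vector `0.5 * (1 - cos(2*pi*k/n))`, k = 0..n-1.
#' @export
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
}

#' Zero-phase digital high-pass filter
#'
#' 4th-order Butterworth applied forward-backward per channel
#' (zero lag, suited to offline analysis). Output length equals input length.
#'
#' @param stream an [emg_stream()].
#' @param cutoff cutoff frequency in Hz; must be below Nyquist.
#' @return The filtered `emg_stream`.
#' @export
highpass_filter <- function(stream, cutoff = 50) {
  stopifnot(inherits(stream, "emg_stream"))
  fs <- stream$sample_rate
  if (cutoff >= fs / 2) stop("cutoff must be below Nyquist", call. = FALSE)
  if (cutoff <= 0) return(stream)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  out <- stream
  for (ch in seq_len(nrow(stream$samples))) {
    out$samples[ch, ] <- signal::filtfilt(bf, stream$samples[ch, ])
  }
  out
}

#' Magnitude-squared spectrum of one windowed frame
#'
#' Applies a periodic Hann window, takes the FFT, and returns `|X_k|^2` for
#' the non-negative frequency bins k = 0..frame_size/2 (bin width
#' `sample_rate / frame_size`).
#'
#' @param frame numeric vector of exactly `frame_size` samples.
#' @param sample_rate sampling frequency in Hz.
#' @param frame_size expected frame length (defaults to `length(frame)`).
#' @return Numeric vector of length `frame_size/2 + 1`.
#' @export
spectral_frame <- function(frame, sample_rate, frame_size = length(frame)) {
  if (length(frame) != frame_size) {
    stop("frame must have exactly frame_size samples", call. = FALSE)
  }
  n <- length(frame)
  x <- stats::fft(frame * hann_window(n))
  Mod(x[seq_len(n %/% 2 + 1)])^2
}

#' Mean band powers over equal-width bands
#'
#' Band j covers `[j*f_max/n_bands, (j+1)*f_max/n_bands)` Hz; each value is
#' the mean of `|X_k|^2` over the bins whose center frequency falls in the
#' band. Bins with `f >= f_max` are ignored.
#'
#' @param spectrum magnitude-squared spectrum from [spectral_frame()]
#'   (bins 0..N/2).
#' @param sample_rate sampling frequency in Hz.
#' @param n_bands number of bands.
#' @param f_max upper band edge in Hz; must not exceed Nyquist.
#' @return Numeric vector of `n_bands` values.
#' @export
band_powers <- function(spectrum, sample_rate, n_bands = 8, f_max = 400) {
  if (f_max > sample_rate / 2 + 1e-9) {
    stop("f_max must not exceed Nyquist", call. = FALSE)
  }
  n_fft <- 2L * (length(spectrum) - 1L)
  freqs <- seq(0, length(spectrum) - 1) * sample_rate / n_fft
  width <- f_max / n_bands
  keep <- freqs < f_max
  band_idx <- floor(freqs[keep] / width)
  out <- numeric(n_bands)
  for (j in seq_len(n_bands) - 1L) {
    bins <- which(band_idx == j)
    if (!length(bins)) {
      stop("band ", j, " contains no FFT bins", call. = FALSE)
    }
    out[j + 1L] <- mean(spectrum[keep][bins])
  }
  out
}

#' Extract the band-power feature stream
#'
#' Per frame and channel: high-pass, Hann window, FFT, band powers; channel
#' blocks are concatenated in channel order with bands fastest-varying, so a
#' 3-channel stream with 8 bands yields 24-dimensional feature vectors.
#' Frame count is `floor((L - frame_size)/hop) + 1`; frame times are the
#' frame centers.
#'
#' @param stream an [emg_stream()] with at least `frame_size` samples.
#' @param config a [feature_config()].
#' @return A `feature_stream`: list with `times` (frame centers, s),
#'   `features` (frames x `n_channels*n_bands` matrix), `n_channels`,
#'   and `config`.
#' @export
extract_feature_stream <- function(stream, config = feature_config()) {
  stopifnot(inherits(stream, "emg_stream"), inherits(config, "feature_config"))
  L <- ncol(stream$samples)
  fsz <- config$frame_size
  if (L < fsz) stop("stream shorter than one frame", call. = FALSE)
  hp <- highpass_filter(stream, config$highpass_cutoff)
  n_frames <- (L - fsz) %/% config$hop + 1L
  nch <- nrow(hp$samples)
  feats <- matrix(0, nrow = n_frames, ncol = nch * config$n_bands)
  times <- numeric(n_frames)
  fs <- stream$sample_rate
  for (i in seq_len(n_frames)) {
    start <- (i - 1L) * config$hop
    idx <- (start + 1L):(start + fsz)
    times[i] <- (start + fsz / 2) / fs
    for (ch in seq_len(nch)) {
      sp <- spectral_frame(hp$samples[ch, idx], fs, fsz)
      bp <- band_powers(sp, fs, config$n_bands, config$f_max)
      feats[i, ((ch - 1L) * config$n_bands + 1L):(ch * config$n_bands)] <- bp
    }
  }
  if (config$log_compress) feats <- log1p(feats)
  colnames(feats) <- paste0("f", sprintf("%02d", seq_len(ncol(feats))))
  structure(list(times = times, features = feats, n_channels = nch,
                 config = config),
            class = "feature_stream")
}
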