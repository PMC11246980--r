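# Seeded surface-EMG simulator: class-dependent band-shaped activation at
# three forearm electrode sites, plus line interference and sensor noise.

#' Default per-class EMG activation profiles
#'
#' Stylized spectral signatures for the five motion classes over three
#' electrode sites (CH1 extensor carpi radialis brevis, CH2 flexor carpi
#' ulnaris, CH3 flexor carpi radialis). Hand grip/open load the low surface-EMG
#' band (60-150 Hz) with flexor- vs extensor-dominant gains; the wrist motions
#' share the muscle groups but sit in a higher band (120-250 Hz) so the
#' band-power feature chain can separate them. Rest has zero gain everywhere.
#'
#' @param n_channels number of electrode channels (gains are recycled or
#'   truncated to this length).
#' @return Named list, one element per motion label, each with `gain`
#'   (per-channel amplitude, unit RMS at gain 1) and `band` (activation band
#'   in Hz, within 20-400 Hz).
#' @export
default_class_profiles <- function(n_channels = 3) {
  adj <- function(g) rep_len(g, n_channels)
  list(
    rest         = list(gain = adj(c(0, 0, 0)),          band = c(60, 150)),
    grip         = list(gain = adj(c(0.4, 1.0, 1.2)),    band = c(60, 150)),
    open         = list(gain = adj(c(1.2, 0.3, 0.3)),    band = c(60, 150)),
    wrist_flex   = list(gain = adj(c(0.2, 0.9, 1.1)),    band = c(120, 250)),
    wrist_extend = list(gain = adj(c(1.1, 0.25, 0.2)),   band = c(120, 250))
  )
}

#' EMG simulation parameters
#'
#' @param sample_rate sampling frequency in Hz.
#' @param n_channels number of electrode channels.
#' @param class_profiles named list mapping motion label to `gain`
#'   (per-channel) and `band` (Hz) as in [default_class_profiles()].
#' @param noise_sigma standard deviation of the white sensor noise
#'   (signal units).
#' @param line_hz power-line interference frequency in Hz.
#' @param line_amplitude amplitude of the sinusoidal line component.
#' @param crosstalk fraction in `[0, 1)` of each channel replaced by the mean
#'   of the other channels.
#' @param seed integer RNG seed; equal parameters and seed give byte-identical
#'   output.
#' @return An object of class `emg_sim_params`.
#' @export
emg_sim_params <- function(sample_rate = 2000, n_channels = 3,
                           class_profiles = default_class_profiles(n_channels),
                           noise_sigma = 0.05, line_hz = 50,
                           line_amplitude = 0.1, crosstalk = 0.05,
                           seed = 1L) {
  check_finite(sample_rate, "sample_rate")
  check_finite(noise_sigma, "noise_sigma")
  check_finite(line_amplitude, "line_amplitude")
  check_finite(crosstalk, "crosstalk")
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (crosstalk < 0 || crosstalk >= 1) {
    stop("crosstalk must be in [0, 1)", call. = FALSE)
  }
  f_hi <- 0
  for (nm in names(class_profiles)) {
    p <- class_profiles[[nm]]
    check_finite(p$gain, paste0("gain[", nm, "]"))
    check_finite(p$band, paste0("band[", nm, "]"))
    if (any(p$gain < 0)) stop("class gains must be >= 0", call. = FALSE)
    if (length(p$band) != 2 || p$band[1] >= p$band[2]) {
      stop("class band must be (low, high) with low < high", call. = FALSE)
    }
    f_hi <- max(f_hi, p$band[2])
  }
  if (sample_rate <= 2 * f_hi) {
    stop("sample_rate must exceed twice the highest profile frequency",
         call. = FALSE)
  }
  structure(
    list(sample_rate = sample_rate, n_channels = as.integer(n_channels),
         class_profiles = class_profiles, noise_sigma = noise_sigma,
         line_hz = line_hz, line_amplitude = line_amplitude,
         crosstalk = crosstalk, seed = as.integer(seed)),
    class = "emg_sim_params"
  )
}

#' Motion-label schedule
#'
#' Ordered, non-overlapping taught segments `(start_s, end_s, label)`.
#'
#' @param start_s,end_s segment boundaries in seconds.
#' @param label motion label per segment (see [motion_labels()]).
#' @return A `label_schedule` data frame.
#' @export
label_schedule <- function(start_s, end_s, label) {
  if (length(start_s) != length(end_s) || length(start_s) != length(label)) {
    stop("start_s, end_s, label must have equal length", call. = FALSE)
  }
  sched <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                      label = as.character(label), stringsAsFactors = FALSE)
  if (nrow(sched)) {
    check_finite(sched$start_s, "start_s")
    check_finite(sched$end_s, "end_s")
    if (any(sched$end_s <= sched$start_s)) {
      stop("each segment needs start < end", call. = FALSE)
    }
    if (is.unsorted(sched$start_s, strictly = TRUE)) {
      stop("segments must be chronologically sorted", call. = FALSE)
    }
    if (nrow(sched) > 1 &&
        any(sched$start_s[-1] < sched$end_s[-nrow(sched)])) {
      stop("segments must not overlap", call. = FALSE)
    }
    bad <- setdiff(unique(sched$label), motion_labels())
    if (length(bad)) {
      stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  class(sched) <- c("label_schedule", "data.frame")
  sched
}

# Smoothed on/off activation envelope: indicator convolved with a normalized
# Hann kernel spanning 2*rise_s, giving ~100-ms rise/fall ramps.
smooth_envelope <- function(ind, sample_rate, rise_s = 0.1) {
  len <- max(3L, 2L * round(rise_s * sample_rate) + 1L)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, len - 1) / (len - 1)))
  w <- w / sum(w)
  n <- length(ind)
  padded <- c(rep(ind[1], len), ind, rep(ind[n], len))
  sm <- stats::filter(padded, w, sides = 2)
  as.numeric(sm[(len + 1):(len + n)])
}

# Band-shaped unit-RMS noise carrier over `band` Hz.
band_carrier <- function(n, sample_rate, band) {
  bf <- signal::butter(2, band / (sample_rate / 2), type = "pass")
  v <- signal::filtfilt(bf, stats::rnorm(n))
  r <- sqrt(mean(v^2))
  if (r == 0) v else v / r
}

#' Simulate a multi-channel surface-EMG recording
#'
#' Generates `n_channels` x `ceiling(duration * sample_rate)` samples. During a
#' scheduled segment with label y, each channel carries white sensor noise,
#' sinusoidal line interference, and a band-shaped stochastic activation
#' scaled by that class's per-channel gain and shaped by a smoothed on/off
#' envelope (100-ms rise). Samples outside all segments are labeled "rest".
#'
#' @param params an [emg_sim_params()] object.
#' @param schedule a [label_schedule()]; must end at or before `duration`.
#' @param duration recording length in seconds.
#' @return An `emg_stream`: list with `sample_rate`, `samples`
#'   (channels x time matrix), `time` (seconds) and `labels`
#'   (per-sample label track).
#' @export
simulate_emg <- function(params, schedule, duration) {
  stopifnot(inherits(params, "emg_sim_params"))
  check_finite(duration, "duration")
  if (nrow(schedule) && max(schedule$end_s) > duration + 1e-12) {
    stop("schedule exceeds duration", call. = FALSE)
  }
  fs <- params$sample_rate
  n <- as.integer(ceiling(duration * fs))
  t <- seq(0, n - 1) / fs

  labels <- rep("rest", n)
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      idx <- t >= schedule$start_s[i] & t < schedule$end_s[i]
      labels[idx] <- schedule$label[i]
    }
  }

  nch <- params$n_channels
  x <- with_seed(params$seed, {
    m <- matrix(stats::rnorm(nch * n, sd = params$noise_sigma),
                nrow = nch, ncol = n)
    for (cls in names(params$class_profiles)) {
      prof <- params$class_profiles[[cls]]
      if (all(prof$gain == 0) || !any(labels == cls)) next
      env <- smooth_envelope(as.numeric(labels == cls), fs)
      for (ch in seq_len(nch)) {
        if (prof$gain[ch] == 0) next
        m[ch, ] <- m[ch, ] +
          prof$gain[ch] * env * band_carrier(n, fs, prof$band)
      }
    }
    m
  })

  if (params$line_amplitude > 0) {
    line <- params$line_amplitude * sin(2 * pi * params$line_hz * t)
    x <- x + matrix(line, nrow = nch, ncol = n, byrow = TRUE)
  }

  if (params$crosstalk > 0 && nch > 1) {
    c_frac <- params$crosstalk
    others <- (matrix(colSums(x), nrow = nch, ncol = n, byrow = TRUE) - x) /
      (nch - 1)
    x <- (1 - c_frac) * x + c_frac * others
  }

  emg_stream(x, fs, labels = labels, time = t)
}

#' Construct an EMG stream container
#'
#' @param samples channels x time numeric matrix (a vector is treated as one
#'   channel).
#' @param sample_rate sampling frequency in Hz.
#' @param labels optional per-sample label track.
#' @param time optional per-sample time vector (seconds); derived from
#'   `sample_rate` when absent.
#' @return An `emg_stream` object.
#' @export
emg_stream <- function(samples, sample_rate, labels = NULL, time = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples) || !all(is.finite(samples))) {
    stop("samples must be a finite numeric matrix", call. = FALSE)
  }
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  n <- ncol(samples)
  if (is.null(time)) time <- seq(0, n - 1) / sample_rate
  if (!is.null(labels) && length(labels) != n) {
    stop("labels must match the number of samples", call. = FALSE)
  }
  structure(list(sample_rate = sample_rate, samples = samples,
                 time = time, labels = labels),
            class = "emg_stream")
}
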