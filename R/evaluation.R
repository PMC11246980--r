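# Condition-level evaluation: trial filtering, slow-trial flags, condition
# differences, t tests, distortion histograms with normal overlays, and
# 30-second block throughput.

#' Filter trials by maximum duration
#'
#' Trials whose duration strictly exceeds `max_duration` are excluded
#' (a trial taking exactly the cutoff is retained).
#'
#' @param trials data frame of trial records with a `duration_s` column.
#' @param max_duration exclusion cutoff in seconds (default 10).
#' @return List with `retained` and `excluded` data frames.
#' @export
filter_trials <- function(trials, max_duration = 10) {
  if (max_duration <= 0) stop("max_duration must be positive", call. = FALSE)
  keep <- trials$duration_s <= max_duration
  list(retained = trials[keep, , drop = FALSE],
       excluded = trials[!keep, , drop = FALSE])
}

#' Flag slow trials
#'
#' Marks trials whose duration strictly exceeds the threshold; used for
#' report and plot annotation only.
#'
#' @param trials data frame with a `duration_s` column.
#' @param threshold seconds (default 4).
#' @return Logical vector, one flag per trial.
#' @export
flag_slow_trials <- function(trials, threshold = 4) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  trials$duration_s > threshold
}

#' Condition difference of two means
#'
#' Conventional minus separate, rounded to report precision
#' (3 significant figures).
#'
#' @param mean_conventional,mean_separate condition means (cm).
#' @param digits significant figures for the report (default 3).
#' @return Signed difference.
#' @export
condition_difference <- function(mean_conventional, mean_separate,
                                 digits = 3) {
  check_finite(mean_conventional, "mean_conventional")
  check_finite(mean_separate, "mean_separate")
  signif(mean_conventional - mean_separate, digits)
}

#' Two-sided t test with explicit variant
#'
#' Wraps the standard t test with the degenerate cases resolved by contract:
#' samples (or paired differences) with zero variance and zero mean
#' difference return `t = 0, p = 1`; zero variance with a nonzero mean
#' difference is an error. Degrees of freedom are `n - 1` (paired),
#' `n_a + n_b - 2` (pooled), or Welch-Satterthwaite (welch).
#'
#' @param a,b numeric samples; paired requires equal lengths >= 2, unpaired
#'   requires each length >= 2.
#' @param variant `"paired"`, `"welch"`, or `"pooled"`.
#' @return List with `t`, `df`, `p`, `variant`, `n_a`, `n_b`.
#' @export
t_test <- function(a, b, variant = c("paired", "welch", "pooled")) {
  variant <- match.arg(variant)
  check_finite(a, "a"); check_finite(b, "b")
  if (variant == "paired") {
    if (length(a) != length(b)) {
      stop("paired test requires equal lengths", call. = FALSE)
    }
    if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
    d <- a - b
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(list(t = 0, df = length(a) - 1, p = 1, variant = variant,
                    n_a = length(a), n_b = length(b)))
      }
      stop("zero variance in paired differences", call. = FALSE)
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2) {
      stop("need at least 2 observations per sample", call. = FALSE)
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        df <- if (variant == "pooled") length(a) + length(b) - 2 else NA_real_
        return(list(t = 0, df = df, p = 1, variant = variant,
                    n_a = length(a), n_b = length(b)))
      }
      stop("zero variance in both samples", call. = FALSE)
    }
    ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), variant = variant,
       n_a = length(a), n_b = length(b))
}

#' Distortion-level histogram with normal overlay
#'
#' Right-open bins of fixed width anchored at 0 (`[0, w), [w, 2w), ...`)
#' covering the data maximum; the overlay parameters are the sample mean and
#' SD of the values.
#'
#' @param values non-empty numeric vector of per-trial distortion levels.
#' @param bin_width rank width (default 50 distortion levels).
#' @return List with `breaks`, `counts`, `bin_width`, `fit_mean`, `fit_sd`,
#'   `n`, and `peak_bin_mid` (midpoint of the fullest bin).
#' @export
distortion_histogram <- function(values, bin_width = 50) {
  if (!length(values)) stop("no values to histogram", call. = FALSE)
  check_finite(values, "values")
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  top <- (floor(max(values) / bin_width) + 1) * bin_width
  breaks <- seq(0, top, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, right = FALSE,
                           plot = FALSE)$counts
  mids <- breaks[-length(breaks)] + bin_width / 2
  list(breaks = breaks, counts = counts, bin_width = bin_width,
       fit_mean = mean(values),
       fit_sd = if (length(values) > 1) stats::sd(values) else 0,
       n = length(values),
       peak_bin_mid = mids[which.max(counts)])
}

#' Block throughput within a time window
#'
#' Number of completion events with time at or below the window length.
#'
#' @param completion_times cumulative completion times within a session (s).
#' @param window window length in seconds (default 30).
#' @return Integer count.
#' @export
throughput <- function(completion_times, window = 30) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  sum(completion_times <= window)
}

# Mean blocks per full window over a long continuous session assembled from
# per-trial cycle times (movement + return). Fractional reporting across
# consecutive windows.
mean_blocks_per_window <- function(cycle_times, window = 30) {
  ct <- cumsum(cycle_times)
  n_win <- floor(ct[length(ct)] / window)
  if (n_win < 1) return(throughput(ct, window))
  counts <- vapply(seq_len(n_win), function(w) {
    sum(ct > (w - 1) * window & ct <= w * window)
  }, numeric(1))
  mean(counts)
}

#' Per-trial records from simulated trials
#'
#' Runs the measurement pipeline on each trial: trunk-angle series from the
#' (noisy) landmarks, distortion level, maximum absolute trunk angle,
#' duration, and base/end elbow heights.
#'
#' @param trials list of `sim_trial` objects (one condition).
#' @param participant participant id recorded in the table.
#' @return Data frame with columns `participant`, `condition`, `duration_s`,
#'   `max_angle_deg`, `distortion`, `base_cm`, `end_cm`, `true_distortion`.
#' @export
build_trial_records <- function(trials, participant = "sim") {
  if (!length(trials)) stop("no trials supplied", call. = FALSE)
  rows <- lapply(trials, function(tr) {
    th <- trunk_angle_series(tr)
    p <- elbow_path(tr)
    data.frame(
      participant = participant,
      condition = tr$condition,
      duration_s = tr$duration,
      max_angle_deg = max(abs(th)),
      distortion = distortion_level(th),
      base_cm = p[tr$grasp_frame, 2],
      end_cm = p[tr$release_frame, 2],
      true_distortion = distortion_level(tr$true_tilt),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
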