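# Trunk-angle and distortion-level computation from landmark streams, plus
# elbow-trajectory resampling, averaging, and grasp/release height summaries.

as_landmark_frame <- function(lms) {
  if (inherits(lms, "sim_trial")) lms <- lms$landmarks
  need <- landmark_columns()
  if (!all(need %in% names(lms))) {
    stop("landmark data must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lms
}

#' Trunk-angle series from shoulder landmarks
#'
#' The trunk angle at frame k is the signed angle of the segment from the
#' left shoulder to the right shoulder relative to horizontal, in degrees
#' (positive when the right shoulder is higher).
#'
#' @param lms a `sim_trial` or a landmark data frame with
#'   [landmark_columns()].
#' @return Numeric vector of angles in degrees, one per frame, in (-90, 90).
#' @export
trunk_angle_series <- function(lms) {
  lm <- as_landmark_frame(lms)
  dx <- lm$rs_x - lm$ls_x
  dy <- lm$rs_y - lm$ls_y
  if (any(dx == 0 & dy == 0)) {
    stop("coincident shoulder landmarks", call. = FALSE)
  }
  atan2(dy, dx) * 180 / pi
}

#' Distortion level of a trunk-angle series
#'
#' The scalar compensatory-movement burden of one trial: the sum of absolute
#' trunk angles over all frames, `D = sum_k |theta_k|`. The optional `dt`
#' multiplier (default 1) converts the frame sum to angle-time units.
#'
#' @param theta numeric trunk-angle series in degrees.
#' @param dt per-frame multiplier (default 1, i.e. a plain frame sum).
#' @return Non-negative scalar distortion level.
#' @export
distortion_level <- function(theta, dt = 1) {
  check_finite(theta, "theta")
  sum(abs(theta)) * dt
}

#' Resample a 2-D path by linear interpolation
#'
#' Interpolates at `target_len` points uniformly spaced in normalized sample
#' index; the first and last points are preserved exactly.
#'
#' @param path numeric matrix or data frame with two columns (x, y) and at
#'   least two rows.
#' @param target_len number of output points (>= 2).
#' @return `target_len` x 2 numeric matrix.
#' @export
resample_trajectory <- function(path, target_len) {
  path <- as.matrix(path)
  if (nrow(path) < 2 || ncol(path) != 2) {
    stop("path must have >= 2 points and 2 columns", call. = FALSE)
  }
  if (target_len < 2) stop("target_len must be >= 2", call. = FALSE)
  s <- seq(0, 1, length.out = nrow(path))
  q <- seq(0, 1, length.out = target_len)
  cbind(stats::approx(s, path[, 1], xout = q)$y,
        stats::approx(s, path[, 2], xout = q)$y)
}

#' Average elbow trajectory with checkpoint dispersion
#'
#' Resamples every trial's path to the length of the longest trial (the
#' standard), takes the per-index mean path, and reports per-axis standard
#' deviations across trials at the six checkpoints dividing the path into
#' five equal parts (start, four interior fifths, goal).
#'
#' @param trials list of elbow paths (n x 2 matrices or data frames).
#' @return List with `mean_path` (L x 2), `checkpoints` (data frame with
#'   `frac`, `x_mean`, `y_mean`, `x_sd`, `y_sd`), `target_len` and `n_trials`.
#' @export
average_trajectory <- function(trials) {
  if (!length(trials)) stop("no trials supplied", call. = FALSE)
  paths <- lapply(trials, function(p) as.matrix(p))
  L <- max(vapply(paths, nrow, integer(1)))
  res <- lapply(paths, resample_trajectory, target_len = L)
  arr <- simplify2array(res)                    # L x 2 x n
  mean_path <- apply(arr, c(1, 2), mean)
  fracs <- seq(0, 1, by = 0.2)
  idx <- round(fracs * (L - 1)) + 1
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  cps <- data.frame(
    frac = fracs,
    x_mean = mean_path[idx, 1],
    y_mean = mean_path[idx, 2],
    x_sd = apply(arr[idx, 1, , drop = FALSE], 1, sd0),
    y_sd = apply(arr[idx, 2, , drop = FALSE], 1, sd0)
  )
  list(mean_path = mean_path, checkpoints = cps,
       target_len = L, n_trials = length(trials))
}

#' Task-side elbow path of a trial
#'
#' @param trial a `sim_trial`.
#' @return n x 2 matrix of the task-arm elbow x,y positions (cm).
#' @export
elbow_path <- function(trial) {
  stopifnot(inherits(trial, "sim_trial"))
  lm <- trial$landmarks
  if (trial$side == "left") {
    cbind(lm$le_x, lm$le_y)
  } else {
    cbind(lm$re_x, lm$re_y)
  }
}

#' Base/end elbow-height summary across trials
#'
#' Base height is the task-side elbow y at the grasp frame and end height the
#' elbow y at the release frame; both are summarized as mean and SD (n-1
#' denominator; SD is 0 by convention for a single trial), in cm.
#'
#' @param trials list of `sim_trial` objects carrying `grasp_frame` and
#'   `release_frame` annotations.
#' @return List with `base` and `end` (each `mean`, `sd`) and `n`.
#' @export
elbow_height_summary <- function(trials) {
  if (!length(trials)) stop("no trials supplied", call. = FALSE)
  hv <- vapply(trials, function(tr) {
    if (is.null(tr$grasp_frame) || is.null(tr$release_frame)) {
      stop("trial lacks grasp/release annotations", call. = FALSE)
    }
    p <- elbow_path(tr)
    c(p[tr$grasp_frame, 2], p[tr$release_frame, 2])
  }, numeric(2))
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  list(base = list(mean = mean(hv[1, ]), sd = sd0(hv[1, ])),
       end = list(mean = mean(hv[2, ]), sd = sd0(hv[2, ])),
       n = length(trials))
}
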