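# Seeded pick-and-place task kinematics: shoulder/elbow landmark streams with
# a half-sine trunk-tilt profile and condition-dependent elbow heights.

#' Task kinematics simulation parameters
#'
#' Describes one socket condition of the cube-transfer task: per-trial
#' durations, elbow heights at the grasp (base) and release (end) points,
#' trunk-tilt amplitude, and landmark measurement noise. Conventional-socket
#' presets use larger heights and tilt than separate-socket presets.
#'
#' @param condition `"conventional"` or `"separate"`.
#' @param n_trials number of trials to generate.
#' @param frame_interval landmark frame spacing in seconds.
#' @param trial_duration_mean,trial_duration_sd per-trial movement duration
#'   (seconds).
#' @param base_height_mean,base_height_sd elbow height above the tabletop at
#'   the grasp frame (cm).
#' @param end_height_mean,end_height_sd elbow height at the release frame (cm).
#' @param tilt_amplitude_mean,tilt_amplitude_sd peak of the per-trial
#'   half-sine trunk-tilt profile (degrees); draws are truncated at zero.
#' @param side task arm, `"right"` or `"left"`; left mirrors the geometry.
#' @param landmark_noise_sd additive Gaussian noise on every landmark
#'   coordinate (cm).
#' @param inter_trial_s return-to-start time between consecutive trials
#'   (seconds), used for block-throughput accounting.
#' @param jitter if `TRUE`, frame spacing varies uniformly by up to +/-1%.
#' @param seed integer RNG seed.
#' @return An object of class `task_sim_params`.
#' @export
task_sim_params <- function(condition = c("conventional", "separate"),
                            n_trials = 10, frame_interval = 0.11,
                            trial_duration_mean = 4.2,
                            trial_duration_sd = 0.5,
                            base_height_mean = 45.1, base_height_sd = 1.38,
                            end_height_mean = 27.6, end_height_sd = 1.37,
                            tilt_amplitude_mean = 7.9,
                            tilt_amplitude_sd = 2.5,
                            side = c("right", "left"),
                            landmark_noise_sd = 0.2,
                            inter_trial_s = 2.0,
                            jitter = FALSE, seed = 1L) {
  condition <- match.arg(condition)
  side <- match.arg(side)
  vals <- c(frame_interval = frame_interval,
            trial_duration_mean = trial_duration_mean,
            base_height_mean = base_height_mean,
            end_height_mean = end_height_mean)
  check_finite(vals, "durations/heights")
  if (any(vals <= 0)) {
    stop("frame_interval, durations and heights must be positive",
         call. = FALSE)
  }
  sds <- c(trial_duration_sd, base_height_sd, end_height_sd,
           tilt_amplitude_sd, landmark_noise_sd)
  check_finite(sds, "sds")
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  structure(
    list(condition = condition, n_trials = as.integer(n_trials),
         frame_interval = frame_interval,
         trial_duration_mean = trial_duration_mean,
         trial_duration_sd = trial_duration_sd,
         base_height_mean = base_height_mean,
         base_height_sd = base_height_sd,
         end_height_mean = end_height_mean, end_height_sd = end_height_sd,
         tilt_amplitude_mean = tilt_amplitude_mean,
         tilt_amplitude_sd = tilt_amplitude_sd,
         side = side, landmark_noise_sd = landmark_noise_sd,
         inter_trial_s = inter_trial_s, jitter = isTRUE(jitter),
         seed = as.integer(seed)),
    class = "task_sim_params"
  )
}

# cubic smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Canonical landmark column order
#'
#' x,y column names for the four tracked landmarks, in the fixed order
#' left shoulder, right shoulder, left elbow, right elbow.
#'
#' @return Character vector of eight column names.
#' @export
landmark_columns <- function() {
  c("ls_x", "ls_y", "rs_x", "rs_y", "le_x", "le_y", "re_x", "re_y")
}

#' Simulate task landmark streams for one condition
#'
#' Each trial produces a frame series of the four landmarks (both shoulders
#' and both elbows; x,y in cm, y-up, tabletop at y = 0). The task-side elbow
#' holds the per-trial base height until the grasp frame, descends along a
#' smoothstep to the end height at the release frame, and the trunk tilts
#' along a half-sine profile (0 -> peak -> 0) whose peak is drawn per trial.
#' Shoulders are placed symmetrically about a fixed midpoint and rotated by
#' the tilt angle, so the inter-shoulder line reproduces the profile exactly
#' before measurement noise.
#'
#' @param params a [task_sim_params()] object.
#' @return List of `sim_trial` objects; each has `landmarks` (data frame
#'   `time_s` plus [landmark_columns()]), `grasp_frame`, `release_frame`,
#'   `true_tilt` (degrees per frame, noise-free), `condition`, `side`,
#'   `duration` and `inter_trial_s`.
#' @export
simulate_task_landmarks <- function(params) {
  stopifnot(inherits(params, "task_sim_params"))
  fi <- params$frame_interval
  shoulder_mid_y <- 55   # cm above tabletop, seated
  half_span <- 18        # half inter-shoulder distance, cm
  with_seed(params$seed, {
    lapply(seq_len(params$n_trials), function(j) {
      dur <- max(8 * fi,
                 stats::rnorm(1, params$trial_duration_mean,
                              params$trial_duration_sd))
      n <- max(4L, as.integer(round(dur / fi)))
      if (params$jitter) {
        steps <- fi * (1 + stats::runif(n, -0.01, 0.01))
        ts <- c(0, cumsum(steps))
      } else {
        ts <- fi * (0:n)
      }
      amp <- max(0, stats::rnorm(1, params$tilt_amplitude_mean,
                                 params$tilt_amplitude_sd))
      theta <- amp * sin(pi * (0:n) / n)
      base_h <- stats::rnorm(1, params$base_height_mean, params$base_height_sd)
      end_h <- stats::rnorm(1, params$end_height_mean, params$end_height_sd)
      grasp <- as.integer(floor(0.15 * n)) + 1L
      release <- n + 1L - as.integer(floor(0.10 * n))
      if (release <= grasp) release <- grasp + 1L

      u <- (seq(0, n) - (grasp - 1)) / (release - grasp)
      s <- smoothstep(u)
      elb_y <- base_h + (end_h - base_h) * s
      elb_x <- 25 - 50 * s  # start area to end area, 50-cm gap

      th <- theta * pi / 180
      rs_x <- half_span * cos(th); rs_y <- shoulder_mid_y + half_span * sin(th)
      ls_x <- -rs_x;               ls_y <- shoulder_mid_y - half_span * sin(th)
      # non-task elbow rests near the trunk
      off_x <- rep(-12, n + 1); off_y <- rep(30, n + 1)

      lm <- data.frame(time_s = ts,
                       ls_x = ls_x, ls_y = ls_y, rs_x = rs_x, rs_y = rs_y,
                       le_x = off_x, le_y = off_y,
                       re_x = elb_x, re_y = elb_y)
      if (params$side == "left") {
        mirrored <- data.frame(
          time_s = ts,
          ls_x = -lm$rs_x, ls_y = lm$rs_y,
          rs_x = -lm$ls_x, rs_y = lm$ls_y,
          le_x = -lm$re_x, le_y = lm$re_y,
          re_x = -lm$le_x, re_y = lm$le_y)
        lm <- mirrored
        theta <- -theta
      }
      if (params$landmark_noise_sd > 0) {
        for (col in landmark_columns()) {
          lm[[col]] <- lm[[col]] +
            stats::rnorm(n + 1, sd = params$landmark_noise_sd)
        }
      }
      structure(
        list(landmarks = lm, grasp_frame = grasp, release_frame = release,
             true_tilt = theta, condition = params$condition,
             side = params$side, duration = ts[length(ts)],
             inter_trial_s = params$inter_trial_s),
        class = "sim_trial"
      )
    })
  })
}

# Preset table used by make_benchmark_scenario(). Heights/SDs come from the
# published per-participant summary tables; tilt amplitudes invert the
# half-sine frame sum against the published distortion summaries; inter-trial
# return times make cycle lengths reproduce the published 30-s block rates.
scenario_presets <- function() {
  list(
    table1_C = list(
      side = "right",
      conventional = list(trial_duration_mean = 4.2, trial_duration_sd = 0.5,
                          base_height_mean = 45.1, base_height_sd = 1.38,
                          end_height_mean = 27.6, end_height_sd = 1.37,
                          tilt_amplitude_mean = 7.90, tilt_amplitude_sd = 2.46,
                          inter_trial_s = 2.30),
      separate = list(trial_duration_mean = 4.0, trial_duration_sd = 0.5,
                      base_height_mean = 22.2, base_height_sd = 1.94,
                      end_height_mean = 10.0, end_height_sd = 1.58,
                      tilt_amplitude_mean = 3.90, tilt_amplitude_sd = 2.15,
                      inter_trial_s = 1.36)
    ),
    table2_D = list(
      side = "left",
      conventional = list(trial_duration_mean = 4.20, trial_duration_sd = 0.5,
                          base_height_mean = 26.4, base_height_sd = 2.58,
                          end_height_mean = 14.8, end_height_sd = 3.68,
                          tilt_amplitude_mean = 15.7, tilt_amplitude_sd = 2.4,
                          inter_trial_s = 5.80),
      separate = list(trial_duration_mean = 4.68, trial_duration_sd = 0.6,
                      base_height_mean = 20.1, base_height_sd = 2.78,
                      end_height_mean = 11.25, end_height_sd = 2.92,
                      tilt_amplitude_mean = 12.95, tilt_amplitude_sd = 2.8,
                      inter_trial_s = 5.32)
    )
  )
}

# Default teaching schedule: three repetitions of each motion class,
# 3-s taught segments separated by 1-s untaught gaps.
default_teaching_schedule <- function(reps = 3, segment_s = 3, gap_s = 1) {
  labs <- rep(motion_labels(), times = reps)
  starts <- (seq_along(labs) - 1) * (segment_s + gap_s)
  label_schedule(starts, starts + segment_s, labs)
}

#' Build a fully specified benchmark scenario
#'
#' Bundles EMG simulation parameters, a teaching label schedule, and task
#' kinematics parameters for both socket conditions under one seed. The
#' `"table1_C"` preset sets conventional base/end elbow heights 45.1/27.6 cm
#' and separate 22.2/10.0 cm with their published SDs; `"table2_D"` encodes
#' the left-arm user with base 26.4/20.1 cm and end 14.8/11.25 cm. Presets
#' default to 10 trials per condition.
#'
#' @param name preset id, one of `"table1_C"`, `"table2_D"`.
#' @param seed integer seed; the two conditions and the EMG stream use
#'   distinct seeds derived from it.
#' @param n_trials trials per condition (default 10).
#' @return A `benchmark_scenario`: list with `name`, `seed`, `emg`
#'   ([emg_sim_params()]), `schedule` ([label_schedule()]) and `task`
#'   (list of [task_sim_params()] for `conventional` and `separate`).
#' @export
make_benchmark_scenario <- function(name, seed = 1L, n_trials = 10) {
  presets <- scenario_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  mk_task <- function(cond, offset) {
    do.call(task_sim_params, c(
      list(condition = cond, n_trials = n_trials, side = p$side,
           seed = child_seed(seed, offset)),
      p[[cond]]))
  }
  structure(
    list(name = name, seed = as.integer(seed),
         emg = emg_sim_params(seed = child_seed(seed, 11L)),
         schedule = default_teaching_schedule(),
         task = list(conventional = mk_task("conventional", 101L),
                     separate = mk_task("separate", 202L))),
    class = "benchmark_scenario"
  )
}
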