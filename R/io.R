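# Delimited-text readers/writers for EMG, schedules, landmarks, features,
# models, and reports.

#' Write / read an EMG stream as CSV
#'
#' Columns: `time_s`, `ch1..chN`. The reader checks the declared sample rate
#' against the median time step.
#'
#' @param stream an [emg_stream()].
#' @param path file path.
#' @return `read_emg_csv` returns an `emg_stream`.
#' @export
write_emg_csv <- function(stream, path) {
  stopifnot(inherits(stream, "emg_stream"))
  df <- data.frame(time_s = stream$time, t(stream$samples))
  names(df) <- c("time_s", paste0("ch", seq_len(nrow(stream$samples))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param sample_rate expected sampling rate in Hz; checked against the
#'   median time step (10% tolerance).
#' @export
read_emg_csv <- function(path, sample_rate = NULL) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("missing time_s column", call. = FALSE)
  chans <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (!length(chans)) stop("no channel columns ch1..chN", call. = FALSE)
  dt <- stats::median(diff(df$time_s))
  fs <- 1 / dt
  if (!is.null(sample_rate) && abs(fs - sample_rate) / sample_rate > 0.1) {
    stop(sprintf("declared rate %g Hz inconsistent with median step (%g Hz)",
                 sample_rate, fs), call. = FALSE)
  }
  m <- t(as.matrix(df[chans]))
  dimnames(m) <- NULL
  emg_stream(m, sample_rate %||% fs, time = df$time_s)
}

#' Write / read a label schedule as CSV
#'
#' Columns: `start_s`, `end_s`, `label`.
#'
#' @param schedule a [label_schedule()].
#' @param path file path.
#' @export
write_label_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_schedule_csv
#' @export
read_label_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_schedule(df$start_s, df$end_s, df$label)
}

#' Write / read landmark series as CSV
#'
#' Columns: `time_s`, then x,y per landmark in the fixed order left shoulder,
#' right shoulder, left elbow, right elbow. The reader can convert
#' pixel-space exports (top-left origin, y-down) to the internal tabletop
#' frame (cm, y-up) via a scale, a y flip, and the tabletop row.
#'
#' @param lms a `sim_trial` or landmark data frame.
#' @param path file path.
#' @export
write_landmarks_csv <- function(lms, path) {
  lm <- as_landmark_frame(lms)
  utils::write.csv(lm[, c("time_s", landmark_columns())], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @param scale_cm_per_px multiply coordinates by this scale (default 1).
#' @param flip_y if `TRUE`, y becomes `table_y - y` (pixel y-down to cm y-up).
#' @param table_y tabletop position in the input y units (default 0).
#' @export
read_landmarks_csv <- function(path, scale_cm_per_px = 1, flip_y = FALSE,
                               table_y = 0) {
  df <- utils::read.csv(path)
  need <- c("time_s", landmark_columns())
  if (!all(need %in% names(df))) {
    stop("missing landmark columns", call. = FALSE)
  }
  for (col in landmark_columns()) {
    v <- df[[col]]
    if (flip_y && grepl("_y$", col)) v <- table_y - v
    df[[col]] <- v * scale_cm_per_px
  }
  df[need]
}

#' Write a feature stream as CSV
#'
#' Columns: `frame_time_s`, `f01..fNN`.
#'
#' @param features a `feature_stream`.
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "feature_stream"))
  df <- data.frame(frame_time_s = features$times, features$features)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Persist / restore a pattern model as JSON
#'
#' Stores the network weights, architecture, class list, and feature
#' standardization constants; `load_pattern_model` rebuilds an equivalent
#' predictor.
#'
#' @param model a `pattern_model`.
#' @param path file path.
#' @export
save_pattern_model <- function(model, path) {
  stopifnot(inherits(model, "pattern_model"))
  obj <- list(weights = model$fit$wts, n = model$fit$n,
              classes = model$classes, input_dim = model$input_dim,
              mu = unname(model$mu), sd = unname(model$sd),
              seed = model$seed, hidden = model$hidden,
              decay = model$decay, train_accuracy = model$train_accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pattern_model
#' @export
load_pattern_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(obj$classes)
  dummy_x <- matrix(0, nrow = max(2, k), ncol = obj$input_dim)
  dummy_y <- diag(k)[rep(seq_len(k), length.out = nrow(dummy_x)), ]
  fit <- nnet::nnet(x = dummy_x, y = dummy_y, size = obj$hidden,
                    softmax = TRUE, maxit = 0, trace = FALSE,
                    Wts = obj$weights, MaxNWts = 100000)
  fit$wts <- obj$weights
  structure(
    list(fit = fit, classes = obj$classes, input_dim = obj$input_dim,
         mu = obj$mu, sd = obj$sd, seed = obj$seed, hidden = obj$hidden,
         decay = obj$decay, train_accuracy = obj$train_accuracy),
    class = "pattern_model"
  )
}

#' Write an intention stream as CSV
#'
#' Columns: `frame_time_s`, `raw`, `stabilized`, `hand_command`.
#'
#' @param times frame times (s).
#' @param raw,stabilized,hand_command per-frame label streams.
#' @param path file path.
#' @export
write_intentions_csv <- function(times, raw, stabilized, hand_command, path) {
  utils::write.csv(
    data.frame(frame_time_s = times, raw = raw, stabilized = stabilized,
               hand_command = hand_command),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' @param report a list (e.g. from [run_move_analysis()]).
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
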