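# Intention-estimation chain: teacher-data buffering, feed-forward classifier
# training, per-frame prediction, recognition-stabilization filtering, and the
# wrist-excluding hand-command mapping.

#' Recognition-stabilization filter configuration
#'
#' @param window number of most recent raw predictions considered (frames).
#' @param threshold modal-proportion threshold tau in `(0, 1]`; the filter
#'   switches its output only when the modal label's share of the window
#'   reaches tau.
#' @return An `rsf_config` object.
#' @export
rsf_config <- function(window = 10, threshold = 0.6) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(window = as.integer(window), threshold = threshold),
            class = "rsf_config")
}

#' Build a teacher dataset from taught segments
#'
#' For each taught segment, feature frames whose center times lie in
#' `[start + skip_s, start + buffer_s]` (capped at the segment end) are
#' buffered and labeled with the taught label; all other frames are excluded.
#' Skipping the first `skip_s` avoids contraction-onset transients.
#'
#' @param features a `feature_stream` from [extract_feature_stream()].
#' @param taught_segments a [label_schedule()] of taught segments.
#' @param buffer_s buffered window length from segment start (seconds).
#' @param skip_s initial transient skipped at each segment start (seconds);
#'   `buffer_s > skip_s >= 0`.
#' @return A `teacher_dataset`: list with `x` (feature matrix), `y` (factor of
#'   labels, levels in canonical order), and `provenance` (per-segment frame
#'   counts).
#' @export
build_teacher_dataset <- function(features, taught_segments,
                                  buffer_s = 2.0, skip_s = 0.5) {
  stopifnot(inherits(features, "feature_stream"))
  if (skip_s < 0 || buffer_s <= skip_s) {
    stop("need buffer_s > skip_s >= 0", call. = FALSE)
  }
  rows <- integer(0)
  labs <- character(0)
  prov <- list()
  if (nrow(taught_segments)) {
    for (i in seq_len(nrow(taught_segments))) {
      seg <- taught_segments[i, ]
      hi <- min(seg$start_s + buffer_s, seg$end_s)
      sel <- which(features$times >= seg$start_s + skip_s - 1e-9 &
                     features$times <= hi + 1e-9)
      rows <- c(rows, sel)
      labs <- c(labs, rep(seg$label, length(sel)))
      prov[[i]] <- list(label = seg$label, n_frames = length(sel))
    }
  }
  if (!length(rows)) stop("no teacher data", call. = FALSE)
  lev <- intersect(motion_labels(), unique(labs))
  structure(list(x = features$features[rows, , drop = FALSE],
                 y = factor(labs, levels = lev),
                 provenance = prov),
            class = "teacher_dataset")
}

#' Train the pattern-recognition model
#'
#' Fits a single-hidden-layer feed-forward network with a softmax output on
#' z-scored features. Training is deterministic given the seed (which fixes
#' the weight initialization). Final training accuracy is recorded in the
#' returned model.
#'
#' @param dataset a [build_teacher_dataset()] result with at least two classes
#'   and at least `min_per_class` examples per class.
#' @param seed integer seed for weight initialization.
#' @param hidden hidden-layer size.
#' @param max_iter optimizer iteration cap; hitting it logs a
#'   non-convergence warning but still returns the model.
#' @param decay weight-decay regularization.
#' @param min_per_class minimum examples required per class.
#' @return A `pattern_model`: the fitted network plus class list, input
#'   dimension, feature standardization constants, hyperparameters, and
#'   `train_accuracy`.
#' @export
train_pattern_model <- function(dataset, seed = 1L, hidden = 16,
                                max_iter = 500, decay = 1e-4,
                                min_per_class = 10) {
  stopifnot(inherits(dataset, "teacher_dataset"))
  counts <- table(dataset$y)
  if (length(counts) < 2) {
    stop("training requires at least two classes", call. = FALSE)
  }
  if (any(counts < min_per_class)) {
    stop("each class needs >= ", min_per_class, " examples", call. = FALSE)
  }
  mu <- colMeans(dataset$x)
  sdv <- apply(dataset$x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(dataset$x, center = mu, scale = sdv)
  y_ind <- nnet::class.ind(dataset$y)
  fit <- with_seed(seed, {
    nnet::nnet(x = xs, y = y_ind, size = hidden, softmax = TRUE,
               maxit = max_iter, decay = decay, trace = FALSE,
               MaxNWts = 100000)
  })
  if (!is.null(fit$convergence) && fit$convergence != 0) {
    warning("pattern model did not converge within ", max_iter,
            " iterations", call. = FALSE)
  }
  classes <- levels(dataset$y)
  pred <- classes[max.col(stats::predict(fit, xs), ties.method = "first")]
  structure(
    list(fit = fit, classes = classes, input_dim = ncol(dataset$x),
         mu = mu, sd = sdv, seed = as.integer(seed), hidden = hidden,
         max_iter = max_iter, decay = decay,
         train_accuracy = mean(pred == as.character(dataset$y))),
    class = "pattern_model"
  )
}

#' Predict motion intention for feature vectors
#'
#' Argmax class of the trained network; deterministic given the model.
#'
#' @param x numeric feature vector of length `model$input_dim`, or a matrix
#'   with that many columns (one prediction per row).
#' @param model a [train_pattern_model()] result.
#' @return Character vector of predicted labels drawn from `model$classes`.
#' @export
predict_intention <- function(x, model) {
  stopifnot(inherits(model, "pattern_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_dim) {
    stop("feature dimension ", ncol(x), " does not match model input ",
         model$input_dim, call. = FALSE)
  }
  xs <- scale(x, center = model$mu, scale = model$sd)
  probs <- stats::predict(model$fit, xs)
  model$classes[max.col(probs, ties.method = "first")]
}

#' Recognition-stabilization filter
#'
#' Slides a window over the raw prediction stream; at each frame the output
#' switches to the modal label of the last `window` raw predictions when that
#' label's proportion reaches the threshold, and otherwise holds the previous
#' output (initially `initial`). Ties break toward the earliest label in the
#' canonical order. Output length equals input length.
#'
#' @param raw character vector of raw per-frame predictions.
#' @param config an [rsf_config()].
#' @param initial output before any switch (default `"rest"`).
#' @return Character vector of stabilized outputs.
#' @export
stabilize_intentions <- function(raw, config = rsf_config(),
                                 initial = "rest") {
  stopifnot(inherits(config, "rsf_config"))
  if (!length(raw)) stop("raw prediction stream is empty", call. = FALSE)
  lev <- c(intersect(motion_labels(), unique(raw)),
           setdiff(unique(raw), motion_labels()))
  out <- character(length(raw))
  prev <- initial
  w <- config$window
  for (k in seq_along(raw)) {
    win <- raw[max(1L, k - w + 1L):k]
    tab <- table(factor(win, levels = lev))
    modal <- lev[which.max(tab)]
    if (max(tab) / length(win) >= config$threshold - 1e-12) prev <- modal
    out[k] <- prev
  }
  out
}

#' Map stabilized intentions to hand commands
#'
#' Grip closes the hand and open opens it; rest and both wrist motions map to
#' hold, so that wrist activity never drives the hand.
#'
#' @param o character vector of motion labels.
#' @return Character vector over `{"close", "open", "hold"}`.
#' @export
map_to_hand_command <- function(o) {
  map <- c(grip = "close", open = "open", rest = "hold",
           wrist_flex = "hold", wrist_extend = "hold")
  bad <- setdiff(unique(o), names(map))
  if (length(bad)) {
    stop("unknown motion labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[o])
}

# Count of transitions in a label/command stream.
switch_count <- function(x) {
  if (length(x) < 2) return(0L)
  sum(x[-1] != x[-length(x)])
}
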