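# Base-graphics report figures used by the analysis drivers.

#' Plot a distortion histogram with its normal overlay
#'
#' @param h a [distortion_histogram()] result.
#' @param main plot title.
#' @param col bar color.
#' @export
plot_distortion_histogram <- function(h, main = "Distortion level",
                                      col = "grey70") {
  mids <- h$breaks[-length(h$breaks)] + h$bin_width / 2
  graphics::barplot(h$counts, names.arg = mids, space = 0, col = col,
                    xlab = "Distortion level", ylab = "Trials per bin",
                    main = main)
  if (h$fit_sd > 0) {
    xs <- seq(0, max(h$breaks), length.out = 200)
    dens <- stats::dnorm(xs, h$fit_mean, h$fit_sd) * h$n * h$bin_width
    graphics::lines(xs / h$bin_width, dens, lwd = 2)
  }
  invisible(h)
}

#' Plot mean elbow trajectories with checkpoint dispersion
#'
#' Draws each condition's mean elbow path with crosses at the five-equal-part
#' checkpoints and dispersion ellipses (1 SD per axis).
#'
#' @param summaries named list of [average_trajectory()] results.
#' @param main plot title.
#' @export
plot_mean_trajectories <- function(summaries, main = "Mean elbow path") {
  cols <- c("black", "red3", "blue3")[seq_along(summaries)]
  xs <- unlist(lapply(summaries, function(s) s$mean_path[, 1]))
  ys <- unlist(lapply(summaries, function(s) s$mean_path[, 2]))
  graphics::plot(range(xs), range(ys), type = "n", xlab = "x (cm)",
                 ylab = "Height above tabletop (cm)", main = main)
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    graphics::lines(s$mean_path, col = cols[i], lwd = 2)
    cp <- s$checkpoints
    graphics::points(cp$x_mean, cp$y_mean, pch = 4, col = cols[i], cex = 1.2)
    phi <- seq(0, 2 * pi, length.out = 60)
    for (j in seq_len(nrow(cp))) {
      graphics::lines(cp$x_mean[j] + cp$x_sd[j] * cos(phi),
                      cp$y_mean[j] + cp$y_sd[j] * sin(phi),
                      col = cols[i], lty = 3)
    }
  }
  graphics::legend("topright", legend = names(summaries), col = cols,
                   lwd = 2, bty = "n")
  invisible(summaries)
}
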