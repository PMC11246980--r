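# Shared fixtures. Heavy pipeline runs are computed once and cached so that
# unit, property and acceptance tests reuse the same objects.

.fixture_cache <- new.env(parent = emptyenv())

fixture_scenario <- function() {
  if (is.null(.fixture_cache$scenario)) {
    .fixture_cache$scenario <- make_benchmark_scenario("table1_C", seed = 1)
  }
  .fixture_cache$scenario
}

# Full closed-loop control run on the benchmark scenario (teach, train,
# estimate on an independent recording).
fixture_control_run <- function() {
  if (is.null(.fixture_cache$control)) {
    .fixture_cache$control <-
      suppressWarnings(run_control_sim(fixture_scenario()))
  }
  .fixture_cache$control
}

# Compensatory-movement analysis at 200 trials per condition.
fixture_move_200 <- function() {
  if (is.null(.fixture_cache$move200)) {
    .fixture_cache$move200 <- run_move_analysis(fixture_scenario(),
                                                n_trials = 200)
  }
  .fixture_cache$move200
}

# Linearly separable 3-class feature fixture (well-separated centroids,
# noise far below the separation) plus its centroids.
separable_dataset <- function(n_per_class = 40, dim = 24, noise_sd = 0.2,
                              seed = 11) {
  centroids <- rbind(rest = rep(0, dim),
                     grip = c(rep(5, dim / 3), rep(0, 2 * dim / 3)),
                     open = c(rep(0, 2 * dim / 3), rep(5, dim / 3)))
  set.seed(seed)
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rep(centroids[i, ], each = n_per_class), nrow = n_per_class) +
      matrix(rnorm(n_per_class * dim, sd = noise_sd), nrow = n_per_class)
  }))
  y <- factor(rep(rownames(centroids), each = n_per_class),
              levels = rownames(centroids))
  list(dataset = structure(list(x = x, y = y, provenance = list()),
                           class = "teacher_dataset"),
       centroids = centroids)
}

# Direct-DFT band-power oracle, independent of the fft-based implementation.
dft_band_oracle <- function(frame, sample_rate, n_bands = 8, f_max = 400) {
  n <- length(frame)
  k <- 0:(n %/% 2)
  basis <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  X <- basis %*% (hann_window(n) * frame)
  p <- Mod(X)^2
  freqs <- k * sample_rate / n
  width <- f_max / n_bands
  keep <- freqs < f_max
  idx <- floor(freqs[keep] / width)
  vapply(seq_len(n_bands) - 1, function(j) mean(p[keep][idx == j]),
         numeric(1))
}

# Brute-force recognition-stabilization oracle: literal restatement of the
# windowed modal-proportion rule, computed per frame from scratch.
rsf_oracle <- function(raw, window, threshold, initial = "rest") {
  lev <- c(intersect(motion_labels(), unique(raw)),
           setdiff(unique(raw), motion_labels()))
  prev <- initial
  out <- character(length(raw))
  for (k in seq_along(raw)) {
    win <- raw[max(1, k - window + 1):k]
    counts <- vapply(lev, function(l) sum(win == l), numeric(1))
    best <- lev[which.max(counts)]
    if (counts[which.max(counts)] / length(win) >= threshold - 1e-12) {
      prev <- best
    }
    out[k] <- prev
  }
  out
}

count_switches <- function(x) sum(x[-1] != x[-length(x)])
count_single_frame_runs <- function(x) sum(rle(x)$lengths == 1)
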