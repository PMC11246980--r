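make_feature_stream <- function(times, features) {
  structure(list(times = times, features = features,
                 n_channels = 3, config = feature_config()),
            class = "feature_stream")
}

test_that("teacher buffering captures the documented frame window", {
  # frames every 0.064 s (hop 128 at 2,000 Hz), centered at 0.064 * i
  times <- 0.064 * (1:38)
  fs <- make_feature_stream(times, matrix(0, nrow = 38, ncol = 24))
  sched <- label_schedule(0, 2.0, "grip")
  td <- build_teacher_dataset(fs, sched, buffer_s = 2.0, skip_s = 0.5)
  expect_equal(nrow(td$x), floor(1.5 / 0.064) + 1)   # 24 frames
  expect_identical(levels(td$y), "grip")

  empty <- label_schedule(numeric(0), numeric(0), character(0))
  expect_error(build_teacher_dataset(fs, empty), "no teacher data")
  expect_error(build_teacher_dataset(fs, sched, buffer_s = 0.4, skip_s = 0.5),
               "buffer_s > skip_s")
})

test_that("dataset label set equals the set of taught labels", {
  times <- 0.064 * (1:120)
  fs <- make_feature_stream(times, matrix(rnorm(120 * 24), ncol = 24))
  sched <- label_schedule(c(0, 3, 6), c(2.5, 5.5, 7.6),
                          c("rest", "grip", "wrist_flex"))
  td <- build_teacher_dataset(fs, sched)
  expect_setequal(levels(td$y), c("rest", "grip", "wrist_flex"))
})

test_that("training is seeded-deterministic and fits separable data", {
  fx <- separable_dataset()
  m1 <- train_pattern_model(fx$dataset, seed = 2)
  m2 <- train_pattern_model(fx$dataset, seed = 2)
  expect_identical(m1$fit$wts, m2$fit$wts)
  expect_identical(m1$classes, levels(fx$dataset$y))

  # independent separability oracle: nearest centroid on the same data
  nc <- apply(fx$dataset$x, 1, function(v) {
    rownames(fx$centroids)[which.min(colSums((t(fx$centroids) - v)^2))]
  })
  expect_gte(mean(nc == as.character(fx$dataset$y)), 0.99)
  expect_gte(m1$train_accuracy, 0.99)
})

test_that("training rejects degenerate datasets", {
  fx <- separable_dataset()
  single <- fx$dataset
  keep <- single$y == "grip"
  single$x <- single$x[keep, ]; single$y <- droplevels(single$y[keep])
  expect_error(train_pattern_model(single), "two classes")
  tiny <- fx$dataset
  tiny$x <- tiny$x[c(1:3, 41:43), ]; tiny$y <- droplevels(tiny$y[c(1:3, 41:43)])
  expect_error(train_pattern_model(tiny), ">= 10")
})

test_that("prediction recovers held-out labels and class centroids", {
  fx <- separable_dataset(n_per_class = 60)
  set.seed(9)
  test_idx <- sort(sample(nrow(fx$dataset$x), nrow(fx$dataset$x) / 2))
  train <- fx$dataset
  train$x <- fx$dataset$x[-test_idx, ]
  train$y <- droplevels(fx$dataset$y[-test_idx])
  model <- train_pattern_model(train, seed = 3)
  pred <- predict_intention(fx$dataset$x[test_idx, ], model)
  expect_true(all(pred %in% model$classes))
  expect_gte(mean(pred == as.character(fx$dataset$y[test_idx])), 0.95)
  for (cls in rownames(fx$centroids)) {
    expect_identical(predict_intention(fx$centroids[cls, ], model), cls)
  }
  expect_error(predict_intention(rnorm(10), model), "dimension")
})

test_that("stabilization filter follows the windowed modal-proportion rule", {
  expect_identical(stabilize_intentions(rep("grip", 20)), rep("grip", 20))

  # window 1 is a pass-through
  set.seed(5)
  raw <- sample(motion_labels(), 50, replace = TRUE)
  expect_identical(stabilize_intentions(raw, rsf_config(window = 1)), raw)

  # single-frame blips are absorbed
  blip <- rep("grip", 30); blip[c(10, 20)] <- "open"
  out <- stabilize_intentions(blip, rsf_config(window = 10, threshold = 0.6))
  expect_identical(out, rep("grip", 30))
  expect_lte(count_switches(out), count_switches(blip))

  # brute-force oracle agreement on random streams
  for (s in 1:10) {
    set.seed(100 + s)
    raw <- sample(c("rest", "grip", "open"), 80, replace = TRUE)
    expect_identical(stabilize_intentions(raw, rsf_config(10, 0.6)),
                     rsf_oracle(raw, 10, 0.6))
  }
  expect_error(stabilize_intentions(character(0)), "empty")
})

test_that("stabilization reduces chatter and never invents labels", {
  for (s in 1:15) {
    set.seed(200 + s)
    raw <- sample(c("rest", "grip", "open", "wrist_flex"), 120,
                  replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1))
    out <- stabilize_intentions(raw)
    expect_lte(count_switches(out), count_switches(raw))
    expect_true(all(out %in% c(unique(raw), "rest")))
  }
})

test_that("larger windows never increase single-frame output blips", {
  # fixture family: constant intention stream corrupted by isolated
  # single-frame misclassifications (the chatter the filter exists for)
  for (s in 1:5) {
    set.seed(300 + s)
    raw <- rep(sample(c("rest", "grip", "open"), 1), 150)
    blip_at <- seq(5, 145, by = sample(7:11, 1))
    raw[blip_at] <- sample(setdiff(motion_labels(), raw[1]),
                           length(blip_at), replace = TRUE)
    blips <- vapply(c(1, 2, 5, 10, 15), function(w) {
      count_single_frame_runs(stabilize_intentions(raw, rsf_config(w, 0.6)))
    }, numeric(1))
    expect_true(all(diff(blips) <= 0))
    expect_equal(blips[[5]], 0)
  }
})

test_that("hand-command mapping excludes wrist motion from hand actions", {
  expect_identical(map_to_hand_command("wrist_flex"), "hold")
  expect_identical(map_to_hand_command("wrist_extend"), "hold")
  expect_identical(map_to_hand_command("grip"), "close")
  expect_identical(map_to_hand_command("open"), "open")
  expect_identical(map_to_hand_command("rest"), "hold")
  expect_error(map_to_hand_command("jump"), "unknown")
})

test_that("filter configuration is validated", {
  expect_error(rsf_config(window = 0), "window")
  expect_error(rsf_config(threshold = 0), "threshold")
  expect_error(rsf_config(threshold = 1.2), "threshold")
})
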