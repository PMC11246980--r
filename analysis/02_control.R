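#!/usr/bin/env Rscript
# Step 2 — closed-loop control simulation.
#
# Teaches the intention classifier from a simulated instruction session
# (rest/grip/open plus both wrist motions), then estimates intentions on an
# independent recording: feature extraction, pattern recognition,
# recognition-stabilization filtering, and the hand-command mapping that
# keeps wrist motion away from the hand.

suppressMessages(library(myocomp))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/control"

scenario <- make_benchmark_scenario("table1_C", seed = seed)
cs <- suppressWarnings(run_control_sim(scenario, out_dir = out))
s <- cs$summary
cat(sprintf("feature dimension: %d (3 channels x 8 bands)\n", s$feature_dim))
cat(sprintf("teacher frames: %d across classes %s\n", s$n_teacher_frames,
            paste(s$classes, collapse = ", ")))
cat(sprintf("training accuracy: %.3f; held-out accuracy: %.3f\n",
            s$train_accuracy, s$heldout_accuracy))
cat("hand-command counts:\n")
print(unlist(s$command_counts))

# wrist-invariance probe: wrist/rest-only activity through the same model
starts <- seq(0, 28, by = 4)
sched <- label_schedule(starts, starts + 3, rep(c("wrist_flex", "rest"), 4))
p <- scenario$emg
p$seed <- as.integer((seed + 7777) %% 2147483647)
st <- simulate_emg(p, sched, 32)
f <- extract_feature_stream(st, feature_config(log_compress = TRUE))
cmd <- map_to_hand_command(
  stabilize_intentions(predict_intention(f$features, cs$model)))
n_events <- sum(rle(cmd)$values %in% c("close", "open"))
cat(sprintf("wrist-only probe: %d hand open/close events over %d frames\n",
            n_events, length(cmd)))
cat("artifacts in", out, "\n")
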