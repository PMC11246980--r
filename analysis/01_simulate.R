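#!/usr/bin/env Rscript
# Step 1 — generate the benchmark datasets.
#
# Builds the "table1_C" scenario (conventional vs separate socket, right arm)
# and writes the raw simulated inputs every later step consumes: a teaching
# EMG recording with its label schedule, and landmark streams for ten trials
# per socket condition.

suppressMessages(library(myocomp))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scenario <- make_benchmark_scenario("table1_C", seed = seed)

stream <- simulate_emg(scenario$emg, scenario$schedule,
                       max(scenario$schedule$end_s) + 1)
write_emg_csv(stream, file.path(out, "teaching_emg.csv"))
write_label_schedule_csv(scenario$schedule, file.path(out, "schedule.csv"))
cat(sprintf("teaching EMG: %d channels x %d samples (%.0f s at %g Hz), %d taught segments\n",
            nrow(stream$samples), ncol(stream$samples),
            ncol(stream$samples) / stream$sample_rate,
            stream$sample_rate, nrow(scenario$schedule)))

for (cond in c("conventional", "separate")) {
  trials <- simulate_task_landmarks(scenario$task[[cond]])
  for (i in seq_along(trials)) {
    write_landmarks_csv(trials[[i]],
                        file.path(out, sprintf("landmarks_%s_%02d.csv",
                                               cond, i)))
  }
  cat(sprintf("%s condition: %d trials, mean duration %.2f s\n",
              cond, length(trials),
              mean(vapply(trials, function(tr) tr$duration, numeric(1)))))
}
cat("wrote raw datasets to", out, "\n")
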