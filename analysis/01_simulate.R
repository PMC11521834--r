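#!/usr/bin/env Rscript

# Step 1 — generate the study-like synthetic SEEG data set.
#
# Eight depth-electrode shafts (64 contacts; ~14% deep white matter, 16%
# shallow white matter, 52% gray matter, 19% outside the brain), an
# independent task-locked 60-140 Hz source at every gray contact, facial
# EMG beyond the superficial shaft ends during response phases (stronger
# when speaking aloud), 1/f background, and a shared white-matter
# recording reference. One auditory-naming run (20 trials, 10-s spacing,
# 1.8-s stimuli) is simulated per vocalization condition.

library(seeghg)

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

run <- run_config(n_trials = 20, first_onset_s = 2, rng_seed = 42L)
sim <- scenario_study_like(seed = 42L)
write_run_config(run, file.path(out_dir, "run.yaml"))
write_sim_config(sim, file.path(out_dir, "sim.yaml"))

for (cond in c("overt", "covert")) {
  res <- simulate_run(sim, run, cond)
  write_recording(res$recording,
                  file.path(out_dir, sprintf("recording_%s.bin", cond)))
  write_event_table(res$events,
                    file.path(out_dir, sprintf("events_%s.tsv", cond)))
  if (cond == "overt") {
    write_channel_table(res$channels, file.path(out_dir, "channels.tsv"))
    gt <- res$ground_truth
    utils::write.table(
      data.frame(contact_id = rownames(gt$weights), gt$weights,
                 check.names = FALSE),
      file.path(out_dir, "ground_truth_weights.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat(sprintf("%s run: %d channels x %.0f s, %d trials\n", cond,
              nrow(res$recording$data),
              ncol(res$recording$data) / res$recording$fs,
              nrow(res$events)))
}

ch <- read_channel_table(file.path(out_dir, "channels.tsv"))
cat("\ncontact categories:\n")
print(table(ch$category))
cat("\nreference contact (flagged artifactual, as in referential SEEG):",
    ch$contact_id[ch$is_artifact], "\n")
cat("wrote", out_dir, "\n")
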