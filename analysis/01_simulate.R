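#!/usr/bin/env Rscript
# Stage 1 -- generate a demonstration shooting session.
#
# A reduced synthetic session (2 subjects x 60 shots, 256 Hz, a
# 16-channel subset of the cap, ~14 s between shots) stands in for the
# undeposited raw recordings; the full-size study conditions are the
# generator's defaults and can be requested by editing `cfg` below.
# Writes: results/session/S0x.edf, events.tsv, behavior.csv,
# ground_truth.json, plus the per-trial artifact log.

library(preshot)
library(jsonlite)

out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(
  n_subjects = 2, n_trials = 60, fs = 256,
  channels = c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "FC5", "FC2", "C3", "Cz", "C4", "CP1", "Pz", "Oz"),
  inter_shot_mean = 14, inter_shot_jitter = 2,
  artifact_rate = 0.5, seed = 20260927L)

session <- simulate_session(cfg)

for (rec in session$recordings) {
  write_edf(rec, file.path(out, paste0(rec$subject_id, ".edf")))
}
write_events(session$events, file.path(out, "events.tsv"))
write_behavior(session$behavior, file.path(out, "behavior.csv"))
write_json(session$ground_truth, file.path(out, "ground_truth.json"),
           dataframe = "rows", digits = NA)
write.table(session$artifact_log, file.path(out, "artifact_log.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %d subjects x %d trials (%.1f min recording each)\n",
            cfg$n_subjects, cfg$n_trials,
            ncol(session$recordings[[1]]$data) / cfg$fs / 60))
cat(sprintf("injected artifacts: %d (%.2f/min)\n",
            nrow(session$artifact_log),
            nrow(session$artifact_log) /
              (cfg$n_subjects * ncol(session$recordings[[1]]$data) /
                 cfg$fs / 60)))
print(table(session$behavior$type))
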