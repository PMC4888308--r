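#!/usr/bin/env Rscript
# Stage 2 -- broadband filtering, epoching, artifact rejection report.
#
# Reads the EDF recordings written by 01_simulate.R, band-pass filters
# 0.3-40 Hz (zero-phase), cuts -6..+4 s epochs around each shot, and
# applies the threshold rejection rules to the pre-shot span.
# Writes results/rejections.tsv (per-subject retained/rejected counts).

library(preshot)

sess_dir <- "results/session"
events <- read_events(file.path(sess_dir, "events.tsv"))

rows <- list()
for (edf in sort(list.files(sess_dir, pattern = "\\.edf$",
                            full.names = TRUE))) {
  rec <- read_edf(edf)
  filtered <- bandpass_broad(rec, 0.3, 40)
  epochs <- artifact_detect(epoch_extract(filtered, events))
  rows[[rec$subject_id]] <- data.frame(
    subject = rec$subject_id,
    n_events = nrow(events[events$subject == rec$subject_id, ]),
    n_dropped_boundary = nrow(epochs$dropped),
    n_rejected_artifact = sum(epochs$artifact_bad),
    n_retained = sum(!epochs$artifact_bad))
  cat(sprintf("%s: %d epochs, %d rejected, %d retained\n",
              rec$subject_id, length(epochs$artifact_bad),
              sum(epochs$artifact_bad), sum(!epochs$artifact_bad)))
}
rej <- do.call(rbind, rows)
write.table(rej, "results/rejections.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("overall retention: %.0f%%\n",
            100 * sum(rej$n_retained) / sum(rej$n_events)))
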