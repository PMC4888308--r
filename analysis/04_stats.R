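#!/usr/bin/env Rscript
# Stage 4 -- quadrant bookkeeping and the electrode-wise ANOVA battery.
#
# One 4 x 3 (performance x time) repeated-measures ANOVA per (band,
# electrode) on the per-subject ERD/ERS cell means, Huynh-Feldt
# correction gated on Mauchly's test, partial eta squared, and Fisher
# LSD post-hocs for significant performance effects. With the 2-subject
# demonstration session this stage is structural (2 subjects give no
# power and singular interaction contrasts -- expect warnings); run
# 01_simulate.R with more subjects for meaningful statistics.
# Writes results/quadrant_counts.tsv, stats.json, stats_significant.tsv.

library(preshot)
library(jsonlite)

behavior <- read_behavior("results/session/behavior.csv")
rule <- quadrant_rule()
counts <- quadrant_counts(behavior, rule)
write.table(data.frame(type = names(counts), n = counts),
            "results/quadrant_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("trials per quadrant (fixed rule 10.2 / 4):\n")
print(counts)

erders <- read_erders_table("results/erders.tsv")
battery <- suppressWarnings(run_stats_battery(erders))
write_json(battery$results, "results/stats.json", dataframe = "rows",
           digits = NA, auto_unbox = TRUE)
write.table(battery$significant, "results/stats_significant.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("\n%d ANOVAs run (%d electrode x band pairs skipped)\n",
            nrow(battery$results) / 3, length(battery$skipped)))
cat(sprintf("%d effects below alpha = .05 (uncorrected family):\n",
            nrow(battery$significant)))
if (nrow(battery$significant) > 0) {
  print(battery$significant[, c("variable", "electrode", "band", "dfs",
                                "F", "p_corrected", "eta_p2")],
        digits = 3, row.names = FALSE)
}
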