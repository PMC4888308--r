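#!/usr/bin/env Rscript
# Stage 5 -- topographic ERD/ERS figures.
#
# Renders, per band, the 4 performance types x 3 pre-shot windows grid
# of scalp maps (inverse-distance interpolation on the 10-20 montage,
# diverging scale symmetric about 0: maximum ERD red, maximum ERS
# blue). Figures go to results/figures/topomap_<band>.png.

library(preshot)
library(jsonlite)

grand <- read_json("results/grand_average.json", simplifyVector = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

frames <- list()
for (g in grand) {
  chans <- unlist(g$channels)
  mat <- do.call(rbind, lapply(g$index, unlist))
  rownames(mat) <- chans
  pos <- montage_1020(chans)
  for (w in seq_len(ncol(mat))) {
    key <- paste(g$band, g$type, paste0("w", w), sep = "|")
    frames[[key]] <- topomap(setNames(mat[, w], chans), pos)
  }
}

for (bd in unique(vapply(grand, `[[`, character(1), "band"))) {
  sel <- frames[startsWith(names(frames), paste0(bd, "|"))]
  lim <- max(abs(unlist(lapply(sel, function(f)
    f$grid[!is.na(f$grid)]))))
  p <- plot_topomaps(sel, limit = lim,
                     title = sprintf("ERD/ERS %% (%s), max |%%| = %.1f",
                                     bd, lim))
  fp <- file.path("results/figures", paste0("topomap_", bd, ".png"))
  ggplot2::ggsave(fp, p, width = 8, height = 9, dpi = 120)
  cat("wrote", fp, "\n")
}
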