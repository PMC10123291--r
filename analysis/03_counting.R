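#!/usr/bin/env Rscript

# Stage 3: automated cell counting in the nuclei channel.
#
# Blur -> Otsu threshold -> fill holes -> watershed -> size filter, then
# assignment of nucleus centroids to cell labels to flag ROIs containing
# multinucleated cells.

suppressMessages(library(gliamorph))

index <- read.csv("results/data/roi_index.csv")
rows <- list()
for (i in seq_len(nrow(index))) {
  roi <- read_roi(index$dir[i])
  cn <- count_nuclei(roi$nuclei, roi$pixel_size_um)
  npc <- suppressWarnings(nuclei_per_cell(roi$labels, cn,
                                          roi$pixel_size_um))
  rows[[i]] <- data.frame(
    animal = index$animal[i], genotype = index$genotype[i],
    treatment = index$treatment[i], n_cells_truth = nrow(roi$truth),
    n_counted = cn$n_cells, density_per_mm2 = cn$density_per_mm2,
    multinucleated = npc$multinucleated)
}
counts <- do.call(rbind, rows)
write.csv(counts, "results/counts.csv", row.names = FALSE)
err <- with(counts, abs(n_counted - n_cells_truth) / pmax(n_cells_truth, 1))
cat(sprintf("counted %d ROIs; median |count error| %.1f%%; %.0f%% of ROIs multinucleated\n",
            nrow(counts), 100 * median(err),
            100 * mean(counts$multinucleated)))
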