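#!/usr/bin/env Rscript

# Stage 1: simulate the study's raw inputs.
#
# One imaging field (ROI) per animal and condition -- 2 genotypes
# (CTRL / KO) x 6 animals x 5 conditions (untreated control, BzATP,
# LPS+BzATP, JNJ-47965567, A-804598) -- plus one multiplex cytokine
# plate with duplicated 6-point 10x standards, two control wells per
# animal and two medium-only background wells.  Everything is written
# under results/data/ with its ground truth.

suppressMessages(library(gliamorph))

seed <- 20260
n_animals <- 6
cells_per_roi <- 15
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mx <- default_mixtures()
conds <- c("control", treatment_levels())
idx <- 0
index <- list()
for (gt in c("CTRL", "KO")) for (a in seq_len(n_animals)) {
  for (tr in conds) {
    idx <- idx + 1
    row <- mx[mx$genotype == gt & mx$treatment == tr, ]
    roi <- generate_roi(
      c(row$round_amoeboid, row$polarized, row$ramified),
      n_cells = cells_per_roi, seed = seed + idx,
      pixel_size_um = 1.5, roi_px = c(380L, 380L))
    dir_i <- file.path(out, sprintf("roi_%s_%d_%s", gt, a,
                                    gsub("[^A-Za-z0-9]", "", tr)))
    write_roi(roi, dir_i)
    index[[idx]] <- data.frame(dir = dir_i, genotype = gt,
                               animal = paste0(gt, "_", a), treatment = tr)
  }
}
write.csv(do.call(rbind, index), file.path(out, "roi_index.csv"),
          row.names = FALSE)
cat("wrote", idx, "ROIs (", n_animals, "animals x 2 genotypes x",
    length(conds), "conditions )\n")

plate <- generate_cytokine_experiment(
  plate_design(n_animals = n_animals), seed = seed)
write_plate(plate, file.path(out, "plate"))
cat("wrote plate:", nrow(plate$standards), "standard wells,",
    nrow(plate$samples), "sample/background wells,",
    length(unique(plate$standards$analyte)), "analytes\n")
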