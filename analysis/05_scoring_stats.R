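#!/usr/bin/env Rscript

# Stage 5: composite Z scores and group statistics.
#
# Trims raw descriptor values per genotype x treatment group (1.7 x IQR
# quartile fences), forms per-animal descriptor n-folds against each
# animal's untreated condition, standardizes KO values against the CTRL
# group per condition (Z tests), averages them into cytokine-cluster and
# shape Z scores, and combines core clusters with the matching shape
# descriptor into the ProIF / AntiIF scores.  Group statistics follow
# the test-to-comparison routing: chi-square for morphotype proportions,
# Welch t for cytokine n-folds, Kruskal-Wallis + Dunn for descriptor
# panels, ANOVA + Tukey for Z-score panels.

suppressMessages(library(gliamorph))

cells <- read.csv("results/cells.csv")
cells$morphotype <- factor(cells$morphotype, levels = morphotype_levels())
records <- read.csv("results/cytokine_records.csv")

shape_folds <- shape_fold_table(cells)
write.csv(shape_folds, "results/shape_folds.csv", row.names = FALSE)

cyto <- subset(records, role == "treatment")
zpanel <- zscore_panel(cyto, shape_folds)
write.csv(zpanel, "results/zscore_panel.csv", row.names = FALSE)
zsum <- aggregate(zpanel[c("z_pro_all", "z_anti_all", "proif", "antiif")],
                  by = list(treatment = zpanel$treatment), FUN = mean,
                  na.rm = TRUE)
print(zsum, digits = 2)

run <- structure(list(cells = cells, cytokines = records,
                      shape_folds = shape_folds, zpanel = zpanel,
                      manifest = list(seed = NA, config_hash = "staged")),
                 class = "pipeline_run")
tests <- pipeline_tests(run)
write.csv(tests, "results/tests.csv", row.names = FALSE)
run$tests <- tests
write_report(run, "results/report.md")
cat("wrote results/tests.csv (", nrow(tests), "tests ) and results/report.md\n")
sig <- subset(tests, stars != "ns")
cat("significant comparisons:", nrow(sig), "of", nrow(tests), "\n")
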