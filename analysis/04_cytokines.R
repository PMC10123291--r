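#!/usr/bin/env Rscript

# Stage 4: multiplex cytokine calibration.
#
# Fits a five-parameter logistic standard curve per analyte from the
# duplicated 6-point 10x serial dilution, interpolates every sample well,
# doubles for the 1:2 sample dilution, subtracts the mean background
# (medium-only) concentration, and expresses each treatment well as
# n-fold of the same animal's pooled control wells.

suppressMessages(library(gliamorph))

plate <- read_plate("results/data/plate")
cal <- calibrate_plate(plate$standards, plate$samples)
write.csv(cal$records, "results/cytokine_records.csv", row.names = FALSE)

calib <- do.call(rbind, lapply(cal$fits, function(f)
  data.frame(analyte = f$analyte, A = f$A, D = f$D, C = f$C, B = f$B,
             g = f$g, sse = f$sse, converged = f$converged)))
write.csv(calib, "results/calibration.csv", row.names = FALSE)
cat("fitted", nrow(calib), "standard curves; all converged:",
    all(calib$converged), "\n")

r <- cal$records
cen <- mean(r$censored != "ok")
cat(sprintf("%d wells interpolated, %.1f%% censored out of range\n",
            nrow(r), 100 * cen))
tr <- subset(r, role == "treatment" & !is.na(n_fold))
fold <- aggregate(list(n_fold = tr$n_fold),
                  by = list(analyte = tr$analyte, genotype = tr$genotype,
                            treatment = tr$treatment), FUN = mean)
write.csv(fold, "results/cytokine_folds.csv", row.names = FALSE)
il6 <- subset(fold, analyte == "IL6" & treatment == "LPS+BzATP")
cat("IL-6 n-fold under LPS+BzATP:",
    paste(sprintf("%s %.1f", il6$genotype, il6$n_fold), collapse = ", "),
    "\n")
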