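# gliamorph

Microglia are the brain's resident immune cells; their activation state
shows up jointly in their **shape** (resting cells are ramified,
activated cells round up) and in the **cytokines** they secrete.
Experiments probing receptor-dependent activation — e.g. comparing
receptor-proficient (CTRL) and knockout (KO) primary cultures across
stimulations (BzATP, LPS+BzATP) and selective antagonists
(JNJ-47965567, A-804598) — therefore need three analysis layers glued
together: single-cell morphometry, multiplex immunoassay calibration,
and a composite score that fuses both readouts per animal.

`gliamorph` implements that pipeline for R, with a synthetic-data
generator that carries ground truth so every stage is testable without
any external dataset. It is aimed at cell-biology labs quantifying
microglial (or macrophage) activation in vitro.

## What it computes

* **Morphometry** (`measure_roi`): per-cell area, sub-pixel perimeter,
  area-preserving ellipse axes, convex area, and the descriptors

  circularity = 4πA/P², aspect ratio = major/minor,
  roundness = 4A/(π·major²) = 1/AR, solidity = A/A_convex,
  complexity index = P/A (1/µm),

  plus a process count and the three-way morphotype call:
  no processes → round/amoeboid; length-to-width ≥ 3 → polarized;
  ≥ 3 processes → ramified.
* **Counting** (`count_nuclei`, `nuclei_per_cell`): blur → Otsu →
  fill → watershed → size filter in the nuclei channel; multinucleation
  flags per ROI.
* **Cytokines** (`fit_5pl`, `calibrate_plate`): five-parameter logistic
  standard curves y = D + (A−D)/(1+(x/C)^B)^g per analyte, closed-form
  inversion with censoring outside the asymptotes, dilution doubling,
  background subtraction, and n-fold against each animal's pooled
  control wells.
* **Scoring** (`trim_outliers`, `zscore_panel`): 1.7×IQR quartile-fence
  trimming on raw values, per-animal descriptor n-folds,
  z = (X−µ)/σ of KO values against the CTRL condition group, cytokine
  cluster means, and the combined scores
  ProIF = (z_{IL-1β,IL-6,TNFα} + z_roundness)/2,
  AntiIF = (z_{IL-4,IL-10} + z_aspect-ratio)/2.
* **Statistics** (`welch_t`, `chi2_morphotype`, `kw_dunn`,
  `anova_tukey`, `stars`): the exact test-to-comparison routing used in
  this kind of study.
* **Simulation** (`generate_roi`, `generate_cytokine_experiment`):
  label/nuclei/intensity rasters with per-cell truth, and multiplex
  plates (duplicated 6-point 10× standards, two control wells per
  animal, medium-only backgrounds, lognormal noise) with true
  concentrations and effect multipliers.

## Worked example

The staged analysis under `analysis/` simulates a full experiment
(2 genotypes × 6 animals × 5 conditions, 10 cytokines) and runs every
layer:

```sh
Rscript analysis/01_simulate.R      # ROIs + plate, with ground truth
Rscript analysis/02_morphometry.R   # per-cell descriptors + morphotypes
Rscript analysis/03_counting.R      # nuclei counts, multinucleation
Rscript analysis/04_cytokines.R     # 5PL calibration + n-folds
Rscript analysis/05_scoring_stats.R # Z panels + group statistics
Rscript analysis/06_replication.R   # direction recovery across reps
```

A run prints, among other things:

```
measured 900 cells; morphotype call matches truth for 100.0%
baseline round/amoeboid fraction: CTRL 0.81, KO 0.79
counted 60 ROIs; median |count error| 0.0%; 3% of ROIs multinucleated
fitted 10 standard curves; all converged: TRUE
IL-6 n-fold under LPS+BzATP: CTRL 13.9, KO 4.6
     treatment z_pro_all z_anti_all proif antiif
1     A-804598       3.0       -5.3   2.8   -2.5
2        BzATP      -2.5        1.9  -2.6    1.3
3 JNJ-47965567       2.4       -3.7   1.5   -1.4
4    LPS+BzATP      -2.4        2.3  -1.8    1.3
```

Reading this: the classifier reproduces the generator's morphotype
truth; the calibration chain recovers the programmed IL-6 effect
(20× in CTRL vs 5× in KO, attenuated by biological noise at n = 6);
and the composite ProIF score of KO animals sits *below* the CTRL
reference (negative) under stimulation — the knockout's
pro-inflammatory response is attenuated — while antagonist conditions
score positive because the antagonists act only in CTRL. Tables land
under `results/`, including `report.md` with all panel families.

`run_pipeline(pipeline_config(seed = 1))` does the same in one call.

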