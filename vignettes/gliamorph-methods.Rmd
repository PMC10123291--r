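---
title: "Methods: morphometry, 5PL calibration and composite Z scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry, 5PL calibration and composite Z scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gliamorph` implements the computational pathway of an in vitro microglia
immunophenotyping experiment: single-cell shape measurement and
morphotype classification from label images, multiplex cytokine
quantification through five-parameter logistic (5PL) standard curves, a
control-well normalization chain, and composite pro-/anti-inflammatory
Z scores that fuse the cytokine and morphology readouts. Because studies
of this kind rarely release raw images or plate files, the package pairs
every analysis stage with a synthetic-data generator that carries ground
truth, so the whole pipeline is verifiable end to end.

## Morphometry

Cells arrive as label rasters (0 = background, k = cell id) with a pixel
size in µm. For each region `measure_cell()` computes:

* **Area** — pixel count × pixel area. Holes are filled first; a region
  must be non-empty and connected.
* **Perimeter** — length of the sub-pixel iso-contour at level 0.5 of
  the mask smoothed with a Gaussian of σ = 1 px. Counting pixel edges
  systematically inflates the perimeter of smooth boundaries, which
  pushes circularity beyond its theoretical bound of 1; the smoothed
  contour stays within ~1% of analytic values for disks and within ~1%
  for squares (slight corner rounding is the price).
* **Ellipse axes** — from the second-order central moments (with the
  1/12 unit-square correction), then rescaled so that the ellipse area
  π·(major/2)·(minor/2) equals the region area exactly. This
  *area-preserving* convention makes roundness the exact reciprocal of
  aspect ratio, an identity the suite checks to 1e-9.
* **Convex area** — shoelace area of the convex hull over the four
  corners of every region pixel, exact for polygonal shapes and never
  below the pixel area.

`shape_descriptors()` derives circularity 4πA/P², aspect ratio
major/minor, roundness 4A/(π·major²), solidity A/A_convex, and the
complexity index P/A (unit 1/µm) — a deliberately simple ramification
proxy: the longer the boundary relative to the enclosed area, the more
complex the cell. Circularity and solidity are clamped to [0, 1]
because discretization can overshoot the closed-form bound. Aspect
ratio is ≥ 1 by construction (major ≥ minor), even though looser
interval statements are sometimes quoted for it.

### Process counting and morphotype classification

The morphotype taxonomy is: round/amoeboid (no processes),
polarized/rod-like (length-to-width ratio ≥ 3), ramified (≥ 3
processes). Published work typically classes cells manually; an
automated surrogate for "has a process" is needed. `count_processes()`
takes the soma as the maximal inscribed disk (distance-transform
maximum), then labels mask pixels outside the disk expanded by 1.15 and
counts components whose radial extent beyond the expanded disk exceeds
`k` × soma radius (`k` = 0.5 by default; exposed because the boundary
between a process and a boundary ruffle is a judgment call). A design
consequence worth stating: the poles of a strongly elongated rod
protrude past its inscribed disk and count as "processes". This is
intended — the decision order in `classify_morphotype()` (no processes →
round; else AR ≥ 3 → polarized; else ≥ 3 processes → ramified) then
routes rods to the polarized class, matching how a human rater treats a
rod's ends. Cells with 1–2 processes and AR < 3 fall outside the
three-class taxonomy; they are assigned round/amoeboid and flagged,
which keeps the binary grouping [round/amoeboid] vs
[polarized + ramified] conservative. Cells touching the ROI border are
excluded by default because truncated geometry corrupts every
descriptor.

## Nuclei counting

`count_nuclei()` emulates a standard counting macro: Gaussian blur
(σ = 2 px) → global Otsu threshold → hole filling → distance-transform
watershed (to split touching nuclei) → size filter (default 10–500 µm²).
All parameters sit in the call signature; the fidelity target is count
accuracy against ground truth (≤ 2% error on well-separated nuclei),
not step-identity with any particular macro. `nuclei_per_cell()` assigns
each nucleus centroid to the cell label under it and flags ROIs
containing a cell with ≥ 2 nuclei (multinucleation).

## Cytokine calibration

The 5PL parameterization is the common immunoassay convention

y = D + (A − D) / (1 + (x/C)^B)^g,

with A the response at zero concentration, D at saturation, C > 0 the
transition concentration, B the slope and g > 0 the asymmetry (g = 1 is
the 4PL). `fit_5pl()` runs Levenberg–Marquardt least squares on
(A, D, log C, B, log g) from a grid of starts (log-spaced C over the
standard range × g ∈ {0.5, 1, 2}), unweighted by default with optional
1/y² weighting. The inverse is closed-form; responses outside the open
interval between the asymptotes are *censored* (flagged low/high), never
extrapolated — standard immunoassay practice. Numerically, the
forward/inverse round trip is exact (≪ 1e-9 relative) across the
quantifiable mid-range of the curve; in the far asymptote tails the
subtraction y − D loses precision in double arithmetic, which is a
property of the function, not the fit, and is why interpolation outside
the standards' range is refused anyway.

The correction chain mirrors the bench protocol: interpolated
concentration × dilution factor (2, for samples mixed 1:1 with diluent)
− mean background concentration of the medium-only wells, floored at 0
(concentrations are physical). Treatment wells are then expressed as
n-fold of the mean of the same animal's two pooled control wells; a
zero control mean produces a missing value with reason code
`zero_control_mean` rather than any pseudo-count — the right divisor fix
is a scientific decision the analyst must make knowingly, so nothing is
imputed silently.

## Trimming, normalization and composite Z scores

Outliers are trimmed from **raw** values per genotype × treatment ×
metric group, using quartile fences Q1 − 1.7·IQR / Q3 + 1.7·IQR. The
1.7 multiplier (wider than Tukey's 1.5) is the analysis default and is
exposed. Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7, the common default of mainstream statistics
software); the convention is recorded in the output because the fences
depend on it. Groups of fewer than 4 values skip the rule with a
warning.

Z scoring standardizes knockout (KO) values against the receptor-
proficient control group: z = (X − µ)/σ with µ, σ the CTRL mean and SD
of the same analyte and condition. Cluster scores are equal-weight means
over non-missing members (when a member is censored it simply drops
out; the alternative — re-weighting or imputing — would manufacture
information). Two cluster variants are provided: "all" (every panel
cytokine with the given directionality) and "core" (IL-1β, IL-6, TNFα
pro-inflammatory; IL-4, IL-10 anti-inflammatory). The combined scores
average the core cytokine cluster with the directionally matched shape
descriptor: ProIF = (z_cluster,pro + z_roundness)/2 and AntiIF =
(z_cluster,anti + z_aspect-ratio)/2. Combined scores are missing if
either component is missing.

## Group statistics

The test-to-comparison routing is fixed: Welch t (two-tailed,
Satterthwaite df) for two-group cytokine n-folds; Pearson χ² without
continuity correction on the 2×2 table [round/amoeboid] vs
[polarized+ramified] × [control, treatment] (cell counts are in the
hundreds, where the Yates correction is negligible); Kruskal–Wallis with
midrank tie correction followed by Dunn's z tests for multi-group
descriptor panels; one-way ANOVA with Tukey HSD for Z-score panels.
Dunn's pairwise p values are Bonferroni-adjusted over the tested pairs —
the adjustment method is not universal across software, so it is
recorded in the output rather than assumed. Significance tiers are
ns / * / ** / *** / **** at 0.05, 0.01, 0.001, 0.0001.

## The synthetic-data generator

**Images.** A cell is a noisy ellipse soma (area-preserving axes,
boundary radius modulated by four random Fourier harmonics, amplitude
6% by default) plus tapered straight processes anchored inside the soma
at jittered angles. Defaults per morphotype — round: soma radius 12 µm,
no processes, elongation 1.15; polarized: soma 9 µm, elongation 3.5,
two polar processes; ramified: soma 7 µm, five processes of ~22 µm —
are stated configuration, chosen as realistic for serum-grown primary
microglia (baseline mean cell area ≈ 450–550 µm²), not inferred from
any dataset. ROIs place cells without overlap (bounded rejection
sampling), default 1000×1000 px at 1 µm/px (~1 mm² field), draw
morphotypes from a configurable mixture, give each cell one nucleus
blob at its soma centre, and make one cell binucleated in 5% of ROIs.
Generators are pure functions of (parameters, seed).

**Plates.** Each analyte has a fixed true 5PL curve (instrument
characteristics). An animal's untreated wells secrete a per-analyte
base concentration times a per-animal lognormal biological factor
(CV 0.25); treatments multiply secretion by an analyte × genotype ×
treatment effect multiplier; wells are diluted 1:2 into medium
background; responses get multiplicative lognormal noise (CV 0.08, the
standard immunoassay error model). Standards are a duplicated 6-point
10× serial dilution from 10 000 pg/mL; two medium-only wells provide
the background. At zero noise the calibration chain inverts the
generator exactly (< 1e-6 relative), which pins down the algebra of the
whole chain.

**Effect tables.** The default multipliers encode qualitative
directions only: stimulation (BzATP, more strongly LPS+BzATP) raises
pro-inflammatory cytokines with larger effects in CTRL than KO (e.g.
IL-6 under LPS+BzATP: 20× vs 5×); BzATP depresses IL-4 about 9-fold in
CTRL and 6-fold in KO; the two P2X7R antagonists lower pro-inflammatory
cytokines and double IL-4 in CTRL only, with no programmed effect in
KO. The morphotype mixtures move in parallel (baseline round fraction
0.79 CTRL / 0.83 KO; stimulation raises it, BzATP more in CTRL;
antagonists lower it to 0.65 in CTRL only). Magnitudes are model
parameters for testing the pipeline, not claims about any biological
dataset. On the antagonist arm the literature is not unanimous
(pro-inflammatory decreases in both genotypes are also reported); the
generator deliberately programs the CTRL-only variant because it gives
the sharper falsifiable contrast for verifying that the pipeline
separates genotypes.

**What the generator does not emulate** — and what passing tests
therefore cannot show about real data: optics (PSF, shading, focus),
segmentation errors (masks are perfect by construction), touching or
overlapping cells, intensity-dependent morphology, plate effects
(edge effects, carry-over, bead aggregation), censoring beyond the
standards' range under realistic concentrations, and any quantitative
effect magnitude. Tests on synthetic data validate the *computational
pathway* — formulas, decision rules, normalization algebra, test
routing — not the biology.

## Interpreting the composite scores on synthetic data

Since Z tests standardize KO values against the CTRL group of the same
condition, a KO population that behaved exactly like CTRL would score
~0. The programmed attenuation of stimulation effects in KO therefore
shows up as ProIF scores *below* the CTRL reference (negative), i.e.
the KO pro-inflammatory response sits nearer the untreated state than
the CTRL response does. The replicate study asserts exactly this
direction, plus the two morphotype directions, in ≥ 90% of replicates.

## Problem sizes and numerical choices

The replicate study (`replication_study()`) uses 100 replicates of
8 animals per genotype, one ROI per animal and condition with 20 cells
at 1.5 µm/px in a 380×380 px field — a deliberately compact imaging
scale the classifier handles without loss (it is exact on clean
single-cell fixtures at both 1.0 and 1.5 µm/px), chosen so a full study
runs in minutes on one core. The staged example analysis under
`analysis/` uses 6 animals per genotype and 15 cells per ROI. Other
constants: contour smoothing σ = 1 px (accuracy of analytic shapes);
soma expansion 1.15 (tolerates boundary noise without spurious
processes); 5PL fit tolerances 1e-15 with up to 15 starts and an early
exit when the curve is essentially exact; placement retries capped at
200 before a placement error. The Kruskal–Wallis χ² approximation is
used for the omnibus p (group sizes ≥ 8 in routed uses).

## Known limitations

* The process counter is radial: a strongly curved process that bends
  back toward the soma can be under-measured. The generator's straight
  processes do not probe this.
* With n-fold normalization, a near-zero control mean produces unstable
  folds upstream of trimming; delta normalization is provided for such
  metrics.
* The 5PL fit is identifiable from 6-point standards only when the
  transition is covered; curves whose C sits outside the dilution range
  converge to boundary solutions and should be reviewed via the stored
  SSE and convergence flag.
* Dunn's test uses the normal approximation; very small groups (< 4)
  deserve exact methods instead.
* The composite scores inherit the CTRL group's sampling noise through
  µ and σ; with few control animals the scores are noisy in ways the
  equal-weight averaging does not repair.
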