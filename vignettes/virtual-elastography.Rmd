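---
title: "Virtual MR elastography from diffusion-weighted MRI: models, simulation design and diagnostic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual MR elastography from diffusion-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmre)
```

## The measurement model

Liver fibrosis stiffens tissue, and stiffness can be measured mechanically
(MR elastography, shear-wave ultrasound) or estimated from water diffusion.
Diffusion-weighted MRI acquired at two non-zero b-values yields the
*shifted apparent diffusion coefficient*,

$$\mathrm{sADC} = \frac{\ln(S_{b_1}/S_{b_2})}{b_2 - b_1},$$

here with $b_1 = 200$ and $b_2 = 1500$ s/mm² so that $b_2 - b_1 = 1300$;
using two non-zero b-values suppresses the perfusion contribution that
contaminates ADC estimates anchored at $b = 0$. *Virtual MR elastography*
(VMRE) converts this diffusivity into a surrogate stiffness through a fixed
linear calibration against conventional MRE:

$$\mathrm{VMRE\ (kPa)} = \alpha \cdot \mathrm{sADC} + \beta,
\qquad \alpha = -12.740,\ \beta = 14.0,$$

with sADC expressed in units of $10^{-3}$ mm²/s. The negative slope encodes
that fibrotic (stiff) tissue restricts diffusion. The package stores sADC on
the $10^{-3}$ mm²/s scale throughout; the worked anchor is
$0.69 \mapsto -12.740 \cdot 0.69 + 14.0 = 5.21$ kPa:

```{r}
m <- compute_sadc_map(dwi_series(array(1000, c(2, 2, 2)),
                                 array(1000 / exp(1300 * 0.69e-3), c(2, 2, 2))))
round(sadc_to_vmre(m)$values[1, 1, 1], 2)
```

Clinical tables print sADC values near 0.7 "mm²/s"; physically these are
$10^{-3}$ mm²/s, and the calibration constants only make sense on that
scale — the anchor above is the consistency check.

### Masking policy

$\ln(S_1/S_2)$ is undefined when either signal is zero, and noise can invert
the decay so that sADC comes out negative (implying VMRE above $\beta$).
`compute_sadc_map()` masks non-positive signals as invalid rather than
clamping them (clamping would fabricate extreme diffusivities), keeps
negative sADC voxels in the values with `valid_mask` set, and flags them in
a secondary `physical_mask`. ROI statistics use the valid mask by default;
silently discarding noise-inverted voxels would bias ROI means in noisy
regions.

## What the simulator emulates

No imaging data is distributed with the study design, so the package
includes a first-class generator with two decoupled paths.

**The phantom path** inverts the measurement model: a single-organ block
phantom (central block with a 1/8 margin) receives a voxelwise true
stiffness drawn from a stage's $(\mu, \sigma)$, the implied sADC is
$(\beta - \text{stiffness})/(-\alpha)$, and noiseless signals are
$S_{200} = s_0$, $S_{1500} = s_0 e^{-1300\,\mathrm{sADC}}$. Voxels whose
stiffness reaches $\beta = 14$ kPa would imply non-positive sADC — a
nonphysical corner of the linear calibration — and are excluded from the
label volume rather than clamped. Magnitude noise is Rician,
$\sqrt{(S+n_1)^2 + n_2^2}$ with $n_i \sim N(0, (s_0/\mathrm{snr})^2)$, the
standard model for MR magnitude images; the acquisition SNR is not a
published quantity, so it is a free simulation knob with default 30 (a
mid-range abdominal DWI figure). With noise disabled the
generate-then-reconstruct round trip is exact to floating-point precision,
which is the core correctness invariant of the map engine. At SNR 30 the
Rician floor biases the median reconstructed stiffness upward by roughly
0.04 kPa on a 4 kPa phantom — visible in the replicate-calibrated tolerance
band used in the tests.

**The cohort path** draws per-patient quantities directly, because the
diagnostic statistics operate on per-patient summaries, not voxels. The
defaults encode the study conditions:

| parameter | default | rationale |
|---|---|---|
| stage counts F0..F4 | 8/16/6/12/7 (n = 49) | the study cohort's METAVIR histogram, counting the three F1 patients without established chronic liver disease who were included in all analyses |
| HBV fraction | 0.67 | gives `round(49 × 0.67) = 33` HBV patients, the analyzed subgroup size |
| true stiffness per stage | MRE reference means/SDs (2.13±0.27 … 5.2±1.02 kPa) | the same table that defines the staging thresholds, so generated stiffness is on the thresholds' scale |
| reader noise SD | 0.21 kPa | back-derived from the reported between-reader difference SD 0.299 kPa ($0.299/\sqrt{2}$); a 200-cohort variance-components check places the mean ICC(2,1) at ≈ 0.97, inside the 0.95–0.99 band of the reported 0.972 |
| ultrasound per stage | 6.0±4.11 … 18.05±4.84 kPa | the all-etiology per-stage ultrasound table |
| stiffness floor | 0.1 kPa | truncation keeping all draws physically positive |

Both ultrasound acquisitions are drawn independently from the stage
distribution. That reproduces the per-stage marginals and the high-AUC
regime for advanced fibrosis, but it makes within-patient ultrasound
variance equal the full between-patient stage SD, so the simulated
ultrasound intra-observer ICC sits well below the reported 0.756; the
cohort model has no separate per-patient ultrasound truth. The reader model
does carry a per-patient truth, so the VMRE inter-reader ICC is faithfully
in the reported regime.

A single master seed fans out to named substreams (truth, readers,
ultrasound, etiology, per-stage phantoms) so regenerating one component, or
adding a stage, does not shift the other streams; identical configuration
and seed give bit-identical volumes and tables.

**What passing tests do not show about real data.** The phantom has no
anatomy, vessels, fat, iron, motion or susceptibility artifacts, and the
cohort model assumes Gaussian stage-conditional distributions with
independent readers. Recovery of the generating parameters here validates
the computational chain, not clinical performance; in particular the
simulated staging concordance is far higher than clinically reported
concordance, because the generator draws truth from the very distributions
that define the thresholds, with no cross-platform offset between DWI-based
and mechanical stiffness scales.

## ROI protocol

Reading follows the clinical protocols: VMRE ROIs must span at least three
consecutive slices (enforced as a validation error); ultrasound-style
circular ROIs default to 10 mm diameter and are rasterized by voxel-center
inclusion with boundary ties counted in. The per-patient summary is the
statistic of per-ROI statistics (mean of ROI means by default — the
protocol averages ROI readings; pooled-voxel medians are available via
`stat = "median"`). Empty ROIs are dropped with a warning; an all-empty set
is an error. The elastography quality rule IQR/median ≤ 30% is boundary
inclusive and uses linear-interpolation (type 7) quartiles — the convention
is not specified clinically, so it is fixed and documented for
reproducibility. Depth-from-capsule constraints are not modeled: the block
phantom has no capsule.

## Staging against fixed MRE thresholds

The reference table gives per-stage means and SDs but no assignment rule
for a continuous value. The package defaults to *midpoint* boundaries
between consecutive means (2.31, 2.66, 3.215, 4.4 kPa), which partition the
line completely and preserve order; *nearest-mean* assignment is provided
for sensitivity analysis (identical here up to boundary ties, but not under
non-uniform spacing). Boundary ties go to the lower, less severe stage — a
conservative choice. Whether the original categorization used SD-derived
(possibly overlapping) bands is unknown; the SDs are carried but unused by
the hard rules. Concordance is summarized as exact match, within-one-stage,
and binary agreement under both clinical groupings (significant fibrosis
F0–1 vs F2–4; advanced fibrosis F0–2 vs F3–4), with percentages rounded to
integers as in clinical reports.

## Diagnostic statistics

* **ROC / Youden.** Empirical ROC over all observed thresholds with
  "≥ cutoff ⇒ positive" (higher stiffness = more fibrosis). The trapezoidal
  AUC equals the Mann–Whitney concordance statistic (ties ½) — asserted in
  tests at 1e-12. The cutoff maximizes $J = \text{sens} + \text{spec} - 1$;
  the argmax is taken on the integer score
  $tp \cdot n_{neg} - fp \cdot n_{pos}$ so exact ties cannot be broken by
  floating-point rounding, with ties resolved toward higher specificity,
  then the lower observed cutoff (reported cutoffs are observed values, not
  midpoints). The AUC interval is a seeded stratified bootstrap (2000
  resamples), since no analytic method was specified.
* **ICC.** Two-way random effects, absolute agreement, single measure —
  ICC(2,1) — computed from the ANOVA mean squares with the standard F-based
  interval. Chosen because two fixed readers measure every subject and
  systematic reader offsets should count against agreement; identical
  columns with subject variation return exactly 1 (flagged), zero total
  variance is undefined (flagged).
* **Bland–Altman.** Mean and sample SD of differences, both the
  conventional ±1.96 SD limits and the ±1 SD band used in the agreement
  plots.
* **Kruskal–Wallis / Dunn.** Tie-corrected H with the chi-square
  approximation (df = k−1); Dunn z on pooled ranks with tie correction and
  Bonferroni adjustment min(1, m·p), m = k(k−1)/2 (10 for five stages). At
  n = 9 the chi-square p deviates from the exact permutation null by up to
  ~0.05 — tests compare against a 10⁵-permutation oracle with that
  approximation bias accounted for, and the H statistic itself matches the
  oracle to 1e-9.
* **ANOVA / normality.** Classical equal-variance one-way F for the
  parametric comparisons; normality screening by Lilliefors-corrected KS
  (parameters estimated from the sample) with a seeded Monte-Carlo null
  rather than the asymptotic table.

## Problem sizes and numerical choices

Phantoms default to 32³ voxels at 4×4×6 mm — enough for stable voxel
statistics while generation plus mapping stays in milliseconds; replicate
counts in tests and the acceptance script (100–200 cohorts, 10⁵
permutations for the rank-test oracle) were chosen to hold Monte-Carlo
error well below the effects being checked. Stiffness draws are floored at
0.1 kPa; kPa is reported to 2 decimals and sADC to 3 in formatted outputs.
Degenerate inputs (single-class labels, all-tied samples, zero variance)
return flagged results or named errors rather than NaNs, and the pipeline
records such per-block errors in the report instead of aborting.

## Known limitations

The printed clinical sADC/VMRE tables are mutually inconsistent under the
affine calibration for most rows (only the all-patients F1 pair 0.69 → 5.21
is exact); the package uses that consistent pair as its anchor and does not
attempt to reconcile the others. Multi-b-value ADC fitting, IVIM,
fat-fraction-corrected VMRE variants, anatomical simulation and DICOM
ingestion are out of scope.
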