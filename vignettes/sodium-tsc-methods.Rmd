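---
title: "Quantifying tissue sodium concentration around radiosurgically treated brain metastases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sodium TSC methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(na23tsc)
```

# The problem

Single-fraction stereotactic radiosurgery (SRS) ablates brain metastases
with steep dose gradients, and early imaging markers of tissue response
are scarce. Sodium (^23^Na) MRI measures the tissue sodium concentration
(TSC, mM), which rises acutely after irradiation (membrane damage,
edema) and later recovers. `na23tsc` provides a fully simulated,
end-to-end re-implementation of a longitudinal TSC quantification
pipeline: a digital head phantom with a three-timepoint TSC evolution, a
simplified Gamma-Knife-like dose model, simulation and regridding
reconstruction of a density-adapted 3-D radial sodium acquisition, rigid
co-registration and tissue segmentation, vitreous-humor (VH) normalized
TSC quantification, isodose-shell dosimetric statistics, and the
longitudinal statistical analysis (paired t-tests, dose–TSC Pearson
correlation).

No clinical raw data are involved anywhere: the phantom generator
defines the ground truth that the measurement chain must recover, which
is what every test in the package checks.

# The quantification model

The sodium signal under a spoiled, long-TR, ultrashort-TE acquisition is
modelled as saturation recovery,

$$ S(\mathbf{x}) = \mathrm{TSC}(\mathbf{x})\,
   \bigl(1 - e^{-TR/T_1(\mathbf{x})}\bigr)\, e^{-TE/T_2^*(\mathbf{x})}, $$

with TR = 100 ms and TE = 0.4 ms so that both weighting factors are
close to 1. Quantification normalizes each reconstructed image to the
mean signal in the patient's left vitreous humor, whose sodium
concentration is taken as a constant 145 mM. Because the VH relaxes
slowly (T1(VH) = 50 ms), its signal is first corrected by the
saturation factor:

$$ \mathrm{SI}_{T_1\mathrm{corr}}(VH) = \frac{\mathrm{SI}(VH)}{1 - e^{-TR/T_1(VH)}},
   \qquad
   \mathrm{TSC}(\mathbf{x}) = \mathrm{SI}(\mathbf{x})\,
   \frac{145\ \mathrm{mM}}{\mathrm{SI}_{T_1\mathrm{corr}}(VH)} . $$

Only the reference is T1-corrected — tissue T1 weighting is deliberately
left in, because the long TR already minimises it. The residual,
predictable bias of a tissue with relaxation time $T_1^t$ is therefore
the tissue's own saturation factor, $1 - e^{-TR/T_1^t}$ (≈ 0.94 for
brain tissue at $T_1$ = 35 ms; TE factors cancel when $T_2^*$ is
uniform). The test suite verifies the measured phantom bias against this
closed form to within 3%; the remaining discrepancy (≈ 2%) is Gibbs
ringing and partial volume at the band limit, which we verified
separately by comparing the reconstruction to an ideal band-limited
truncation of the same object (agreement ≈ 0.1%).

A consequence worth noting: under this normalization convention the
VH itself maps to $145(1 - e^{-TR/T_1(VH)}) \approx 125$ mM in the TSC
map, not 145 mM — only fully relaxed tissue would reach the nominal
value.

# The phantom

`generate_phantom()` builds an ellipsoidal head at (by default) 1 mm
isotropic resolution: a white-matter core, a 4 mm cortical grey-matter
ribbon, ventricular and subarachnoid CSF, two 11 mm-radius vitreous-humor
spheres anterior to the brain, spherical contrast-enhancing lesions with
an exponentially decaying peritumoral edema halo, and a scalp/orbital
soft-tissue envelope (25 mM) so that organ boundaries face realistic
steps rather than vacuum. Baseline concentrations are literature values:
WM 40, GM 45, CSF 135, VH 145 (fixed), lesion 61 mM. The ground-truth
grid is deliberately much finer than the 4 mm nominal acquisition so
partial-volume effects in the simulated images are *emergent*, not
modelled.

The longitudinal evolution (`compose_evolution()`) is phenomenological —
the study this emulates reports observed means, not a mechanism:

* baseline gains `baseline_slope_gamma` (0.5 mM/Gy) times the eventual
  local dose, encoding that vasogenic edema tracks proximity to the
  lesion;
* scan II (5 days post-SRS) adds `acute_alpha` (0.35 mM/Gy) times dose;
* scan III (40 days) subtracts `late_beta` (0.55 mM/Gy) times the dose
  above a 2 Gy floor, dropping irradiated tissue below baseline;
* the GTV follows its own rise-then-fall offsets (+7 / −3 mM), since its
  response is not dose-resolved in the source data;
* CSF and VH never change (the VH at 145 mM at all timepoints is the
  calibration anchor).

Effect sizes were chosen once to reproduce the reported qualitative
pattern (shell means rising ~1–6 mM at scan II and falling below
baseline at scan III, ordered by dose). Voxel-wise biological jitter
defaults to 2 mM, and at the study level each simulated patient draws a
baseline offset (SD 4 mM for healthy tissue, 8 mM for the lesion),
reproducing across-lesion spreads of the reported size (±5–10 mM).
These spreads are otherwise unconstrained by the source material.

What the phantom does **not** emulate: cortical folding and realistic
atlas anatomy, biexponential sodium T2* decay, readout-duration T2*
blurring, B0/B1 inhomogeneity, coil sensitivity profiles, and lesion
mass effect (the ROIs are rigid across timepoints, as in the clinical
analysis). Passing tests therefore demonstrate correctness of the
measurement chain under these idealisations, not clinical performance.

# Dose model and isodose shells

`compute_dose()` replaces a clinical planning system with geometry: with
$s$ the signed Euclidean distance to the PTV surface (GTV plus a 0 or
1 mm margin), the dose is

$$ D(\mathbf{x}) = 2\,rx \cdot \min\!\bigl(1,\ 0.5\cdot 2^{-s/h}\bigr), $$

i.e. exactly the prescription on the PTV surface (the "prescribed to the
50% isodose" convention), twice the prescription in the core, and
exponential fall-off with half-distance $h$ (default 2 mm, mimicking
radiosurgical gradients; the source material gives no quantitative
gradient, so this is a free simulator parameter). Distances are computed
with an exact Euclidean distance transform, shifted by half a voxel so
the digital surface sits between voxel layers; without that correction
the innermost (18 Gy) shell is unpopulated at practical grids. Shells
are rings between consecutive levels of D = 2, 3, 4, 6, 8, 10, 12,
18 Gy, closed from inside by the prescription isodose, with GTV and PTV
voxels excluded so tumour signal never contaminates "peritumoral"
statistics; their disjointness and exact union are asserted voxel-wise
in the tests. Because the 18 Gy ring is ~0.6 mm thick at a 22 Gy
prescription, dose and shells must live on the ~1 mm ground-truth grid;
the TSC maps are brought to that grid, never the reverse.

# Acquisition and reconstruction

`make_trajectory()` builds a density-adapted 3-D radial readout: spoke
directions on a Fibonacci (spiral-phyllotaxis) lattice — a stand-in for
the scanner's unpublished scheme — and radial samples uniform in $k$ on
an inner ramp (up to $k_0 = 0.2\,k_{max}$, configurable) and uniform in
density ($k^3$ linear in sample index) beyond, with analytic
density-compensation weights ($\propto k^2\,dk$: quadratic on the ramp,
constant beyond). $k_{max} = 1/(2 \cdot 4\,\mathrm{mm})$.

The forward model (`simulate_acquisition()`) evaluates the object's
Fourier transform at the trajectory points. An exact non-uniform DFT is
retained as the test oracle; the default fast path samples a 2–4×
oversampled FFT spectrum with deapodized trilinear interpolation and
agrees with the oracle to ≲0.3% RMS (tested at ≤1%), and with the
analytic transform of a sphere to ≲1% (tested at ≤2%). Complex Gaussian
noise is added per channel with a fixed seed.

`reconstruct()` implements regridding: analytic density compensation,
convolution onto a Cartesian grid (1.5× oversampled to keep the
kernel's image-domain rolloff shallow) with a separable Hann kernel of
full width 4 cells — our reading of the protocol's "Hanning filter with
the width of 4" — zero-filling of the spectrum by 2 (4 mm nominal →
2 mm apparent voxels), inverse FFT, analytic deapodization, cropping to
the acquired FOV, and a final magnitude step. A post-hoc radial Hann
apodization is available as a flag for the alternative reading, but it
halves the effective resolution and roughly doubles partial-volume bias,
so the kernel reading is the default. On ball phantoms at realistic FOV
the reconstruction is quantitative to ≲0.5% in amplitude with <1%
background, and intensity ratios between compartments survive to <3%.

Numerical conventions: all world coordinates are LPS (DICOM patient
convention); the reconstruction grid is voxel-centre aligned with the
source FOV; deapodization is guarded at 2% of its peak to avoid
amplifying the FOV corners.

# Registration and segmentation

All sodium images are rigidly registered to the scan-I anatomical
reference (6 degrees of freedom), maximising normalized mutual
information over a multi-resolution pyramid with Nelder–Mead, a fresh
simplex restart at the finest level, and light box-smoothing of the
fixed image to regularize the histogram metric. On reconstructed sodium
phantoms, perturbations up to 5 mm / 5° are recovered to ≤0.1 mm and
≤0.35°. In simulation the true motion is always known, and a
`registration = "true"` bypass isolates downstream stages from
registration error.

Segmentation into WM/GM/CSF is a three-class Gaussian mixture on
anatomical intensities within the brain mask (classes ordered by mean:
CSF darkest, WM brightest on T1-like contrast). The EM fit is seeded
from quantile-anchored k-means because generic hierarchical
initialization tends to split the dominant WM mode instead of isolating
CSF. Voxel-wise agreement with the phantom labels exceeds 95%, and CSF
subtraction (posterior > 0.5) is applied to every ROI before statistics.

# Statistics

Per region (GTV, pooled healthy cylinders, eight shells) and scan, the
lesion-level mean TSC enters: two-sided paired t-tests for the three
scan pairs at α = 0.05 (pairwise-available: a lesion missing a scan
drops out of only the comparisons that need it), gated by a Lilliefors
Kolmogorov–Smirnov normality check used as a warning rather than a
stop; and a Pearson correlation between the eight dose levels and the
lesion-averaged shell means, one coefficient per scan. No
multiple-testing correction is applied, for fidelity to the emulated
analysis; percent changes are reported at integer precision. The
published correlation coefficients (0.92/0.96/0.86) were computed on
unrounded means that are not recoverable from printed tables, so only
sign and magnitude properties are asserted; on the printed rounded
scan-I means the coefficient is 0.9033. Lesions are treated as
independent units (the source leaves pooling across multi-lesion
patients unstated).

# Problem sizes and determinism

The clinical protocol (9,000 spokes × 384 samples, ~180 mm FOV) is
simulated at reduced sizes chosen once: quantification and registration
analyses use a 64³ × 2.5 mm phantom with 2,000 spokes (the full 384
radial samples are kept — radial density near the k-space centre is
what quantitative accuracy depends on); shell and dose-response analyses
use a 128³ × 1 mm reference grid with the acquisition simulated from a
2 mm block-average of the signal; the simulated cohort has 6 lesions ×
3 scans. Every random stage (phantom jitter, k-space noise, motion,
placement, segmentation) derives its stream from one master seed, and
fixed seeds give bit-identical phantoms, k-space, and reports.

# Known limitations

* The dose model is geometric; no beam/sector physics, heterogeneity
  corrections or DVH metrics.
* The registration validates on simulated sodium contrast; real
  sodium-to-MPRAGE registration may need the proton image of a
  dual-tuned coil (the emulated study does not say which was used; we
  register the sodium magnitude image).
* VH calibration inherits a few-percent Gibbs/partial-volume error that
  is intrinsic to an 11 mm reference organ at a 4 mm band limit; the
  erosion depth (one apparent voxel) is our choice, as the source does
  not state whether its VH contours were eroded.
* The RT-STRUCT writer's contour tracer assumes star-convex per-slice
  shapes (spheres, cylinders); it is an import/export convenience, not a
  general contouring tool.
* Whether shell "areas" were evaluated in 2-D slices or 3-D volumes is
  ambiguous in the source; we use 3-D volumes throughout.
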