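# na23tsc

Simulation and analysis pipeline for quantitative sodium (²³Na) MRI of
brain metastases treated with single-fraction stereotactic radiosurgery
(SRS).

Sodium MRI measures the tissue sodium concentration (TSC, in mM), which
is elevated in metastases and their edema, rises acutely in the
peritumoral tissue days after irradiation, and recovers over weeks.
`na23tsc` is aimed at methods researchers in quantitative MRI and
radiation oncology physics who want a fully tested, fully synthetic
re-implementation of such a longitudinal TSC study: every stage from
digital phantom to statistical report is simulated, so the ground truth
is always known and the measurement chain can be validated end to end.

## What it implements

* **Phantom** — longitudinal digital head phantom (WM/GM/CSF, two
  vitreous-humor spheres, lesions with edema halo, soft-tissue envelope)
  at 1 mm ground truth, with a three-timepoint, dose-coupled TSC
  evolution (`generate_phantom()`, `compose_evolution()`).
* **Dose model** — GTV→PTV margin growth and a Gamma-Knife-like field
  prescribed to the 50% isodose: `dose = 2·rx · min(1, 0.5·2^(−s/h))`
  with `s` the signed distance to the PTV surface
  (`expand_margin()`, `compute_dose()`).
* **Acquisition + reconstruction** — density-adapted 3-D radial sodium
  readout (9,000 spokes × 384 samples at full scale), saturation-recovery
  signal model `S = TSC·(1−e^(−TR/T1))·e^(−TE/T2*)`, exact NUDFT oracle
  plus fast FFT forward model, and regridding reconstruction with a
  width-4 Hann kernel, two-fold zero filling (4 mm nominal → 2 mm
  apparent) and analytic deapodization (`make_trajectory()`,
  `simulate_acquisition()`, `reconstruct()`).
* **Registration + segmentation** — 6-DOF rigid registration of every
  sodium scan to the scan-I anatomy by normalized mutual information;
  three-class Gaussian-mixture WM/GM/CSF segmentation
  (`register_rigid()`, `segment_tissues()`).
* **Quantification** — the central equation
  `TSC(x) = SI(x) · 145 mM / SI_T1corr(VH)`, normalizing to the left
  vitreous humor with a `1 − e^(−TR/T1)` correction at T1(VH) = 50 ms
  (`calibrate_vh()`, `quantify_tsc()`).
* **ROI dosimetry** — nested isodose shells for D = 2, 3, 4, 6, 8, 10,
  12, 18 Gy (rings between consecutive levels, tumour excluded), two
  cylindrical healthy white-matter ROIs (r = 5 mm, h = 10 mm), CSF
  subtraction, per-ROI statistics (`build_isodose_shells()`,
  `place_healthy_rois()`, `subtract_csf()`, `roi_statistics()`).
* **Longitudinal statistics** — Lilliefors-gated paired t-tests between
  scans, integer percent changes, and the per-scan Pearson correlation
  between dose level and shell mean TSC; `run_study()` drives the whole
  cohort simulation and writes a tabular report
  (`analyze_roi_stats()`, `paired_t_test()`, `dose_tsc_correlation()`).
* **I/O** — NIfTI volumes with JSON provenance sidecars, JSON
  structure sets (run-length-encoded masks), YAML study configs, and a
  minimal DICOM RT-STRUCT importer/exporter.

## Worked example

```r
library(na23tsc)

# one simulated patient: phantom -> dose -> three sodium scans ->
# reconstruction -> registration -> TSC maps -> ROI statistics
cfg <- study_config(n_lesions = 1, seed = 1)
les <- simulate_lesion_study(cfg, 1)
subset(les$stats, scan == "I",
       select = c(roi, n_voxels, mean_tsc, sd_tsc))
```

```
    roi n_voxels mean_tsc sd_tsc
1   GTV     1462     57.5   2.25
2    HR     1782     37.2   2.37
3   2Gy     3172     44.2   3.92
4   3Gy     1638     45.6   3.70
5   4Gy     2227     47.1   4.09
6   6Gy     1654     48.6   2.91
7   8Gy     1102     49.9   2.10
8  10Gy      292     51.1   1.89
9  12Gy     1388     52.5   2.06
10 18Gy      668     54.8   2.00
```

The lesion (GTV) reads highest; the healthy cylinders (HR) sit at the
white-matter level times the predictable T1 bias (40 mM × 0.94); and the
shell means increase monotonically with dose level — the baseline
dose–TSC correlation the study design expects. A full cohort
(`run_study(study_config(seed = 1))`, ~5 min) adds the scan II rise,
the scan III recovery below baseline, paired t-tests with direction
arrows, and Pearson r ≈ 0.9–1.0 per scan:

```r
rep <- run_study(study_config(seed = 1))
rep$correlations        # per-scan dose-TSC Pearson r
rep$gtv_percent_change  # integer % change of the GTV group mean
```

A thin command-line wrapper exists for shell use:

```sh
Rscript inst/cli/na23tsc-run.R --config study.yaml --seed 1 --out report
```

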