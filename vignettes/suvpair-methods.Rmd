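---
title: "suvpair: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{suvpair: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model, the algorithmic conventions, and the
design decisions behind `suvpair` — the things a maintainer or reviewer
needs to know that are not obvious from the function reference. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

Quantitative SPECT and PET both report, per voxel, an estimate of
tracer activity concentration. PET reconstructions arrive calibrated in
Bq/ml; SPECT reconstructions arrive as count rate (cps) and require a
scanner conversion factor measured on a uniform cylinder phantom:

* `compute_calibration_factor()` implements the defining ratio
  `f = A_true / sum(cps over VOI)` in kBq/cps. The homogeneity of the
  VOI is the caller's responsibility (use the cylinder core, away from
  edge roll-off).
* Count rate is stored **per voxel**; `counts_to_concentration()`
  therefore divides by the voxel volume (`cps * f * 1000 / v_ml`). The
  kBq/cps unit of a published factor is ambiguous between per-voxel and
  per-ml count rate; per-voxel is the convention here, chosen because it
  makes the factor a property of a plain voxel-sum, and it is recorded
  in this one place.

The standardized uptake value normalizes concentration by injected
activity per gram of body weight,

`SUV = C * W / A_dc`,

dimensionless under the 1 ml/g convention. `A_dc` is the injected
activity decayed from injection time to **scan start** — the usual SUV
convention; the reference time matters at the few-percent level for
Tc-99m at 3 h uptake delay and is therefore fixed and documented rather
than configurable per call. Half-lives: Tc-99m 6.0067 h, F-18
109.77 min; both overridable through `acquisition_record()`.

Injected activity may be per-patient or a cohort average (historical
SPECT protocols often lack per-syringe residual measurements); the
`acquisition_record` simply carries whatever the caller supplies, and
the JSON/YAML record keeps that provenance with the data.

## Segmentation and volume matching

The paired protocol segments lesions on the better-resolved reference
modality (PET) as the **26-connected component** of voxels with
`SUV > t` (strict inequality, default `t = 15`) around a physician
seed, then finds on the other modality the threshold whose component
volume best matches the reference VOI volume. Conventions:

* 26-connectivity: lesions are compact blobs; the permissive standard
  avoids splitting a lesion across a face-diagonal.
* Component volume is a non-increasing **step function** of the
  threshold, so the volume match searches achievable component sizes,
  not a continuous bisection. The implementation grows the component by
  widest-path ("path-max") region growing: the component changes exactly
  when the threshold crosses the largest value on its outer boundary,
  and each recorded state carries a representative threshold (the new
  boundary maximum). Ties in `|V - target|` break toward the larger
  volume (lower threshold).
* A growth step that reaches a flat plateau (e.g. uniform background)
  could flood the image; the search abandons any candidate component
  once it grows provably worse than the best state so far (past
  `2 * target` voxels, or past the mismatch tolerance), which bounds the
  work without changing the result.
* Matching fails, with the best achieved mismatch attached to the error
  condition, when no threshold gets within `max_mismatch` (default 20%)
  of the target. In cohort runs such lesions are flagged and skipped;
  with 4.8-mm SPECT voxels this genuinely happens for the smallest
  lesions, where one voxel is a large volume fraction.
* Voxel indices are 1-based (R convention) and all geometry is physical:
  voxel centers at `(i - 0.5) * spacing` mm, volumes in cm^3 =
  voxels x `prod(spacing)` / 1000.

The clinical rule of manually lowering the reference threshold when the
VOI is clearly smaller than the visible uptake is subjective; the
analysis instead honours a per-lesion `threshold_override` column in
the seed table, so the judgement stays with the user (or, for
simulations, with the generator — see below).

## Uptake metrics

* `suv_peak()` searches all cubes of per-axis edge
  `max(1, round(10 mm / spacing))` voxels whose **center voxel belongs
  to the VOI**. This operationalizes "positioned within the lesion"
  while allowing the cube to overhang small lesions — which is why
  `SUV_peak < SUV_mean` is possible and deliberately not clamped. For
  even edges the center voxel is the `floor((d-1)/2)` offset from the
  cube's low corner; cubes are clipped at image borders and averaged
  over in-bounds voxels. The physical cube volume differs between grids
  (0.885 cm^3 on a 4.8-mm grid, 1.176 cm^3 on 3.65/3.27 mm), a finite
  voxel-size fact surfaced in the returned `cube_volume_cm3`.
* `background_voi()` unions axial disk ROIs (default 1 cm diameter,
  voxel membership by in-plane voxel center, single slice per ROI);
  duplicated voxels count once. Five to ten ROIs is protocol; outside
  that range the function warns rather than errors, since ROI count is
  a protocol matter, not a mathematical one.
* SUVRs divide the three lesion SUVs by the background mean, making
  them invariant to any global rescaling of the image — the practical
  reason SUVRs need neither calibration nor dose/weight bookkeeping.

## Agreement statistics

* Sign convention, fixed package-wide: `d = 100 * (PET - SPECT) /
  SPECT`, so positive medians mean PET reads higher.
* Bland-Altman limits use the **median and empirical 2.5th/97.5th
  percentiles** (not mean ± 1.96 SD), because SUV differences are
  typically non-normal; the Shapiro-Wilk gate (`normality_gate()`)
  documents that choice per measure. Percentiles interpolate linearly
  between order statistics at `h = (n - 1) p + 1` (R's type-7 default);
  the even-n median is the mean of the central pair.
* Wilcoxon signed-rank: zeros dropped before ranking (classical
  convention); exact null via the signed-rank distribution for
  `n <= 25` without ties, otherwise normal approximation with tie and
  continuity corrections. Mann-Whitney U: exact for combined
  `n <= 20` without ties, otherwise the corrected normal approximation;
  a one-sided variant supports the directional metastatic > benign
  hypothesis. Exact branches delegate to R's `psignrank`/`pwilcox`;
  the test suite verifies both branches against full `2^n` and
  `C(m+n, m)` enumerations.
* Size stratification uses equal-count volume strata (quartiles by
  default, extra records to the earliest strata, mirroring the
  58/58/58/57 style of splitting 231 records).
* No multiple-testing adjustment is applied anywhere, matching common
  practice for descriptive agreement studies.

## The synthetic world

`make_paired_cohort()` produces the ground-truthed inputs every test
and the acceptance report run on. What it emulates, and what it
deliberately does not:

* **Geometry.** Spherical lesions rasterized by voxel-center membership
  (no anti-aliasing; true volumes are integer voxel counts) on two
  grids sharing one physical field of view: SPECT 4.8 mm isotropic, PET
  3.65 x 3.65 x 3.27 mm (the alternative clinical grid 5.47 x 5.47 x
  3.27 mm is a parameter). Lesions sit on a jittered 72-mm lattice
  inside axial slabs assigned to five skeletal sites — placement is
  collision-free by construction, which is what lets zero-blur runs
  recover programmed values exactly.
* **Intensities.** Site backgrounds (SPECT-SUV 2.0 skull to 6.1 spine)
  follow typical normal-bone medians, highest in spine, lowest in
  skull. Lesion SPECT SUVs are lognormal (meanlog log 30, sdlog 0.3)
  truncated to [22, 80]; metastatic lesions (probability 129/231) get a
  1.3x shift. The truncation keeps every lesion segmentable at the
  PET threshold of 15 after blur — the clinical analogue (manually
  lowering the threshold per lesion) is subjective and out of scope, so
  the simulated cohort is conditioned on threshold validity instead.
  Lesion volumes are log-uniform over 0.55-60 cm^3.
* **Modality contrast.** The PET image is the SPECT SUV pattern times a
  single programmable uptake ratio (default 1.2) applied to lesions and
  background alike — a stand-in for the higher bone extraction of the
  PET tracer. It is exactly what the idealized acceptance run must
  recover as a +20% Bland-Altman median with zero-width LOA.
* **System model.** One effective Gaussian blur per modality (default
  FWHM 12 mm SPECT, 8 mm PET), representing reconstruction resolution
  and postfilter combined. Real scanners' total resolution is not
  published for this protocol; the defaults are conventions chosen so
  SPECT remains coarser than PET after compensation, and they are
  parameters, not claims. Convolution is separable with zero padding;
  sigma = FWHM / 2.3548 per axis in voxel units.
* **Noise.** Independent Gaussian per voxel with SD proportional to
  sqrt(signal) (scales chosen to give a few percent SUV noise at
  lesion levels: 0.3 SPECT / 0.15 PET in SUV units), clipped at zero.
  This is a pragmatic stand-in for reconstruction noise;
  Poisson-on-pseudo-counts is deliberately not implemented because the
  pipeline never touches raw projections.
* **Adaptive reference threshold.** For each lesion the generator emits
  a `threshold_override` of `min(15, bg + 0.5 * (local peak - bg))` on
  the measured PET image — the standard adaptive 50%-of-peak-contrast
  segmentation rule — emulating the clinical practice of lowering the
  fixed threshold when blur leaves a small lesion's suprathreshold core
  clearly smaller than its uptake area. At high contrast the cap at 15
  makes this the plain fixed-threshold protocol.
* **Background ROIs.** Seven centers per lesion on a shell 10-18 mm
  (about 2-4 SPECT voxels) outside the lesion surface, constrained to
  the lesion's own lattice cell so no ROI can touch a neighbouring
  lesion. Under blur the ROIs see some spill-over from their own
  lesion — as real background ROIs do.
* **Not modeled.** Attenuation, scatter, collimator response (handled
  upstream by scanner software in practice), anatomy (no CT, no bladder
  or kidney activity), tracer pharmacokinetics, and the days-long
  interval between the two scans. A green test therefore establishes
  algorithmic correctness and the partial-volume mechanism — it does
  not establish that any particular clinical cohort's numbers would be
  reproduced.

The counts branch (`to_counts_branch()`) converts the measured SPECT
concentration into per-voxel cps with a programmed factor (default
0.107 kBq/cps, a typical phantom-derived magnitude), so cohort analyses
exercise the full calibration path and round-trip it exactly.

## Numerical choices and degenerate inputs

* Strict `>` thresholding throughout; a seed voxel exactly at the
  threshold is an error, not an empty VOI.
* `R^2` is defined as 0 for constant responses; constant predictors are
  a degenerate-input error.
* Zero-variance samples are errors for the Shapiro-Wilk gate (W is
  undefined) and for the signed-rank test when all differences are 0.
* NIfTI volumes are written as float64 so quantitative round trips
  through disk are exact; the reader accepts the common integer and
  float datatypes with `scl_slope`/`scl_inter` scaling.
* All randomness is seeded: the cohort generator takes one seed and
  derives sub-seeds (< 2^31) for the two modalities' noise draws;
  rerunning any CLI command with the same seed reproduces outputs
  byte-for-byte (checked via the manifest hashes).

## Known limitations

* Volume matching is quantized by the coarse-grid voxel: for sub-cm^3
  targets the best achievable mismatch can exceed the 20% tolerance,
  and such lesions are flagged rather than forced.
* The peak-cube rule reproduces the ~1 cm^3 intent, but vendor
  implementations differ in how they round the cube and whether they
  allow sub-voxel placement; cross-software SUV_peak values are
  comparable only qualitatively.
* The simulator's single multiplicative uptake ratio cannot produce
  modality differences that vary by site or lesion type; it is a
  mechanism probe, not a biological model.
* Background ROI placement in the simulator is geometric; real
  placement avoids visible pathology, a judgement the generator does
  not model.
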