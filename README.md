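# suvpair

Quantitative, paired analysis of bone-tracer uptake measured with two
emission tomography modalities — typically a calibrated ^99m^Tc-HDP
SPECT/CT scan and an ^18^F-NaF PET/CT scan of the same patient. The
package is aimed at nuclear-medicine physicists and imaging researchers
who want a tested, scriptable version of the standard clinical
quantification workflow: calibrated SUV maps, cross-modality
volume-matched lesion segmentation, SUV and SUVR extraction, and
nonparametric agreement statistics, plus a ground-truthed digital
phantom generator to validate every stage.

## The quantities it computes

The standardized uptake value of a voxel is

```
SUV = C (Bq/ml) * W (g) / A_dc (Bq)   [* 1 ml/g]
```

where `C` is the activity concentration, `W` the patient weight and
`A_dc` the injected activity decay-corrected from injection to scan
start (`A_dc = A0 * 2^(-dt / T_half)`). SPECT voxels come off the
scanner as reconstructed count rate (cps); a uniform-phantom session
provides the conversion factor `f = A_true / sum(cps)` (kBq/cps) that
turns them into Bq/ml.

Per lesion, on a volume of interest (VOI):

* `SUV_max` — hottest voxel in the VOI;
* `SUV_peak` — maximal mean over a ~1 cm^3 cube whose center voxel lies
  in the VOI (per-axis edge = nearest integer to 10 mm / voxel size);
* `SUV_mean` — mean over the VOI;
* `SUVR_*` — each of the above divided by `SUV_mean,bg`, the mean SUV of
  a background VOI formed by uniting five to ten 1-cm disk ROIs placed
  on adjacent normal bone. SUVRs are invariant under global rescaling,
  so they need no scanner calibration.

Lesions are segmented on the reference modality (PET) as the
26-connected component above a fixed SUV threshold (default 15), and on
the other modality at the threshold whose component volume best matches
the reference VOI volume. Agreement between modalities is summarized
nonparametrically: least-squares regression, Bland-Altman with median
difference and 2.5th/97.5th-percentile limits of agreement of
`d = 100 * (PET - SPECT) / SPECT`, Wilcoxon signed-rank and
Mann-Whitney U tests, with a Shapiro-Wilk gate motivating the
median/percentile summaries.

## Worked example

Simulate a paired cohort of 40 lesions (effective blur 12 mm SPECT /
8 mm PET, signal-scaled noise, programmed PET/SPECT uptake ratio 1.2),
run the full pipeline, and print the agreement report:

```r
library(suvpair)

coh <- make_paired_cohort(n_lesions = 40, seed = 99)
spect_suv <- to_suv(
  counts_to_concentration(coh$spect_counts,
                          calibration_factor(coh$calibration_kBq_per_cps)),
  coh$acq_spect)
pet_suv <- to_suv(coh$pet_conc, coh$acq_pet)

res    <- analyze_paired_lesions(spect_suv, pet_suv, coh$seeds, coh$bg_rois)
paired <- pair_lesion_records(res$lesions)
compare_modalities(paired)
#> <agreement_report> 40 lesions (27 metastatic, 13 benign)
#>   suv_max   R2=0.793  median diff +38.8% (LOA +12.7% .. +163.3%)  Wilcoxon p=3.71e-08
#>   suv_peak  R2=0.928  median diff +45.0% (LOA +16.8% .. +108.7%)  Wilcoxon p=3.71e-08
#>   suv_mean  R2=0.920  median diff +45.7% (LOA +29.9% .. +121.7%)  Wilcoxon p=3.71e-08
#>   suvr_max  R2=0.834  median diff +26.2% (LOA -1.4% .. +117.4%)  Wilcoxon p=8.49e-08
#>   suvr_peak R2=0.940  median diff +27.6% (LOA +1.6% .. +80.5%)  Wilcoxon p=4.32e-08
#>   suvr_mean R2=0.929  median diff +31.8% (LOA +10.8% .. +83.1%)  Wilcoxon p=3.71e-08
#>   volume matching |dV|/V: median 0.27%, max 6.47%
```

Reading the output: SUVs correlate strongly between the modalities but
PET reads systematically higher — partly the programmed 20% uptake
ratio, partly the stronger partial-volume loss of the coarser SPECT
system. SUVRs largely cancel the shared background difference. The
volume-matching line confirms the paired VOIs have nearly identical
volumes, so the SUV comparison is not confounded by VOI size. On an
idealized cohort (`psf_fwhm = c(spect = 0, pet = 0)`,
`noise_model = "none"`) the median difference is exactly +20% with
zero-width limits of agreement — the programmed ratio is recovered.

The same pipeline is scriptable from the shell:

```sh
exec/suvpair simulate --out sim/ --seed 7 --n-lesions 50
exec/suvpair analyze  --config run.yaml --out results/
```

## Layout

* `R/` — implementation: containers and NIfTI-1 I/O, calibration and
  the SUV transform, segmentation and volume matching, uptake metrics,
  agreement statistics, phantom simulator, CLI.
* `tests/testthat/` — unit, property and acceptance tests (all expected
  values computed by independent brute-force oracles or pinned from
  closed forms).
* `vignettes/suvpair-methods.Rmd` — the methods notes: model
  assumptions, algorithmic conventions, simulator design, limitations.
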