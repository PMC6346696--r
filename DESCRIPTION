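Package: suvpair
Title: Paired SPECT/PET Standardized Uptake Value Analysis for Skeletal Lesions
Version: 0.1.0
Authors@R: person("suvpair", "maintainers", email = "suvpair@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of paired bone-seeking tracer scans
    (99mTc-HDP SPECT/CT and 18F-NaF PET/CT): phantom-based scanner
    calibration (kBq/cps conversion factors), standardized uptake value
    (SUV) maps from calibrated activity-concentration volumes,
    threshold-based lesion segmentation with cross-modality volume
    matching, SUV_max/SUV_peak/SUV_mean and background-normalized SUV
    ratio (SUVR) extraction, and nonparametric agreement statistics
    (median/percentile Bland-Altman, Wilcoxon signed-rank, Mann-Whitney
    U). Includes a paired digital-phantom simulator with Gaussian system
    blur and scaled noise for ground-truthed end-to-end validation, a
    minimal NIfTI-1 reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
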