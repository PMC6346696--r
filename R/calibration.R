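#' Scanner calibration factor from a uniform phantom session
#'
#' Quantitative SPECT requires a conversion factor from reconstructed
#' count rate to activity. It is measured by scanning a uniform
#' (Jaszczak-type) cylinder of known activity and taking the ratio
#' between the true activity inside a homogeneous volume of interest
#' and the reconstructed count rate summed over the same VOI. The VOI
#' must avoid the phantom edges; homogeneity is the caller's
#' responsibility.
#'
#' @param counts_volume A [quant_volume()] with unit `"cps"`
#'   (count rate per voxel).
#' @param true_activity_kBq True activity contained in the VOI, kBq.
#' @param voi A [lesion_voi()] (or any object with an `idx` matrix of
#'   1-based voxel indices) on the volume's grid.
#' @return An object of class `calibration_factor` with fields `value`
#'   (kBq per cps) and `source`.
#' @seealso [counts_to_concentration()]
#' @export
compute_calibration_factor <- function(counts_volume, true_activity_kBq, voi) {
  assert_unit(counts_volume, "cps")
  stopifnot_scalar_num(true_activity_kBq, "true_activity_kBq", positive = TRUE)
  idx <- voi_indices(voi, dim(counts_volume$values))
  total_cps <- sum(counts_volume$values[idx])
  if (total_cps <= 0) {
    abort_suvpair("total reconstructed count rate in VOI is not positive",
                  "suvpair_degenerate_input")
  }
  calibration_factor(true_activity_kBq / total_cps,
                     source = sprintf("uniform phantom VOI of %d voxels",
                                      length(idx)))
}

#' Construct a calibration factor
#'
#' @param value Conversion factor in kBq per cps (> 0).
#' @param source Free-text description of the phantom session.
#' @return An object of class `calibration_factor`.
#' @export
calibration_factor <- function(value, source = "unspecified") {
  stopifnot_scalar_num(value, "value", positive = TRUE)
  structure(list(value = value, source = as.character(source)[1L]),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %.6g kBq/cps (%s)\n", x$value, x$source))
  invisible(x)
}

#' Convert a count-rate volume to activity concentration
#'
#' Applies a phantom-derived calibration factor to a reconstructed
#' count-rate volume. Count rate is stored per voxel, so the conversion
#' to a concentration is `cps * factor_kBq_per_cps * 1000 / voxel
#' volume (ml)`, giving Bq/ml.
#'
#' @param counts_volume A [quant_volume()] with unit `"cps"`.
#' @param factor A [calibration_factor()].
#' @return A [quant_volume()] with unit `"Bq_per_ml"`.
#' @export
counts_to_concentration <- function(counts_volume, factor) {
  assert_unit(counts_volume, "cps")
  if (!inherits(factor, "calibration_factor")) {
    abort_suvpair("expected a `calibration_factor`", "suvpair_invalid_argument")
  }
  scale <- factor$value * 1000 / voxel_volume_ml(counts_volume)
  quant_volume(counts_volume$values * scale, counts_volume$spacing,
               unit = "Bq_per_ml", modality = counts_volume$modality)
}

#' Convert an activity-concentration volume to SUV
#'
#' The standardized uptake value normalizes tracer concentration by the
#' injected activity per unit body weight:
#' `SUV = concentration (Bq/ml) * weight (g) / decay-corrected injected
#' activity (Bq)`, dimensionless under the 1 ml/g tissue-density
#' convention. The injected activity is decayed from injection time to
#' scan start.
#'
#' @param conc_volume A [quant_volume()] with unit `"Bq_per_ml"`.
#' @param acq An [acquisition_record()].
#' @return A [quant_volume()] with unit `"SUV"`.
#' @examples
#' v <- quant_volume(array(9600, c(2, 2, 2)), c(4.8, 4.8, 4.8),
#'                   unit = "Bq_per_ml", modality = "SPECT")
#' acq <- acquisition_record(672e6, "2020-01-01 09:00", "2020-01-01 09:00",
#'                           patient_weight_g = 70000)
#' to_suv(v, acq)$values[1, 1, 1]  # 1.0
#' @export
to_suv <- function(conc_volume, acq) {
  assert_unit(conc_volume, "Bq_per_ml")
  a <- decay_corrected_activity(acq)
  if (a <= 0) {
    abort_suvpair("decay-corrected injected activity must be > 0",
                  "suvpair_invalid_argument")
  }
  quant_volume(conc_volume$values * acq$patient_weight_g / a,
               conc_volume$spacing, unit = "SUV",
               modality = conc_volume$modality)
}
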