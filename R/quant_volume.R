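#' Quantitative 3-D volume with voxel spacing and a unit tag
#'
#' The basic container of the package: a 3-D scalar field together with
#' its per-axis voxel edge lengths in millimetres and a tag recording
#' what the voxel values mean. Three units are tracked through the
#' pipeline: reconstructed count rate (`"cps"`, per voxel), activity
#' concentration (`"Bq_per_ml"`), and the dimensionless standardized
#' uptake value (`"SUV"`). Voxel centers sit at physical coordinates
#' `(i - 0.5) * spacing` (1-based indices), so the grid origin is the
#' corner of voxel `(1,1,1)`.
#'
#' @param values 3-D numeric array of finite values.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm,
#'   all strictly positive.
#' @param unit One of `"cps"`, `"Bq_per_ml"`, `"SUV"`.
#' @param modality Free-text label, e.g. `"SPECT"` or `"PET"`.
#'
#' @return An object of class `quant_volume`: a list with elements
#'   `values`, `spacing`, `unit`, `modality`.
#' @examples
#' v <- quant_volume(array(1, c(4, 4, 4)), spacing = c(4.8, 4.8, 4.8),
#'                   unit = "SUV", modality = "SPECT")
#' voxel_volume_ml(v)
#' @export
quant_volume <- function(values, spacing, unit = c("cps", "Bq_per_ml", "SUV"),
                         modality = "unknown") {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort_suvpair("`values` must be a 3-D array", "suvpair_invalid_argument")
  }
  if (!all(is.finite(values))) {
    abort_suvpair("`values` must be finite everywhere", "suvpair_invalid_argument")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort_suvpair("`spacing` must be 3 positive voxel edge lengths in mm",
                  "suvpair_invalid_argument")
  }
  structure(
    list(values = values, spacing = spacing, unit = unit,
         modality = as.character(modality)[1L]),
    class = "quant_volume"
  )
}

#' @export
print.quant_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<quant_volume> %s [%s]  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$modality, x$unit, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

is_quant_volume <- function(x) inherits(x, "quant_volume")

assert_unit <- function(vol, unit) {
  if (!is_quant_volume(vol)) {
    abort_suvpair("expected a `quant_volume`", "suvpair_invalid_argument")
  }
  if (vol$unit != unit) {
    abort_suvpair(sprintf("volume has unit '%s' but '%s' is required",
                          vol$unit, unit), "suvpair_unit_error")
  }
  invisible(vol)
}

#' Voxel volume of a quantitative volume
#'
#' @param vol A [quant_volume()].
#' @return Voxel volume in millilitres (= cm^3), i.e.
#'   `prod(spacing) / 1000`.
#' @export
voxel_volume_ml <- function(vol) {
  if (!is_quant_volume(vol)) {
    abort_suvpair("expected a `quant_volume`", "suvpair_invalid_argument")
  }
  prod(vol$spacing) / 1000
}

# Physical coordinates (mm) of voxel centers, rows matching `ijk`.
voxel_centers_mm <- function(ijk, spacing) {
  sweep(ijk - 0.5, 2L, spacing, `*`)
}

# Voxel index (1-based, clamped to the grid) containing physical point `xyz` mm.
point_to_voxel <- function(xyz, spacing, dim) {
  idx <- floor(xyz / spacing) + 1L
  pmin(pmax(as.integer(idx), 1L), as.integer(dim))
}
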