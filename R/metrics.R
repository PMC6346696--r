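#' Maximum SUV within a VOI
#'
#' The SUV of the most active voxel inside the lesion VOI.
#'
#' @param suv_volume A [quant_volume()] with unit `"SUV"`.
#' @param voi A [lesion_voi()] on the same grid.
#' @return A single SUV value.
#' @export
suv_max <- function(suv_volume, voi) {
  assert_unit(suv_volume, "SUV")
  max(suv_volume$values[voi_indices(voi, dim(suv_volume$values))])
}

#' Mean SUV within a VOI
#'
#' Arithmetic mean SUV over all voxels of the lesion VOI.
#'
#' @inheritParams suv_max
#' @return A single SUV value.
#' @export
suv_mean <- function(suv_volume, voi) {
  assert_unit(suv_volume, "SUV")
  mean(suv_volume$values[voi_indices(voi, dim(suv_volume$values))])
}

# Per-axis voxel counts of the ~1 cm^3 peak cube: nearest integer to
# 10 mm / spacing, at least 1. Finite voxel size means the cube volume is
# generally not exactly 1 cm^3 and differs between grids.
peak_cube_dims <- function(spacing) {
  pmax(1L, as.integer(floor(10 / spacing + 0.5)))
}

#' Peak SUV: maximal mean over a ~1 cm^3 cube positioned in the lesion
#'
#' Searches all axis-aligned cubes of approximately 1 cm^3 (per-axis
#' edge = nearest integer voxel count to 10 mm, minimum 1) whose center
#' voxel belongs to the VOI, and returns the maximal enclosed mean SUV.
#' Cubes may extend outside the VOI; in small lesions this can make
#' SUV_peak smaller than SUV_mean. Cubes reaching past the image border
#' are clipped and the mean is taken over in-bounds voxels only.
#'
#' For even cube edges the center voxel is taken as the
#' `floor((d - 1) / 2)`-offset voxel from the cube's low corner, i.e.
#' a cube of edge `d` spans `c - floor((d-1)/2) ... c + floor(d/2)`
#' around its center voxel `c`.
#'
#' @inheritParams suv_max
#' @return A list with `suv_peak`, `cube_anchor` (low-corner voxel index
#'   of the clipped winning cube), `cube_dims` (unclipped per-axis voxel
#'   counts), and `cube_volume_cm3` (physical volume of the clipped
#'   cube).
#' @export
suv_peak <- function(suv_volume, voi) {
  assert_unit(suv_volume, "SUV")
  d <- dim(suv_volume$values)
  lin <- voi_indices(voi, d)
  ijk <- lin_to_ijk(lin, d)
  dims <- peak_cube_dims(suv_volume$spacing)
  lo_off <- (dims - 1L) %/% 2L
  hi_off <- dims %/% 2L
  vals <- suv_volume$values
  best <- -Inf
  best_anchor <- c(NA_integer_, NA_integer_, NA_integer_)
  best_nvox <- 0L
  for (r in seq_len(nrow(ijk))) {
    c_ <- ijk[r, ]
    lo <- pmax(c_ - lo_off, 1L)
    hi <- pmin(c_ + hi_off, d)
    m <- mean(vals[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]])
    if (m > best) {
      best <- m
      best_anchor <- lo
      best_nvox <- prod(hi - lo + 1L)
    }
  }
  list(suv_peak = best, cube_anchor = as.integer(best_anchor),
       cube_dims = dims,
       cube_volume_cm3 = best_nvox * prod(suv_volume$spacing) / 1000)
}

#' Background VOI from circular bone ROIs
#'
#' Clinical protocol: place five to ten circular ROIs of 1-cm diameter
#' on adjacent normal-appearing bone; their union forms the background
#' VOI whose mean SUV normalizes the lesion SUVs. Each ROI is a disk of
#' voxels on one axial slice (the slice containing the center point);
#' a voxel belongs to the disk when its in-plane center lies inside the
#' circle. Voxels covered by several ROIs are counted once.
#'
#' @param suv_volume A [quant_volume()] with unit `"SUV"`.
#' @param roi_centers_mm Numeric matrix (n x 3) of physical ROI center
#'   points in mm.
#' @param diameter_mm ROI diameter in mm (default 10).
#' @return An object of class `background_voi` with fields
#'   `roi_centers_mm`, `roi_diameter_mm`, `idx` (union voxel set),
#'   `suv_mean_bg`, `n_rois`.
#' @export
background_voi <- function(suv_volume, roi_centers_mm, diameter_mm = 10) {
  assert_unit(suv_volume, "SUV")
  stopifnot_scalar_num(diameter_mm, "diameter_mm", positive = TRUE)
  roi_centers_mm <- matrix(as.numeric(roi_centers_mm), ncol = 3L)
  n_rois <- nrow(roi_centers_mm)
  if (n_rois == 0L) {
    abort_suvpair("at least one ROI center is required", "suvpair_invalid_argument")
  }
  if (n_rois < 5L || n_rois > 10L) {
    warn_suvpair(sprintf("protocol expects 5-10 background ROIs, got %d", n_rois),
                 "suvpair_protocol_warning")
  }
  d <- dim(suv_volume$values)
  sp <- suv_volume$spacing
  r2 <- (diameter_mm / 2)^2
  xc <- (seq_len(d[1L]) - 0.5) * sp[1L]
  yc <- (seq_len(d[2L]) - 0.5) * sp[2L]
  lin_all <- integer(0)
  for (r in seq_len(n_rois)) {
    ctr <- roi_centers_mm[r, ]
    if (ctr[1L] < 0 || ctr[1L] > d[1L] * sp[1L] ||
        ctr[2L] < 0 || ctr[2L] > d[2L] * sp[2L] ||
        ctr[3L] < 0 || ctr[3L] > d[3L] * sp[3L]) {
      abort_suvpair("ROI center falls outside the volume", "suvpair_invalid_argument")
    }
    k <- point_to_voxel(ctr, sp, d)[3L]
    in_disk <- outer((xc - ctr[1L])^2, (yc - ctr[2L])^2, `+`) <= r2
    ij <- which(in_disk, arr.ind = TRUE)
    if (nrow(ij) > 0L) {
      lin_all <- c(lin_all, ijk_to_lin(cbind(ij, k), d))
    }
  }
  lin_all <- unique(lin_all)
  if (length(lin_all) == 0L) {
    abort_suvpair("background ROI union contains no voxels (diameter too small?)",
                  "suvpair_degenerate_input")
  }
  structure(
    list(roi_centers_mm = roi_centers_mm, roi_diameter_mm = diameter_mm,
         idx = lin_to_ijk(sort(lin_all), d), dim = d, spacing = sp,
         n_rois = n_rois,
         suv_mean_bg = mean(suv_volume$values[lin_all])),
    class = "background_voi"
  )
}

#' @export
print.background_voi <- function(x, ...) {
  cat(sprintf("<background_voi> %d ROIs (%.3g mm), %d voxels, SUV_mean_bg %.4g\n",
              x$n_rois, x$roi_diameter_mm, nrow(x$idx), x$suv_mean_bg))
  invisible(x)
}

#' All SUV metrics for one lesion
#'
#' Convenience wrapper computing SUV_max, SUV_peak, and SUV_mean of a
#' VOI in one call.
#'
#' @inheritParams suv_max
#' @return A list with `suv_max`, `suv_peak`, `suv_mean`, plus the peak
#'   cube descriptors of [suv_peak()].
#' @export
uptake_metrics <- function(suv_volume, voi) {
  pk <- suv_peak(suv_volume, voi)
  list(suv_max = suv_max(suv_volume, voi),
       suv_peak = pk$suv_peak,
       suv_mean = suv_mean(suv_volume, voi),
       cube_anchor = pk$cube_anchor, cube_dims = pk$cube_dims,
       cube_volume_cm3 = pk$cube_volume_cm3)
}

#' SUV ratios relative to local bone background
#'
#' Divides the lesion's SUV_max/peak/mean by the mean SUV of its own
#' background VOI. SUVRs are invariant under global rescaling of the
#' image, so unlike SUVs they require neither scanner calibration nor
#' injected-dose/weight bookkeeping.
#'
#' @param metrics Result of [uptake_metrics()] (or a list with
#'   `suv_max`, `suv_peak`, `suv_mean`).
#' @param bg A [background_voi()] (or a positive scalar `suv_mean_bg`).
#' @return A list with `suvr_max`, `suvr_peak`, `suvr_mean`.
#' @export
compute_suvr <- function(metrics, bg) {
  bg_mean <- if (inherits(bg, "background_voi")) bg$suv_mean_bg else as.numeric(bg)
  if (!is.finite(bg_mean) || bg_mean <= 0) {
    abort_suvpair("background SUV_mean must be > 0", "suvpair_invalid_argument")
  }
  list(suvr_max = metrics$suv_max / bg_mean,
       suvr_peak = metrics$suv_peak / bg_mean,
       suvr_mean = metrics$suv_mean / bg_mean)
}

#' Sample background ROI centers on a shell outside a VOI
#'
#' Simulation convenience (not part of the clinical protocol, where
#' background ROIs are placed manually): samples ROI center points on a
#' shell 2-4 voxels outside the lesion VOI, at the axial levels the VOI
#' spans, so that phantom runs can build background VOIs automatically.
#'
#' @param suv_volume A [quant_volume()] (grid/spacing source).
#' @param voi A [lesion_voi()].
#' @param n Number of ROI centers (default 7).
#' @param shell_voxels Inner/outer shell distance in voxel layers
#'   (default `c(2, 4)`).
#' @return An n x 3 matrix of physical points (mm).
#' @export
sample_background_centers <- function(suv_volume, voi, n = 7,
                                      shell_voxels = c(2L, 4L)) {
  d <- dim(suv_volume$values)
  lin <- voi_indices(voi, d)
  inside <- logical(prod(d))
  inside[lin] <- TRUE
  layer <- inside
  shell <- integer(0)
  for (depth in seq_len(shell_voxels[2L])) {
    nb <- unique(neighbours26_lin(lin_to_ijk(which(layer), d), d))
    nb <- nb[!layer[nb]]
    if (depth >= shell_voxels[1L]) shell <- c(shell, nb)
    layer[nb] <- TRUE
  }
  shell <- unique(shell)
  if (length(shell) == 0L) {
    abort_suvpair("no shell voxels available outside the VOI",
                  "suvpair_degenerate_input")
  }
  pick <- shell[sample.int(length(shell), size = min(n, length(shell)),
                           replace = length(shell) < n)]
  voxel_centers_mm(lin_to_ijk(pick, d), suv_volume$spacing)
}
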