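# Paired digital phantoms: analytic sphere lesions over site-dependent
# bone background, rasterized onto SPECT-like and PET-like grids sharing
# one physical field of view, then degraded by an effective Gaussian
# system blur and optional signal-scaled noise.

#' Phantom specification
#'
#' Ground-truth description of a paired digital phantom. Both grids
#' cover the same physical field of view; lesions are spheres given in
#' physical mm. Lesion and background intensities are specified as
#' SPECT SUV-equivalents; the PET image is the SPECT image scaled by a
#' programmable multiplicative uptake ratio (modelling the higher bone
#' extraction of the PET tracer). Acquisition records fix the
#' SUV-to-concentration conversion per modality.
#'
#' @param fov_mm Physical field of view, length-3 mm.
#' @param spect_spacing,pet_spacing Voxel spacing per modality, mm.
#'   Defaults: SPECT 4.8 mm isotropic; PET 3.65 x 3.65 x 3.27 mm
#'   (alternative clinical grid: 5.47 x 5.47 x 3.27 mm).
#' @param lesions data.frame with columns `x_mm, y_mm, z_mm, radius_mm,
#'   suv, site, class` (suv = SPECT SUV-equivalent of the lesion).
#' @param background data.frame of axial slabs with columns `site,
#'   z_min_mm, z_max_mm, suv`, or a single number for a uniform
#'   background.
#' @param uptake_ratio PET/SPECT multiplicative uptake factor applied
#'   to lesions and background (default 1.2).
#' @param psf_fwhm Named vector `c(spect = , pet = )` of effective
#'   system-blur FWHM in mm (defaults 12 and 8; these model
#'   reconstruction plus postfilter combined and are conventions, not
#'   measured scanner resolutions).
#' @param noise_model `"none"` or `"gaussian_scaled"`.
#' @param noise_scale_suv Named vector `c(spect = , pet = )`: noise SD
#'   at SUV v is `noise_scale_suv * sqrt(v)` (in SUV units).
#' @param calibration_kBq_per_cps Conversion factor used by the SPECT
#'   counts branch (default 0.107, a typical phantom-derived value).
#' @param acq_spect,acq_pet [acquisition_record()]s per modality.
#' @param seed Integer seed for the stochastic parts.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(fov_mm,
                         spect_spacing = c(4.8, 4.8, 4.8),
                         pet_spacing = c(3.65, 3.65, 3.27),
                         lesions = NULL,
                         background = 5,
                         uptake_ratio = 1.2,
                         psf_fwhm = c(spect = 12, pet = 8),
                         noise_model = c("none", "gaussian_scaled"),
                         noise_scale_suv = c(spect = 0.3, pet = 0.15),
                         calibration_kBq_per_cps = 0.107,
                         acq_spect = default_acquisition("SPECT"),
                         acq_pet = default_acquisition("PET"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  fov_mm <- as.numeric(fov_mm)
  if (length(fov_mm) != 3L || any(fov_mm <= 0)) {
    abort_suvpair("fov_mm must be 3 positive lengths", "suvpair_invalid_argument")
  }
  if (is.null(lesions)) {
    lesions <- data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                          radius_mm = numeric(0), suv = numeric(0),
                          site = character(0), class = character(0))
  }
  if (nrow(lesions) > 0L) {
    if (any(lesions$radius_mm <= 0) || any(lesions$suv <= 0)) {
      abort_suvpair("lesion radii and intensities must be > 0",
                    "suvpair_invalid_argument")
    }
    out_of_fov <-
      lesions$x_mm - lesions$radius_mm < 0 | lesions$x_mm + lesions$radius_mm > fov_mm[1] |
      lesions$y_mm - lesions$radius_mm < 0 | lesions$y_mm + lesions$radius_mm > fov_mm[2] |
      lesions$z_mm - lesions$radius_mm < 0 | lesions$z_mm + lesions$radius_mm > fov_mm[3]
    if (any(out_of_fov)) {
      abort_suvpair(sprintf("lesion(s) outside the field of view: %s",
                            paste(which(out_of_fov), collapse = ", ")),
                    "suvpair_invalid_argument")
    }
  }
  if (is.numeric(background) && length(background) == 1L) {
    background <- data.frame(site = "spine", z_min_mm = 0, z_max_mm = fov_mm[3],
                             suv = as.numeric(background))
  }
  if (any(background$suv <= 0)) {
    abort_suvpair("background levels must be > 0", "suvpair_invalid_argument")
  }
  stopifnot_scalar_num(uptake_ratio, "uptake_ratio", positive = TRUE)
  if (any(psf_fwhm < 0)) {
    abort_suvpair("psf_fwhm must be >= 0", "suvpair_invalid_argument")
  }
  structure(
    list(fov_mm = fov_mm, spect_spacing = as.numeric(spect_spacing),
         pet_spacing = as.numeric(pet_spacing), lesions = lesions,
         background = background, uptake_ratio = uptake_ratio,
         psf_fwhm = psf_fwhm, noise_model = noise_model,
         noise_scale_suv = noise_scale_suv,
         calibration_kBq_per_cps = calibration_kBq_per_cps,
         acq_spect = acq_spect, acq_pet = acq_pet, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default acquisition records for phantom simulations
#'
#' Cohort-typical values: SPECT 672 MBq Tc-99m scanned 180 min after
#' injection; PET 209 MBq F-18 scanned 64 min after injection; 75 kg
#' patient weight for both.
#'
#' @param modality `"SPECT"` or `"PET"`.
#' @return An [acquisition_record()].
#' @export
default_acquisition <- function(modality = c("SPECT", "PET")) {
  modality <- match.arg(modality)
  t0 <- as.POSIXct("2020-01-01 08:00:00", tz = "UTC")
  if (modality == "SPECT") {
    acquisition_record(672e6, t0, t0 + 180 * 60, 75000, isotope = "Tc-99m")
  } else {
    acquisition_record(209e6, t0, t0 + 64 * 60, 75000, isotope = "F-18")
  }
}

# Bq/ml corresponding to SUV = 1 for an acquisition record.
conc_per_suv <- function(acq) {
  decay_corrected_activity(acq) / acq$patient_weight_g
}

rasterize_one_grid <- function(spec, spacing, suv_scale) {
  d <- pmax(1L, as.integer(round(spec$fov_mm / spacing)))
  vals <- array(0, d)
  zc <- (seq_len(d[3L]) - 0.5) * spacing[3L]
  for (b in seq_len(nrow(spec$background))) {
    sel <- zc >= spec$background$z_min_mm[b] & zc < spec$background$z_max_mm[b]
    if (any(sel)) vals[, , sel] <- spec$background$suv[b] * suv_scale
  }
  n_vox <- integer(nrow(spec$lesions))
  xc <- (seq_len(d[1L]) - 0.5) * spacing[1L]
  yc <- (seq_len(d[2L]) - 0.5) * spacing[2L]
  for (l in seq_len(nrow(spec$lesions))) {
    les <- spec$lesions[l, ]
    ir <- which(abs(xc - les$x_mm) <= les$radius_mm)
    jr <- which(abs(yc - les$y_mm) <= les$radius_mm)
    kr <- which(abs(zc - les$z_mm) <= les$radius_mm)
    if (length(ir) * length(jr) * length(kr) == 0L) next
    dist2 <- outer(outer((xc[ir] - les$x_mm)^2, (yc[jr] - les$y_mm)^2, `+`),
                   (zc[kr] - les$z_mm)^2, `+`)
    inside <- dist2 <= les$radius_mm^2
    n_vox[l] <- sum(inside)
    sub <- vals[ir, jr, kr, drop = FALSE]
    sub[inside] <- les$suv * suv_scale
    vals[ir, jr, kr] <- sub
  }
  list(values = vals, n_vox = n_vox)
}

#' Rasterize a phantom onto both modality grids
#'
#' Analytic spheres are rasterized by voxel-center membership (a voxel
#' belongs to a lesion when its center lies inside the sphere; no
#' anti-aliasing), lesion values override background, and the PET image
#' equals the SPECT SUV pattern scaled by the uptake ratio. Outputs are
#' noise- and blur-free activity-concentration volumes plus the ground
#' truth needed for round-trip tests.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `spect` and `pet` ([quant_volume()]s in
#'   Bq_per_ml) and `truth` (per-lesion true SUVs, voxel counts and
#'   volumes per grid, per-slab backgrounds, SUV-to-concentration
#'   factors).
#' @export
rasterize_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    abort_suvpair("expected a `phantom_spec`", "suvpair_invalid_argument")
  }
  cps_spect <- conc_per_suv(spec$acq_spect)
  cps_pet <- conc_per_suv(spec$acq_pet)
  rs <- rasterize_one_grid(spec, spec$spect_spacing, suv_scale = 1)
  rp <- rasterize_one_grid(spec, spec$pet_spacing, suv_scale = spec$uptake_ratio)
  truth <- list(
    lesions = cbind(spec$lesions,
                    spect_suv = spec$lesions$suv,
                    pet_suv = spec$lesions$suv * spec$uptake_ratio,
                    volume_true_cm3 = 4 / 3 * pi * spec$lesions$radius_mm^3 / 1000,
                    n_vox_spect = rs$n_vox, n_vox_pet = rp$n_vox),
    background = spec$background,
    uptake_ratio = spec$uptake_ratio,
    conc_per_suv = c(spect = cps_spect, pet = cps_pet)
  )
  list(
    spect = quant_volume(rs$values * cps_spect, spec$spect_spacing,
                         unit = "Bq_per_ml", modality = "SPECT"),
    pet = quant_volume(rp$values * cps_pet, spec$pet_spacing,
                       unit = "Bq_per_ml", modality = "PET"),
    truth = truth
  )
}

# Separable Gaussian convolution with zero padding; sigma = fwhm / 2.3548.
blur_gaussian <- function(values, spacing, fwhm_mm) {
  if (fwhm_mm == 0) return(values)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    s_vox <- sigma_mm / spacing[axis]
    r <- max(1L, as.integer(ceiling(4 * s_vox)))
    w <- stats::dnorm((-r):r, sd = s_vox)
    w <- w / sum(w)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(values, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1L])
    out <- matrix(0, nrow = d[1L], ncol = ncol(m))
    for (oi in seq_along(w)) {
      o <- oi - r - 1L
      if (abs(o) >= d[1L]) next
      if (o == 0L) {
        out <- out + w[oi] * m
      } else if (o > 0L) {
        rows <- (1L + o):d[1L]
        out[rows, ] <- out[rows, ] + w[oi] * m[rows - o, , drop = FALSE]
      } else {
        rows <- 1L:(d[1L] + o)
        out[rows, ] <- out[rows, ] + w[oi] * m[rows - o, , drop = FALSE]
      }
    }
    values <- aperm(array(out, d), order(perm))
  }
  values
}

#' Apply the effective system model (blur + noise) to a true volume
#'
#' Convolves with a separable Gaussian of the given FWHM (sigma =
#' FWHM / 2.3548 per axis, in voxels sigma_mm / spacing; zero padding
#' at borders) and optionally adds independent Gaussian noise with
#' voxel SD `noise_scale * sqrt(value)`, clipped at zero. Deterministic
#' under a fixed seed.
#'
#' @param true_volume A [quant_volume()].
#' @param fwhm_mm Effective system resolution, mm (>= 0).
#' @param noise_model `"none"` or `"gaussian_scaled"`.
#' @param noise_scale Noise scale (same value units as
#'   `sqrt(voxel value)`).
#' @param seed Optional integer seed.
#' @return A [quant_volume()] with the same unit tag.
#' @export
apply_system_model <- function(true_volume, fwhm_mm,
                               noise_model = c("none", "gaussian_scaled"),
                               noise_scale = 0, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is_quant_volume(true_volume)) {
    abort_suvpair("expected a `quant_volume`", "suvpair_invalid_argument")
  }
  stopifnot_scalar_num(fwhm_mm, "fwhm_mm", nonneg = TRUE)
  vals <- blur_gaussian(true_volume$values, true_volume$spacing, fwhm_mm)
  if (noise_model == "gaussian_scaled" && noise_scale > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    noise <- stats::rnorm(length(vals), mean = 0,
                          sd = noise_scale * sqrt(pmax(vals, 0)))
    vals <- pmax(vals + noise, 0)
  }
  quant_volume(vals, true_volume$spacing, unit = true_volume$unit,
               modality = true_volume$modality)
}

#' Convert a concentration volume to the scanner's count-rate branch
#'
#' Exact inverse of [counts_to_concentration()]: emulates what the
#' scanner reconstruction would report before calibration, enabling
#' round-trip tests of the calibration path.
#'
#' @param conc_volume A [quant_volume()] with unit `"Bq_per_ml"`.
#' @param factor A [calibration_factor()] (or its numeric value in
#'   kBq/cps).
#' @return A [quant_volume()] with unit `"cps"`.
#' @export
to_counts_branch <- function(conc_volume, factor) {
  assert_unit(conc_volume, "Bq_per_ml")
  value <- if (inherits(factor, "calibration_factor")) factor$value else as.numeric(factor)
  stopifnot_scalar_num(value, "factor", positive = TRUE)
  scale <- voxel_volume_ml(conc_volume) / (value * 1000)
  quant_volume(conc_volume$values * scale, conc_volume$spacing,
               unit = "cps", modality = conc_volume$modality)
}
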