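# Cohort-scale paired phantom generation: many sphere lesions placed on
# a jittered lattice inside site-specific background slabs, with sizes,
# intensities, sites and benign/metastatic labels drawn from
# distributions that mimic a clinical bone-lesion cohort.

# SPECT SUV-equivalent background levels per skeletal site (clinically
# typical normal-bone medians; spine highest, skull lowest).
default_site_backgrounds <- function() {
  c(skull = 2.0, spine = 6.1, rib_cage = 2.5, pelvis = 4.7, limbs = 3.2)
}

#' Generate a paired simulated lesion cohort
#'
#' Builds one paired digital phantom containing `n_lesions` spherical
#' lesions, together with everything the analysis pipeline needs:
#' measured (blurred/noisy) volumes per modality, the SPECT count-rate
#' branch, lesion seed points per modality, background-ROI centers on
#' normal bone, and the generating ground truth.
#'
#' Stated-world defaults: lesion volumes log-uniform over 0.55-60 cm^3
#' (clinical range, median near 5-6 cm^3); SPECT lesion SUVs lognormal
#' (meanlog log 30, sdlog 0.3) truncated to 22-80 so every lesion stays
#' segmentable at the PET threshold of 15 after blur; metastatic
#' fraction 129/231 with a 1.3x uptake shift; PET/SPECT uptake ratio
#' 1.2 for lesions and background alike; site-dependent backgrounds
#' (spine 6.1 down to skull 2.0 SPECT-SUV); effective blur 12 mm SPECT
#' / 8 mm PET; signal-scaled Gaussian noise.
#'
#' Lesions are placed on a jittered lattice (cell 72 mm) inside axial
#' slabs assigned to the five skeletal sites, which keeps lesions
#' non-overlapping by construction. Background ROI centers are sampled
#' on a shell roughly 2-4 SPECT voxels outside each lesion surface at
#' the lesion's axial level.
#'
#' @param n_lesions Number of lesions (default 231, a typical cohort).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param uptake_ratio PET/SPECT multiplicative uptake factor.
#' @param psf_fwhm Named vector `c(spect=, pet=)`, mm; use
#'   `c(spect = 0, pet = 0)` for an idealized blur-free cohort.
#' @param noise_model,noise_scale_suv Noise switch and per-modality
#'   scales (SD at SUV v is `scale * sqrt(v)`).
#' @param volume_range_cm3 Log-uniform lesion-volume range.
#' @param suv_meanlog,suv_sdlog,suv_range Lognormal parameters and
#'   truncation range for benign SPECT lesion SUVs.
#' @param met_prob Probability a lesion is metastatic.
#' @param met_factor Multiplicative SUV shift for metastatic lesions.
#' @param site_probs Named sampling probabilities over the five sites.
#' @param site_backgrounds Named SPECT-SUV background levels per site.
#' @param pet_spacing PET grid spacing (default 3.65 x 3.65 x 3.27 mm).
#' @param calibration_kBq_per_cps Factor used by the counts branch.
#' @param n_bg_rois Background ROIs per lesion (5-10; default 7).
#' @return A list of class `paired_cohort`: `spec` ([phantom_spec()]),
#'   `truth`, `seeds` (data.frame), `bg_rois` (data.frame),
#'   `spect_counts`, `pet_conc` (measured volumes), `spect_conc_true`,
#'   `pet_conc_true`, and the acquisition records and calibration value.
#' @export
make_paired_cohort <- function(n_lesions = 231L, seed = 1L,
                               uptake_ratio = 1.2,
                               psf_fwhm = c(spect = 12, pet = 8),
                               noise_model = c("gaussian_scaled", "none"),
                               noise_scale_suv = c(spect = 0.3, pet = 0.15),
                               volume_range_cm3 = c(0.55, 60),
                               suv_meanlog = log(30), suv_sdlog = 0.3,
                               suv_range = c(22, 80),
                               met_prob = 129 / 231, met_factor = 1.3,
                               site_probs = c(skull = 0.10, spine = 0.35,
                                              rib_cage = 0.20, pelvis = 0.20,
                                              limbs = 0.15),
                               site_backgrounds = default_site_backgrounds(),
                               pet_spacing = c(3.65, 3.65, 3.27),
                               calibration_kBq_per_cps = 0.107,
                               n_bg_rois = 7L) {
  noise_model <- match.arg(noise_model)
  if (n_lesions < 1L) {
    abort_suvpair("n_lesions must be >= 1", "suvpair_invalid_argument")
  }
  set.seed(as.integer(seed))
  sites <- names(site_probs)

  ## ---- sample lesion properties ------------------------------------
  vol_cm3 <- exp(stats::runif(n_lesions, log(volume_range_cm3[1]),
                              log(volume_range_cm3[2])))
  radius_mm <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)
  site <- sample(sites, n_lesions, replace = TRUE, prob = site_probs)
  is_met <- stats::runif(n_lesions) < met_prob
  suv <- stats::rlnorm(n_lesions, suv_meanlog, suv_sdlog)
  suv <- pmin(pmax(suv, suv_range[1]), suv_range[2])
  suv[is_met] <- suv[is_met] * met_factor

  ## ---- lattice placement inside site slabs -------------------------
  cell_mm <- 72                         # 15 SPECT voxels
  cells_xy <- 5L                        # 5 x 5 cells per axial layer
  margin_mm <- 4.8
  per_layer <- cells_xy * cells_xy
  fov_xy <- cells_xy * cell_mm + 2 * margin_mm  # 345.6 mm
  site_counts <- table(factor(site, levels = sites))
  layers_per_site <- stats::setNames(
    pmax(1L, as.integer(ceiling(as.numeric(site_counts) / per_layer))), sites)
  slab_z0 <- margin_mm + c(0, cumsum(layers_per_site * cell_mm))[seq_along(sites)]
  names(slab_z0) <- sites
  fov_z <- margin_mm * 2 + sum(layers_per_site * cell_mm)

  x_mm <- y_mm <- z_mm <- numeric(n_lesions)
  cell_ctr_x <- cell_ctr_y <- cell_ctr_z <- numeric(n_lesions)
  for (st in sites) {
    idx <- which(site == st)
    if (length(idx) == 0L) next
    n_cells <- layers_per_site[[st]] * per_layer
    cells <- sample.int(n_cells, length(idx))  # distinct cells, no overlap
    cx <- (cells - 1L) %% cells_xy
    cy <- ((cells - 1L) %/% cells_xy) %% cells_xy
    cz <- (cells - 1L) %/% per_layer
    cell_ctr_x[idx] <- margin_mm + (cx + 0.5) * cell_mm
    cell_ctr_y[idx] <- margin_mm + (cy + 0.5) * cell_mm
    cell_ctr_z[idx] <- slab_z0[[st]] + (cz + 0.5) * cell_mm
    jit_max <- pmax(0, cell_mm / 2 - radius_mm[idx] - 6)
    x_mm[idx] <- cell_ctr_x[idx] + stats::runif(length(idx), -1, 1) * jit_max
    y_mm[idx] <- cell_ctr_y[idx] + stats::runif(length(idx), -1, 1) * jit_max
    z_mm[idx] <- cell_ctr_z[idx] + stats::runif(length(idx), -1, 1) * jit_max
  }

  lesions <- data.frame(
    lesion_id = sprintf("L%03d", seq_len(n_lesions)),
    x_mm = x_mm, y_mm = y_mm, z_mm = z_mm, radius_mm = radius_mm,
    suv = suv, site = site,
    class = ifelse(is_met, "metastatic", "benign"),
    stringsAsFactors = FALSE
  )
  background <- data.frame(
    site = sites,
    z_min_mm = slab_z0 - margin_mm,
    z_max_mm = slab_z0 + layers_per_site * cell_mm + margin_mm,
    suv = unname(site_backgrounds[sites]),
    stringsAsFactors = FALSE
  )
  # slabs partition the FOV: close gaps introduced by the double margin
  background$z_min_mm <- c(0, head(background$z_max_mm, -1))
  background$z_max_mm[nrow(background)] <- fov_z

  spec <- phantom_spec(
    fov_mm = c(fov_xy, fov_xy, fov_z),
    pet_spacing = pet_spacing,
    lesions = lesions[, c("x_mm", "y_mm", "z_mm", "radius_mm", "suv",
                          "site", "class")],
    background = background, uptake_ratio = uptake_ratio,
    psf_fwhm = psf_fwhm, noise_model = noise_model,
    noise_scale_suv = noise_scale_suv,
    calibration_kBq_per_cps = calibration_kBq_per_cps, seed = seed
  )

  ## ---- background ROI centers --------------------------------------
  # ROI centers stay inside the lesion's own lattice cell (5-mm disk plus
  # 1-mm guard from the cell face), which guarantees 5+ mm clearance from
  # every neighbouring lesion surface by construction, and on a shell
  # 10-18 mm (about 2-4 SPECT voxels) outside the lesion surface.
  box <- cell_mm / 2 - 6
  bg_list <- vector("list", n_lesions)
  for (l in seq_len(n_lesions)) {
    r <- radius_mm[l]
    ctr <- c(cell_ctr_x[l], cell_ctr_y[l], cell_ctr_z[l])
    pts <- matrix(NA_real_, n_bg_rois, 3L)
    for (q in seq_len(n_bg_rois)) {
      for (try in seq_len(300L)) {
        dz <- stats::runif(1, -8, 8)
        rho <- sqrt(max(r^2 - dz^2, 0)) + stats::runif(1, 10, 18)
        phi <- stats::runif(1, 0, 2 * pi)
        p <- c(x_mm[l] + rho * cos(phi), y_mm[l] + rho * sin(phi), z_mm[l] + dz)
        if (all(abs(p - ctr) <= box)) {
          pts[q, ] <- p
          break
        }
      }
      if (anyNA(pts[q, ])) {
        # very large lesion with adverse jitter: fall back to an in-plane
        # cell corner, the farthest available point from the lesion center
        ang <- pi / 4 + (q %% 4L) * pi / 2
        pts[q, ] <- c(ctr[1L] + box * sign(cos(ang)),
                      ctr[2L] + box * sign(sin(ang)), z_mm[l])
      }
    }
    bg_list[[l]] <- data.frame(lesion_id = lesions$lesion_id[l],
                               x_mm = pts[, 1L], y_mm = pts[, 2L],
                               z_mm = pts[, 3L])
  }
  bg_rois <- do.call(rbind, bg_list)

  ## ---- rasterize, degrade, counts branch ---------------------------
  rast <- rasterize_phantom(spec)
  spect_meas <- apply_system_model(
    rast$spect, psf_fwhm[["spect"]], noise_model,
    noise_scale = noise_scale_suv[["spect"]] *
      sqrt(rast$truth$conc_per_suv[["spect"]]),
    seed = seed + 1000L
  )
  pet_meas <- apply_system_model(
    rast$pet, psf_fwhm[["pet"]], noise_model,
    noise_scale = noise_scale_suv[["pet"]] *
      sqrt(rast$truth$conc_per_suv[["pet"]]),
    seed = seed + 2000L
  )
  spect_counts <- to_counts_branch(spect_meas, calibration_kBq_per_cps)

  ## ---- seed table ---------------------------------------------------
  centers <- cbind(x_mm, y_mm, z_mm)
  seed_spect <- t(apply(centers, 1L, point_to_voxel,
                        spacing = spec$spect_spacing,
                        dim = dim(rast$spect$values)))
  seed_pet <- t(apply(centers, 1L, point_to_voxel,
                      spacing = spec$pet_spacing,
                      dim = dim(rast$pet$values)))

  # Adaptive per-lesion PET threshold, emulating the clinical rule of
  # lowering the fixed threshold when blur leaves a small lesion's VOI
  # clearly smaller than its area of increased uptake: half the local
  # peak contrast over site background, capped at the default 15.
  pet_suv_meas <- pet_meas$values / rast$truth$conc_per_suv[["pet"]]
  dpet <- dim(pet_suv_meas)
  override <- numeric(n_lesions)
  for (l in seq_len(n_lesions)) {
    s0 <- seed_pet[l, ]
    lo <- pmax(s0 - 1L, 1L); hi <- pmin(s0 + 1L, dpet)
    local_max <- max(pet_suv_meas[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
    bg_pet <- site_backgrounds[[site[l]]] * uptake_ratio
    override[l] <- min(15, bg_pet + 0.5 * max(local_max - bg_pet, 0))
  }

  seeds <- rbind(
    data.frame(lesion_id = lesions$lesion_id, modality = "SPECT",
               i = seed_spect[, 1], j = seed_spect[, 2], k = seed_spect[, 3],
               site = site, class = lesions$class,
               threshold_override = NA_real_, stringsAsFactors = FALSE),
    data.frame(lesion_id = lesions$lesion_id, modality = "PET",
               i = seed_pet[, 1], j = seed_pet[, 2], k = seed_pet[, 3],
               site = site, class = lesions$class,
               threshold_override = override, stringsAsFactors = FALSE)
  )

  truth <- rast$truth
  truth$lesions <- cbind(lesion_id = lesions$lesion_id, truth$lesions,
                         bg_suv_spect = unname(site_backgrounds[site]),
                         bg_suv_pet = unname(site_backgrounds[site]) * uptake_ratio)

  structure(
    list(spec = spec, truth = truth, seeds = seeds, bg_rois = bg_rois,
         spect_counts = spect_counts, pet_conc = pet_meas,
         spect_conc_true = rast$spect, pet_conc_true = rast$pet,
         acq_spect = spec$acq_spect, acq_pet = spec$acq_pet,
         calibration_kBq_per_cps = calibration_kBq_per_cps),
    class = "paired_cohort"
  )
}
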