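#' Lesion volume of interest
#'
#' A VOI is an explicit set of voxel indices on a named grid, together
#' with the SUV threshold that defined it and its physical volume.
#' Indices are 1-based matrix rows `(i, j, k)`.
#'
#' @param idx Integer matrix (n x 3) of voxel indices, 1-based.
#' @param spacing Voxel spacing (mm) of the grid the VOI lives on.
#' @param dim Grid dimensions.
#' @param threshold SUV threshold that produced the VOI (strictly
#'   greater-than semantics), or `NA` for hand-built VOIs.
#' @param site Skeletal-site label: one of `"skull"`, `"spine"`,
#'   `"rib_cage"`, `"pelvis"`, `"limbs"`, or `NA`.
#' @param lesion_class `"metastatic"`, `"benign"`, or `"unknown"`.
#' @return An object of class `lesion_voi` with the above fields plus
#'   `volume_cm3`.
#' @export
lesion_voi <- function(idx, spacing, dim, threshold = NA_real_,
                       site = NA_character_, lesion_class = "unknown") {
  idx <- matrix(as.integer(idx), ncol = 3L,
                dimnames = list(NULL, c("i", "j", "k")))
  if (nrow(idx) == 0L) {
    abort_suvpair("VOI must contain at least one voxel", "suvpair_empty_voi")
  }
  if (!all(in_bounds(idx, dim))) {
    abort_suvpair("VOI voxel indices fall outside the grid",
                  "suvpair_invalid_argument")
  }
  spacing <- as.numeric(spacing)
  structure(
    list(idx = idx, spacing = spacing, dim = as.integer(dim),
         threshold = as.numeric(threshold),
         volume_cm3 = nrow(idx) * prod(spacing) / 1000,
         site = site, lesion_class = lesion_class),
    class = "lesion_voi"
  )
}

#' @export
print.lesion_voi <- function(x, ...) {
  cat(sprintf("<lesion_voi> %d voxels, %.3g cm^3, threshold %s, site %s, class %s\n",
              nrow(x$idx), x$volume_cm3,
              if (is.na(x$threshold)) "NA" else sprintf("%.4g", x$threshold),
              x$site, x$lesion_class))
  invisible(x)
}

# Linear indices of a VOI on a grid of dimension `dim` (with bounds check).
voi_indices <- function(voi, dim) {
  if (inherits(voi, "lesion_voi")) {
    if (!identical(as.integer(voi$dim), as.integer(dim))) {
      abort_suvpair("VOI grid does not match volume grid",
                    "suvpair_invalid_argument")
    }
    idx <- voi$idx
  } else if (is.matrix(voi) && ncol(voi) == 3L) {
    idx <- voi
  } else {
    abort_suvpair("expected a `lesion_voi` or an n x 3 index matrix",
                  "suvpair_invalid_argument")
  }
  if (nrow(idx) == 0L) {
    abort_suvpair("VOI is empty", "suvpair_empty_voi")
  }
  if (!all(in_bounds(idx, dim))) {
    abort_suvpair("VOI voxel indices fall outside the grid",
                  "suvpair_invalid_argument")
  }
  ijk_to_lin(idx, dim)
}

#' Threshold-based lesion segmentation
#'
#' Segments the lesion containing `seed` as the 26-connected component
#' of voxels with SUV strictly greater than `threshold`. This is the
#' reference-modality step of the paired workflow: lesions are first
#' delineated on the higher-resolution modality with a fixed threshold
#' (clinical default SUV > 15).
#'
#' @param suv_volume A [quant_volume()] with unit `"SUV"`.
#' @param seed Length-3 integer voxel index (1-based) inside the lesion.
#' @param threshold SUV threshold; membership is `value > threshold`.
#' @param site,lesion_class Labels carried into the VOI.
#' @return A [lesion_voi()].
#' @examples
#' vals <- array(5, c(9, 9, 9)); vals[4:6, 4:6, 4:6] <- 30
#' v <- quant_volume(vals, c(4.8, 4.8, 4.8), unit = "SUV")
#' segment_threshold(v, c(5, 5, 5), threshold = 15)
#' @export
segment_threshold <- function(suv_volume, seed, threshold = 15,
                              site = NA_character_, lesion_class = "unknown") {
  assert_unit(suv_volume, "SUV")
  stopifnot_scalar_num(threshold, "threshold")
  d <- dim(suv_volume$values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || !all(in_bounds(matrix(seed, ncol = 3L), d))) {
    abort_suvpair("seed voxel is outside the grid", "suvpair_invalid_argument")
  }
  seed_lin <- ijk_to_lin(matrix(seed, ncol = 3L), d)
  vals <- as.vector(suv_volume$values)
  if (vals[seed_lin] <= threshold) {
    abort_suvpair(sprintf("seed voxel SUV %.4g does not exceed threshold %.4g",
                          vals[seed_lin], threshold), "suvpair_empty_segmentation")
  }
  comp <- connected_component(vals > threshold, seed_lin, d)
  lesion_voi(lin_to_ijk(comp, d), suv_volume$spacing, d, threshold = threshold,
             site = site, lesion_class = lesion_class)
}

# Grow the seed's component by lowering the threshold step by step.
#
# Widest-path ("path-max") region growing: the 26-connected component of
# {value > t} containing the seed, as t sweeps downward, changes exactly when
# t crosses the largest value on the component's outer boundary. Each growth
# step admits that boundary voxel together with everything newly reachable
# through it at the same level. Recording the boundary maximum after each step
# gives, for every plateau of the (non-increasing, stepwise) volume-vs-threshold
# curve, a representative threshold at which the component equals the recorded
# voxel set.
#
# Growth stops once `stop_voxels` voxels have been admitted or the image is
# exhausted. A closure that would grow past `hard_cap` voxels is abandoned
# (incomplete = TRUE): with hard_cap = max(2 * stop_voxels, tolerance bound),
# its true volume would already be farther from the target than the previous
# state, or beyond the caller's tolerance, so it can never win the volume
# match. This keeps a threshold step that reaches a flat background plateau
# from flooding the whole image.
grow_threshold_curve <- function(values, dim, seed_lin, stop_voxels,
                                 hard_cap = ceiling(2 * stop_voxels)) {
  n <- length(values)
  visited <- logical(n)
  admitted <- integer(0)
  level <- values[seed_lin]

  # BFS over voxels with value >= level; aborts (complete = FALSE) when more
  # than `max_admit` voxels would be admitted.
  admit_closure <- function(frontier, level, max_admit) {
    added <- integer(0)
    frontier <- unique(frontier[!visited[frontier] & values[frontier] >= level])
    visited[frontier] <<- TRUE
    complete <- TRUE
    while (length(frontier) > 0L) {
      added <- c(added, frontier)
      if (length(added) > max_admit) {
        complete <- FALSE
        break
      }
      nb <- unique(neighbours26_lin(lin_to_ijk(frontier, dim), dim))
      nb <- nb[!visited[nb] & values[nb] >= level]
      visited[nb] <<- TRUE
      frontier <- nb
    }
    list(added = added, complete = complete)
  }

  boundary <- integer(0)
  states_n <- integer(0)
  states_thr <- numeric(0)
  frontier <- seed_lin
  incomplete <- FALSE
  repeat {
    max_admit <- hard_cap - length(admitted)
    cl <- admit_closure(frontier, level, max_admit)
    if (!cl$complete) {
      incomplete <- TRUE
      break
    }
    admitted <- c(admitted, cl$added)
    nb <- unique(neighbours26_lin(lin_to_ijk(cl$added, dim), dim))
    boundary <- unique(c(boundary, nb[!visited[nb]]))
    boundary <- boundary[!visited[boundary]]
    thr <- if (length(boundary) > 0L) max(values[boundary]) else -Inf
    states_n <- c(states_n, length(admitted))
    states_thr <- c(states_thr, thr)
    if (length(admitted) >= stop_voxels || length(boundary) == 0L) break
    level <- thr
    frontier <- boundary[values[boundary] >= level]
  }
  list(admitted = admitted, states_n = states_n, states_thr = states_thr,
       incomplete = incomplete)
}

#' Volume-matched lesion segmentation
#'
#' Finds, on a second modality's SUV image, the threshold whose
#' 26-connected component containing `seed` has a physical volume
#' closest to `target_volume_cm3` (typically the volume segmented on
#' the reference modality). Because the component volume is a
#' non-increasing step function of the threshold, the search runs over
#' the achievable component sizes rather than a continuous bisection;
#' ties in `|volume - target|` are broken toward the larger volume
#' (lower threshold).
#'
#' @param suv_volume A [quant_volume()] with unit `"SUV"`.
#' @param seed Length-3 integer voxel index (1-based) inside the lesion.
#' @param target_volume_cm3 Target volume in cm^3 (> 0).
#' @param max_mismatch Maximum tolerated relative volume mismatch
#'   `|V - target| / target` (default 0.2); exceeding it raises a
#'   `suvpair_matching_failure` error carrying the best achieved
#'   mismatch in its `best_mismatch` field.
#' @param site,lesion_class Labels carried into the VOI.
#' @return A [lesion_voi()] with an extra `mismatch` field, the achieved
#'   relative volume mismatch.
#' @export
match_volume_threshold <- function(suv_volume, seed, target_volume_cm3,
                                   max_mismatch = 0.2,
                                   site = NA_character_,
                                   lesion_class = "unknown") {
  assert_unit(suv_volume, "SUV")
  stopifnot_scalar_num(target_volume_cm3, "target_volume_cm3", positive = TRUE)
  d <- dim(suv_volume$values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || !all(in_bounds(matrix(seed, ncol = 3L), d))) {
    abort_suvpair("seed voxel is outside the grid", "suvpair_invalid_argument")
  }
  seed_lin <- ijk_to_lin(matrix(seed, ncol = 3L), d)
  vox_cm3 <- prod(suv_volume$spacing) / 1000
  target_vox <- target_volume_cm3 / vox_cm3
  # Once the component size reaches the target, further growth only
  # increases |V - target|; one extra state is recorded by construction.
  hard_cap <- if (is.finite(max_mismatch)) {
    max(ceiling(2 * ceiling(target_vox)),
        ceiling(target_vox * (1 + max_mismatch)) + 1)
  } else {
    Inf
  }
  curve <- grow_threshold_curve(as.vector(suv_volume$values), d, seed_lin,
                                stop_voxels = ceiling(target_vox),
                                hard_cap = hard_cap)
  if (length(curve$states_n) == 0L) {
    # even the tightest threshold admits a component beyond both twice the
    # target and the tolerance bound (e.g. the seed sits on a large plateau)
    abort_suvpair(
      sprintf("smallest achievable component already exceeds the %.3g cm^3 target beyond tolerance",
              target_volume_cm3),
      "suvpair_matching_failure",
      best_mismatch = if (is.finite(hard_cap)) {
        (hard_cap * vox_cm3 - target_volume_cm3) / target_volume_cm3
      } else {
        1
      }
    )
  }
  err <- abs(curve$states_n * vox_cm3 - target_volume_cm3)
  # tie-break toward larger volume: states are in increasing volume order,
  # so take the LAST state attaining the minimum
  best <- max(which(err == min(err)))
  mismatch <- err[best] / target_volume_cm3
  if (mismatch > max_mismatch) {
    abort_suvpair(
      sprintf("no threshold yields a volume within %.0f%% of target (best %.1f%%)",
              100 * max_mismatch, 100 * mismatch),
      "suvpair_matching_failure", best_mismatch = mismatch
    )
  }
  idx <- lin_to_ijk(sort(curve$admitted[seq_len(curve$states_n[best])]), d)
  voi <- lesion_voi(idx, suv_volume$spacing, d,
                    threshold = curve$states_thr[best],
                    site = site, lesion_class = lesion_class)
  voi$mismatch <- mismatch
  voi
}

#' Physical volume of a VOI
#'
#' @param voi A [lesion_voi()] or an n x 3 index matrix.
#' @param spacing Voxel spacing in mm; defaults to the VOI's own.
#' @return Volume in cm^3: voxel count times voxel volume (mm^3) / 1000.
#' @export
voi_volume <- function(voi, spacing = NULL) {
  if (inherits(voi, "lesion_voi")) {
    n <- nrow(voi$idx)
    if (is.null(spacing)) spacing <- voi$spacing
  } else if (is.matrix(voi) && ncol(voi) == 3L) {
    n <- nrow(voi)
    if (is.null(spacing)) {
      abort_suvpair("spacing is required for a bare index matrix",
                    "suvpair_invalid_argument")
    }
  } else {
    abort_suvpair("expected a `lesion_voi` or an n x 3 index matrix",
                  "suvpair_invalid_argument")
  }
  n * prod(as.numeric(spacing)) / 1000
}

#' Read lesion seed points from CSV
#'
#' Expected columns: `lesion_id, modality, i, j, k, site, class,
#' threshold_override` (indices 1-based; `threshold_override` may be
#' blank/NA to use the run default).
#'
#' @param path CSV path.
#' @return A data.frame with validated columns.
#' @export
read_lesion_seeds <- function(path) {
  if (!file.exists(path)) {
    abort_suvpair(sprintf("file not found: %s", path), "suvpair_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lesion_id", "modality", "i", "j", "k", "site", "class")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    abort_suvpair(sprintf("seed CSV missing columns: %s",
                          paste(missing, collapse = ", ")),
                  "suvpair_validation_error")
  }
  if (!"threshold_override" %in% names(df)) df$threshold_override <- NA_real_
  bad <- which(!is.finite(df$i) | !is.finite(df$j) | !is.finite(df$k))
  if (length(bad) > 0L) {
    abort_suvpair(sprintf("seed CSV has non-numeric indices in rows: %s",
                          paste(bad, collapse = ", ")),
                  "suvpair_validation_error")
  }
  df
}

#' Export a set of VOIs as a NIfTI label mask
#'
#' Builds an integer label volume (0 = background, `labels[i]` for the
#' i-th VOI) on the grid of `template` and writes it with
#' [write_nifti()].
#'
#' @param vois List of [lesion_voi()] objects on a common grid.
#' @param template A [quant_volume()] supplying grid and spacing.
#' @param path Output NIfTI path.
#' @param labels Integer labels, default `seq_along(vois)`.
#' @return `path`, invisibly.
#' @export
write_voi_mask <- function(vois, template, path, labels = seq_along(vois)) {
  d <- dim(template$values)
  lab <- array(0, d)
  for (m in seq_along(vois)) {
    lab[voi_indices(vois[[m]], d)] <- labels[m]
  }
  write_nifti(quant_volume(lab, template$spacing, unit = "SUV",
                           modality = paste0(template$modality, "-labels")),
              path)
}
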