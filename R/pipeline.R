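# End-to-end paired analysis: reference-modality segmentation,
# volume-matched segmentation on the other modality, per-lesion metrics,
# and the cross-modality agreement report.

#' Per-lesion paired analysis of two SUV volumes
#'
#' For every lesion in `seeds`: segment the reference modality (PET by
#' default) with a fixed SUV threshold (honouring per-lesion
#' `threshold_override`), volume-match the other modality to the
#' reference VOI, compute SUV_max/peak/mean, the background VOI from
#' the lesion's ROI centers, and SUVRs for both modalities. Lesions
#' whose segmentation or matching fails are reported in `failures` and
#' skipped; the run continues.
#'
#' @param spect_suv,pet_suv [quant_volume()]s with unit `"SUV"`.
#' @param seeds Seed data.frame (see [read_lesion_seeds()]): one row
#'   per lesion and modality.
#' @param bg_rois data.frame with `lesion_id, x_mm, y_mm, z_mm` of
#'   background ROI centers (physical mm, shared by both grids).
#' @param threshold Default reference-segmentation SUV threshold
#'   (default 15).
#' @param max_mismatch Volume-matching tolerance (default 0.2).
#' @param reference `"PET"` (default) or `"SPECT"`: modality segmented
#'   with the fixed threshold; the other is volume-matched.
#' @param bg_diameter_mm Background ROI diameter (default 10).
#' @return A list with `lesions` (long data.frame, one row per lesion
#'   and modality with volume, threshold, mismatch, SUVs, SUVRs) and
#'   `failures` (data.frame of lesion_id + message).
#' @export
analyze_paired_lesions <- function(spect_suv, pet_suv, seeds, bg_rois,
                                   threshold = 15, max_mismatch = 0.2,
                                   reference = c("PET", "SPECT"),
                                   bg_diameter_mm = 10) {
  reference <- match.arg(reference)
  assert_unit(spect_suv, "SUV"); assert_unit(pet_suv, "SUV")
  vols <- list(SPECT = spect_suv, PET = pet_suv)
  other <- if (reference == "PET") "SPECT" else "PET"
  ids <- unique(seeds$lesion_id)
  rows <- list()
  failures <- list()
  for (id in ids) {
    ref_row <- seeds[seeds$lesion_id == id & seeds$modality == reference, ]
    oth_row <- seeds[seeds$lesion_id == id & seeds$modality == other, ]
    if (nrow(ref_row) != 1L || nrow(oth_row) != 1L) {
      failures[[id]] <- sprintf("expected one %s and one %s seed row",
                                reference, other)
      next
    }
    thr <- if (is.finite(ref_row$threshold_override)) {
      ref_row$threshold_override
    } else {
      threshold
    }
    res <- tryCatch({
      ref_voi <- segment_threshold(vols[[reference]],
                                   c(ref_row$i, ref_row$j, ref_row$k), thr,
                                   site = ref_row$site,
                                   lesion_class = ref_row$class)
      oth_voi <- match_volume_threshold(vols[[other]],
                                        c(oth_row$i, oth_row$j, oth_row$k),
                                        ref_voi$volume_cm3,
                                        max_mismatch = max_mismatch,
                                        site = oth_row$site,
                                        lesion_class = oth_row$class)
      ctr <- as.matrix(bg_rois[bg_rois$lesion_id == id,
                               c("x_mm", "y_mm", "z_mm")])
      if (nrow(ctr) == 0L) {
        abort_suvpair(sprintf("no background ROI centers for lesion %s", id),
                      "suvpair_validation_error")
      }
      per_mod <- list()
      vois <- stats::setNames(list(ref_voi, oth_voi), c(reference, other))
      for (mod in c("SPECT", "PET")) {
        m <- uptake_metrics(vols[[mod]], vois[[mod]])
        bg <- suppressWarnings(background_voi(vols[[mod]], ctr, bg_diameter_mm))
        sr <- compute_suvr(m, bg)
        per_mod[[mod]] <- data.frame(
          lesion_id = id, modality = mod,
          volume_cm3 = vois[[mod]]$volume_cm3,
          threshold = vois[[mod]]$threshold,
          mismatch = if (is.null(vois[[mod]]$mismatch)) NA_real_
                     else vois[[mod]]$mismatch,
          suv_max = m$suv_max, suv_peak = m$suv_peak, suv_mean = m$suv_mean,
          suv_mean_bg = bg$suv_mean_bg,
          suvr_max = sr$suvr_max, suvr_peak = sr$suvr_peak,
          suvr_mean = sr$suvr_mean,
          site = ref_row$site, class = ref_row$class,
          stringsAsFactors = FALSE
        )
      }
      rbind(per_mod$SPECT, per_mod$PET)
    }, suvpair_error = function(e) e)
    if (inherits(res, "suvpair_error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      rows[[id]] <- res
    }
  }
  fail_df <- if (length(failures) > 0L) {
    data.frame(lesion_id = names(failures),
               message = unlist(failures, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(lesion_id = character(0), message = character(0))
  }
  list(lesions = if (length(rows) > 0L) do.call(rbind, c(rows, list(make.row.names = FALSE)))
                 else NULL,
       failures = fail_df)
}

#' Pivot a long per-lesion metrics table into paired form
#'
#' Joins the SPECT and PET rows of each lesion into one row with
#' `spect_*` / `pet_*` columns, ready for the agreement statistics.
#'
#' @param lesions Long data.frame from [analyze_paired_lesions()] (or
#'   the per-lesion CSV, two rows per lesion).
#' @return A data.frame with one row per lesion: `lesion_id`, `site`,
#'   `class`, `volume_cm3` (reference = PET volume), `mismatch`, and
#'   `spect_`/`pet_`-prefixed metric columns.
#' @export
pair_lesion_records <- function(lesions) {
  metric_cols <- c("volume_cm3", "threshold", "suv_max", "suv_peak", "suv_mean",
                   "suv_mean_bg", "suvr_max", "suvr_peak", "suvr_mean")
  s <- lesions[lesions$modality == "SPECT", ]
  p <- lesions[lesions$modality == "PET", ]
  common <- intersect(s$lesion_id, p$lesion_id)
  s <- s[match(common, s$lesion_id), ]
  p <- p[match(common, p$lesion_id), ]
  out <- data.frame(lesion_id = common, site = s$site, class = s$class,
                    volume_cm3 = p$volume_cm3,
                    mismatch = pmax(s$mismatch, p$mismatch, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  for (m in metric_cols) {
    out[[paste0("spect_", m)]] <- s[[m]]
    out[[paste0("pet_", m)]] <- p[[m]]
  }
  out
}

#' Cross-modality agreement report
#'
#' The statistical comparison between paired SPECT and PET lesion
#' measurements: per measure (SUVs and SUVRs) a least-squares
#' regression of PET on SPECT, the nonparametric Bland-Altman summary
#' (median difference and 2.5th/97.5th percentile limits of agreement,
#' relative to SPECT), the Wilcoxon signed-rank test on paired
#' differences, and the Shapiro-Wilk normality gate that motivates the
#' nonparametric summaries. Additionally: Mann-Whitney U tests of
#' metastatic versus benign lesions per measure (one-sided, metastatic
#' greater), the size-stratified difference table, and the per-site
#' background summary.
#'
#' @param paired Paired data.frame from [pair_lesion_records()].
#' @param measures Measure suffixes to compare.
#' @return A list of class `agreement_report`.
#' @export
compare_modalities <- function(paired,
                               measures = c("suv_max", "suv_peak", "suv_mean",
                                            "suvr_max", "suvr_peak", "suvr_mean")) {
  if (!is.data.frame(paired) || nrow(paired) < 3L) {
    abort_suvpair("need at least 3 paired lesions", "suvpair_invalid_argument")
  }
  per_measure <- list()
  for (m in measures) {
    sv <- paired[[paste0("spect_", m)]]
    pv <- paired[[paste0("pet_", m)]]
    d <- pv - sv
    nz <- d[d != 0]
    per_measure[[m]] <- list(
      regression = least_squares_fit(sv, pv),
      bland_altman = bland_altman_median(sv, pv)[
        c("median_diff", "loa_low", "loa_high", "n", "normalization")],
      wilcoxon = if (length(nz) == 0L) list(statistic = NA, p_value = 1,
                                            n = 0, method = "degenerate")
                 else wilcoxon_signed_rank(d),
      normality = tryCatch(normality_gate(d),
                           suvpair_error = function(e) {
                             list(is_normal = NA, p_value = NA_real_,
                                  W = NA_real_, n = length(d))
                           }),
      met_vs_benign = {
        met <- paired$class == "metastatic"
        if (any(met) && any(!met)) {
          list(SPECT = mann_whitney_u(sv[met], sv[!met], "greater"),
               PET = mann_whitney_u(pv[met], pv[!met], "greater"))
        } else {
          NULL
        }
      }
    )
  }
  structure(
    list(n_lesions = nrow(paired),
         n_metastatic = sum(paired$class == "metastatic"),
         n_benign = sum(paired$class == "benign"),
         per_measure = per_measure,
         size_strata = size_stratified_summary(paired),
         site_background = site_background_summary(paired),
         volume_matching = if (all(is.na(paired$mismatch))) {
           list(median_mismatch = NA_real_, max_mismatch = NA_real_)
         } else {
           list(median_mismatch = stats::median(paired$mismatch, na.rm = TRUE),
                max_mismatch = max(paired$mismatch, na.rm = TRUE))
         }),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d lesions (%d metastatic, %d benign)\n",
              x$n_lesions, x$n_metastatic, x$n_benign))
  for (m in names(x$per_measure)) {
    pm <- x$per_measure[[m]]
    cat(sprintf("  %-9s R2=%.3f  median diff %+.1f%% (LOA %+.1f%% .. %+.1f%%)  Wilcoxon p=%.3g\n",
                m, pm$regression$r_squared, pm$bland_altman$median_diff,
                pm$bland_altman$loa_low, pm$bland_altman$loa_high,
                pm$wilcoxon$p_value))
  }
  cat(sprintf("  volume matching |dV|/V: median %.2f%%, max %.2f%%\n",
              100 * x$volume_matching$median_mismatch,
              100 * x$volume_matching$max_mismatch))
  invisible(x)
}

#' Write / read the per-lesion metrics CSV
#'
#' Long format, one row per lesion and modality, with the columns
#' `lesion_id, modality, volume_cm3, threshold, suv_max, suv_peak,
#' suv_mean, suv_mean_bg, suvr_max, suvr_peak, suvr_mean, site, class`
#' (plus `mismatch` for the volume-matched modality).
#'
#' @param lesions Long data.frame from [analyze_paired_lesions()].
#' @param path CSV path.
#' @return `path` invisibly; `read_lesion_metrics` returns the
#'   data.frame.
#' @export
write_lesion_metrics <- function(lesions, path) {
  utils::write.csv(lesions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lesion_metrics
#' @export
read_lesion_metrics <- function(path) {
  if (!file.exists(path)) {
    abort_suvpair(sprintf("file not found: %s", path), "suvpair_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lesion_id", "modality", "volume_cm3", "suv_max", "suv_peak",
              "suv_mean", "suv_mean_bg", "suvr_max", "suvr_peak", "suvr_mean",
              "site", "class")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    abort_suvpair(sprintf("metrics CSV missing columns: %s",
                          paste(missing, collapse = ", ")),
                  "suvpair_validation_error")
  }
  df
}

# Serialize an agreement report to a plain list for JSON output.
report_to_list <- function(report) {
  out <- unclass(report)
  out$size_strata <- as.list(report$size_strata)
  out$site_background <- as.list(report$site_background)
  out
}
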