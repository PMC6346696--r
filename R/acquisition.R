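#' Isotope half-lives
#'
#' Physical half-lives of the isotopes used by the bone-imaging
#' pipeline, in seconds: Tc-99m 6.0067 h, F-18 109.77 min. Any other
#' isotope can be used by passing an explicit `half_life_s` to
#' [acquisition_record()].
#'
#' @param isotope Isotope label, e.g. `"Tc-99m"` or `"F-18"`.
#' @return Half-life in seconds.
#' @examples
#' half_life_s("Tc-99m") / 3600  # hours
#' @export
half_life_s <- function(isotope) {
  tab <- c("Tc-99m" = 6.0067 * 3600, "F-18" = 109.77 * 60)
  if (!isotope %in% names(tab)) {
    abort_suvpair(sprintf("unknown isotope '%s'; pass half_life_s explicitly",
                          isotope), "suvpair_invalid_argument")
  }
  unname(tab[[isotope]])
}

#' Acquisition record for one scan
#'
#' The non-voxel quantities of the SUV equation: injected activity,
#' injection and scan times, patient weight, and isotope half-life.
#' Activities are stored in Bq and weight in grams, matching the units
#' the SUV definition uses.
#'
#' @param injected_activity_Bq Activity in Bq at injection time (> 0).
#' @param t_injection,t_scan Timestamps (`POSIXct` or anything
#'   `as.POSIXct` accepts); `t_scan` must not precede `t_injection`.
#' @param patient_weight_g Patient weight in grams (> 0).
#' @param isotope Isotope label used to look up the half-life when
#'   `half_life_s` is `NULL`.
#' @param half_life_s Half-life in seconds; overrides `isotope`.
#' @return An object of class `acquisition_record`.
#' @examples
#' acq <- acquisition_record(
#'   injected_activity_Bq = 672e6,
#'   t_injection = "2020-01-01 09:00:00", t_scan = "2020-01-01 12:00:00",
#'   patient_weight_g = 75000, isotope = "Tc-99m"
#' )
#' decay_corrected_activity(acq) / 1e6  # MBq at scan start
#' @export
acquisition_record <- function(injected_activity_Bq, t_injection, t_scan,
                               patient_weight_g, isotope = "Tc-99m",
                               half_life_s = NULL) {
  stopifnot_scalar_num(injected_activity_Bq, "injected_activity_Bq", positive = TRUE)
  stopifnot_scalar_num(patient_weight_g, "patient_weight_g", positive = TRUE)
  if (is.null(half_life_s)) half_life_s <- half_life_s(isotope)
  stopifnot_scalar_num(half_life_s, "half_life_s", positive = TRUE)
  # accept ISO-8601 "T" separators regardless of R version
  if (is.character(t_injection)) t_injection <- sub("T", " ", t_injection, fixed = TRUE)
  if (is.character(t_scan)) t_scan <- sub("T", " ", t_scan, fixed = TRUE)
  t_injection <- as.POSIXct(t_injection, tz = "UTC")
  t_scan <- as.POSIXct(t_scan, tz = "UTC")
  if (is.na(t_injection) || is.na(t_scan)) {
    abort_suvpair("could not parse timestamps", "suvpair_invalid_argument")
  }
  if (t_scan < t_injection) {
    abort_suvpair("t_scan must be >= t_injection", "suvpair_invalid_argument")
  }
  structure(
    list(injected_activity_Bq = injected_activity_Bq,
         t_injection = t_injection, t_scan = t_scan,
         patient_weight_g = patient_weight_g,
         isotope = isotope, half_life_s = half_life_s),
    class = "acquisition_record"
  )
}

#' Radioactive decay correction
#'
#' Decays an activity over an elapsed time:
#' `A(t) = A0 * 2^(-elapsed / half_life)`. Used to express the injected
#' activity at scan start, the denominator of the SUV equation.
#'
#' @param activity_Bq Activity in Bq (>= 0).
#' @param elapsed_s Elapsed time in seconds (>= 0).
#' @param half_life_s Half-life in seconds (> 0).
#' @return Decayed activity in Bq.
#' @examples
#' decay_correct(100, 3600, 3600)  # one half-life -> 50
#' @export
decay_correct <- function(activity_Bq, elapsed_s, half_life_s) {
  stopifnot_scalar_num(activity_Bq, "activity_Bq", nonneg = TRUE)
  stopifnot_scalar_num(elapsed_s, "elapsed_s", nonneg = TRUE)
  stopifnot_scalar_num(half_life_s, "half_life_s", positive = TRUE)
  activity_Bq * 2^(-elapsed_s / half_life_s)
}

#' Injected activity decay-corrected to scan start
#'
#' @param acq An [acquisition_record()].
#' @return Activity in Bq at `t_scan`.
#' @export
decay_corrected_activity <- function(acq) {
  if (!inherits(acq, "acquisition_record")) {
    abort_suvpair("expected an `acquisition_record`", "suvpair_invalid_argument")
  }
  elapsed <- as.numeric(difftime(acq$t_scan, acq$t_injection, units = "secs"))
  decay_correct(acq$injected_activity_Bq, elapsed, acq$half_life_s)
}

#' Read an acquisition record from JSON or YAML
#'
#' Expects fields `injected_activity_MBq`, `t_injection`, `t_scan`
#' (ISO-8601), `patient_weight_kg`, and `isotope` (optionally
#' `half_life_s`). Activities are given in MBq and weights in kg in the
#' file, following clinical reporting convention, and converted to
#' Bq / g internally.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [acquisition_record()].
#' @export
read_acquisition <- function(path) {
  if (!file.exists(path)) {
    abort_suvpair(sprintf("file not found: %s", path), "suvpair_io_error")
  }
  rec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  needed <- c("injected_activity_MBq", "t_injection", "t_scan", "patient_weight_kg")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0L) {
    abort_suvpair(sprintf("acquisition record missing fields: %s",
                          paste(missing, collapse = ", ")),
                  "suvpair_validation_error")
  }
  acquisition_record(
    injected_activity_Bq = as.numeric(rec$injected_activity_MBq) * 1e6,
    t_injection = rec$t_injection, t_scan = rec$t_scan,
    patient_weight_g = as.numeric(rec$patient_weight_kg) * 1000,
    isotope = if (is.null(rec$isotope)) "Tc-99m" else rec$isotope,
    half_life_s = if (is.null(rec$half_life_s)) NULL else as.numeric(rec$half_life_s)
  )
}

#' Write an acquisition record to JSON
#'
#' Inverse of [read_acquisition()] (JSON flavour).
#'
#' @param acq An [acquisition_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acq, path) {
  jsonlite::write_json(
    list(injected_activity_MBq = acq$injected_activity_Bq / 1e6,
         t_injection = format(acq$t_injection, "%Y-%m-%dT%H:%M:%S"),
         t_scan = format(acq$t_scan, "%Y-%m-%dT%H:%M:%S"),
         patient_weight_kg = acq$patient_weight_g / 1000,
         isotope = acq$isotope, half_life_s = acq$half_life_s),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
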