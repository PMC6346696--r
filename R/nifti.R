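# Minimal NIfTI-1 I/O.
#
# No NIfTI package is assumed to be installed, so the 348-byte NIfTI-1
# header is read and written directly. Only what the pipeline needs is
# supported: single-file .nii (optionally gzipped), 3-D volumes,
# datatypes uint8/int16/int32/float32/float64 on read (float64 on
# write), scl_slope/scl_inter scaling, and spacing from pixdim. The
# unit and modality tags of a `quant_volume` are round-tripped through
# the 80-byte `descrip` field.

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Write a volume to a NIfTI-1 file
#'
#' Writes a [quant_volume()] as a single-file NIfTI-1 image (float64 so
#' quantitative round trips are exact, spatial units mm, sform set to a
#' diagonal spacing matrix). The unit
#' and modality tags are stored in the header `descrip` field so that
#' [read_nifti()] can restore them.
#'
#' @param vol A [quant_volume()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  if (!is_quant_volume(vol)) {
    abort_suvpair("expected a `quant_volume`", "suvpair_invalid_argument")
  }
  d <- dim(vol$values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_chr <- function(x, n) {
    raw_x <- charToRaw(x)
    if (length(raw_x) > n) raw_x <- raw_x[seq_len(n)]
    writeBin(c(raw_x, raw(n - length(raw_x))), con)
  }
  w_i32(348L)                               # sizeof_hdr
  w_chr("", 10L); w_chr("", 18L)            # data_type, db_name (unused)
  w_i32(0L); w_i16(0L); w_chr("r", 1L)      # extents, session_error, regular
  writeBin(raw(1L), con)                    # dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))           # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)              # intent_p1..3, intent_code
  w_i16(64L); w_i16(64L); w_i16(0L)         # datatype float64, bitpix, slice_start
  w_f32(c(1, vol$spacing, 1, 1, 1, 1))      # pixdim[8] (qfac = 1)
  w_f32(352); w_f32(1); w_f32(0)            # vox_offset, scl_slope, scl_inter
  w_i16(0L)                                 # slice_end
  writeBin(as.raw(c(0L, 2L)), con)          # slice_code, xyzt_units = NIFTI_UNITS_MM
  w_f32(c(0, 0, 0, 0))                      # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                          # glmax, glmin
  w_chr(sprintf("suvpair unit=%s modality=%s", vol$unit, vol$modality), 80L)
  w_chr("", 24L)                            # aux_file
  w_i16(0L); w_i16(1L)                      # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                # quatern b,c,d, qoffset x,y,z
  w_f32(c(vol$spacing[1], 0, 0, 0))         # srow_x
  w_f32(c(0, vol$spacing[2], 0, 0))         # srow_y
  w_f32(c(0, 0, vol$spacing[3], 0))         # srow_z
  w_chr("", 16L)                            # intent_name
  w_chr("n+1", 4L)                          # magic
  writeBin(raw(4L), con)                    # extension flag
  writeBin(as.numeric(vol$values), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (plain or gzipped) into a
#' [quant_volume()]. `scl_slope`/`scl_inter` scaling is applied. The
#' unit/modality tags written by [write_nifti()] are restored when
#' present; otherwise `unit` and `modality` arguments are used.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param unit,modality Fallback tags when the file does not carry
#'   suvpair tags in its `descrip` field.
#' @return A [quant_volume()].
#' @export
read_nifti <- function(path, unit = "SUV", modality = "unknown") {
  if (!file.exists(path)) {
    abort_suvpair(sprintf("file not found: %s", path), "suvpair_io_error")
  }
  con <- gzfile(path, "rb")  # gzfile transparently reads uncompressed files
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) {
    abort_suvpair("truncated NIfTI header", "suvpair_io_error")
  }
  rd <- function(raw, what, n, size, offset, endian, signed = TRUE) {
    readBin(raw[(offset + 1L):(offset + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(hdr_raw, "integer", 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd(hdr_raw, "integer", 1L, 4L, 0L, endian) != 348L) {
      abort_suvpair("not a NIfTI-1 file (bad sizeof_hdr)", "suvpair_io_error")
    }
  }
  dim8 <- rd(hdr_raw, "integer", 8L, 2L, 40L, endian)
  if (dim8[1L] < 3L) {
    abort_suvpair("expected a 3-D NIfTI volume", "suvpair_io_error")
  }
  d <- dim8[2:4]
  n_extra <- if (dim8[1L] > 3L) prod(pmax(dim8[5:(dim8[1L] + 1L)], 1L)) else 1L
  if (n_extra != 1L) {
    abort_suvpair("only single-frame 3-D volumes are supported", "suvpair_io_error")
  }
  datatype <- rd(hdr_raw, "integer", 1L, 2L, 70L, endian)
  pixdim <- rd(hdr_raw, "double", 8L, 4L, 76L, endian)
  vox_offset <- rd(hdr_raw, "double", 1L, 4L, 108L, endian)
  scl_slope <- rd(hdr_raw, "double", 1L, 4L, 112L, endian)
  scl_inter <- rd(hdr_raw, "double", 1L, 4L, 116L, endian)
  descrip_raw <- hdr_raw[149:228]
  descrip <- rawToChar(descrip_raw[seq_len(max(0L, which(descrip_raw != as.raw(0))))])
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) {
    abort_suvpair(sprintf("unsupported NIfTI datatype %d", datatype),
                  "suvpair_io_error")
  }
  # skip from end of header to vox_offset
  to_skip <- as.integer(round(vox_offset)) - 348L
  if (to_skip > 0L) readBin(con, "raw", n = to_skip)
  n_vox <- prod(d)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n_vox) {
    abort_suvpair("truncated NIfTI data section", "suvpair_io_error")
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  m <- regmatches(descrip, regexec("suvpair unit=(\\S+) modality=(\\S+)", descrip))[[1]]
  if (length(m) == 3L) {
    unit <- m[2L]
    modality <- m[3L]
  }
  quant_volume(array(vals, dim = d), spacing = pixdim[2:4], unit = unit,
               modality = modality)
}
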