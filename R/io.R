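#' Write / read a respiratory trace as CSV
#'
#' Two-column CSV with header `time_s,amplitude`, the on-disk exchange format
#' for RPM-style amplitude traces.
#'
#' @param trace a `resp_trace` (see [generate_respiratory_trace()]).
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s, amplitude = trace$amplitude),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "amplitude") %in% names(d)))
  new_resp_trace(d$time_s, d$amplitude)
}

#' Write / read an R-peak trigger list as CSV
#'
#' One-column CSV with header `r_peak_s`.
#'
#' @param triggers a `trigger_list`.
#' @param path file path.
#' @export
write_triggers_csv <- function(triggers, path) {
  stopifnot(inherits(triggers, "trigger_list"))
  utils::write.csv(data.frame(r_peak_s = as.numeric(triggers)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_triggers_csv
#' @export
read_triggers_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot("r_peak_s" %in% names(d))
  new_trigger_list(d$r_peak_s)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O. No NIfTI package ships with this stack, and the subset
# needed here is small: single-file .nii, float32 or uint8, RAS with the
# spacing on the pixdim/sform diagonal. Not a general-purpose reader.
# ---------------------------------------------------------------------------

#' Write a volume as single-file NIfTI-1
#'
#' @param vol `dg_volume` (3D array with spacing attribute).
#' @param path output path ending in `.nii`.
#' @param datatype `"float32"` for images, `"uint8"` for masks.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  sp <- spacing_of(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                          # sizeof_hdr
  writeBin(raw(36), con)               # data_type..dim_info (unused)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)     # dim[8]
  wf(c(0, 0, 0))                       # intent_p1..p3
  wi(0L, 2)                            # intent_code
  dt <- if (datatype == "float32") c(16L, 32L) else c(2L, 8L)
  wi(dt, 2)                            # datatype, bitpix
  wi(0L, 2)                            # slice_start
  wf(c(1, sp, 1, 1, 1, 1))             # pixdim[8] (qfac 1)
  wf(352)                              # vox_offset
  wf(c(1, 0))                          # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end/code/xyzt
  wf(c(0, 0))                          # cal_max, cal_min
  wf(c(0, 0))                          # slice_duration, toffset
  wi(c(0L, 0L), 4)                     # glmax, glmin
  writeBin(raw(80 + 24), con)          # descrip, aux_file
  wi(c(0L, 1L), 2)                     # qform_code 0, sform_code 1
  wf(rep(0, 6))                        # quatern b,c,d, qoffset x,y,z
  wf(c(sp[1], 0, 0, 0))                # srow_x (RAS, spacing on diagonal)
  wf(c(0, sp[2], 0, 0))                # srow_y
  wf(c(0, 0, sp[3], 0))                # srow_z
  writeBin(raw(16), con)               # intent_name, magic written next
  seek(con, 344)
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  seek(con, 348)
  writeBin(raw(4), con)                # extension flag
  if (datatype == "float32") {
    writeBin(as.numeric(vol), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(vol)), con, size = 1, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1) readBin(hdr[(off + 1):(off + size * n)],
                                           "integer", n = n, size = size,
                                           endian = "little")
  rf <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                     n = n, size = 4, endian = "little")
  stopifnot(ri(0, 4) == 348L)
  dims <- ri(40, 2, 8)
  stopifnot(dims[1] == 3L)
  d <- dims[2:4]
  dtype <- ri(70, 2)
  sp <- rf(76, 8)[2:4]
  voff <- rf(108)
  seek(con, voff)
  n <- prod(d)
  vals <- if (dtype == 16L) {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else if (dtype == 2L) {
    readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little")
  } else stop("unsupported NIfTI datatype: ", dtype)
  as_volume(array(vals, d), sp)
}

#' Write a list as pretty JSON (reports, logs)
#' @param x list.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
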