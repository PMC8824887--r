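#' RF frame-sequence container
#'
#' An `RFSequence` holds a block of raw radio-frequency echo amplitudes
#' indexed `(frame, line, sample)` together with the acquisition metadata
#' needed to interpret it. Amplitudes are signed 16-bit integers, the
#' native sample format of research ultrasound machines. Depth increases
#' with the sample index; all coordinates in this package are 0-based and
#' half-open.
#'
#' @param data 3-D integer array, dimensions `(n_frames, n_lines, n_samples)`,
#'   values within the signed 16-bit range.
#' @param center_frequency_hz Transmit center frequency in Hz. Must be
#'   below the Nyquist frequency `sampling_rate_hz / 2`.
#' @param sampling_rate_hz Axial (depth) sampling rate in Hz.
#' @param frame_rate_hz Frame acquisition rate in Hz.
#' @param depth_cm Imaging depth in cm.
#'
#' @return An object of class `RFSequence`: a list with elements `data`,
#'   `n_frames`, `n_lines`, `n_samples`, `center_frequency_hz`,
#'   `sampling_rate_hz`, `frame_rate_hz`, `depth_cm`.
#' @examples
#' a <- array(0L, dim = c(4, 8, 16))
#' seq <- rf_sequence(a, center_frequency_hz = 6e6, sampling_rate_hz = 40e6,
#'                    frame_rate_hz = 12.8, depth_cm = 10)
#' seq$n_frames
#' @export
rf_sequence <- function(data, center_frequency_hz, sampling_rate_hz,
                        frame_rate_hz, depth_cm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation("`data` must be a 3-D array indexed (frame, line, sample)")
  if (any(!is.finite(data)))
    stop_validation("`data` contains non-finite amplitudes")
  if (any(data < -32768 | data > 32767))
    stop_validation("amplitudes exceed the signed 16-bit range [-32768, 32767]")
  if (any(data != round(data)))
    stop_validation("amplitudes must be integers")
  storage.mode(data) <- "integer"
  d <- dim(data)
  for (v in c("center_frequency_hz", "sampling_rate_hz", "frame_rate_hz",
              "depth_cm")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop_validation("`%s` must be a single positive number", v)
  }
  if (center_frequency_hz >= sampling_rate_hz / 2)
    stop_validation(
      "center frequency (%g Hz) must be below the Nyquist frequency (%g Hz)",
      center_frequency_hz, sampling_rate_hz / 2)
  structure(list(
    data = data,
    n_frames = d[[1]], n_lines = d[[2]], n_samples = d[[3]],
    center_frequency_hz = as.numeric(center_frequency_hz),
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    frame_rate_hz = as.numeric(frame_rate_hz),
    depth_cm = as.numeric(depth_cm)
  ), class = "RFSequence")
}

#' @export
print.RFSequence <- function(x, ...) {
  cat(sprintf(
    "RFSequence: %d frames x %d lines x %d samples\n  fc = %.3g MHz, fs = %.3g MHz, frame rate = %.3g Hz, depth = %g cm\n",
    x$n_frames, x$n_lines, x$n_samples,
    x$center_frequency_hz / 1e6, x$sampling_rate_hz / 1e6,
    x$frame_rate_hz, x$depth_cm))
  invisible(x)
}

#' Region-of-interest specification
#'
#' Defines a rectangular ROI on the scan-line / depth-sample grid using
#' 0-based, half-open intervals, optionally tagged with a class label
#' (e.g. `"tumor"`, `"normal"`, or a differentiation grade). The default
#' grid mapping used throughout the package is 1 pixel per mm, so a
#' 70 x 20 mm ROI becomes 70 lines x 20 samples.
#'
#' @param line_start,line_stop Half-open scan-line interval `[start, stop)`.
#' @param sample_start,sample_stop Half-open depth-sample interval.
#' @param label Optional class tag, kept verbatim.
#' @return An object of class `ROISpec`.
#' @examples
#' roi_spec(0, 70, 0, 20, label = "tumor")
#' @export
roi_spec <- function(line_start, line_stop, sample_start, sample_stop,
                     label = NULL) {
  for (v in c("line_start", "line_stop", "sample_start", "sample_stop")) {
    val <- get(v)
    if (!is_count(val) || val < 0)
      stop_validation("`%s` must be a non-negative integer", v)
  }
  if (line_start >= line_stop)
    stop_validation("empty or inverted line interval [%d, %d)",
                    line_start, line_stop)
  if (sample_start >= sample_stop)
    stop_validation("empty or inverted sample interval [%d, %d)",
                    sample_start, sample_stop)
  structure(list(
    line_start = as.integer(line_start), line_stop = as.integer(line_stop),
    sample_start = as.integer(sample_start),
    sample_stop = as.integer(sample_stop),
    label = if (is.null(label)) NULL else as.character(label)
  ), class = "ROISpec")
}

#' @export
print.ROISpec <- function(x, ...) {
  cat(sprintf("ROISpec: lines [%d, %d) x samples [%d, %d)%s\n",
              x$line_start, x$line_stop, x$sample_start, x$sample_stop,
              if (is.null(x$label)) "" else paste0("  label: ", x$label)))
  invisible(x)
}

# Checks that `roi` fits inside `seq`; errors otherwise.
validate_roi_in_sequence <- function(roi, seq) {
  if (roi$line_stop > seq$n_lines || roi$sample_stop > seq$n_samples)
    stop_validation(
      "ROI (lines [%d,%d) x samples [%d,%d)) exceeds sequence bounds (%d lines x %d samples)",
      roi$line_start, roi$line_stop, roi$sample_start, roi$sample_stop,
      seq$n_lines, seq$n_samples)
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## On-disk dialects
##
## ultrasonix_raw (".rf"): a self-contained approximation of the raw export
## of the Sonix-family research interface (the vendor layout is not publicly
## documented). Fixed 40-byte header of ten little-endian int32 fields:
##   1 magic 0x52463031 ("RF01")   2 version (1)
##   3 n_frames  4 n_lines  5 n_samples
##   6 center_frequency_hz  7 sampling_rate_hz        (integer Hz)
##   8 frame_rate_mhz (millihertz) 9 depth_um (micrometres)  10 reserved (0)
## followed by frame-major little-endian int16 samples: within a frame the
## depth sample varies fastest, then the scan line, then the frame.
##
## portable (".rfraw" + ".json"): the same frame-major int16 payload with a
## JSON sidecar carrying every RFSequence metadata field at full precision.
## ---------------------------------------------------------------------------

RF_MAGIC <- 0x52463031L

# Metadata fields the portable JSON sidecar must carry.
PORTABLE_FIELDS <- c("n_frames", "n_lines", "n_samples",
                     "center_frequency_hz", "sampling_rate_hz",
                     "frame_rate_hz", "depth_cm")

#' Write an RF frame sequence
#'
#' Serializes an [rf_sequence()] to disk in one of two documented dialects.
#' Both store the amplitude block as frame-major little-endian int16, so
#' `read_rf(write_rf(seq))` is bit-exact. The `ultrasonix_raw` dialect
#' encodes metadata as scaled integers (Hz, millihertz, micrometres): the
#' frame rate must be representable in whole millihertz and the depth in
#' whole micrometres, and the two frequencies in whole Hz. The `portable`
#' dialect has no such restriction; its sidecar (same path with extension
#' `.json`) stores metadata at full double precision.
#'
#' @param seq An `RFSequence`.
#' @param path Output file path (`.rf` or `.rfraw`).
#' @param dialect `"ultrasonix_raw"` or `"portable"`.
#' @return `path`, invisibly.
#' @seealso [read_rf()]
#' @export
write_rf <- function(seq, path, dialect = c("portable", "ultrasonix_raw")) {
  dialect <- match.arg(dialect)
  if (!inherits(seq, "RFSequence"))
    stop_validation("`seq` must be an RFSequence")
  # (sample, line, frame) in memory gives frame-major order on disk
  payload <- as.integer(aperm(seq$data, c(3L, 2L, 1L)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (dialect == "ultrasonix_raw") {
    frame_rate_mhz <- round(seq$frame_rate_hz * 1e3)
    depth_um <- round(seq$depth_cm * 1e4)
    if (abs(frame_rate_mhz - seq$frame_rate_hz * 1e3) > 1e-6)
      stop_validation("frame rate %g Hz is not representable in whole millihertz",
                      seq$frame_rate_hz)
    if (abs(depth_um - seq$depth_cm * 1e4) > 1e-6)
      stop_validation("depth %g cm is not representable in whole micrometres",
                      seq$depth_cm)
    if (seq$center_frequency_hz != round(seq$center_frequency_hz) ||
        seq$sampling_rate_hz != round(seq$sampling_rate_hz))
      stop_validation("frequencies must be whole Hz for the ultrasonix_raw dialect")
    header <- as.integer(c(RF_MAGIC, 1L, seq$n_frames, seq$n_lines,
                           seq$n_samples, seq$center_frequency_hz,
                           seq$sampling_rate_hz, frame_rate_mhz, depth_um, 0L))
    writeBin(header, con, size = 4L, endian = "little")
  } else {
    meta <- seq[PORTABLE_FIELDS]
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  writeBin(payload, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an RF frame sequence
#'
#' Reads a file written by [write_rf()]. The payload length is checked
#' against the header dimensions: a mismatch is always an error, never a
#' silent truncation or padding.
#'
#' @param path File path.
#' @param dialect `"ultrasonix_raw"` or `"portable"`. For `portable` the
#'   sidecar `<path>.json` (extension replaced) must exist and carry all
#'   metadata fields.
#' @return An [rf_sequence()].
#' @export
read_rf <- function(path, dialect = c("portable", "ultrasonix_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_usage("file not found: %s", path)
  total <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (dialect == "ultrasonix_raw") {
    if (total < 40)
      stop_format("file too short for the 40-byte ultrasonix_raw header")
    header <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
    if (header[[1]] != RF_MAGIC)
      stop_format("bad magic number: not an ultrasonix_raw RF file")
    if (header[[2]] != 1L)
      stop_format("unsupported ultrasonix_raw version %d", header[[2]])
    meta <- list(n_frames = header[[3]], n_lines = header[[4]],
                 n_samples = header[[5]],
                 center_frequency_hz = as.numeric(header[[6]]),
                 sampling_rate_hz = as.numeric(header[[7]]),
                 frame_rate_hz = header[[8]] / 1e3,
                 depth_cm = header[[9]] / 1e4)
    payload_bytes <- total - 40
  } else {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop_format("missing portable sidecar: %s", sc)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    missing <- setdiff(PORTABLE_FIELDS, names(meta))
    if (length(missing))
      stop_format("sidecar %s is missing metadata field(s): %s",
                  sc, paste(missing, collapse = ", "))
    payload_bytes <- total
  }
  n <- meta$n_frames * meta$n_lines * meta$n_samples
  if (payload_bytes != 2 * n)
    stop_format("payload length mismatch: header says %d samples (%d bytes), file has %d bytes",
                n, 2 * n, payload_bytes)
  raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  data <- aperm(array(raw, dim = c(meta$n_samples, meta$n_lines,
                                   meta$n_frames)), c(3L, 2L, 1L))
  rf_sequence(data, meta$center_frequency_hz, meta$sampling_rate_hz,
              meta$frame_rate_hz, meta$depth_cm)
}

sidecar_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".json")

#' Read / write an ROI specification
#'
#' The `.roi` format is plain `key: value` text with keys `line_start`,
#' `line_stop`, `sample_start`, `sample_stop` and optional `label`;
#' intervals are 0-based and half-open.
#'
#' @param path File path.
#' @return `read_roi` returns an [roi_spec()]; `write_roi` returns `path`
#'   invisibly.
#' @export
read_roi <- function(path) {
  if (!file.exists(path))
    stop_usage("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop_format("unparseable .roi line: %s", lines[bad][[1]])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  need <- c("line_start", "line_stop", "sample_start", "sample_stop")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop_format("%s is missing required key(s): %s", path,
                paste(missing, collapse = ", "))
  get_num <- function(k) {
    v <- suppressWarnings(as.numeric(vals[match(k, keys)]))
    if (is.na(v)) stop_format("non-numeric value for key `%s`", k)
    v
  }
  label <- if ("label" %in% keys) vals[match("label", keys)] else NULL
  roi_spec(get_num("line_start"), get_num("line_stop"),
           get_num("sample_start"), get_num("sample_stop"), label = label)
}

#' @rdname read_roi
#' @param roi An [roi_spec()].
#' @export
write_roi <- function(roi, path) {
  if (!inherits(roi, "ROISpec"))
    stop_validation("`roi` must be an ROISpec")
  lines <- c(sprintf("line_start: %d", roi$line_start),
             sprintf("line_stop: %d", roi$line_stop),
             sprintf("sample_start: %d", roi$sample_start),
             sprintf("sample_stop: %d", roi$sample_stop))
  if (!is.null(roi$label)) lines <- c(lines, sprintf("label: %s", roi$label))
  writeLines(lines, path)
  invisible(path)
}

stop_format <- function(...) {
  stop(structure(class = c("rfseries_format_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

stop_validation <- function(...) {
  stop(structure(class = c("rfseries_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}
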