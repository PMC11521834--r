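#' Read a multichannel recording from disk
#'
#' Two formats are supported: the package's own single-file matrix container
#' (a one-line JSON header followed by little-endian float32 voltages; see
#' [write_recording()]) and EDF (European Data Format, read-only).
#'
#' @param path Path to the file.
#' @param format `"auto"` (sniff from content), `"seegmat"` or `"edf"`.
#' @param channels Optional `seeg_channels` sidecar; if given, the channel
#'   count must match the file.
#' @param fs Optional expected sampling rate; a mismatch is an error.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "seegmat", "edf"),
                           channels = NULL, fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    head8 <- readBin(path, "raw", n = 8)
    format <- if (rawToChar(head8[1]) == "{") "seegmat"
              else if (grepl("^0", rawToChar(head8))) "edf"
              else stop("cannot determine format of ", path,
                        " (expected seegmat or EDF)", call. = FALSE)
  }
  rec <- switch(format,
                seegmat = .read_seegmat(path),
                edf = .read_edf(path))
  if (!is.null(fs) && !isTRUE(all.equal(rec$fs, fs))) {
    stop(sprintf("sampling rate mismatch: file has %g Hz, expected %g Hz",
                 rec$fs, fs), call. = FALSE)
  }
  if (!is.null(channels)) {
    if (nrow(channels) != nrow(rec$data)) {
      stop(sprintf("channel count mismatch: file has %d channels, sidecar table has %d",
                   nrow(rec$data), nrow(channels)), call. = FALSE)
    }
  }
  rec
}

#' Write a recording to the package's matrix container
#'
#' The container is a single file: one line of JSON (fs, channel order,
#' montage tag, matrix shape) terminated by a newline, followed by the
#' voltage matrix as little-endian float32, sample-major (all channels at
#' sample 1, then sample 2, ...). Reading back a file written by this
#' function reproduces the float32-quantised matrix bit-exactly.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "seeg_recording"))
  hdr <- jsonlite::toJSON(
    list(format = "seegmat", version = 1L, fs = rec$fs,
         n_channels = nrow(rec$data), n_samples = ncol(rec$data),
         channel_ids = rec$channel_ids, montage_tag = rec$montage_tag),
    auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(path)
}

.read_seegmat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("truncated seegmat header in ", path, call. = FALSE)
    if (b == charToRaw("\n")) break
    hdr_raw <- c(hdr_raw, b)
  }
  hdr <- jsonlite::fromJSON(rawToChar(hdr_raw))
  if (!identical(hdr$format, "seegmat")) {
    stop("not a seegmat file: ", path, call. = FALSE)
  }
  n <- hdr$n_channels * hdr$n_samples
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) stop("truncated seegmat data in ", path, call. = FALSE)
  recording(matrix(vals, nrow = hdr$n_channels), fs = hdr$fs,
            channel_ids = hdr$channel_ids, montage_tag = hdr$montage_tag)
}

# Minimal EDF reader: fixed-layout ASCII header (256 bytes + 256 per signal)
# followed by int16 little-endian data records; annotation signals are
# skipped and all remaining signals must share one sampling rate.
.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fld <- function(nc) trimws(rawToChar(readBin(con, "raw", n = nc)))
  version <- fld(8)
  if (!identical(version, "0")) stop("not an EDF file: ", path, call. = FALSE)
  fld(80); fld(80); fld(8); fld(8)          # patient, recording ids, date, time
  fld(8)                                     # header byte count
  fld(44)                                    # reserved
  n_records <- as.integer(fld(8))
  record_dur <- as.numeric(fld(8))
  ns <- as.integer(fld(4))
  labels <- vapply(seq_len(ns), function(i) fld(16), "")
  for (i in seq_len(ns)) fld(80)             # transducer
  for (i in seq_len(ns)) fld(8)              # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(fld(8)), 0)
  for (i in seq_len(ns)) fld(80)             # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(fld(8)), 0L)  # samples/record
  for (i in seq_len(ns)) fld(32)             # reserved

  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (!any(keep)) stop("EDF file contains no signal channels", call. = FALSE)
  if (length(unique(spr[keep])) != 1) {
    stop("EDF signals have mixed sampling rates; not supported", call. = FALSE)
  }
  fs <- spr[keep][1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min

  out <- matrix(0, nrow = sum(keep), ncol = n_records * spr[keep][1])
  row_of <- cumsum(keep)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) != spr[i]) stop("truncated EDF data record", call. = FALSE)
      if (keep[i]) {
        cols <- ((r - 1) * spr[i] + 1):(r * spr[i])
        out[row_of[i], cols] <- v * gain[i] + offset[i]
      }
    }
  }
  recording(out, fs = fs, channel_ids = labels[keep], montage_tag = "original")
}

#' Read a multi-patient batch manifest
#'
#' The manifest is a TSV with columns `patient_id`, `recording`, `channels`,
#' `events`; paths are resolved relative to the manifest's directory. Each
#' entry is loaded into a list with elements `recording`, `channels`,
#' `events`.
#'
#' @param path Path to the manifest TSV.
#' @return A named list, one element per patient.
#' @export
read_batch_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  man <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("patient_id", "recording", "channels", "events")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  base <- dirname(path)
  res <- lapply(seq_len(nrow(man)), function(i) {
    ch <- read_channel_table(file.path(base, man$channels[i]))
    list(patient_id = as.character(man$patient_id[i]),
         recording = read_recording(file.path(base, man$recording[i]),
                                    channels = ch),
         channels = ch,
         events = read_event_table(file.path(base, man$events[i])))
  })
  names(res) <- as.character(man$patient_id)
  res
}
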