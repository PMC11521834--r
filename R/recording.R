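#' Construct a continuous multichannel recording
#'
#' A recording is a channels-by-samples voltage matrix (microvolts) with its
#' sampling rate, an ordered channel-id vector and a tag recording which
#' referencing scheme produced it. Time is expressed in seconds relative to
#' recording start; sample indices are 0-based, so sample `n` covers time
#' `n / fs`.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (default 1200).
#' @param channel_ids Character vector, one id per row of `data`.
#' @param montage_tag One of `"original"`, `"car"`, `"bipolar"`,
#'   `"laplacian"`.
#' @return An object of class `seeg_recording`.
#' @export
recording <- function(data, fs = 1200, channel_ids = rownames(data),
                      montage_tag = "original") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data)) {
    stop("channel_ids length (", length(channel_ids),
         ") must equal number of data rows (", nrow(data), ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  montage_tag <- match.arg(montage_tag,
                           c("original", "car", "bipolar", "laplacian"))
  rownames(data) <- channel_ids
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 montage_tag = montage_tag),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<seeg_recording> %d channels x %d samples @ %g Hz (%.1f s), montage: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$montage_tag))
  invisible(x)
}

#' Construct a trial event table
#'
#' One row per stimulus presentation: `trial_id`, `onset_s` (seconds in the
#' recording clock), `condition` (`"overt"` or `"covert"` response) and an
#' optional `keep` flag (defaults to `TRUE`; no filter is applied by the
#' pipeline itself, the flag lets callers mark e.g. "I do not know" trials).
#'
#' @param x Data frame with columns `trial_id`, `onset_s`, `condition`, and
#'   optionally `keep`.
#' @return A tibble of class `seeg_events`.
#' @export
event_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("trial_id", "onset_s", "condition")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$trial_id <- as.integer(x$trial_id)
  x$onset_s <- as.numeric(x$onset_s)
  x$condition <- as.character(x$condition)
  if (!"keep" %in% names(x)) x$keep <- TRUE
  x$keep <- .as_flag(x$keep, "keep")
  if (!all(x$condition %in% c("overt", "covert"))) {
    stop("condition must be 'overt' or 'covert'", call. = FALSE)
  }
  if (anyDuplicated(x$trial_id)) stop("duplicate trial_id", call. = FALSE)
  if (nrow(x) > 1 && any(diff(x$onset_s) <= 0)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  class(x) <- c("seeg_events", class(x))
  x
}

#' Read / write a trial event table (TSV: `trial_id onset_s condition`)
#'
#' @param path Path to a TSV file.
#' @return [read_event_table()] returns a `seeg_events` tibble.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  event_table(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_event_table
#' @param events A `seeg_events` table.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "seeg_events"))
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
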