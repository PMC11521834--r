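#' Select channels for analysis
#'
#' Applies the clinical exclusion rules: drops channels flagged as
#' seizure-onset zone or continuous artifact and channels in the
#' cerebrospinal-fluid space. Extracranial (`outside`) contacts are
#' retained — they are analyzed (they carry the EMG contamination the
#' montage comparison is about). Irritative-zone channels are also retained
#' here; they are excluded only from the CAR averaging set (see
#' [build_car()]), the two sets being deliberately distinct.
#'
#' @param channels A [channel_table()].
#' @return The filtered `seeg_channels` table.
#' @export
select_channels <- function(channels) {
  stopifnot(inherits(channels, "seeg_channels"))
  keep <- !channels$is_soz & !channels$is_artifact &
    channels$category != "csf"
  if (!any(keep)) {
    stop("channel selection removed every channel", call. = FALSE)
  }
  channels[keep, ]
}

#' Segment a continuous recording into trial epochs
#'
#' Extracts one epoch per event over the half-open window
#' `[onset + window_s[1], onset + window_s[2])`, sample-exactly: epoch
#' sample at relative time t equals the recording at `onset + t`. The
#' default extraction window is padded 200 ms before and 100 ms after the
#' analyzed window so that no analyzed time-frequency sample is
#' edge-contaminated. Events whose window does not fit inside the recording
#' are dropped with a warning (never silently) and remaining trials keep
#' their original `trial_id`.
#'
#' @param rec A [recording()].
#' @param events A [event_table()].
#' @param window_s Two-vector, half-open epoch window in seconds relative
#'   to stimulus onset.
#' @return An object of class `seeg_epochs`: a channel x trial x sample
#'   array plus `t0_s`, `fs`, `trial_id`, `condition` and montage metadata.
#' @export
epoch_recording <- function(rec, events, window_s = c(-0.7, 5.1)) {
  stopifnot(inherits(rec, "seeg_recording"), inherits(events, "seeg_events"))
  fs <- rec$fs
  n_rec <- ncol(rec$data)
  n_win <- as.integer(round((window_s[2] - window_s[1]) * fs))
  off0 <- as.integer(round(window_s[1] * fs))

  starts <- as.integer(round(events$onset_s * fs)) + off0
  ok <- starts >= 0L & (starts + n_win) <= n_rec
  if (any(!ok)) {
    warning(sprintf("dropped %d trial(s) whose epoch window falls outside the recording: %s",
                    sum(!ok),
                    paste(events$trial_id[!ok], collapse = ", ")),
            call. = FALSE)
  }
  kept <- which(ok)
  data <- array(0, dim = c(nrow(rec$data), length(kept), n_win),
                dimnames = list(rec$channel_ids, NULL, NULL))
  for (j in seq_along(kept)) {
    idx <- starts[kept[j]] + seq_len(n_win)   # 1-based slice of 0-based start
    data[, j, ] <- rec$data[, idx]
  }
  structure(list(data = data, fs = fs, t0_s = window_s[1],
                 window_s = window_s,
                 trial_id = events$trial_id[kept],
                 condition = events$condition[kept],
                 channel_ids = rec$channel_ids,
                 montage_tag = rec$montage_tag),
            class = "seeg_epochs")
}

#' Subset an epoch set by trial
#'
#' @param epochs A `seeg_epochs`.
#' @param trial_ids Trial ids to keep.
#' @return A `seeg_epochs` containing only the requested trials.
#' @export
subset_epochs <- function(epochs, trial_ids) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  j <- which(epochs$trial_id %in% trial_ids)
  epochs$data <- epochs$data[, j, , drop = FALSE]
  epochs$trial_id <- epochs$trial_id[j]
  epochs$condition <- epochs$condition[j]
  epochs
}

#' @export
print.seeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<seeg_epochs> %d channels x %d trials x %d samples @ %g Hz, window [%g, %g) s, montage: %s\n",
              d[1], d[2], d[3], x$fs, x$window_s[1], x$window_s[2],
              x$montage_tag))
  invisible(x)
}
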