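#' Phase-wise maximum percent change per trial
#'
#' The dependent variable of the montage/vocalization analysis: for every
#' derived channel and trial, the maximum of the broadband high-gamma
#' percent-change series within the stimulus phase and within the response
#' phase. A 10-ms step whose centre falls exactly at the stimulus offset
#' (1.8 s) belongs to the stimulus phase (closed right edge); the response
#' phase is the half-open interval up to 5 s.
#'
#' @param pc_series A `seeg_pc` (see [percent_change()]).
#' @param channel_category Named character vector mapping derived channel
#'   ids to anatomical categories (e.g. a montage transform's
#'   `derived_category` named by `derived_ids`); defaults to `NA`.
#' @param patient_id Patient label attached to every row.
#' @param stimulus_phase_s,response_phase_s Phase windows in seconds;
#'   stimulus is closed `[t0, t1]`, response is `(t1, t2]` with `t1` the
#'   stimulus window end.
#' @return A tibble with one row per (channel, trial, phase): columns
#'   `patient_id`, `channel_id`, `category`, `trial_id`, `condition`,
#'   `montage`, `phase`, `max_pc`.
#' @export
phase_max <- function(pc_series, channel_category = NULL,
                      patient_id = "p01",
                      stimulus_phase_s = c(0, 1.8),
                      response_phase_s = c(1.81, 5.0)) {
  stopifnot(inherits(pc_series, "seeg_pc"))
  t <- pc_series$times_s
  eps <- 1e-9
  stim_cols <- which(t >= stimulus_phase_s[1] - eps &
                     t <= stimulus_phase_s[2] + eps)
  resp_cols <- which(t > stimulus_phase_s[2] + eps &
                     t <= response_phase_s[2] + eps)
  if (length(stim_cols) == 0 || length(resp_cols) == 0) {
    stop("phase window falls outside the percent-change time axis",
         call. = FALSE)
  }
  d <- dim(pc_series$pc)
  cat_of <- function(id) {
    if (is.null(channel_category)) NA_character_
    else unname(channel_category[id])
  }
  rows <- lapply(seq_len(d[1]), function(ch) {
    id <- pc_series$channel_ids[ch]
    tibble::tibble(
      patient_id = patient_id,
      channel_id = id,
      category = cat_of(id),
      trial_id = rep(pc_series$trial_id, 2),
      condition = rep(pc_series$condition, 2),
      montage = pc_series$montage_tag,
      phase = rep(c("stimulus", "response"), each = d[2]),
      max_pc = c(apply(pc_series$pc[ch, , stim_cols, drop = FALSE], 2, max),
                 apply(pc_series$pc[ch, , resp_cols, drop = FALSE], 2, max)))
  })
  dplyr::bind_rows(rows)
}

#' Median amplitude-change reduction between two montages
#'
#' Summarises how much smaller the median phase-maximum percent change of a
#' stratum (anatomical category x phase x condition) is under a comparison
#' montage than under the reference montage:
#' `100 * (median_ref - median_cmp) / median_ref`, reference = CAR by
#' convention. Positive values mean the comparison montage reduced the
#' deflection.
#'
#' @param features Feature table from [phase_max()] (rows from several
#'   montages bound together).
#' @param category,phase,condition Stratum selectors.
#' @param montage_a Reference montage (default `"car"`).
#' @param montage_b Comparison montage.
#' @return The reduction in percent, or `NA` (with a message) when the
#'   reference median is not positive.
#' @export
median_reduction <- function(features, category, phase, condition,
                             montage_a = "car", montage_b) {
  sel <- features$category == category & features$phase == phase &
    features$condition == condition
  a <- features$max_pc[sel & features$montage == montage_a]
  b <- features$max_pc[sel & features$montage == montage_b]
  if (length(a) == 0 || length(b) == 0) {
    stop("both montages must be present for the stratum", call. = FALSE)
  }
  med_a <- stats::median(a)
  if (med_a <= 0) {
    message("reference-montage median is not positive; reduction undefined")
    return(NA_real_)
  }
  100 * (med_a - stats::median(b)) / med_a
}

#' Write a feature table as long-format TSV
#'
#' @param features Tibble from [phase_max()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
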