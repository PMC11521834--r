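#' Subset a recording to a set of channels
#'
#' @param rec A [recording()].
#' @param channel_ids Ids to keep, in the requested order.
#' @return A [recording()].
#' @export
subset_recording <- function(rec, channel_ids) {
  stopifnot(inherits(rec, "seeg_recording"))
  miss <- setdiff(channel_ids, rec$channel_ids)
  if (length(miss) > 0) {
    stop("recording lacks channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  recording(rec$data[channel_ids, , drop = FALSE], fs = rec$fs,
            channel_ids = channel_ids, montage_tag = rec$montage_tag)
}

#' Run the full high-gamma mapping pipeline for one recording
#'
#' Channel selection, montage construction and application, epoching,
#' Morlet high-gamma percent change and phase-maximum feature extraction,
#' for each requested montage. This is the single entry point the analysis
#' scripts, tests and acceptance checks share.
#'
#' @param rec A referential [recording()].
#' @param channels Its [channel_table()].
#' @param events Its [event_table()].
#' @param cfg A [run_config()].
#' @param montages Subset of `c("car", "bipolar", "laplacian")`.
#' @param patient_id Label attached to the feature rows.
#' @param keep_pc If `TRUE`, the per-montage percent-change series are
#'   returned alongside the features (they are large; off by default).
#' @return A list: `features` (tibble, all montages bound), `transforms`
#'   (named list of `seeg_montage`), `channels_used`, and `pc` (named list
#'   of `seeg_pc`, if requested).
#' @export
hg_pipeline <- function(rec, channels, events, cfg = run_config(),
                        montages = c("car", "bipolar", "laplacian"),
                        patient_id = "p01", keep_pc = FALSE) {
  montages <- match.arg(montages, several.ok = TRUE)
  sel <- select_channels(channels)
  rec_sel <- subset_recording(rec, sel$contact_id)
  feats <- list()
  pcs <- list()
  transforms <- list()
  for (m in montages) {
    mt <- switch(m,
                 car = build_car(sel),
                 bipolar = build_bipolar(sel),
                 laplacian = build_laplacian(sel))
    derived <- apply_montage(rec_sel, mt)
    epochs <- epoch_recording(derived, events, cfg$epoch_window_s)
    pc <- highgamma_pc(epochs, cfg)
    feats[[m]] <- phase_max(
      pc,
      channel_category = stats::setNames(mt$derived_category, mt$derived_ids),
      patient_id = patient_id,
      stimulus_phase_s = cfg$stimulus_phase_s,
      response_phase_s = cfg$response_phase_s)
    transforms[[m]] <- mt
    if (keep_pc) pcs[[m]] <- pc
  }
  out <- list(features = dplyr::bind_rows(feats), transforms = transforms,
              channels_used = sel)
  if (keep_pc) out$pc <- pcs
  out
}

#' Pipeline features for a simulated cohort
#'
#' Applies [hg_pipeline()] to every run of every patient of a
#' [simulate_cohort()] result and binds the feature tables.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param cfg A [run_config()].
#' @param montages Passed to [hg_pipeline()].
#' @return A feature tibble covering all patients, conditions and montages.
#' @export
cohort_features <- function(cohort, cfg = run_config(),
                            montages = c("car", "bipolar", "laplacian")) {
  feats <- lapply(cohort, function(pat) {
    runs <- pat[setdiff(names(pat), c("patient_id", "sim"))]
    dplyr::bind_rows(lapply(runs, function(r) {
      hg_pipeline(r$recording, r$channels, r$events, cfg,
                  montages = montages,
                  patient_id = pat$patient_id)$features
    }))
  })
  dplyr::bind_rows(feats)
}
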