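#' Analysis run configuration
#'
#' Bundles every tunable of the high-gamma mapping pipeline with the study
#' defaults: the 60-140 Hz band scanned in 2-Hz bins with 7-cycle Morlet
#' wavelets sliding in 10-ms steps; a -500 to -200 ms pre-stimulus baseline;
#' the 0-1.8 s stimulus phase (auditory question) and the 1.81-5 s response
#' phase (answer production); 100 trials presented every 10 s.
#'
#' The epoch extraction window is padded beyond the analyzed window
#' (`epoch_window_s` vs `analysis_window_s`) so that no analyzed sample sits
#' within half a wavelet of a data edge; see the methods vignette.
#'
#' @param band_lo,band_hi High-gamma band edges in Hz.
#' @param freq_step Frequency-bin width in Hz.
#' @param n_cycles Morlet wavelet width in cycles.
#' @param tf_step_ms Time-frequency sliding-step in milliseconds.
#' @param baseline_window_s Two-vector, baseline window in seconds relative
#'   to stimulus onset (must precede 0).
#' @param stimulus_phase_s,response_phase_s Phase windows in seconds. A
#'   10-ms step centred exactly at 1.8 s counts as stimulus phase.
#' @param analysis_window_s Window over which percent change is reported.
#' @param epoch_window_s Internal (edge-padded) extraction window.
#' @param n_trials,isi_s,stim_dur_s,first_onset_s Task structure: number of
#'   trials, inter-stimulus interval, stimulus duration, onset of trial 1.
#' @param rng_seed Integer seed for every stochastic step.
#' @param df_method Degrees-of-freedom method for mixed-model t tests:
#'   `"residual"` (default) or `"satterthwaite"`.
#' @return A list of class `seeg_config`.
#' @export
run_config <- function(band_lo = 60, band_hi = 140, freq_step = 2,
                       n_cycles = 7, tf_step_ms = 10,
                       baseline_window_s = c(-0.5, -0.2),
                       stimulus_phase_s = c(0, 1.8),
                       response_phase_s = c(1.81, 5.0),
                       analysis_window_s = c(-0.5, 5.0),
                       epoch_window_s = c(-0.7, 5.1),
                       n_trials = 100, isi_s = 10, stim_dur_s = 1.8,
                       first_onset_s = 0, rng_seed = 1L,
                       df_method = c("residual", "satterthwaite")) {
  cfg <- list(band_lo = band_lo, band_hi = band_hi, freq_step = freq_step,
              n_cycles = n_cycles, tf_step_ms = tf_step_ms,
              baseline_window_s = baseline_window_s,
              stimulus_phase_s = stimulus_phase_s,
              response_phase_s = response_phase_s,
              analysis_window_s = analysis_window_s,
              epoch_window_s = epoch_window_s,
              n_trials = as.integer(n_trials), isi_s = isi_s,
              stim_dur_s = stim_dur_s, first_onset_s = first_onset_s,
              rng_seed = as.integer(rng_seed),
              df_method = match.arg(df_method))
  validate_run_config(cfg)
  structure(cfg, class = "seeg_config")
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (!(band_lo < band_hi)) stop("band_lo must be < band_hi", call. = FALSE)
    if (freq_step <= 0 || n_cycles <= 0 || tf_step_ms <= 0) {
      stop("freq_step, n_cycles and tf_step_ms must be positive", call. = FALSE)
    }
    if (!(baseline_window_s[1] < baseline_window_s[2] &&
          baseline_window_s[2] <= 0)) {
      stop("baseline window must precede stimulus onset", call. = FALSE)
    }
    if (stimulus_phase_s[2] > response_phase_s[1] + 0.011) {
      stop("stimulus and response phase windows must be disjoint", call. = FALSE)
    }
    if (epoch_window_s[1] > analysis_window_s[1] ||
        epoch_window_s[2] < analysis_window_s[2]) {
      stop("epoch window must contain the analysis window", call. = FALSE)
    }
    if (isi_s < stim_dur_s) {
      stop("inter-stimulus interval must be at least the stimulus duration",
           call. = FALSE)
    }
    if (n_trials < 0) stop("n_trials must be non-negative", call. = FALSE)
  })
  invisible(cfg)
}

#' Frequency grid implied by a run configuration
#'
#' At defaults: 60, 62, ..., 140 Hz (41 bins).
#'
#' @param cfg A `seeg_config`.
#' @return Numeric vector of bin-centre frequencies in Hz.
#' @export
config_freqs <- function(cfg) {
  seq(cfg$band_lo, cfg$band_hi, by = cfg$freq_step)
}

#' Read a run configuration from a YAML (or JSON) key-value file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path Path to the config file.
#' @return A `seeg_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg A `seeg_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "seeg_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.seeg_config <- function(x, ...) {
  cat(sprintf("<seeg_config> %g-%g Hz in %g-Hz bins, %g cycles, %g-ms steps\n",
              x$band_lo, x$band_hi, x$freq_step, x$n_cycles, x$tf_step_ms))
  cat(sprintf("  baseline [%g, %g] s; stimulus [%g, %g] s; response (%g, %g] s\n",
              x$baseline_window_s[1], x$baseline_window_s[2],
              x$stimulus_phase_s[1], x$stimulus_phase_s[2],
              x$stimulus_phase_s[2], x$response_phase_s[2]))
  cat(sprintf("  %d trials every %g s\n", x$n_trials, x$isi_s))
  invisible(x)
}
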