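# Synthetic SEEG generator.
#
# The generator produces referential recordings with the statistical
# structure the high-gamma mapping analysis assumes: gray-matter contacts
# carry task-locked band-limited high-gamma sources; every contact receives
# distance-attenuated (inverse-power) copies of those sources (quasi-static
# volume conduction, instantaneous mixing); extracranial contacts
# additionally receive broadband facial-EMG activity during the response
# phase, stronger for overt than covert speech; each contact has independent
# 1/f background noise; and all channels are recorded against the potential
# of one shared white-matter contact, exactly as a referential SEEG montage
# does.

#' Describe one depth-electrode shaft
#'
#' Contacts are collinear. `origin` is the position of contact 1, the
#' deepest contact; contact k sits at `origin + (k-1) * spacing *
#' unit(orientation)`, so the orientation vector points from deep to
#' superficial. The two commercial geometries are supported: 6 contacts at
#' 10-mm or 10 contacts at 5-mm centre-to-centre spacing.
#'
#' @param shaft_id Character id.
#' @param n_contacts 6 or 10.
#' @param origin Numeric 3-vector, mm; position of the deepest contact.
#' @param orientation Numeric 3-vector; deep-to-superficial direction.
#' @param spacing_mm Centre-to-centre spacing; must pair with `n_contacts`
#'   (6 contacts / 10 mm, 10 contacts / 5 mm). Defaults from `n_contacts`.
#' @param categories Character vector of length `n_contacts` drawn from
#'   [contact_categories]; default: deepest contacts `deep_wm`, then
#'   `shallow_wm`, then `gray`, outermost `outside`.
#' @return A list of class `seeg_shaft_spec`.
#' @export
shaft_spec <- function(shaft_id, n_contacts, origin, orientation = c(0, 0, 1),
                       spacing_mm = NULL, categories = NULL) {
  if (!n_contacts %in% c(6L, 10L)) {
    stop("n_contacts must be 6 or 10", call. = FALSE)
  }
  expected_spacing <- if (n_contacts == 6) 10 else 5
  if (is.null(spacing_mm)) spacing_mm <- expected_spacing
  if (spacing_mm != expected_spacing) {
    stop(sprintf("shaft geometry pairing violated: %d contacts requires %g mm spacing",
                 n_contacts, expected_spacing), call. = FALSE)
  }
  if (is.null(categories)) categories <- default_shaft_categories(n_contacts)
  if (length(categories) != n_contacts ||
      !all(categories %in% contact_categories)) {
    stop("categories must be length n_contacts, drawn from contact_categories",
         call. = FALSE)
  }
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation must be non-zero", call. = FALSE)
  structure(list(shaft_id = as.character(shaft_id),
                 n_contacts = as.integer(n_contacts),
                 origin = as.numeric(origin),
                 orientation = as.numeric(orientation) / nrm,
                 spacing_mm = spacing_mm,
                 categories = categories),
            class = "seeg_shaft_spec")
}

#' @rdname shaft_spec
#' @export
default_shaft_categories <- function(n_contacts) {
  if (n_contacts == 6) {
    c("deep_wm", "shallow_wm", "gray", "gray", "gray", "outside")
  } else {
    c("deep_wm", "deep_wm", "shallow_wm", "shallow_wm",
      "gray", "gray", "gray", "gray", "outside", "outside")
  }
}

#' Task-locked gray-matter high-gamma source
#'
#' A band-limited Gaussian-noise waveform placed at a gray-matter contact,
#' multiplied by a trapezoidal trial envelope: amplitude `baseline_amp`
#' between trials, `baseline_amp * stim_gain` during the stimulus phase and
#' `baseline_amp * resp_gain` during the response phase.
#'
#' @param at_contact Contact id of the hosting gray-matter contact.
#' @param baseline_amp Baseline RMS amplitude, microvolts.
#' @param stim_gain,resp_gain Multiplicative envelope factors (>= 0).
#' @param band Source band in Hz.
#' @param rise_ms,fall_ms Envelope ramp durations.
#' @return A list of class `seeg_gray_source`.
#' @export
gray_source <- function(at_contact, baseline_amp = 5, stim_gain = 2.5,
                        resp_gain = 2.0, band = c(60, 140),
                        rise_ms = 100, fall_ms = 100) {
  if (stim_gain < 0 || resp_gain < 0) stop("gains must be >= 0", call. = FALSE)
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band", call. = FALSE)
  structure(list(at_contact = as.character(at_contact),
                 baseline_amp = baseline_amp, stim_gain = stim_gain,
                 resp_gain = resp_gain, band = as.numeric(band),
                 rise_ms = rise_ms, fall_ms = fall_ms),
            class = "seeg_gray_source")
}

#' Response-phase facial-EMG source at extracranial contacts
#'
#' Broadband muscle activity active only during the response phase of each
#' trial, injected exclusively at `outside`-category contacts with
#' inverse-power spatial decay from `locus`. The per-condition amplitudes
#' (`overt_gain` > `covert_gain` >= 0, microvolts RMS at the locus) model
#' the stronger orofacial EMG of vocalized speech.
#'
#' @param locus Numeric 3-vector, mm.
#' @param overt_gain,covert_gain Source RMS amplitude per condition (uV).
#' @param band EMG band in Hz (clipped to Nyquist at simulation time).
#' @param decay_exponent Spatial decay exponent (EMG is diffuse; default 1).
#' @param rise_ms,fall_ms Envelope ramp durations.
#' @return A list of class `seeg_emg_source`.
#' @export
emg_source <- function(locus, overt_gain = 150, covert_gain = 40,
                       band = c(20, 300), decay_exponent = 1,
                       rise_ms = 150, fall_ms = 300) {
  if (!(overt_gain > covert_gain && covert_gain >= 0)) {
    stop("require overt_gain > covert_gain >= 0", call. = FALSE)
  }
  structure(list(locus = as.numeric(locus), overt_gain = overt_gain,
                 covert_gain = covert_gain, band = as.numeric(band),
                 decay_exponent = decay_exponent,
                 rise_ms = rise_ms, fall_ms = fall_ms),
            class = "seeg_emg_source")
}

#' Simulation configuration
#'
#' @param shafts List of [shaft_spec()] objects.
#' @param sources List of [gray_source()] objects.
#' @param emg An [emg_source()] or `NULL`.
#' @param reference_contact_id Id of the shared recording-reference contact;
#'   must be a white-matter (`deep_wm`/`shallow_wm`) contact with no
#'   exclusion flag. In the generated channel table this contact is flagged
#'   `is_artifact = TRUE`, because a channel recorded against itself is flat
#'   and carries no signal (as in real referential SEEG, where the reference
#'   contact is excluded from analysis).
#' @param conduction_exponent,conduction_floor Inverse-power decay law for
#'   volume conduction: weight `(d0 / (d + d0))^p` at distance `d` mm (see
#'   [mixing_weight()]); defaults p = 2, d0 = 1 mm.
#' @param background_alpha 1/f exponent of the per-contact background noise.
#' @param background_rms_uv RMS of the background within the 60-140 Hz
#'   analysis band, microvolts (the in-band quantity is specified because it
#'   is what baseline high-gamma amplitude is made of; total broadband RMS
#'   then depends on recording length through the lowest resolved frequency).
#' @param common_mode_gain Scale applied to the reference-contact potential
#'   before subtraction (1 = physical referential recording).
#' @param rng_seed Integer seed.
#' @return A list of class `seeg_sim_config`.
#' @export
sim_config <- function(shafts, sources = list(), emg = NULL,
                       reference_contact_id,
                       conduction_exponent = 2, conduction_floor = 1,
                       background_alpha = 1, background_rms_uv = 1.5,
                       common_mode_gain = 1, rng_seed = 1L) {
  if (!length(shafts) || !all(vapply(shafts, inherits, TRUE, "seeg_shaft_spec"))) {
    stop("shafts must be a non-empty list of shaft_spec objects", call. = FALSE)
  }
  if (conduction_exponent <= 0 || conduction_floor <= 0) {
    stop("conduction exponent and floor must be positive", call. = FALSE)
  }
  structure(list(shafts = shafts, sources = sources, emg = emg,
                 reference_contact_id = as.character(reference_contact_id),
                 conduction_exponent = conduction_exponent,
                 conduction_floor = conduction_floor,
                 background_alpha = background_alpha,
                 background_rms_uv = background_rms_uv,
                 common_mode_gain = common_mode_gain,
                 rng_seed = as.integer(rng_seed)),
            class = "seeg_sim_config")
}

#' Build the channel table implied by a simulation configuration
#'
#' Contacts are placed collinearly per shaft at the stated centre-to-centre
#' spacing; contact ids are `<shaft_id><contact_index>` with index 1 the
#' deepest contact. All exclusion flags start `FALSE`.
#'
#' @param sim A [sim_config()] (or a bare list of [shaft_spec()]).
#' @return A [channel_table()].
#' @export
build_geometry <- function(sim) {
  shafts <- if (inherits(sim, "seeg_sim_config")) sim$shafts else sim
  rows <- lapply(shafts, function(s) {
    k <- seq_len(s$n_contacts)
    pos <- t(vapply(k, function(i) {
      s$origin + (i - 1) * s$spacing_mm * s$orientation
    }, numeric(3)))
    tibble::tibble(contact_id = sprintf("%s%02d", s$shaft_id, k),
                   shaft_id = s$shaft_id, contact_index = k,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   category = s$categories,
                   is_soz = FALSE, is_irritative = FALSE, is_artifact = FALSE)
  })
  channel_table(dplyr::bind_rows(rows))
}

#' Volume-conduction mixing weight
#'
#' Inverse-power amplitude decay with a floor distance, normalized so a
#' source measured at its own contact has weight 1:
#' `w(d) = (d0 / (d + d0))^p`, strictly decreasing in distance `d`.
#'
#' @param contact_xyz,source_xyz Numeric 3-vectors (mm), or a matrix of
#'   contact positions (rows).
#' @param p Decay exponent (> 0).
#' @param d0 Floor distance in mm (> 0).
#' @return Dimensionless weight(s) in (0, 1].
#' @export
mixing_weight <- function(contact_xyz, source_xyz, p = 2, d0 = 1) {
  if (p <= 0 || d0 <= 0) stop("p and d0 must be positive", call. = FALSE)
  m <- if (is.matrix(contact_xyz)) contact_xyz else matrix(contact_xyz, ncol = 3)
  d <- sqrt(rowSums((m - matrix(source_xyz, nrow(m), 3, byrow = TRUE))^2))
  (d0 / (d + d0))^p
}

# --- waveform helpers ------------------------------------------------------

# Gaussian white noise brick-wall band-passed in the frequency domain,
# scaled to unit RMS. Uses the current RNG state.
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs <- pmin(freqs, fs - freqs)          # two-sided axis
  sp[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  y / stats::sd(y)
}

# 1/f^alpha (power) noise, scaled so the RMS of its component inside
# `norm_band` equals 1. Uses the current RNG state.
pink_noise <- function(n, fs, alpha, norm_band = c(60, 140)) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs <- pmin(freqs, fs - freqs)
  scale <- ifelse(freqs > 0, freqs^(-alpha / 2), 0)
  sp <- sp * scale
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  inband <- freqs >= norm_band[1] & freqs <= norm_band[2]
  # Parseval: RMS of the in-band component from the scaled spectrum
  rms_inband <- sqrt(sum(Mod(sp[inband])^2) / n^2)
  y / rms_inband
}

# Trapezoidal window: 0 before t0, linear rise over rise_s, 1 on
# [t0 + rise_s, t1], linear fall over fall_s, 0 after.
trapezoid <- function(t, t0, t1, rise_s, fall_s) {
  up <- if (rise_s > 0) pmin(1, pmax(0, (t - t0) / rise_s)) else as.numeric(t >= t0)
  down <- if (fall_s > 0) pmin(1, pmax(0, 1 - (t - t1) / fall_s)) else as.numeric(t <= t1)
  pmin(up, down)
}

# Per-trial task envelope of a gray source: 1 between trials, stim_gain
# during the stimulus phase, resp_gain during the response phase.
gray_envelope <- function(t_rel, src, run) {
  stim <- trapezoid(t_rel, run$stimulus_phase_s[1], run$stimulus_phase_s[2],
                    src$rise_ms / 1000, src$fall_ms / 1000)
  resp <- trapezoid(t_rel, run$stimulus_phase_s[2], run$response_phase_s[2],
                    src$rise_ms / 1000, src$fall_ms / 1000)
  # response ramp starts where the stimulus window ends; where the two
  # trapezoids overlap the larger gain wins
  pmax(1 + (src$stim_gain - 1) * stim, 1 + (src$resp_gain - 1) * resp)
}

emg_envelope <- function(t_rel, emg, run) {
  trapezoid(t_rel, run$stimulus_phase_s[2], run$response_phase_s[2],
            emg$rise_ms / 1000, emg$fall_ms / 1000)
}

# Add `per_trial(t_rel)` evaluated around every onset into a length-n
# accumulator defined on the recording clock.
accumulate_trials <- function(n, fs, onsets, span_s, per_trial) {
  acc <- numeric(n)
  for (o in onsets) {
    i0 <- max(0L, floor((o + span_s[1]) * fs))
    i1 <- min(n - 1L, ceiling((o + span_s[2]) * fs))
    if (i1 < i0) next
    idx <- i0:i1
    acc[idx + 1L] <- acc[idx + 1L] + per_trial(idx / fs - o)
  }
  acc
}

#' Simulate one referential SEEG run
#'
#' Generates the four core artifacts of a run: the recording (each channel
#' is its contact's potential minus the shared reference-contact potential),
#' the channel table, the event table, and a ground-truth ledger holding the
#' exact mixing weights and trial envelopes for oracle tests.
#'
#' Determinism: the RNG is seeded from `sim$rng_seed`, and the draw order
#' does not depend on `condition`, so overt and covert runs with the same
#' seed share background and gray-source waveforms exactly and differ only
#' in the EMG amplitude at `outside`-category contacts during response
#' phases.
#'
#' @param sim A [sim_config()].
#' @param run A [run_config()].
#' @param condition `"overt"` or `"covert"`.
#' @param keep_potentials If `TRUE`, the ground truth additionally stores
#'   the per-contact pre-reference potentials and the reference series.
#' @return A list with elements `recording`, `channels`, `events`,
#'   `ground_truth`.
#' @export
simulate_run <- function(sim, run, condition = c("overt", "covert"),
                         keep_potentials = FALSE) {
  stopifnot(inherits(sim, "seeg_sim_config"), inherits(run, "seeg_config"))
  condition <- match.arg(condition)
  channels <- build_geometry(sim)
  fs <- 1200

  ref_row <- match(sim$reference_contact_id, channels$contact_id)
  if (is.na(ref_row)) {
    stop("reference contact '", sim$reference_contact_id,
         "' not found in geometry", call. = FALSE)
  }
  if (!channels$category[ref_row] %in% c("deep_wm", "shallow_wm")) {
    stop("reference contact must be a white-matter contact", call. = FALSE)
  }
  if (channels$is_soz[ref_row] || channels$is_irritative[ref_row] ||
      channels$is_artifact[ref_row]) {
    stop("reference contact is excluded by flags", call. = FALSE)
  }

  onsets <- run$first_onset_s + run$isi_s * (seq_len(run$n_trials) - 1)
  events <- event_table(tibble::tibble(
    trial_id = seq_len(run$n_trials), onset_s = onsets,
    condition = condition, keep = TRUE, stim_dur_s = run$stim_dur_s))

  dur <- if (run$n_trials > 0) {
    max(onsets) + run$epoch_window_s[2] + 0.5
  } else 10
  n <- as.integer(ceiling(dur * fs))
  pos <- as.matrix(channels[, c("x", "y", "z")])
  n_ch <- nrow(channels)

  set.seed(sim$rng_seed)

  # independent 1/f background per contact
  potentials <- matrix(0, n_ch, n)
  if (sim$background_rms_uv > 0) {
    for (c in seq_len(n_ch)) {
      potentials[c, ] <- sim$background_rms_uv *
        pink_noise(n, fs, sim$background_alpha,
                   norm_band = c(run$band_lo, run$band_hi))
    }
  }

  # gray-matter sources with task-locked envelopes, volume-conducted to
  # every contact by the inverse-power mixing law
  weights <- matrix(0, n_ch, length(sim$sources) + 1,
                    dimnames = list(channels$contact_id,
                                    c(if (length(sim$sources))
                                        paste0("src", seq_along(sim$sources)),
                                      "emg")))
  src_series <- list()
  span <- c(run$epoch_window_s[1] - 0.2,
            run$response_phase_s[2] + 1)
  for (si in seq_along(sim$sources)) {
    src <- sim$sources[[si]]
    host <- match(src$at_contact, channels$contact_id)
    if (is.na(host)) {
      stop("gray source host contact '", src$at_contact, "' not found",
           call. = FALSE)
    }
    if (channels$category[host] != "gray") {
      stop("gray source must be placed at a gray-matter contact", call. = FALSE)
    }
    carrier <- bandlimited_noise(n, fs, src$band)
    env <- rep(1, n)
    delta <- accumulate_trials(n, fs, onsets, span, function(t_rel) {
      gray_envelope(t_rel, src, run) - 1
    })
    env <- env + delta
    wave <- src$baseline_amp * env * carrier
    w <- mixing_weight(pos, pos[host, ], sim$conduction_exponent,
                       sim$conduction_floor)
    weights[, si] <- w
    potentials <- potentials + tcrossprod(w, wave)
    src_series[[si]] <- if (keep_potentials) wave else NULL
  }

  # EMG: injected only at outside-category contacts, response phases only
  emg_gain <- 0
  if (!is.null(sim$emg)) {
    emg <- sim$emg
    emg_gain <- if (condition == "overt") emg$overt_gain else emg$covert_gain
    band <- c(max(0.5, emg$band[1]), min(emg$band[2], fs / 2 - 1))
    carrier <- bandlimited_noise(n, fs, band)
    env <- accumulate_trials(n, fs, onsets, span, function(t_rel) {
      emg_envelope(t_rel, emg, run)
    })
    wave <- emg_gain * env * carrier
    outside <- channels$category == "outside"
    w <- mixing_weight(pos, emg$locus, emg$decay_exponent,
                       sim$conduction_floor)
    w[!outside] <- 0
    weights[, "emg"] <- w
    if (any(outside)) {
      potentials[outside, ] <- potentials[outside, , drop = FALSE] +
        tcrossprod(w[outside], wave)
    }
  }

  ref_series <- sim$common_mode_gain * potentials[ref_row, ]
  data <- potentials - matrix(ref_series, n_ch, n, byrow = TRUE)

  out_channels <- channels
  out_channels$is_artifact[ref_row] <- TRUE   # flat channel: v = phi - phi = 0

  step_times <- seq(run$analysis_window_s[1], run$analysis_window_s[2],
                    by = run$tf_step_ms / 1000)
  gt <- list(
    weights = weights,
    reference_contact_id = sim$reference_contact_id,
    emg_gain = emg_gain,
    envelope_times_s = step_times,
    source_envelopes = lapply(sim$sources, function(src) {
      gray_envelope(step_times, src, run)
    }),
    emg_envelope = if (!is.null(sim$emg)) {
      emg_envelope(step_times, sim$emg, run)
    } else NULL)
  if (keep_potentials) {
    gt$potentials <- potentials
    gt$reference_series <- ref_series
    gt$source_series <- src_series
  }

  list(recording = recording(data, fs = fs,
                             channel_ids = channels$contact_id,
                             montage_tag = "original"),
       channels = out_channels, events = events, ground_truth = gt)
}
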