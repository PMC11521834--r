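# Ready-made simulation scenarios.
#
# Amplitude scales are fixed package-wide choices (see the methods
# vignette): gray-matter high-gamma sources of 5 uV RMS baseline rising by
# a factor 2.5 during the stimulus phase and 2.0 during the response phase;
# per-contact 1/f background with 1.5 uV RMS inside the analysis band;
# facial EMG of 150 uV (overt) / 40 uV (covert) RMS at its locus. Because
# the percent-change normalisation is per-trial and per-channel, only the
# ratios of these numbers matter.

#' Two-shaft scenario for montage-attenuation experiments
#'
#' Two parallel 10-contact shafts 25 mm apart, category pattern (deep to
#' superficial) deep/deep/shallow/shallow/gray x4/outside x2, an
#' independent task-locked high-gamma source at every gray contact (cortex
#' is locally active everywhere it is sampled), a facial-EMG source beyond
#' the superficial shaft ends, and the recording reference on the deepest
#' contact of shaft B.
#'
#' @param seed RNG seed.
#' @param effect_scale Multiplies the task effects (envelope gains minus
#'   one, and the EMG amplitudes); 1 = study-like defaults, 0 = null.
#' @return A [sim_config()].
#' @export
scenario_shaft_pair <- function(seed = 1L, effect_scale = 1) {
  pat <- c("deep_wm", "deep_wm", "shallow_wm", "shallow_wm",
           "gray", "gray", "gray", "gray", "outside", "outside")
  shafts <- list(
    shaft_spec("A", 10, origin = c(0, 0, 0), orientation = c(0, 0, 1),
               categories = pat),
    shaft_spec("B", 10, origin = c(25, 0, 0), orientation = c(0, 0, 1),
               categories = pat))
  src <- function(id) {
    gray_source(id, baseline_amp = 5,
                stim_gain = 1 + 1.5 * effect_scale,
                resp_gain = 1 + 1.0 * effect_scale)
  }
  # facial-muscle locus just beyond shaft A's superficial end (the anchor
  # bolt sits in the temporal muscle); amplitudes are at-the-muscle RMS
  emg <- if (effect_scale > 0) {
    emg_source(locus = c(0, 0, 58),
               overt_gain = 300 * effect_scale,
               covert_gain = 75 * effect_scale)
  } else NULL
  gray_ids <- paste0(rep(c("A", "B"), each = 4), "0", 5:8)
  sim_config(shafts = shafts, sources = lapply(gray_ids, src),
             emg = emg, reference_contact_id = "B01", rng_seed = seed)
}

#' Single-shaft null scenario
#'
#' One 10-contact shaft carrying gray sources whose stimulus and response
#' gains are exactly 1 (no task locking) and no EMG: every channel is
#' band-limited noise over 1/f background, so downstream percent change is
#' statistically indistinguishable from zero. The category pattern keeps
#' all four compartments representable under all three montages despite the
#' flat reference channel (deepest contact) being flagged out.
#'
#' @param seed RNG seed.
#' @param shaft_id Shaft label (distinct per simulated patient).
#' @return A [sim_config()].
#' @export
scenario_null <- function(seed = 1L, shaft_id = "N") {
  pat <- c("deep_wm", "deep_wm", "deep_wm", "shallow_wm", "shallow_wm",
           "gray", "gray", "gray", "outside", "outside")
  shafts <- list(shaft_spec(shaft_id, 10, origin = c(0, 0, 0),
                            orientation = c(0, 0, 1), categories = pat))
  srcs <- lapply(paste0(shaft_id, c("06", "07", "08")), function(id) {
    gray_source(id, baseline_amp = 5, stim_gain = 1, resp_gain = 1)
  })
  sim_config(shafts = shafts, sources = srcs, emg = NULL,
             reference_contact_id = paste0(shaft_id, "01"), rng_seed = seed)
}

#' Study-like multi-shaft scenario
#'
#' Eight shafts (four 10-contact at 5 mm, four 6-contact at 10 mm), 64
#' contacts with category proportions echoing a typical SEEG implantation
#' for language mapping (about 14% deep white matter, 16% shallow white
#' matter, 52% gray matter, 19% outside the brain), an independent
#' task-locked source at every gray contact, one shared EMG source,
#' reference on a deep white-matter contact.
#'
#' @inheritParams scenario_shaft_pair
#' @return A [sim_config()].
#' @export
scenario_study_like <- function(seed = 1L, effect_scale = 1) {
  d <- "deep_wm"; s <- "shallow_wm"; g <- "gray"; o <- "outside"
  pats10 <- list(c(d, d, s, g, g, g, g, g, o, o),
                 c(d, s, s, g, g, g, g, g, g, o),
                 c(d, d, s, s, g, g, g, g, o, o),
                 c(d, s, g, g, g, g, g, g, o, o))
  pats6 <- list(c(d, s, g, g, g, o),
                c(s, g, g, g, g, o),
                c(d, s, g, g, o, o),
                c(d, g, g, g, g, o))
  shafts <- list()
  xy <- expand.grid(x = c(0, 30), y = c(0, 30, 60, 90))
  for (i in 1:4) {
    shafts[[i]] <- shaft_spec(LETTERS[i], 10,
                              origin = c(xy$x[i], xy$y[i], 0),
                              orientation = c(0, 0, 1),
                              categories = pats10[[i]])
  }
  for (i in 1:4) {
    shafts[[4 + i]] <- shaft_spec(LETTERS[4 + i], 6,
                                  origin = c(xy$x[4 + i], xy$y[4 + i], 0),
                                  orientation = c(0, 0, 1),
                                  categories = pats6[[i]])
  }
  geom <- build_geometry(shafts)
  src <- function(id) {
    gray_source(id, baseline_amp = 5,
                stim_gain = 1 + 1.5 * effect_scale,
                resp_gain = 1 + 1.0 * effect_scale)
  }
  hosts <- geom$contact_id[geom$category == "gray"]
  emg <- if (effect_scale > 0) {
    emg_source(locus = c(0, 0, 58),
               overt_gain = 300 * effect_scale,
               covert_gain = 75 * effect_scale)
  } else NULL
  sim_config(shafts = shafts, sources = lapply(hosts, src), emg = emg,
             reference_contact_id = "A01", rng_seed = seed)
}

#' Simulate a cohort of patients under both vocalization conditions
#'
#' Each patient gets an independent realisation of the scenario (seed
#' offset per patient) with a patient-specific multiplicative heterogeneity
#' factor on the task effects (lognormal, SD 0.2 on the log scale) — this
#' is what makes the patient random intercept of the mixed model real.
#' Overt and covert runs of one patient share the patient seed, so they
#' differ only in EMG amplitude.
#'
#' @param n_patients Number of simulated patients.
#' @param run A [run_config()].
#' @param scenario Function `(seed, effect_scale) -> sim_config`.
#' @param conditions Conditions to simulate per patient.
#' @param base_seed Seed from which patient seeds and heterogeneity are
#'   derived.
#' @param effect_scale Cohort-level task-effect scale.
#' @return A list with one element per patient: `patient_id`, `sim`, and
#'   one simulated run (see [simulate_run()]) per condition.
#' @export
simulate_cohort <- function(n_patients, run, scenario = scenario_shaft_pair,
                            conditions = c("overt", "covert"),
                            base_seed = 1L, effect_scale = 1) {
  set.seed(base_seed)
  het <- exp(stats::rnorm(n_patients, 0, 0.2))
  seeds <- base_seed + 1000L * seq_len(n_patients)
  lapply(seq_len(n_patients), function(p) {
    sim <- scenario(seed = seeds[p],
                    effect_scale = effect_scale * het[p])
    runs <- lapply(conditions, function(cond) {
      simulate_run(sim, run, condition = cond)
    })
    names(runs) <- conditions
    c(list(patient_id = sprintf("p%02d", p), sim = sim), runs)
  })
}
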