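#' Read / write a simulation configuration as YAML
#'
#' Serialises every field of a [sim_config()] — shaft geometry, gray
#' sources, EMG source, conduction law, background and reference — so a
#' scenario can ship as a plain-text fixture shared by tests, docs and
#' scripts.
#'
#' @param path Path to the YAML file.
#' @return [read_sim_config()] returns a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  shafts <- lapply(y$shafts, function(s) {
    shaft_spec(s$shaft_id, s$n_contacts, origin = unlist(s$origin),
               orientation = unlist(s$orientation),
               spacing_mm = s$spacing_mm,
               categories = unlist(s$categories))
  })
  sources <- lapply(y$sources, function(s) {
    gray_source(s$at_contact, baseline_amp = s$baseline_amp,
                stim_gain = s$stim_gain, resp_gain = s$resp_gain,
                band = unlist(s$band), rise_ms = s$rise_ms,
                fall_ms = s$fall_ms)
  })
  emg <- if (!is.null(y$emg)) {
    emg_source(locus = unlist(y$emg$locus), overt_gain = y$emg$overt_gain,
               covert_gain = y$emg$covert_gain, band = unlist(y$emg$band),
               decay_exponent = y$emg$decay_exponent,
               rise_ms = y$emg$rise_ms, fall_ms = y$emg$fall_ms)
  } else NULL
  sim_config(shafts = shafts, sources = sources, emg = emg,
             reference_contact_id = y$reference_contact_id,
             conduction_exponent = y$conduction_exponent,
             conduction_floor = y$conduction_floor,
             background_alpha = y$background_alpha,
             background_rms_uv = y$background_rms_uv,
             common_mode_gain = y$common_mode_gain,
             rng_seed = y$rng_seed)
}

#' @rdname read_sim_config
#' @param sim A [sim_config()].
#' @export
write_sim_config <- function(sim, path) {
  stopifnot(inherits(sim, "seeg_sim_config"))
  y <- list(
    shafts = lapply(sim$shafts, function(s) {
      list(shaft_id = s$shaft_id, n_contacts = s$n_contacts,
           origin = as.list(s$origin),
           orientation = as.list(s$orientation),
           spacing_mm = s$spacing_mm, categories = as.list(s$categories))
    }),
    sources = lapply(sim$sources, function(s) {
      list(at_contact = s$at_contact, baseline_amp = s$baseline_amp,
           stim_gain = s$stim_gain, resp_gain = s$resp_gain,
           band = as.list(s$band), rise_ms = s$rise_ms, fall_ms = s$fall_ms)
    }),
    emg = if (!is.null(sim$emg)) {
      list(locus = as.list(sim$emg$locus), overt_gain = sim$emg$overt_gain,
           covert_gain = sim$emg$covert_gain, band = as.list(sim$emg$band),
           decay_exponent = sim$emg$decay_exponent,
           rise_ms = sim$emg$rise_ms, fall_ms = sim$emg$fall_ms)
    } else NULL,
    reference_contact_id = sim$reference_contact_id,
    conduction_exponent = sim$conduction_exponent,
    conduction_floor = sim$conduction_floor,
    background_alpha = sim$background_alpha,
    background_rms_uv = sim$background_rms_uv,
    common_mode_gain = sim$common_mode_gain,
    rng_seed = sim$rng_seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
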