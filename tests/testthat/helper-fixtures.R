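# Shared fixture builders. Everything is generated in code at test time.

# one shaft, deep -> superficial along +z
toy_channels <- function(n = 6, shaft = "S", categories = NULL,
                         soz = integer(0), artifact = integer(0),
                         irritative = integer(0)) {
  if (is.null(categories)) categories <- default_shaft_categories(n)
  channel_table(tibble::tibble(
    contact_id = sprintf("%s%02d", shaft, seq_len(n)),
    shaft_id = shaft, contact_index = seq_len(n),
    x = 0, y = 0, z = (seq_len(n) - 1) * ifelse(n == 6, 10, 5),
    category = categories,
    is_soz = seq_len(n) %in% soz,
    is_irritative = seq_len(n) %in% irritative,
    is_artifact = seq_len(n) %in% artifact))
}

# channel table with the anatomical-category proportions of a 12-patient
# language-mapping implantation: 67 deep WM, 86 shallow WM, 309 gray, 111
# outside (573 contacts, no exclusion flags)
study_proportion_channels <- function() {
  counts <- c(deep_wm = 67, shallow_wm = 86, gray = 309, outside = 111)
  cats <- rep(names(counts), counts)
  n <- length(cats)
  channel_table(tibble::tibble(
    contact_id = sprintf("c%03d", seq_len(n)),
    shaft_id = sprintf("sh%02d", rep(seq_len(ceiling(n / 10)), each = 10)[seq_len(n)]),
    contact_index = rep(1:10, length.out = n),
    x = seq_len(n), y = 0, z = 0,
    category = cats,
    is_soz = FALSE, is_irritative = FALSE, is_artifact = FALSE))
}

# wrap a plain channels x samples matrix as a minimal epoch set
as_toy_epochs <- function(x, fs = 1200, t0_s = -0.7,
                          trial_id = NULL, condition = "overt",
                          montage_tag = "original") {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1, ncol(x)))
  n_tr <- dim(x)[2]
  structure(list(data = x, fs = fs, t0_s = t0_s,
                 window_s = c(t0_s, t0_s + dim(x)[3] / fs),
                 trial_id = trial_id %||% seq_len(n_tr),
                 condition = rep(condition, length.out = n_tr),
                 channel_ids = sprintf("ch%02d", seq_len(dim(x)[1])),
                 montage_tag = montage_tag),
            class = "seeg_epochs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force direct-convolution Morlet oracle: amplitude of signal `x`
# (vector, fs) at frequency f0 and 0-based sample n0, analytic wavelet,
# support +- L samples. Independent of the package's FFT path.
oracle_morlet_amp <- function(x, fs, f0, n0, n_cycles = 7, L = 2000) {
  sigma <- n_cycles / (2 * pi * f0)
  k <- (-L):L
  keep <- (n0 + k) >= 0 & (n0 + k) < length(x)
  tk <- k / fs
  psi <- 2 / (fs * sigma * sqrt(2 * pi)) *
    exp(-tk^2 / (2 * sigma^2)) * exp(-2i * pi * f0 * tk)
  Mod(sum(x[n0 + k[keep] + 1] * psi[keep]))
}

# small simulated run shared by feature/viz tests (memoised: the first call
# pays the simulation, later calls reuse it)
.tiny_cache <- new.env(parent = emptyenv())
tiny_pipeline <- function() {
  if (is.null(.tiny_cache$res)) {
    run <- run_config(n_trials = 6, first_onset_s = 2, rng_seed = 11L)
    sim <- scenario_shaft_pair(seed = 11L)
    r <- simulate_run(sim, run, "overt")
    pl <- hg_pipeline(r$recording, r$channels, r$events, run, keep_pc = TRUE)
    .tiny_cache$res <- list(run = run, sim = sim, raw = r, pipeline = pl)
  }
  .tiny_cache$res
}

# build a tiny two-signal EDF file byte by byte from the format definition
# (ascii fixed-width header fields, int16 little-endian data records)
write_toy_edf <- function(path, fs = 100, n_records = 2,
                          digital = NULL) {
  ns <- 2L
  spr <- as.integer(fs)                      # record duration 1 s
  if (is.null(digital)) {
    set.seed(42)
    digital <- matrix(sample(-500:500, ns * spr * n_records, replace = TRUE),
                      nrow = ns)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(value, width) {
    s <- formatC(as.character(value), width = -width)
    s <- substr(s, 1, width)
    writeBin(charToRaw(s), con)
  }
  put("0", 8); put("toy patient", 80); put("toy recording", 80)
  put("01.01.24", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8); put("", 44)
  put(n_records, 8); put("1", 8); put(ns, 4)
  for (i in 1:ns) put(sprintf("SIG%d", i), 16)
  for (i in 1:ns) put("toy", 80)
  for (i in 1:ns) put("uV", 8)
  for (i in 1:ns) put("-1000", 8)            # phys min
  for (i in 1:ns) put("1000", 8)             # phys max
  for (i in 1:ns) put("-32768", 8)           # dig min
  for (i in 1:ns) put("32767", 8)            # dig max
  for (i in 1:ns) put("none", 80)
  for (i in 1:ns) put(spr, 8)
  for (i in 1:ns) put("", 32)
  for (r in seq_len(n_records)) {
    for (i in 1:ns) {
      cols <- ((r - 1) * spr + 1):(r * spr)
      writeBin(as.integer(digital[i, cols]), con, size = 2,
               endian = "little")
    }
  }
  gain <- 2000 / 65535
  offset <- -1000 - gain * (-32768)
  list(path = path, fs = fs, physical = digital * gain + offset)
}
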