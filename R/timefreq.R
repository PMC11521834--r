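# Complex Morlet wavelet time-frequency amplitude and baseline
# percent-change normalisation.
#
# Conventions (documented in the methods vignette):
# * wavelet: psi(t) = A * exp(-t^2 / (2 sigma^2)) * exp(i 2 pi f t) with
#   sigma = n_cycles / (2 pi f); the gain A = 2 / (fs sigma sqrt(2 pi)) is
#   chosen so that a unit-amplitude sinusoid at f yields coefficient
#   magnitude 1, flat across frequency.
# * "amplitude" is the magnitude of the complex coefficient, not power.
# * convolution is computed by frequency-domain multiplication on the
#   zero-padded epoch; the 10-ms output grid is obtained exactly by
#   spectral folding (aliasing) followed by a short inverse FFT, which
#   equals sampling the full convolution every `fs * step` samples.
# * the per-trial baseline mean is taken on a twice-finer (5-ms) grid that
#   interleaves the output steps, so baseline percent change at the output
#   steps is an estimate, not an identity.

#' Complex Morlet wavelet kernel
#'
#' @param f Centre frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param n_cycles Wavelet width in cycles; the Gaussian envelope SD is
#'   `n_cycles / (2 pi f)` seconds.
#' @param trunc_sd Support truncation in envelope SDs (default 4).
#' @return Complex vector of length `2L + 1` with attribute `half_len` (L);
#'   the centre element is the t = 0 tap.
#' @export
morlet_kernel <- function(f, fs, n_cycles = 7, trunc_sd = 4) {
  if (f >= fs / 2) stop("frequency ", f, " Hz is at or above Nyquist", call. = FALSE)
  sigma <- n_cycles / (2 * pi * f)
  L <- as.integer(ceiling(trunc_sd * sigma * fs))
  t <- (-L:L) / fs
  gain <- 2 / (fs * sigma * sqrt(2 * pi))
  k <- gain * exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t)
  attr(k, "half_len") <- L
  k
}

# 2-3-5-7-smooth FFT length >= n that is a multiple of `mult`
.nice_fft_size <- function(n, mult) {
  n <- as.integer(ceiling(n / mult)) * mult
  repeat {
    m <- n / mult
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0) m <- m / p
    mm <- n
    for (p in c(2L, 3L, 5L, 7L)) while (mm %% p == 0) mm <- mm / p
    if (mm == 1) return(as.integer(n))
    n <- n + mult
  }
}

# Precompute everything reusable across epochs of identical length.
.tf_plan <- function(n_samples, fs, t0_s, cfg) {
  freqs <- config_freqs(cfg)
  if (max(freqs) >= fs / 2) {
    stop("frequency grid reaches Nyquist (", fs / 2, " Hz)", call. = FALSE)
  }
  D <- cfg$tf_step_ms / 1000 * fs
  if (abs(D - round(D)) > 1e-9) {
    stop("tf_step_ms must be an integer number of samples at fs = ", fs,
         call. = FALSE)
  }
  D <- as.integer(round(D))
  kernels <- lapply(freqs, morlet_kernel, fs = fs, n_cycles = cfg$n_cycles)
  Lmax <- max(vapply(kernels, function(k) attr(k, "half_len"), integer(1)))
  N <- .nice_fft_size(n_samples + 2L * Lmax, D)
  M <- N %/% D

  K <- vapply(kernels, function(k) {
    L <- attr(k, "half_len")
    kk <- complex(length.out = N)
    kk[1:(L + 1)] <- k[(L + 1):(2 * L + 1)]      # taps 0..L
    kk[(N - L + 1):N] <- k[1:L]                  # taps -L..-1
    stats::fft(kk)
  }, complex(N))

  off <- D %/% 2L                                 # interleaved half-step grid
  phase <- exp(2i * pi * (0:(N - 1)) * off / N)

  # decimated-grid index m (0-based) <-> epoch time t0 + m D / fs
  m_time <- t0_s + (0:(M - 1)) * D / fs
  m_time_off <- t0_s + ((0:(M - 1)) * D + off) / fs

  step_times <- seq(cfg$analysis_window_s[1], cfg$analysis_window_s[2],
                    by = cfg$tf_step_ms / 1000)
  step_m <- round((step_times - t0_s) * fs / D)
  if (any(step_m < 0 | step_m > (n_samples - 1) / D)) {
    stop("analysis window extends beyond the epoch", call. = FALSE)
  }
  # interior (edge-clean) requirement: kernel support inside the epoch
  clean <- step_m * D >= Lmax & step_m * D <= n_samples - 1 - Lmax
  if (!all(clean)) {
    stop("analysis window is edge-contaminated: increase the epoch padding",
         call. = FALSE)
  }

  bw <- cfg$baseline_window_s
  base_on <- which(m_time >= bw[1] & m_time < bw[2])
  base_off <- which(m_time_off >= bw[1] & m_time_off < bw[2])
  if (length(base_on) + length(base_off) == 0) {
    stop("baseline window contains no time-frequency samples", call. = FALSE)
  }

  list(freqs = freqs, N = N, M = M, D = D, K = K, phase = phase,
       n_samples = n_samples, Lmax = Lmax,
       step_times = step_times, step_rows = step_m + 1L,
       base_on = base_on, base_off = base_off)
}

.fold <- function(Y, M, D) {
  out <- Y[seq_len(M), , drop = FALSE]
  for (r in seq_len(D - 1)) {
    out <- out + Y[(r * M + 1):((r + 1) * M), , drop = FALSE]
  }
  out
}

# Amplitude of one epoch on the decimated grids.
# Returns list(amp = steps x freq matrix at the analysis grid,
#              baseline = per-freq baseline mean amplitude)
.epoch_tf <- function(x, plan) {
  N <- plan$N
  X <- stats::fft(c(x, numeric(N - length(x))))
  Y <- plan$K * X
  Z_on <- stats::mvfft(.fold(Y, plan$M, plan$D), inverse = TRUE) / N
  amp_on <- Mod(Z_on)
  Z_off <- stats::mvfft(.fold(Y * plan$phase, plan$M, plan$D),
                        inverse = TRUE) / N
  amp_off <- Mod(Z_off)
  baseline <- colMeans(rbind(amp_on[plan$base_on, , drop = FALSE],
                             amp_off[plan$base_off, , drop = FALSE]))
  list(amp = amp_on[plan$step_rows, , drop = FALSE], baseline = baseline)
}

#' Morlet wavelet amplitude map of an epoch set
#'
#' Computes, for every channel and trial, the magnitude of the complex
#' Morlet coefficient on the configured frequency grid (60, 62, ..., 140 Hz
#' at defaults) sampled every `tf_step_ms` over the analysis window. The
#' per-trial mean baseline amplitude of each frequency bin (taken on a 5-ms
#' grid within the baseline window) is stored alongside for
#' [percent_change()].
#'
#' @param epochs A `seeg_epochs` (see [epoch_recording()]); the epoch
#'   window must pad the analysis window by at least half a wavelet.
#' @param cfg A [run_config()].
#' @return An object of class `seeg_tfmap`: `amp` is a channel x trial x
#'   frequency x step array (microvolts), `baseline` a channel x trial x
#'   frequency array, plus `freqs`, `times_s` and trial metadata.
#' @export
morlet_amplitude <- function(epochs, cfg = run_config()) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  d <- dim(epochs$data)
  plan <- .tf_plan(d[3], epochs$fs, epochs$t0_s, cfg)
  n_steps <- length(plan$step_times)
  nf <- length(plan$freqs)
  amp <- array(0, c(d[1], d[2], nf, n_steps))
  baseline <- array(0, c(d[1], d[2], nf))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      res <- .epoch_tf(epochs$data[ch, tr, ], plan)
      amp[ch, tr, , ] <- t(res$amp)
      baseline[ch, tr, ] <- res$baseline
    }
  }
  structure(list(amp = amp, baseline = baseline, freqs = plan$freqs,
                 times_s = plan$step_times,
                 baseline_window_s = cfg$baseline_window_s,
                 channel_ids = epochs$channel_ids,
                 trial_id = epochs$trial_id, condition = epochs$condition,
                 montage_tag = epochs$montage_tag),
            class = "seeg_tfmap")
}

#' Broadband high-gamma percent change from a time-frequency map
#'
#' Per trial, channel and frequency bin, the percent change
#' `100 * (amp - B) / B` against that trial's mean baseline amplitude `B`
#' of the bin; the per-bin series are then averaged across bins into one
#' broadband series. Normalising per bin before averaging compensates the
#' 1/f amplitude slope so every bin contributes comparably.
#'
#' @param tfmap A `seeg_tfmap` from [morlet_amplitude()].
#' @param baseline_window_s Baseline window; must equal the window the map
#'   stored its per-trial baselines for (the map carries the baseline at
#'   5-ms resolution, finer than the step grid).
#' @return An object of class `seeg_pc`: `pc` is a channel x trial x step
#'   matrix of percent change, with `times_s` and trial metadata.
#' @export
percent_change <- function(tfmap, baseline_window_s = tfmap$baseline_window_s) {
  stopifnot(inherits(tfmap, "seeg_tfmap"))
  if (!isTRUE(all.equal(baseline_window_s, tfmap$baseline_window_s))) {
    stop("baseline window differs from the one the map was built with",
         call. = FALSE)
  }
  d <- dim(tfmap$amp)
  zero <- which(tfmap$baseline == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop(sprintf("zero baseline amplitude at channel '%s', trial %d, %g Hz",
                 tfmap$channel_ids[zero[1, 1]],
                 tfmap$trial_id[zero[1, 2]],
                 tfmap$freqs[zero[1, 3]]), call. = FALSE)
  }
  pc <- array(0, c(d[1], d[2], d[4]))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      b <- tfmap$baseline[ch, tr, ]
      pc_bins <- 100 * (tfmap$amp[ch, tr, , ] / b - 1)   # freq x step
      pc[ch, tr, ] <- colMeans(pc_bins)
    }
  }
  .pc_series(pc, tfmap)
}

.pc_series <- function(pc, meta) {
  structure(list(pc = pc, times_s = meta$times_s,
                 baseline_window_s = meta$baseline_window_s,
                 channel_ids = meta$channel_ids,
                 trial_id = meta$trial_id, condition = meta$condition,
                 montage_tag = meta$montage_tag),
            class = "seeg_pc")
}

#' High-gamma percent change straight from epochs
#'
#' Fused [morlet_amplitude()] + [percent_change()] that never materialises
#' the full channel x trial x frequency x step amplitude array; the memory
#' footprint stays at one epoch's spectrum regardless of epoch count. The
#' result is identical to the two-step route.
#'
#' @inheritParams morlet_amplitude
#' @return A `seeg_pc` (see [percent_change()]).
#' @export
highgamma_pc <- function(epochs, cfg = run_config()) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  d <- dim(epochs$data)
  plan <- .tf_plan(d[3], epochs$fs, epochs$t0_s, cfg)
  pc <- array(0, c(d[1], d[2], length(plan$step_times)))
  for (ch in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      res <- .epoch_tf(epochs$data[ch, tr, ], plan)
      if (any(res$baseline == 0)) {
        f0 <- plan$freqs[which(res$baseline == 0)[1]]
        stop(sprintf("zero baseline amplitude at channel '%s', trial %d, %g Hz",
                     epochs$channel_ids[ch], epochs$trial_id[tr], f0),
             call. = FALSE)
      }
      pc_bins <- 100 * (res$amp / matrix(res$baseline, nrow(res$amp),
                                         ncol(res$amp), byrow = TRUE) - 1)
      pc[ch, tr, ] <- rowMeans(pc_bins)
    }
  }
  meta <- list(times_s = plan$step_times,
               baseline_window_s = cfg$baseline_window_s,
               channel_ids = epochs$channel_ids,
               trial_id = epochs$trial_id, condition = epochs$condition,
               montage_tag = epochs$montage_tag)
  .pc_series(pc, meta)
}

#' Export a percent-change series as a long TSV
#'
#' One row per (channel, trial, time step).
#'
#' @param pc_series A `seeg_pc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pc_tsv <- function(pc_series, path) {
  stopifnot(inherits(pc_series, "seeg_pc"))
  d <- dim(pc_series$pc)
  df <- expand.grid(channel_id = pc_series$channel_ids,
                    trial = pc_series$trial_id,
                    time_s = pc_series$times_s,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$pc <- as.vector(pc_series$pc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.seeg_pc <- function(x, ...) {
  d <- dim(x$pc)
  cat(sprintf("<seeg_pc> %d channels x %d trials x %d steps (%g to %g s), montage: %s\n",
              d[1], d[2], d[3], min(x$times_s), max(x$times_s),
              x$montage_tag))
  invisible(x)
}
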