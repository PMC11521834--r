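test_that("channel table validates its closed vocabulary and uniqueness", {
  ch <- toy_channels(6)
  expect_s3_class(ch, "seeg_channels")
  expect_equal(ch$contact_index, 1:6)

  bad <- tibble::as_tibble(ch)
  bad$category[3] <- "ventricle"
  expect_error(channel_table(bad), "ventricle")
  expect_error(channel_table(bad), "row 3")

  dup <- tibble::as_tibble(ch)
  dup$contact_id[2] <- dup$contact_id[1]
  expect_error(channel_table(dup), "duplicate contact_id")

  expect_error(channel_table(tibble::as_tibble(ch)[, -3]),
               "missing column")
})

test_that("channel table TSV round-trip is lossless, including the study-scale table", {
  for (ch in list(toy_channels(10), study_proportion_channels())) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_channel_table(ch, path)
    back <- read_channel_table(path)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(ch))
  }
  big <- study_proportion_channels()
  expect_equal(unname(table(big$category)[c("deep_wm", "shallow_wm",
                                            "gray", "outside")]),
               c(67, 86, 309, 111), ignore_attr = TRUE)
})

test_that("matrix container round-trips a recording bit-exactly", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 1200), 4), fs = 1200,
                   channel_ids = c("a", "b", "c", "d"))
  p1 <- withr::local_tempfile(fileext = ".bin")
  p2 <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, p1)
  r1 <- read_recording(p1)
  expect_equal(r1$fs, 1200)
  expect_equal(r1$channel_ids, rec$channel_ids)
  expect_equal(r1$data, rec$data, tolerance = 1e-7)  # float32 quantisation
  write_recording(r1, p2)
  r2 <- read_recording(p2)
  expect_identical(r2$data, r1$data)                 # stable thereafter
})

test_that("recording reader enforces sidecar consistency", {
  rec <- recording(matrix(0, 3, 100), fs = 500)
  path <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, path)
  expect_error(read_recording(path, fs = 1200), "sampling rate mismatch")
  expect_error(read_recording(path, channels = toy_channels(6)),
               "channel count mismatch")
  expect_silent(read_recording(path, fs = 500, channels = toy_channels(6)[1:3, ]))
})

test_that("EDF files are read with physical scaling, and fs mismatch errors", {
  path <- withr::local_tempfile(fileext = ".edf")
  edf <- write_toy_edf(path, fs = 100, n_records = 2)
  rec <- read_recording(path)            # format sniffed from content
  expect_equal(rec$fs, 100)
  expect_equal(rec$channel_ids, c("SIG1", "SIG2"))
  expect_equal(rec$data, edf$physical, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(read_recording(path, fs = 1200), "sampling rate mismatch")
})

test_that("a multi-patient batch manifest loads one object set per patient", {
  dir <- withr::local_tempdir()
  n_pat <- 12
  man <- tibble::tibble(patient_id = sprintf("p%02d", 1:n_pat),
                        recording = sprintf("p%02d.bin", 1:n_pat),
                        channels = sprintf("p%02d_ch.tsv", 1:n_pat),
                        events = sprintf("p%02d_ev.tsv", 1:n_pat))
  for (i in seq_len(n_pat)) {
    write_recording(recording(matrix(rnorm(6 * 100), 6), fs = 1200,
                              channel_ids = sprintf("S%02d", 1:6)),
                    file.path(dir, man$recording[i]))
    write_channel_table(toy_channels(6), file.path(dir, man$channels[i]))
    write_event_table(event_table(data.frame(trial_id = 1, onset_s = 0.01,
                                             condition = "overt")),
                      file.path(dir, man$events[i]))
  }
  utils::write.table(as.data.frame(man), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  batch <- read_batch_manifest(file.path(dir, "manifest.tsv"))
  expect_length(batch, n_pat)
  expect_named(batch, man$patient_id)
  expect_true(all(vapply(batch, function(b)
    inherits(b$recording, "seeg_recording") &&
      inherits(b$channels, "seeg_channels") &&
      inherits(b$events, "seeg_events"), TRUE)))
})

test_that("event tables enforce ordering and condition vocabulary", {
  ev <- event_table(data.frame(trial_id = 1:3, onset_s = c(0, 10, 20),
                               condition = "overt"))
  expect_true(all(ev$keep))
  expect_error(event_table(data.frame(trial_id = 1:2, onset_s = c(10, 10),
                                      condition = "overt")),
               "strictly increasing")
  expect_error(event_table(data.frame(trial_id = 1, onset_s = 0,
                                      condition = "loud")),
               "overt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_table(ev, path)
  expect_equal(tibble::as_tibble(read_event_table(path)),
               tibble::as_tibble(ev))
})

test_that("run config validates, round-trips through YAML, and builds the 41-bin grid", {
  cfg <- run_config()
  expect_length(config_freqs(cfg), 41)
  expect_equal(config_freqs(cfg)[1:3], c(60, 62, 64))
  expect_error(run_config(band_lo = 140, band_hi = 60), "band_lo")
  expect_error(run_config(baseline_window_s = c(0.1, 0.3)), "baseline")
  expect_error(run_config(isi_s = 1), "inter-stimulus")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(run_config(n_trials = 17, rng_seed = 5L), path)
  back <- read_run_config(path)
  expect_equal(back$n_trials, 17L)
  expect_equal(back$rng_seed, 5L)
  expect_equal(back$band_hi, 140)
  writeLines("bogus_key: 1", path)
  expect_error(read_run_config(path), "unknown config key")
})
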