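test_that("shaft geometry places contacts at the stated spacing", {
  # 10-contact shaft, 5-mm spacing: all 9 adjacent pairs 5.0 mm apart
  g10 <- build_geometry(list(shaft_spec("A", 10, origin = c(3, -2, 7),
                                        orientation = c(1, 2, 2))))
  pos <- as.matrix(g10[, c("x", "y", "z")])
  d <- sqrt(rowSums((pos[-1, ] - pos[-10, ])^2))
  expect_equal(d, rep(5, 9))

  # 6-contact shaft along +x from the origin: contact 6 at x = 50 mm
  g6 <- build_geometry(list(shaft_spec("B", 6, origin = c(0, 0, 0),
                                       orientation = c(1, 0, 0))))
  expect_equal(g6$x[6], 50)
  expect_equal(g6$y, rep(0, 6))

  # two parallel shafts 20 mm apart: cross-shaft nearest distance 20 mm
  gg <- build_geometry(list(
    shaft_spec("A", 6, origin = c(0, 0, 0), orientation = c(0, 0, 1)),
    shaft_spec("B", 6, origin = c(20, 0, 0), orientation = c(0, 0, 1))))
  pa <- as.matrix(gg[gg$shaft_id == "A", c("x", "y", "z")])
  pb <- as.matrix(gg[gg$shaft_id == "B", c("x", "y", "z")])
  cross <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
    sqrt(sum((pa[i, ] - pb[j, ])^2))))
  expect_equal(min(cross), 20)

  # contact-count / spacing pairing is enforced
  expect_error(shaft_spec("C", 10, origin = c(0, 0, 0), spacing_mm = 10),
               "pairing violated")
  expect_error(shaft_spec("C", 6, origin = c(0, 0, 0), spacing_mm = 5),
               "pairing violated")
})

test_that("mixing weight follows the normalised inverse-power decay", {
  expect_equal(mixing_weight(c(0, 0, 0), c(0, 0, 0), p = 2, d0 = 1), 1)
  # closed form: p = 2, d0 = 1, d = 9 mm -> (1/10^2)/(1/1^2) = 0.01
  expect_equal(mixing_weight(c(9, 0, 0), c(0, 0, 0), p = 2, d0 = 1), 0.01)
  w5 <- mixing_weight(c(5, 0, 0), c(0, 0, 0))
  w10 <- mixing_weight(c(10, 0, 0), c(0, 0, 0))
  expect_gt(w5, w10)
  expect_error(mixing_weight(c(1, 0, 0), c(0, 0, 0), p = -1), "positive")
})

test_that("simulated event tables follow the task structure", {
  run <- run_config(n_trials = 100)
  sim <- scenario_null(seed = 1)
  res <- simulate_run(sim, run, "overt")
  expect_equal(res$events$onset_s, seq(0, 990, by = 10))
  expect_equal(unique(res$events$stim_dur_s), 1.8)
  expect_equal(res$events$trial_id, 1:100)
  expect_true(all(diff(res$events$onset_s) >= 1.8))
})

test_that("same seed reproduces the recording bit-identically", {
  run <- run_config(n_trials = 2)
  sim <- scenario_shaft_pair(seed = 5)
  r1 <- simulate_run(sim, run, "overt")
  r2 <- simulate_run(sim, run, "overt")
  expect_identical(r1$recording$data, r2$recording$data)
})

test_that("overt and covert runs with one seed differ only at outside contacts during response phases", {
  run <- run_config(n_trials = 3, first_onset_s = 2)
  sim <- scenario_shaft_pair(seed = 9)
  ov <- simulate_run(sim, run, "overt")
  cv <- simulate_run(sim, run, "covert")
  outside <- ov$channels$category == "outside"
  expect_identical(ov$recording$data[!outside, ], cv$recording$data[!outside, ])
  diff_mask <- ov$recording$data != cv$recording$data
  expect_true(any(diff_mask[outside, ]))
  # differing samples fall inside response-phase windows (incl. envelope fall)
  t <- (seq_len(ncol(ov$recording$data)) - 1) / ov$recording$fs
  in_response <- rep(FALSE, length(t))
  for (o in ov$events$onset_s) {
    in_response <- in_response | (t >= o + 1.8 & t <= o + 5.0 + 0.4)
  }
  expect_true(all(in_response[which(colSums(diff_mask) > 0)]))
})

test_that("the reference potential is an exact common mode of the recording", {
  run <- run_config(n_trials = 2, first_onset_s = 2)
  sim <- scenario_shaft_pair(seed = 3)
  res <- simulate_run(sim, run, "overt", keep_potentials = TRUE)
  v <- res$recording$data
  phi <- res$ground_truth$potentials
  # v_c = phi_c - ref for every channel, and pairwise differences cancel ref
  expect_equal(v[2, ] - v[7, ], phi[2, ] - phi[7, ], tolerance = 1e-12)
  ref_row <- match(res$ground_truth$reference_contact_id,
                   res$channels$contact_id)
  expect_equal(v[ref_row, ], rep(0, ncol(v)))
  expect_true(res$channels$is_artifact[ref_row])
})

test_that("induced source amplitude at each contact is proportional to its mixing weight", {
  sh <- shaft_spec("A", 10, origin = c(0, 0, 0), orientation = c(0, 0, 1),
                   categories = c("deep_wm", "shallow_wm", rep("gray", 6),
                                  "outside", "outside"))
  sim <- sim_config(shafts = list(sh),
                    sources = list(gray_source("A05")), emg = NULL,
                    reference_contact_id = "A01",
                    background_rms_uv = 0, rng_seed = 2)
  run <- run_config(n_trials = 2, first_onset_s = 2)
  res <- simulate_run(sim, run, "overt", keep_potentials = TRUE)
  amp <- apply(res$ground_truth$potentials, 1, stats::sd)
  w <- res$ground_truth$weights[, "src1"]
  expect_equal(unname(amp / amp[5]), unname(w / w[5]), tolerance = 1e-9)
  # strictly decreasing with distance on the superficial side
  expect_true(all(diff(amp[5:10]) < 0))
})

test_that("simulation rejects invalid reference and source placements", {
  sh <- shaft_spec("A", 6, origin = c(0, 0, 0))
  run <- run_config(n_trials = 1)
  expect_error(
    simulate_run(sim_config(shafts = list(sh), reference_contact_id = "A04",
                            rng_seed = 1), run, "overt"),
    "white-matter")
  expect_error(
    simulate_run(sim_config(shafts = list(sh),
                            sources = list(gray_source("A01")),
                            reference_contact_id = "A01", rng_seed = 1),
                 run, "overt"),
    "gray-matter contact")
  expect_error(
    simulate_run(sim_config(shafts = list(sh), reference_contact_id = "Z99",
                            rng_seed = 1), run, "overt"),
    "not found")
})

test_that("simulation configs round-trip through YAML", {
  sim <- scenario_shaft_pair(seed = 21)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(sim, path)
  back <- read_sim_config(path)
  expect_equal(build_geometry(back), build_geometry(sim))
  expect_equal(length(back$sources), length(sim$sources))
  expect_equal(back$emg$overt_gain, sim$emg$overt_gain)
  run <- run_config(n_trials = 1, first_onset_s = 1)
  expect_identical(simulate_run(back, run, "overt")$recording$data,
                   simulate_run(sim, run, "overt")$recording$data)
})
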