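test_that("CAR subtracts the mean of the eligible set from every channel", {
  ch <- toy_channels(6)   # deep, shallow, gray x3, outside
  mt <- build_car(ch)
  expect_equal(mt$scheme, "car")
  expect_equal(nrow(mt$weights), 6)          # applied to every channel
  expect_setequal(mt$included_in_average, sprintf("S%02d", 1:5))

  # instantaneous values (2, 4, 6) on the included channels -> (-2, 0, 2)
  rec <- recording(matrix(c(2, 4, 6), 3, 10), fs = 1200,
                   channel_ids = c("g1", "g2", "g3"))
  ch3 <- channel_table(tibble::tibble(
    contact_id = c("g1", "g2", "g3"), shaft_id = "G", contact_index = 1:3,
    x = 0, y = 0, z = 0:2, category = "gray",
    is_soz = FALSE, is_irritative = FALSE, is_artifact = FALSE))
  out <- apply_montage(rec, build_car(ch3))
  expect_equal(out$data[, 1], c(-2, 0, 2), ignore_attr = TRUE)
  expect_equal(out$montage_tag, "car")

  # identical signal on all included channels -> all-zero output there
  rec2 <- recording(matrix(7, 3, 5), fs = 1200, channel_ids = ch3$contact_id)
  expect_equal(max(abs(apply_montage(rec2, build_car(ch3))$data)), 0)
})

test_that("outside channels are re-referenced by CAR but contribute no weight to the average", {
  ch <- toy_channels(6)
  mt <- build_car(ch)
  out_row <- which(ch$category == "outside")
  # outside channel value 10, included average 4 -> CAR value 6
  vals <- c(4, 4, 4, 4, 4, 10)
  rec <- recording(matrix(vals, 6, 3), fs = 1200,
                   channel_ids = ch$contact_id)
  derived <- apply_montage(rec, mt)
  expect_equal(derived$data[out_row, 1], 6, ignore_attr = TRUE)
  # zero weight of the outside channel in every row's average part
  avg_part <- mt$weights - diag(6)
  expect_equal(unname(avg_part[, out_row]), rep(0, 6))
})

test_that("CAR averaging set excludes flagged, CSF and outside channels, and errors when empty", {
  ch <- toy_channels(6, soz = 3, irritative = 4, artifact = 5)
  mt <- build_car(ch)
  expect_setequal(mt$included_in_average, c("S01", "S02"))
  all_bad <- toy_channels(6, artifact = 1:6)
  expect_error(build_car(all_bad), "averaging set")
})

test_that("bipolar derivations subtract the adjacent deeper contact", {
  ch <- toy_channels(3, categories = c("gray", "gray", "gray"))
  # shaft values deep -> superficial (5, 3, 2): derived (-2, -1)
  rec <- recording(matrix(c(5, 3, 2), 3, 4), fs = 1200,
                   channel_ids = ch$contact_id)
  mt <- build_bipolar(ch)
  out <- apply_montage(rec, mt)
  expect_equal(out$data[, 1], c(-2, -1), ignore_attr = TRUE)
  expect_equal(mt$derived_ids, c("S02-S01", "S03-S02"))

  # 10-contact shaft -> 9 derived channels; deepest yields none
  expect_equal(nrow(build_bipolar(toy_channels(10))$weights), 9)

  # identical signal on adjacent contacts -> exactly 0
  rec2 <- recording(matrix(3.3, 3, 4), fs = 1200,
                    channel_ids = ch$contact_id)
  expect_equal(max(abs(apply_montage(rec2, mt)$data)), 0)

  # derived channels inherit the superficial contact's category
  mt10 <- build_bipolar(toy_channels(10))
  expect_equal(mt10$derived_category,
               default_shaft_categories(10)[2:10])
})

test_that("laplacian derivations subtract the mean of both shaft neighbours", {
  ch <- toy_channels(3, categories = rep("gray", 3))
  mt <- build_laplacian(ch)
  # interior contact 3 with neighbours 5 and 2 -> 3 - 3.5 = -0.5
  rec <- recording(matrix(c(5, 3, 2), 3, 2), fs = 1200,
                   channel_ids = ch$contact_id)
  expect_equal(apply_montage(rec, mt)$data[1, 1], -0.5, ignore_attr = TRUE)

  # linear gradient along the shaft is annihilated
  ch4 <- toy_channels(4, categories = rep("gray", 4))
  rec4 <- recording(matrix(1:4, 4, 3), fs = 1200,
                    channel_ids = ch4$contact_id)
  expect_equal(max(abs(apply_montage(rec4, build_laplacian(ch4))$data)), 0)

  # 6-contact shaft -> 4 derived channels (no shaft ends)
  expect_equal(nrow(build_laplacian(toy_channels(6))$weights), 4)
  # centre contact's category is inherited
  expect_equal(build_laplacian(toy_channels(6))$derived_category,
               default_shaft_categories(6)[2:5])
})

test_that("a missing intermediate contact breaks adjacency instead of bridging it", {
  ch <- toy_channels(6)[-3, ]    # drop contact_index 3
  bp <- build_bipolar(ch)
  expect_false(any(grepl("S04-S02", bp$derived_ids)))
  expect_setequal(bp$derived_ids, c("S02-S01", "S05-S04", "S06-S05"))
  lp <- build_laplacian(ch)
  expect_equal(lp$derived_ids, "S05")        # only contact with both neighbours
})

test_that("montage rows sum to zero over their referenced sets", {
  ch <- select_channels(build_geometry(scenario_shaft_pair(seed = 1)$shafts))
  for (mt in list(build_bipolar(ch), build_laplacian(ch))) {
    expect_equal(max(abs(rowSums(mt$weights))), 0)
  }
  car <- build_car(ch)
  avg_rows <- car$derived_ids %in% car$included_in_average
  expect_equal(max(abs(rowSums(car$weights[avg_rows, , drop = FALSE]))), 0)
})

test_that("apply_montage is linear and preserves an identity transform", {
  ch <- toy_channels(6)
  set.seed(3)
  x <- recording(matrix(rnorm(6 * 50), 6), fs = 1200,
                 channel_ids = ch$contact_id)
  y <- recording(matrix(rnorm(6 * 50), 6), fs = 1200,
                 channel_ids = ch$contact_id)
  w_id <- diag(6)
  colnames(w_id) <- ch$contact_id
  id <- montage_transform(w_id, derived_ids = ch$contact_id,
                          scheme = "car",
                          included_in_average = character(0))
  expect_equal(apply_montage(x, id)$data, x$data, ignore_attr = TRUE)

  mt <- build_laplacian(ch)
  ax_plus_by <- recording(2 * x$data + 3 * y$data, fs = 1200,
                          channel_ids = ch$contact_id)
  expect_equal(apply_montage(ax_plus_by, mt)$data,
               2 * apply_montage(x, mt)$data + 3 * apply_montage(y, mt)$data)

  bad <- recording(matrix(0, 4, 10), fs = 1200,
                   channel_ids = sprintf("zz%d", 1:4))
  expect_error(apply_montage(bad, mt), "do not match")
})

test_that("every montage cancels the simulated reference common mode to machine precision", {
  run <- run_config(n_trials = 2, first_onset_s = 2)
  res <- simulate_run(scenario_shaft_pair(seed = 4), run, "overt",
                      keep_potentials = TRUE)
  sel <- select_channels(res$channels)
  rec <- subset_recording(res$recording, sel$contact_id)
  # a recording consisting of the pure common-mode component
  cm <- recording(matrix(res$ground_truth$reference_series,
                         nrow(sel), ncol(rec$data), byrow = TRUE),
                  fs = rec$fs, channel_ids = sel$contact_id)
  rms_in <- sqrt(mean(cm$data^2))
  for (build in list(build_bipolar, build_laplacian)) {
    out <- apply_montage(cm, build(sel))
    expect_lt(sqrt(mean(out$data^2)) / rms_in, 1e-10)
  }
  car <- build_car(sel)
  out <- apply_montage(cm, car)
  expect_lt(sqrt(mean(out$data^2)) / rms_in, 1e-10)
})

test_that("montage weight matrices export as TSV for audit", {
  ch <- toy_channels(6)
  mt <- build_bipolar(ch)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_montage_tsv(mt, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$derived_id, mt$derived_ids)
  expect_equal(as.matrix(back[, ch$contact_id]), mt$weights,
               ignore_attr = TRUE)
})
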