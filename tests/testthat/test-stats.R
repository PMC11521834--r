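# simulate a feature table from the additive generative model
# y = intercept + b_bp I(bipolar) + b_lap I(laplacian) + b_cov I(covert)
#   + patient offset + N(0, sigma)
make_features <- function(n_patients, n_trials, b = c(bp = -90, lap = -90,
                                                      cov = 20),
                          intercept = 300, patient_sd = 25, sigma = 0,
                          category = "gray", phase = "response") {
  grid <- expand.grid(patient_id = sprintf("p%02d", seq_len(n_patients)),
                      trial_id = seq_len(n_trials),
                      montage = c("car", "bipolar", "laplacian"),
                      condition = c("overt", "covert"),
                      stringsAsFactors = FALSE)
  offs <- stats::setNames(stats::rnorm(n_patients, 0, patient_sd),
                          sprintf("p%02d", seq_len(n_patients)))
  grid$max_pc <- intercept +
    b["bp"] * (grid$montage == "bipolar") +
    b["lap"] * (grid$montage == "laplacian") +
    b["cov"] * (grid$condition == "covert") +
    offs[grid$patient_id] +
    stats::rnorm(nrow(grid), 0, sigma)
  tibble::as_tibble(cbind(grid, channel_id = "c1", category = category,
                          phase = phase))
}

test_that("noiseless features recover the generative contrasts exactly", {
  set.seed(31)
  f <- make_features(4, 10, sigma = 0)
  # zero residual variance sits on the boundary of lmer's convergence
  # checks; the estimates are exact regardless
  res <- suppressWarnings(fit_mixed(f, "gray", "response"))
  est <- stats::setNames(res$estimate, res$term)
  expect_equal(est[["BP"]], -90, tolerance = 1e-8)
  expect_equal(est[["LAP"]], -90, tolerance = 1e-8)
  expect_equal(est[["Covert response"]], 20, tolerance = 1e-8)
  # reference rows are reported with NA, as the montage tables print them
  ref <- res[res$term == "CAR (reference)", ]
  expect_true(all(is.na(ref[, c("estimate", "se", "t", "p")])))
  # CI equals estimate +/- t_crit * SE with the residual df
  bp <- res[res$term == "BP", ]
  tcrit <- stats::qt(0.975, bp$df)
  expect_equal(bp$ci_lo, bp$estimate - tcrit * bp$se)
  expect_equal(bp$ci_hi, bp$estimate + tcrit * bp$se)
  expect_equal(attr(res, "n_patients"), 4)
})

test_that("residual df equals observations minus fixed effects", {
  set.seed(32)
  f <- make_features(3, 7, sigma = 5)
  res <- fit_mixed(f, "gray", "response")
  n_obs <- nrow(f)
  expect_equal(unique(res$df[!is.na(res$df)]), n_obs - 4)
})

test_that("a single patient collapses to the OLS group contrasts", {
  set.seed(33)
  f <- make_features(1, 30, patient_sd = 0, sigma = 10)
  expect_message(res <- fit_mixed(f, "gray", "response"), "single patient")
  ols <- stats::lm(max_pc ~ factor(montage, c("car", "bipolar", "laplacian")) +
                     factor(condition, c("overt", "covert")), data = f)
  expect_equal(res$estimate[res$term == "BP"],
               unname(stats::coef(ols)[2]))
  expect_equal(res$estimate[res$term == "Covert response"],
               unname(stats::coef(ols)[4]))
  expect_equal(attr(res, "fit_type"), "ols")
})

test_that("adding a constant shifts only the intercept", {
  set.seed(34)
  f <- make_features(4, 8, sigma = 8)
  r1 <- fit_mixed(f, "gray", "response")
  f2 <- f
  f2$max_pc <- f2$max_pc + 500
  r2 <- fit_mixed(f2, "gray", "response")
  est1 <- stats::setNames(r1$estimate, r1$term)
  est2 <- stats::setNames(r2$estimate, r2$term)
  expect_equal(est2[["(Intercept)"]] - est1[["(Intercept)"]], 500,
               tolerance = 1e-6)
  for (term in c("BP", "LAP", "Covert response")) {
    expect_equal(est2[[term]], est1[[term]], tolerance = 1e-6)
  }
})

test_that("missing montage levels are rejected for a stratum", {
  set.seed(35)
  f <- make_features(3, 5, sigma = 5)
  expect_error(fit_mixed(f[f$montage == "car", ], "gray", "response"),
               "CAR plus at least one other")
  expect_error(fit_mixed(f, "outside", "response"), "no observations")
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  # hand-computed: sorted p (0.01, 0.02, 0.04, 0.9), m = 4:
  # p(3) * 4/3 = 0.05333...; cumulative minima give (0.04, 0.04, 0.0533, 0.9)
  expect_equal(round(fdr_adjust(c(0.01, 0.02, 0.04, 0.9)), 4),
               c(0.04, 0.04, 0.0533, 0.9))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_error(fdr_adjust(c(0.1, 1.2)), "outside")
  expect_error(fdr_adjust(c(-0.1)), "outside")
})

test_that("run_contrasts fits every stratum and controls one FDR family", {
  set.seed(36)
  f <- dplyr::bind_rows(
    make_features(3, 6, sigma = 10, category = "gray", phase = "stimulus"),
    make_features(3, 6, sigma = 10, category = "gray", phase = "response"),
    make_features(3, 6, sigma = 10, category = "outside", phase = "response"))
  out <- run_contrasts(f)
  expect_equal(nrow(out), 3 * 5)   # 5 reported terms per stratum
  fam <- out[out$term %in% c("BP", "LAP", "Covert response"), ]
  expect_equal(fam$p_fdr, fdr_adjust(fam$p))
  expect_true(all(is.na(out$p_fdr[out$term == "(Intercept)"])))
  dir <- withr::local_tempdir()
  write_contrast_tables(out, dir)
  expect_length(list.files(dir, pattern = "^contrasts_.*\\.tsv$"), 3)
})

test_that("mixed-model coverage is nominal on simulated cohorts", {
  # 40 replicates here as a smoke check; the acceptance suite runs 200
  set.seed(37)
  hits <- 0
  for (r in 1:40) {
    f <- make_features(5, 8, b = c(bp = -50, lap = -30, cov = 15),
                       patient_sd = 20, sigma = 30)
    res <- suppressMessages(fit_mixed(f, "gray", "response"))
    bp <- res[res$term == "BP", ]
    hits <- hits + (bp$ci_lo <= -50 && -50 <= bp$ci_hi)
  }
  expect_gte(hits / 40, 0.85)
})
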