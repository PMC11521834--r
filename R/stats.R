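#' Mixed-model contrast of montage and vocalization for one stratum
#'
#' Fits, for one anatomical category and task phase, the linear mixed model
#' `max_pc ~ montage + condition + (1 | patient)` by REML, with the common
#' average reference montage and the overt response as reference levels, so
#' the `BP`, `LAP` and `Covert response` estimates are differences (in
#' percent-change units) from CAR / overt. Trials are treated as
#' independent observations within patient; there is no channel-level
#' random effect.
#'
#' Degenerate designs degrade explicitly rather than fail: with a single
#' patient the random intercept is unidentifiable and an ordinary
#' least-squares fit is used (estimates equal the OLS group contrasts); a
#' singular mixed fit is refit as fixed-effects, with a message either way.
#' If only one condition level is present the condition term is dropped.
#'
#' @param features Feature table from [phase_max()].
#' @param category,phase Stratum to fit.
#' @param df_method `"residual"` (default; df = observations minus fixed
#'   effects, matching the large denominator df reported with trial-level
#'   SEEG fits) or `"satterthwaite"` (requires the lmerTest package).
#' @return A tibble of class `seeg_mixed_result`, one row per reported
#'   term (`(Intercept)`, `CAR (reference)`, `BP`, `LAP`, `Covert
#'   response`) with `estimate`, `se`, `df`, `t`, `p`, `ci_lo`, `ci_hi`;
#'   reference rows carry `NA`. Attributes: `n_obs`, `n_patients`,
#'   `fit_type`.
#' @export
fit_mixed <- function(features, category, phase,
                      df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  dat <- features[features$category == category & features$phase == phase, ]
  if (nrow(dat) == 0) stop("no observations for stratum", call. = FALSE)
  montages <- intersect(c("car", "bipolar", "laplacian"),
                        unique(dat$montage))
  if (length(montages) < 2 || !"car" %in% montages) {
    stop("montage contrast needs CAR plus at least one other montage in the stratum",
         call. = FALSE)
  }
  dat$montage <- factor(dat$montage, levels = montages)
  has_condition <- length(unique(dat$condition)) > 1
  if (has_condition) {
    dat$condition <- factor(dat$condition, levels = c("overt", "covert"))
  }
  n_patients <- length(unique(dat$patient_id))
  form_fixed <- if (has_condition) max_pc ~ montage + condition else
    max_pc ~ montage

  fit_type <- "lmm"
  fit <- NULL
  if (n_patients >= 2) {
    form <- stats::update(form_fixed, . ~ . + (1 | patient_id))
    fit <- lme4::lmer(form, data = dat, REML = TRUE)
    if (lme4::isSingular(fit, tol = 1e-6)) {
      message("singular mixed fit for ", category, "/", phase,
              "; downgraded to fixed-effects model")
      fit <- NULL
    }
  } else {
    message("single patient for ", category, "/", phase,
            "; random intercept absorbed, fitting OLS")
  }
  if (is.null(fit) || n_patients < 2) {
    fit <- stats::lm(form_fixed, data = dat)
    fit_type <- "ols"
  }

  co <- if (fit_type == "lmm") lme4::fixef(fit) else stats::coef(fit)
  se <- if (fit_type == "lmm") {
    sqrt(diag(as.matrix(stats::vcov(fit))))
  } else {
    sqrt(diag(stats::vcov(fit)))
  }
  n_obs <- nrow(dat)
  if (df_method == "residual" || fit_type == "ols") {
    dfs <- rep(n_obs - length(co), length(co))
  } else {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("df_method = 'satterthwaite' requires the lmerTest package",
           call. = FALSE)
    }
    form <- stats::update(form_fixed, . ~ . + (1 | patient_id))
    lt <- lmerTest::lmer(form, data = dat, REML = TRUE)
    dfs <- summary(lt)$coefficients[, "df"]
  }
  tval <- co / se
  pval <- 2 * stats::pt(-abs(tval), dfs)
  tcrit <- stats::qt(0.975, dfs)

  label_of <- function(nm) {
    switch(nm,
           "(Intercept)" = "(Intercept)",
           "montagebipolar" = "BP",
           "montagelaplacian" = "LAP",
           "conditioncovert" = "Covert response",
           nm)
  }
  est_rows <- tibble::tibble(
    term = vapply(names(co), label_of, ""),
    estimate = unname(co), se = unname(se), df = unname(dfs),
    t = unname(tval), p = unname(pval),
    ci_lo = unname(co - tcrit * se), ci_hi = unname(co + tcrit * se))
  ref_row <- tibble::tibble(term = "CAR (reference)", estimate = NA_real_,
                            se = NA_real_, df = NA_real_, t = NA_real_,
                            p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  order_terms <- c("(Intercept)", "CAR (reference)", "BP", "LAP",
                   "Covert response")
  out <- dplyr::bind_rows(est_rows, ref_row)
  out <- out[order(match(out$term, order_terms)), ]
  out <- tibble::add_column(out, category = category, phase = phase,
                            .before = 1)
  attr(out, "n_obs") <- n_obs
  attr(out, "n_patients") <- n_patients
  attr(out, "fit_type") <- fit_type
  class(out) <- c("seeg_mixed_result", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values; a thin, validating front
#' end to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-value outside [0, 1]: ", p[which(bad)[1]], call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Montage and vocalization contrasts for all strata, with FDR control
#'
#' Fits [fit_mixed()] separately for every anatomical category x phase
#' stratum present in the feature table (separate models per phase), then
#' applies Benjamini-Hochberg FDR adjustment jointly across all estimable
#' fixed-effect terms of the run (the `BP`, `LAP` and `Covert response`
#' rows of every stratum form one family; intercepts are excluded) and
#' flags significance at FDR 0.05.
#'
#' @param features Feature table from [phase_max()].
#' @param df_method Passed to [fit_mixed()].
#' @param fdr_alpha Significance level on the adjusted p-values.
#' @return A tibble binding all stratum results, with columns `p_fdr` and
#'   `significant` added to the contrast rows.
#' @export
run_contrasts <- function(features, df_method = c("residual", "satterthwaite"),
                          fdr_alpha = 0.05) {
  df_method <- match.arg(df_method)
  cats <- intersect(c("deep_wm", "shallow_wm", "gray", "outside"),
                    unique(features$category))
  phases <- intersect(c("stimulus", "response"), unique(features$phase))
  res <- list()
  for (cat in cats) {
    for (ph in phases) {
      fit <- tryCatch(fit_mixed(features, cat, ph, df_method = df_method),
                      error = function(e) {
                        message("skipping ", cat, "/", ph, ": ",
                                conditionMessage(e))
                        NULL
                      })
      if (!is.null(fit)) res[[paste(cat, ph)]] <- fit
    }
  }
  if (length(res) == 0) stop("no stratum could be fit", call. = FALSE)
  out <- dplyr::bind_rows(res)
  family <- out$term %in% c("BP", "LAP", "Covert response")
  out$p_fdr <- NA_real_
  out$p_fdr[family] <- fdr_adjust(out$p[family])
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < fdr_alpha
  out
}

#' Write contrast tables, one TSV per category x phase
#'
#' @param contrasts Result of [run_contrasts()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_contrast_tables <- function(contrasts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- unique(contrasts[, c("category", "phase")])
  for (i in seq_len(nrow(key))) {
    sel <- contrasts$category == key$category[i] &
      contrasts$phase == key$phase[i]
    utils::write.table(
      as.data.frame(contrasts[sel, ]),
      file.path(dir, sprintf("contrasts_%s_%s.tsv",
                             key$category[i], key$phase[i])),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
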