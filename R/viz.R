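#' Spatial snapshots of high-gamma percent change
#'
#' Renders, for each requested time, an abstract 3-D scatter (x against z,
#' y mapped to point shape grouping is deliberately avoided; depth is
#' conveyed by the coordinates themselves) of the trial-mean percent change
#' at every contact: colour encodes signed percent change and glyph size
#' encodes its magnitude, both monotone in |pc|. No brain mesh is drawn —
#' contact coordinates are plotted as-is. Alongside every PNG a TSV of the
#' plotted values is written, so a frame is fully auditable.
#'
#' Derived bipolar channels (ids like `A05-A04`) are placed at their
#' superficial contact's coordinates.
#'
#' @param pc_series A `seeg_pc`.
#' @param channels The [channel_table()] supplying coordinates.
#' @param times_s Times to render; must lie on the percent-change grid.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix (default the series' montage tag).
#' @return Tibble with one row per written frame (`time_s`, `png`, `tsv`),
#'   invisibly.
#' @export
render_snapshots <- function(pc_series, channels,
                             times_s = c(0, 0.25, 3.0), out_dir,
                             prefix = pc_series$montage_tag) {
  stopifnot(inherits(pc_series, "seeg_pc"), inherits(channels, "seeg_channels"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- vapply(times_s, function(tt) {
    j <- which(abs(pc_series$times_s - tt) < 1e-9)
    if (length(j) != 1) {
      stop("time ", tt, " s is not on the percent-change grid", call. = FALSE)
    }
    j
  }, 0L)
  coords <- .derived_coords(pc_series$channel_ids, channels)

  out <- lapply(seq_along(times_s), function(i) {
    vals <- apply(pc_series$pc[, , cols[i], drop = FALSE], 1, mean)
    df <- tibble::tibble(channel_id = pc_series$channel_ids,
                         x = coords$x, y = coords$y, z = coords$z,
                         category = coords$category,
                         time_s = times_s[i], pc = vals)
    stem <- file.path(out_dir, sprintf("%s_t%+05.0fms", prefix,
                                       1000 * times_s[i]))
    utils::write.table(as.data.frame(df), paste0(stem, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                          colour = .data$pc,
                                          size = abs(.data$pc))) +
      ggplot2::geom_point(alpha = 0.9) +
      ggplot2::scale_colour_gradient2(low = "navy", mid = "grey85",
                                      high = "firebrick", midpoint = 0,
                                      name = "% change") +
      ggplot2::scale_size_continuous(range = c(1, 8), limits = c(0, NA),
                                     name = "|% change|") +
      ggplot2::labs(title = sprintf("%s montage, t = %g s", prefix,
                                    times_s[i]),
                    x = "x (mm)", y = "z (mm)") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(paste0(stem, ".png"), p, width = 5, height = 4,
                    dpi = 120)
    tibble::tibble(time_s = times_s[i], png = paste0(stem, ".png"),
                   tsv = paste0(stem, ".tsv"))
  })
  invisible(dplyr::bind_rows(out))
}

.derived_coords <- function(ids, channels) {
  base <- sub("-.*$", "", ids)           # bipolar 'sup-deep' -> superficial
  j <- match(base, channels$contact_id)
  if (anyNA(j)) {
    stop("no coordinates for channel(s): ",
         paste(ids[is.na(j)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(x = channels$x[j], y = channels$y[j], z = channels$z[j],
                 category = channels$category[j])
}

#' Temporal dynamics of percent change for a channel stratum
#'
#' Plots the across-trial mean percent change with a 95% confidence ribbon
#' (t critical value on trials - 1 df; channels of the stratum are averaged
#' within trial first), one line per montage x condition, with vertical
#' markers at stimulus onset (0 s, black) and stimulus offset (1.8 s, red).
#'
#' @param pc_list A `seeg_pc` or a list of them (e.g. one per montage /
#'   condition).
#' @param channel_ids Stratum: derived-channel ids to average; `NULL` = all
#'   channels of each series.
#' @param out_file Optional PNG path; a TSV of the plotted values is
#'   written alongside.
#' @param stim_offset_s Stimulus offset marker (default 1.8 s).
#' @return The ggplot object, invisibly.
#' @export
plot_dynamics <- function(pc_list, channel_ids = NULL, out_file = NULL,
                          stim_offset_s = 1.8) {
  if (inherits(pc_list, "seeg_pc")) pc_list <- list(pc_list)
  stopifnot(all(vapply(pc_list, inherits, TRUE, "seeg_pc")))
  df <- dplyr::bind_rows(lapply(pc_list, .dynamics_frame,
                                channel_ids = channel_ids))
  if (nrow(df) == 0) stop("empty stratum", call. = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mean_pc,
                                        colour = .data$series,
                                        fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, colour = "black") +
    ggplot2::geom_vline(xintercept = stim_offset_s, colour = "red") +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = "high-gamma change (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out_file)) {
    utils::write.table(as.data.frame(df),
                       sub("\\.[a-zA-Z]+$", ".tsv", out_file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ggplot2::ggsave(out_file, p, width = 6, height = 4, dpi = 120)
  }
  invisible(p)
}

.dynamics_frame <- function(pc_series, channel_ids = NULL) {
  keep <- if (is.null(channel_ids)) {
    seq_along(pc_series$channel_ids)
  } else {
    # bipolar derived ids ('A09-A08') are matched via their superficial
    # contact so a stratum can be named by original contact ids
    which(pc_series$channel_ids %in% channel_ids |
            sub("-.*$", "", pc_series$channel_ids) %in% channel_ids)
  }
  if (length(keep) == 0) return(tibble::tibble())
  res <- list()
  for (cond in unique(pc_series$condition)) {
    tr <- which(pc_series$condition == cond)
    if (length(tr) < 2) {
      stop("need at least 2 trials per stratum for a confidence ribbon",
           call. = FALSE)
    }
    # average the stratum's channels within trial, then mean/CI over trials
    trial_mean <- apply(pc_series$pc[keep, tr, , drop = FALSE], c(2, 3), mean)
    m <- colMeans(trial_mean)
    se <- apply(trial_mean, 2, stats::sd) / sqrt(length(tr))
    tcrit <- stats::qt(0.975, length(tr) - 1)
    res[[cond]] <- tibble::tibble(
      series = paste(pc_series$montage_tag, cond, sep = "/"),
      time_s = pc_series$times_s, mean_pc = m,
      ci_lo = m - tcrit * se, ci_hi = m + tcrit * se)
  }
  dplyr::bind_rows(res)
}
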