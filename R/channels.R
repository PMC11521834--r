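#' @importFrom rlang .data
NULL

#' Anatomical category vocabulary for depth-electrode contacts
#'
#' Closed five-value vocabulary used to classify every SEEG contact:
#' `deep_wm` (white matter deeper than the bottoms of two adjacent sulci),
#' `shallow_wm` (white matter more superficial than that), `gray`
#' (cerebral cortex), `csf` (ventricle or subarachnoid space) and
#' `outside` (outside the arachnoid surface of the brain).
#'
#' @export
contact_categories <- c("deep_wm", "shallow_wm", "gray", "csf", "outside")

#' Construct a validated channel table
#'
#' The channel table is the per-contact metadata every pipeline stage
#' consults: shaft membership, position along the shaft, 3-D coordinates in
#' millimetres, anatomical category and the clinical exclusion flags
#' (seizure-onset zone, irritative zone, continuous artifact).
#'
#' @param x A data frame with columns `contact_id`, `shaft_id`,
#'   `contact_index` (integer, 1 = deepest contact of the shaft), `x`, `y`,
#'   `z` (mm), `category` (one of [contact_categories]), `is_soz`,
#'   `is_irritative`, `is_artifact` (logical).
#' @return A tibble of class `seeg_channels`.
#' @export
channel_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("contact_id", "shaft_id", "contact_index", "x", "y", "z",
                "category", "is_soz", "is_irritative", "is_artifact")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("channel table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$contact_id <- as.character(x$contact_id)
  x$shaft_id <- as.character(x$shaft_id)
  x$contact_index <- as.integer(x$contact_index)
  for (col in c("x", "y", "z")) x[[col]] <- as.numeric(x[[col]])
  x$category <- as.character(x$category)
  for (col in c("is_soz", "is_irritative", "is_artifact")) {
    x[[col]] <- .as_flag(x[[col]], col)
  }

  if (anyDuplicated(x$contact_id)) {
    dup <- unique(x$contact_id[duplicated(x$contact_id)])
    stop("duplicate contact_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !(x$category %in% contact_categories)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown category '%s' at row %d (contact_id '%s'); must be one of: %s",
                 x$category[i], i, x$contact_id[i],
                 paste(contact_categories, collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(as.matrix(x[, c("x", "y", "z")])))) {
    stop("contact coordinates must be finite", call. = FALSE)
  }
  dup_idx <- x |>
    dplyr::count(.data$shaft_id, .data$contact_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_idx) > 0) {
    stop("contact_index must be unique within shaft (shaft ",
         dup_idx$shaft_id[1], ", index ", dup_idx$contact_index[1], ")",
         call. = FALSE)
  }
  class(x) <- c("seeg_channels", class(x))
  x
}

.as_flag <- function(v, name) {
  if (is.logical(v)) return(v)
  if (is.numeric(v) && all(v %in% c(0, 1))) return(v == 1)
  if (is.character(v) && all(toupper(v) %in% c("TRUE", "FALSE", "0", "1"))) {
    return(toupper(v) %in% c("TRUE", "1"))
  }
  stop("flag column '", name, "' must be logical or 0/1", call. = FALSE)
}

#' Read a channel table from a tab-separated file
#'
#' Expected header:
#' `contact_id shaft_id contact_index x y z category is_soz is_irritative is_artifact`.
#'
#' @param path Path to a TSV file.
#' @return A `seeg_channels` tibble (see [channel_table()]).
#' @export
read_channel_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  channel_table(df)
}

#' Write a channel table to a tab-separated file
#'
#' @param channels A `seeg_channels` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_table <- function(channels, path) {
  stopifnot(inherits(channels, "seeg_channels"))
  utils::write.table(as.data.frame(channels), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.seeg_channels <- function(x, ...) {
  cat(sprintf("<seeg_channels> %d contacts on %d shaft(s)\n",
              nrow(x), length(unique(x$shaft_id))))
  tab <- table(factor(x$category, levels = contact_categories))
  cat("  categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  NextMethod()
}
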