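#' Construct a montage transform
#'
#' A montage transform is an explicit linear re-referencing operator: a
#' derived-channel x recorded-channel weight matrix plus per-derived-channel
#' metadata. Usually built with [build_car()], [build_bipolar()] or
#' [build_laplacian()]; the raw constructor is exposed for audits and tests.
#'
#' @param weights Numeric matrix, derived x recorded; column names must be
#'   recorded channel ids.
#' @param derived_ids Character vector of derived-channel ids.
#' @param derived_category Anatomical category per derived channel.
#' @param scheme `"car"`, `"bipolar"` or `"laplacian"`.
#' @param included_in_average For CAR only: ids of the channels entering
#'   the average.
#' @return A list of class `seeg_montage`.
#' @export
montage_transform <- function(weights, derived_ids = rownames(weights),
                              derived_category = NULL,
                              scheme = c("car", "bipolar", "laplacian"),
                              included_in_average = character(0)) {
  scheme <- match.arg(scheme)
  weights <- as.matrix(weights)
  if (is.null(colnames(weights))) {
    stop("weights must have recorded channel ids as column names", call. = FALSE)
  }
  if (is.null(derived_ids)) derived_ids <- sprintf("d%03d", seq_len(nrow(weights)))
  rownames(weights) <- derived_ids
  structure(list(weights = weights, derived_ids = derived_ids,
                 derived_category = derived_category, scheme = scheme,
                 included_in_average = included_in_average),
            class = "seeg_montage")
}

#' Common average reference montage
#'
#' The average is computed over channels that carry no exclusion flag and
#' whose category is neither `outside` nor `csf` (clinically: seizure-onset
#' zone, irritative zone, artifactual, extracranial and CSF channels do not
#' contribute to the reference). The subtraction is then applied to every
#' channel of the supplied table — including `outside` contacts, which are
#' analyzed under CAR even though they never enter the average.
#'
#' @param channels A [channel_table()] restricted to the channels of the
#'   recording the transform will be applied to (see [select_channels()]).
#' @return A `seeg_montage` with one derived channel per input channel;
#'   derived categories equal the recorded categories.
#' @export
build_car <- function(channels) {
  stopifnot(inherits(channels, "seeg_channels"))
  eligible <- !channels$is_soz & !channels$is_irritative &
    !channels$is_artifact & !(channels$category %in% c("outside", "csf"))
  n_avg <- sum(eligible)
  if (n_avg < 2) {
    stop("CAR averaging set is empty or degenerate (", n_avg,
         " eligible channel(s); need >= 2)", call. = FALSE)
  }
  n <- nrow(channels)
  w <- diag(1, n)
  w[, eligible] <- w[, eligible] - 1 / n_avg
  colnames(w) <- channels$contact_id
  montage_transform(w, derived_ids = channels$contact_id,
                    derived_category = channels$category, scheme = "car",
                    included_in_average = channels$contact_id[eligible])
}

#' Bipolar montage
#'
#' Each contact is referenced to its adjacent neighbour on the deeper side
#' of the same shaft (contact index 1 = deepest): the derived channel for
#' contact k (k >= 2) is `contact_k - contact_{k-1}`. The deepest contact
#' of each shaft yields no derived channel. Adjacency is strict on
#' `contact_index`: if the deeper neighbour is missing from the table
#' (excluded), the pair is broken, never bridged. Each derived channel
#' inherits the identity and anatomical category of its superficial
#' (non-reference) contact.
#'
#' @inheritParams build_car
#' @return A `seeg_montage`.
#' @export
build_bipolar <- function(channels) {
  stopifnot(inherits(channels, "seeg_channels"))
  .adjacency_montage(channels, scheme = "bipolar")
}

#' Laplacian montage
#'
#' Each interior contact is referenced to the average of its two shaft
#' neighbours: derived = contact - (deeper + superficial) / 2. Shaft-end
#' contacts yield no derived channel (the scheme cannot measure responses
#' at the ends of a depth electrode), and a missing neighbour breaks the
#' derivation rather than being bridged. Derived channels inherit the
#' centre contact's identity and category.
#'
#' @inheritParams build_car
#' @return A `seeg_montage`.
#' @export
build_laplacian <- function(channels) {
  stopifnot(inherits(channels, "seeg_channels"))
  .adjacency_montage(channels, scheme = "laplacian")
}

.adjacency_montage <- function(channels, scheme) {
  n <- nrow(channels)
  idx_of <- function(shaft, k) {
    which(channels$shaft_id == shaft & channels$contact_index == k)
  }
  rows <- list()
  ids <- character(0)
  cats <- character(0)
  for (i in seq_len(n)) {
    k <- channels$contact_index[i]
    shaft <- channels$shaft_id[i]
    deeper <- idx_of(shaft, k - 1)
    if (scheme == "bipolar") {
      if (length(deeper) != 1) next
      w <- numeric(n)
      w[i] <- 1
      w[deeper] <- -1
      rows[[length(rows) + 1]] <- w
      ids <- c(ids, paste0(channels$contact_id[i], "-",
                           channels$contact_id[deeper]))
      cats <- c(cats, channels$category[i])
    } else {
      sup <- idx_of(shaft, k + 1)
      if (length(deeper) != 1 || length(sup) != 1) next
      w <- numeric(n)
      w[i] <- 1
      w[deeper] <- -0.5
      w[sup] <- -0.5
      rows[[length(rows) + 1]] <- w
      ids <- c(ids, channels$contact_id[i])
      cats <- c(cats, channels$category[i])
    }
  }
  weights <- do.call(rbind, c(rows, list(matrix(0, 0, n))))
  colnames(weights) <- channels$contact_id
  montage_transform(weights, derived_ids = ids, derived_category = cats,
                    scheme = scheme)
}

#' Apply a montage transform to a recording
#'
#' Pure linear map: derived data = weights x recorded data. The recording's
#' channel order must match the transform's columns (a permutation is
#' resolved by name; a genuine mismatch is an error).
#'
#' @param rec A [recording()].
#' @param transform A `seeg_montage`.
#' @return A derived [recording()] with `montage_tag` set to the scheme.
#' @export
apply_montage <- function(rec, transform) {
  stopifnot(inherits(rec, "seeg_recording"), inherits(transform, "seeg_montage"))
  w <- transform$weights
  if (!identical(colnames(w), rec$channel_ids)) {
    if (setequal(colnames(w), rec$channel_ids)) {
      w <- w[, rec$channel_ids, drop = FALSE]
    } else {
      stop("recording channels do not match montage transform columns",
           call. = FALSE)
    }
  }
  recording(w %*% rec$data, fs = rec$fs,
            channel_ids = transform$derived_ids,
            montage_tag = transform$scheme)
}

#' Export a montage transform's weight matrix as TSV for audit
#'
#' @param transform A `seeg_montage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage_tsv <- function(transform, path) {
  stopifnot(inherits(transform, "seeg_montage"))
  df <- data.frame(derived_id = transform$derived_ids,
                   derived_category = transform$derived_category %||%
                     NA_character_,
                   transform$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.seeg_montage <- function(x, ...) {
  cat(sprintf("<seeg_montage> %s: %d derived from %d recorded channel(s)\n",
              x$scheme, nrow(x$weights), ncol(x$weights)))
  invisible(x)
}
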