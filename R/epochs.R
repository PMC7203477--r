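#' Epoched EEG dataset
#'
#' The universal currency of the package: a 3-D array of epoched trials with
#' per-trial metadata.  The array axis convention is fixed as
#' `(trial, channel, time)`; a single trial is therefore a channels x bins
#' matrix, the orientation the pair comparator consumes.
#'
#' @param data Numeric array of dim `(n_trials, n_channels, n_timepoints)`,
#'   in microvolts when raw, dimensionless after [scale_amplitudes()].
#' @param meta Data frame with one row per trial and at least the columns
#'   `subject_id` (character/factor), `trial_id` (integer, unique within
#'   subject) and `class_label` (one of `labels`).  Extra columns are kept.
#' @param sampling_rate Sampling rate in Hz.
#' @param labels Declared class label set; defaults to the labels present.
#' @param is_binned Whether time-bin averaging has been applied.
#' @param bin_width Bin width in ms when binned, `NA` otherwise.
#' @return An object of class `epoch_dataset`.
#' @seealso [validate_epochs()], [scale_amplitudes()], [bin_time_average()]
#' @export
epoch_dataset <- function(data, meta, sampling_rate,
                          labels = NULL, is_binned = FALSE, bin_width = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_invalid("`data` must be a 3-D array (trial, channel, time)")
  }
  meta <- as_tibble(meta)
  need <- c("subject_id", "trial_id", "class_label")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop_format(paste0("metadata is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (nrow(meta) != dim(data)[1]) {
    stop_format(sprintf("metadata has %d rows but data has %d trials",
                        nrow(meta), dim(data)[1]))
  }
  meta$subject_id <- as.character(meta$subject_id)
  meta$trial_id <- as.integer(meta$trial_id)
  meta$class_label <- as.character(meta$class_label)
  labels <- labels %||% sort(unique(meta$class_label))
  structure(
    list(data = data, meta = meta,
         sampling_rate = as.numeric(sampling_rate),
         labels = as.character(labels),
         is_binned = isTRUE(is_binned),
         bin_width = as.numeric(bin_width)),
    class = "epoch_dataset"
  )
}

#' @export
print.epoch_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_dataset> %d trials x %d channels x %d %s\n",
              d[1], d[2], d[3], if (x$is_binned) "bins" else "timepoints"))
  cat(sprintf("  subjects: %d | classes: %s | %g Hz%s\n",
              length(unique(x$meta$subject_id)),
              paste(x$labels, collapse = "/"),
              x$sampling_rate,
              if (x$is_binned) sprintf(" | bin width %g ms", x$bin_width) else ""))
  invisible(x)
}

#' @export
dim.epoch_dataset <- function(x) dim(x$data)

#' Number of trials in a dataset
#' @param ds An [epoch_dataset()].
#' @return Integer trial count.
#' @export
n_trials <- function(ds) dim(ds$data)[1]

#' Keep only the trials at the given indices
#' @param ds An [epoch_dataset()].
#' @param idx Integer or logical trial index vector.
#' @return A new `epoch_dataset`.
#' @export
subset_trials <- function(ds, idx) {
  ds$data <- ds$data[idx, , , drop = FALSE]
  ds$meta <- ds$meta[idx, , drop = FALSE]
  ds
}

#' Keep only the trials of the given subjects
#' @param ds An [epoch_dataset()].
#' @param subjects Character vector of subject ids.
#' @return A new `epoch_dataset`.
#' @export
filter_subjects <- function(ds, subjects) {
  subset_trials(ds, ds$meta$subject_id %in% subjects)
}

#' Validate an epoch dataset without throwing
#'
#' Checks every container invariant and returns a report listing each
#' violation; an empty report means the dataset is valid.  Unlike the
#' constructors, this never throws, so it can be used to triage a
#' questionable container.
#'
#' @param ds An [epoch_dataset()].
#' @return A tibble with columns `rule`, `message` and (where applicable)
#'   `trial`, `channel`, `bin`; zero rows iff the dataset is valid.
#'   Class `ptc_validation`, serializable to JSON with [jsonlite::toJSON()].
#' @export
validate_epochs <- function(ds) {
  rows <- list()
  add <- function(rule, message, trial = NA_integer_,
                  channel = NA_integer_, bin = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble(
      rule = rule, message = message,
      trial = trial, channel = channel, bin = bin)
  }
  if (nrow(ds$meta) != dim(ds$data)[1]) {
    add("meta_rows", sprintf("metadata has %d rows for %d trials",
                             nrow(ds$meta), dim(ds$data)[1]))
  }
  bad <- which(!is.finite(ds$data))
  if (length(bad) > 0) {
    d <- dim(ds$data)
    for (i in head(bad, 20L)) {
      i0 <- i - 1L
      add("finite_values", "non-finite value",
          trial = i0 %% d[1] + 1L,
          channel = (i0 %/% d[1]) %% d[2] + 1L,
          bin = i0 %/% (d[1] * d[2]) + 1L)
    }
  }
  unknown <- setdiff(unique(ds$meta$class_label), ds$labels)
  if (length(unknown) > 0) {
    add("label_set", paste0("class labels outside declared set: ",
                            paste(unknown, collapse = ", ")))
  }
  dup <- ds$meta %>%
    dplyr::count(.data$subject_id, .data$trial_id) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    for (i in seq_len(nrow(dup))) {
      add("trial_id_unique",
          sprintf("trial_id %d duplicated within subject %s",
                  dup$trial_id[i], dup$subject_id[i]),
          trial = dup$trial_id[i])
    }
  }
  out <- if (length(rows) == 0) {
    tibble(rule = character(), message = character(),
           trial = integer(), channel = integer(), bin = integer())
  } else {
    bind_rows(rows)
  }
  class(out) <- c("ptc_validation", class(out))
  out
}

#' Rescale amplitudes by a fixed divisor
#'
#' Divides every value by a constant, by default 20, chosen so that raw
#' microvolt EEG lands approximately in the -1..1 range where network
#' optimization behaves well.  Linear, so it commutes with
#' [bin_time_average()].
#'
#' @param ds An [epoch_dataset()].
#' @param divisor Positive scale divisor (default 20).
#' @return A new `epoch_dataset`; the input is unmodified.
#' @export
scale_amplitudes <- function(ds, divisor = 20) {
  if (!is.numeric(divisor) || length(divisor) != 1L || !is.finite(divisor) ||
      divisor <= 0) {
    stop_invalid("`divisor` must be a single positive number")
  }
  ds$data <- ds$data / divisor
  ds
}

#' Average consecutive timepoints into non-overlapping bins
#'
#' Replaces each consecutive group of `factor` timepoints by its arithmetic
#' mean.  At the canonical 250 Hz sampling rate with `factor = 10` this
#' yields 40 ms bins, reducing a 31 x 370 trial to the 31 x 37 = 1147
#' features the classifiers consume.  When `factor` does not divide the
#' epoch length, trailing remainder samples are dropped.
#'
#' @param ds An [epoch_dataset()].
#' @param factor Positive integer decimation factor (default 10).
#' @return A new binned `epoch_dataset` with
#'   `bin_width = factor / sampling_rate * 1000` ms.
#' @export
bin_time_average <- function(ds, factor = 10) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop_invalid("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  d <- dim(ds$data)
  if (factor > d[3]) {
    stop_invalid(sprintf("bin factor %d exceeds epoch length %d", factor, d[3]))
  }
  n_bins <- d[3] %/% factor
  kept <- ds$data[, , seq_len(n_bins * factor), drop = FALSE]
  dim(kept) <- c(d[1] * d[2], factor, n_bins)
  binned <- colMeans(aperm(kept, c(2L, 1L, 3L)))
  dim(binned) <- c(d[1], d[2], n_bins)
  ds$data <- binned
  ds$is_binned <- TRUE
  ds$bin_width <- factor / ds$sampling_rate * 1000
  ds
}

container_version <- "ptcnet-epochs-1"

#' Save an epoch dataset to an on-disk container
#'
#' The container is a directory holding the 3-D array in Arrow/feather form
#' (`epochs.feather`, one row per trial x channel, bit-exact doubles), the
#' per-trial metadata as UTF-8 CSV (`metadata.csv`) and the dataset
#' attributes plus a format version as JSON (`attrs.json`).  Round trips are
#' lossless for data, metadata and flags.
#'
#' @param ds An [epoch_dataset()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ds$data)
  mat <- matrix(aperm(ds$data, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  tab <- as_tibble(mat, .name_repair = ~ sprintf("t%04d", seq_len(d[3])))
  tab <- dplyr::bind_cols(
    tibble(trial = rep(seq_len(d[1]), each = d[2]),
           channel = rep(seq_len(d[2]), times = d[1])),
    tab)
  arrow::write_feather(tab, file.path(path, "epochs.feather"))
  readr::write_csv(ds$meta, file.path(path, "metadata.csv"))
  attrs <- list(format = container_version,
                n_trials = d[1], n_channels = d[2], n_timepoints = d[3],
                sampling_rate = ds$sampling_rate,
                labels = ds$labels,
                is_binned = ds$is_binned,
                bin_width = ds$bin_width)
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Load an epoch dataset from an on-disk container
#'
#' @param path Directory written by [save_epochs()].
#' @return An [epoch_dataset()].
#' @export
load_epochs <- function(path) {
  for (f in c("epochs.feather", "metadata.csv", "attrs.json")) {
    if (!file.exists(file.path(path, f))) {
      stop_format(sprintf("container is missing %s", f))
    }
  }
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"),
                               simplifyVector = TRUE)
  if (!identical(attrs$format, container_version)) {
    stop_format(sprintf("unknown container format version '%s' (expected '%s')",
                        attrs$format %||% "<missing>", container_version))
  }
  tab <- arrow::read_feather(file.path(path, "epochs.feather"))
  meta <- readr::read_csv(file.path(path, "metadata.csv"),
                          show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "trial_id", "class_label")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop_format(paste0("container metadata is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  d <- c(attrs$n_trials, attrs$n_channels, attrs$n_timepoints)
  if (nrow(tab) != d[1] * d[2] || ncol(tab) != d[3] + 2L) {
    stop_format("epochs table shape does not match recorded dimensions")
  }
  if (nrow(meta) != d[1]) {
    stop_format(sprintf("container metadata has %d rows but %d trials recorded",
                        nrow(meta), d[1]))
  }
  mat <- as.matrix(tab[, -(1:2)])
  arr <- aperm(array(mat, dim = c(d[2], d[1], d[3])), c(2L, 1L, 3L))
  epoch_dataset(arr, meta, sampling_rate = attrs$sampling_rate,
                labels = attrs$labels, is_binned = attrs$is_binned,
                bin_width = attrs$bin_width %||% NA_real_)
}
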