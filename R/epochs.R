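# Containers for epoched source-space data and derived objects.

#' Epoched source-space trial container
#'
#' @param data numeric array `[trials x regions x samples]`.
#' @param time_axis sample times in seconds, 0 = stimulus onset, strictly
#'   increasing.
#' @param sampling_rate Hz.
#' @param subject_id subject identifier.
#' @param group group label.
#' @param trial_labels per-trial condition labels (e.g. "correct" /
#'   "incorrect").
#' @param region_labels parcel names, one per region.
#' @param band optional `band_definition` if the data are band-limited.
#' @return a `source_epochs` object.
#' @export
source_epochs <- function(data, time_axis, sampling_rate, subject_id = "S01",
                          group = NA_character_, trial_labels = NULL,
                          region_labels = NULL, band = NULL) {
  d <- dim(data)
  if (length(d) != 3) stop("data must be a trials x regions x samples array")
  if (length(time_axis) != d[3])
    stop("time_axis length must equal the number of samples")
  if (any(diff(time_axis) <= 0)) stop("time_axis must be strictly increasing")
  stopifnot_finite(data, "epoch data")
  if (is.null(trial_labels)) trial_labels <- rep("correct", d[1])
  if (length(trial_labels) != d[1])
    stop("one trial label per trial required")
  if (is.null(region_labels)) region_labels <- sprintf("R%03d", seq_len(d[2]))
  structure(list(data = data, time_axis = time_axis,
                 sampling_rate = sampling_rate, subject_id = subject_id,
                 group = group, trial_labels = trial_labels,
                 region_labels = region_labels, band = band),
            class = "source_epochs")
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<source_epochs> %s (%s): %d trials x %d regions x %d samples @ %g Hz\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  time %.3f..%.3f s; band: %s\n", x$time_axis[1],
              x$time_axis[length(x$time_axis)],
              if (is.null(x$band)) "broadband" else x$band$name))
  invisible(x)
}

#' Select trials of one condition
#'
#' Returns the subset of trials whose label equals `condition`, preserving
#' trial order.
#'
#' @param epochs a `source_epochs`.
#' @param condition condition label to keep.
#' @return `source_epochs` restricted to the matching trials.
#' @export
select_condition_trials <- function(epochs, condition) {
  keep <- which(epochs$trial_labels == condition)
  if (!length(keep)) {
    counts <- table(epochs$trial_labels)
    stop(sprintf("no trials with condition '%s'; available: %s", condition,
                 paste(sprintf("%s (%d)", names(counts), counts),
                       collapse = ", ")))
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_labels <- epochs$trial_labels[keep]
  epochs
}

# Restrict any epoch-like array container to a half-open ms window.
crop_time <- function(x, window_ms) {
  idx <- window_index(x$time_axis, window_ms)
  x$data <- x$data[, , idx, drop = FALSE]
  x$time_axis <- x$time_axis[idx]
  x
}
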