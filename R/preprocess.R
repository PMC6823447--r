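# Filtering and trial screening.
#
# Filters follow the event-related MEG convention: design once with
# signal::butter, apply forward-backward (zero phase) per trial and region
# with MATLAB-style odd-reflection padding and steady-state initial
# conditions (compiled in src/filters.cpp). The epoch is filtered whole;
# analyses later truncate to -500..1250 ms so filter edge effects never
# reach a statistic.

# Steady-state (unit step) initial filter state; solves the same linear
# system MATLAB's filtfilt uses.
filt_zi <- function(b, a) {
  nord <- max(length(b), length(a))
  b <- c(b, rep(0, nord - length(b)))
  a <- c(a, rep(0, nord - length(a)))
  if (nord == 1) return(numeric(0))
  if (nord == 2) return((b[2] - b[1] * a[2]) / (1 + a[2]))
  n1 <- nord - 1
  shift <- cbind(rbind(diag(n1 - 1), rep(0, n1 - 1)))
  A <- diag(n1) - cbind(-a[2:nord], shift)
  solve(A, b[2:nord] - b[1] * a[2:nord])
}

# Zero-phase filtering of every column of a samples x traces matrix, with
# the conventional odd-reflection pad of 3 * (order) samples and
# steady-state initial conditions (the MATLAB filtfilt scheme). Narrowband
# designs still ring near the epoch edges; the pipeline filters the full
# -1..2 s epoch and truncates to the analysis window afterwards, so those
# transients never reach a statistic.
filtfilt_mat <- function(x, b, a) {
  b <- b / a[1]; a <- a / a[1]
  nord <- max(length(b), length(a))
  npad <- 3L * (nord - 1L)
  min_len <- 3L * npad + 1L
  if (nrow(x) < min_len)
    stop(sprintf(
      "epoch too short to filter: %d samples, minimum %d for this filter",
      nrow(x), min_len))
  root_mag <- max(Mod(polyroot(rev(a))))
  if (root_mag >= 1)
    stop("designed filter is unstable; widen the band or lower the order")
  cpp_filtfilt(x, b, a, filt_zi(b, a), npad)
}

# Apply a cascade of (b, a) filters to all trials/regions of an epochs
# object.
apply_filters <- function(epochs, filters) {
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(3, 1, 2)), d[3], d[1] * d[2])
  for (f in filters) m <- filtfilt_mat(m, f$b, f$a)
  epochs$data <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Broadband filter with power-line notch
#'
#' Zero-phase (two-pass) 4th-order Butterworth band-pass, default 1-150 Hz,
#' followed by a two-pass second-order IIR notch (quality factor `notch_q`)
#' at the power-line frequency.
#'
#' @param epochs a `source_epochs`.
#' @param f_low,f_high band-pass edges, Hz.
#' @param notch notch frequency, Hz (`NULL` to skip).
#' @param order Butterworth order.
#' @param notch_q notch quality factor.
#' @return filtered `source_epochs` (same shape).
#' @export
broadband_filter <- function(epochs, f_low = 1, f_high = 150, notch = 60,
                             order = 4, notch_q = 30) {
  fs <- epochs$sampling_rate
  if (fs <= 300) stop("sampling rate must exceed 300 Hz")
  bp <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  filters <- list(list(b = bp$b, a = bp$a))
  if (!is.null(notch)) {
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha) / (1 + alpha)
    filters <- c(filters, list(list(b = b, a = a)))
  }
  apply_filters(epochs, filters)
}

#' Band-pass filter into an analysis band
#'
#' Zero-phase 4th-order Butterworth band-pass into `band`; the band is
#' recorded on the returned object.
#'
#' @param epochs a `source_epochs`.
#' @param band a [frequency_band()].
#' @param order Butterworth order.
#' @return band-limited `source_epochs`.
#' @export
band_filter <- function(epochs, band, order = 4) {
  fs <- epochs$sampling_rate
  if (band$f_high >= fs / 2)
    stop(sprintf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
                 band$f_high, fs / 2))
  bp <- signal::butter(order, c(band$f_low, band$f_high) / (fs / 2),
                       type = "pass")
  out <- apply_filters(epochs, list(list(b = bp$b, a = bp$a)))
  out$band <- band
  out
}

#' Screen trials by head motion and sensor amplitude
#'
#' A trial is rejected if strictly more than 10% of its samples lie strictly
#' beyond 5 mm from the reference head position, or if any channel's peak
#' absolute amplitude strictly exceeds 2000 fT. When both rules fire, the
#' motion rule is recorded as the reason.
#'
#' @param traces an `artifact_traces` aligned with `epochs` by trial.
#' @param epochs the `source_epochs` being screened.
#' @param motion_mm,motion_frac,amplitude_ft rule parameters.
#' @return a `screen_report` data frame with columns `trial`, `keep`,
#'   `reason` and attributes `n_kept` / `n_rejected`.
#' @export
screen_trials <- function(traces, epochs, motion_mm = 5, motion_frac = 0.10,
                          amplitude_ft = 2000) {
  n_trials <- dim(epochs$data)[1]
  if (nrow(traces$head_position) != n_trials ||
      nrow(traces$peak_amplitude) != n_trials)
    stop(sprintf("trial count mismatch: %d epochs vs %d / %d trace rows",
                 n_trials, nrow(traces$head_position),
                 nrow(traces$peak_amplitude)))
  frac <- rowMeans(traces$head_position > motion_mm)
  motion <- frac > motion_frac
  amplitude <- apply(abs(traces$peak_amplitude), 1, max) > amplitude_ft
  reason <- ifelse(motion, "motion", ifelse(amplitude, "amplitude", "none"))
  report <- data.frame(trial = seq_len(n_trials),
                       keep = !(motion | amplitude), reason = reason,
                       stringsAsFactors = FALSE)
  structure(report, class = c("screen_report", "data.frame"),
            n_kept = sum(report$keep), n_rejected = sum(!report$keep))
}

#' Drop rejected trials from an epochs object
#'
#' @param epochs a `source_epochs`.
#' @param report a `screen_report` from [screen_trials()].
#' @return `source_epochs` restricted to kept trials.
#' @export
apply_screen <- function(epochs, report) {
  keep <- which(report$keep)
  if (!length(keep)) stop("screening rejected every trial")
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_labels <- epochs$trial_labels[keep]
  epochs
}
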