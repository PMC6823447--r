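# Instantaneous phase and time-resolved wPLI connectivity.
#
# The weighted phase lag index at one time sample, across trials k, for the
# analytic signals z_i, z_j of two regions:
#
#   X_k  = z_ik * conj(z_jk)              (single-sample cross-spectrum)
#   wPLI = |sum_k Im(X_k)| / sum_k |Im(X_k)|,   0 when the denominator is 0.
#
# Values range from 0 (random phase differences) to 1 (constant phase
# difference); weighting by |Im| makes the estimator insensitive to
# zero-lag (volume-conduction-like) coupling.

#' Analytic signal of band-limited epochs
#'
#' Per trial and region, returns `x(t) + i * H[x](t)` where `H` is the
#' Hilbert transform; the argument is instantaneous phase and the modulus
#' instantaneous amplitude. The FFT is computed at the next 5-smooth length
#' (zero-padded, then truncated), which keeps the transform fast at prime
#' epoch lengths; edge effects are confined to the epoch ends that the
#' analysis window later discards.
#'
#' @param epochs a band-limited `source_epochs`.
#' @return an `analytic_epochs` with complex `data`.
#' @export
analytic_signal <- function(epochs) {
  stopifnot_finite(epochs$data, "epoch data")
  d <- dim(epochs$data)
  n <- d[3]
  m <- matrix(aperm(epochs$data, c(3, 1, 2)), n, d[1] * d[2])
  nfft <- nextn(n, c(2, 3, 5))
  if (nfft > n) m <- rbind(m, matrix(0, nfft - n, ncol(m)))
  h <- numeric(nfft)
  h[1] <- 1
  if (nfft %% 2 == 0) {
    h[nfft / 2 + 1] <- 1
    h[2:(nfft / 2)] <- 2
  } else {
    h[2:((nfft + 1) / 2)] <- 2
  }
  za <- mvfft(mvfft(m) * h, inverse = TRUE) / nfft
  za <- za[seq_len(n), , drop = FALSE]
  out <- epochs
  out$data <- aperm(array(za, c(n, d[1], d[2])), c(2, 3, 1))
  class(out) <- "analytic_epochs"
  out
}

#' Analytic-epochs container
#'
#' Wraps an existing complex trials-by-regions-by-samples array (e.g. one
#' constructed analytically) so it can feed [wpli_timeseries()] directly.
#'
#' @param data complex array `[trials x regions x samples]`.
#' @param time_axis seconds; defaults to samples at `sampling_rate`.
#' @param sampling_rate Hz.
#' @param band optional `band_definition`.
#' @param subject_id,trial_labels,region_labels metadata.
#' @return an `analytic_epochs` object.
#' @export
analytic_epochs <- function(data, time_axis = NULL, sampling_rate = 600,
                            band = NULL, subject_id = "S01",
                            trial_labels = NULL, region_labels = NULL) {
  d <- dim(data)
  if (length(d) != 3 || !is.complex(data))
    stop("data must be a complex trials x regions x samples array")
  if (is.null(time_axis)) time_axis <- (seq_len(d[3]) - 1) / sampling_rate
  if (is.null(trial_labels)) trial_labels <- rep("correct", d[1])
  if (is.null(region_labels)) region_labels <- sprintf("R%03d", seq_len(d[2]))
  structure(list(data = data, time_axis = time_axis,
                 sampling_rate = sampling_rate, subject_id = subject_id,
                 group = NA_character_, trial_labels = trial_labels,
                 region_labels = region_labels, band = band),
            class = "analytic_epochs")
}

#' @export
print.analytic_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<analytic_epochs> %s: %d trials x %d regions x %d samples\n",
              x$subject_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Time-resolved wPLI connectivity
#'
#' Computes the weighted phase lag index between all region pairs at every
#' time sample, across trials. The result is symmetric with a zero diagonal
#' and all values in `[0, 1]`.
#'
#' @param analytic an `analytic_epochs`.
#' @param trials optional integer vector of trials to use (default all).
#' @return a `conn_ts` object: `values` array `[samples x N x N]`, plus
#'   time axis, band, subject and condition metadata.
#' @export
wpli_timeseries <- function(analytic, trials = NULL) {
  z <- analytic$data
  if (!is.null(trials)) z <- z[trials, , , drop = FALSE]
  d <- dim(z)
  if (d[1] < 2) stop("wPLI needs at least 2 trials")
  stopifnot_finite(Mod(z), "analytic signal")
  vals <- cpp_wpli(as.complex(z), as.integer(d))
  condition <- unique(if (is.null(trials)) analytic$trial_labels
                      else analytic$trial_labels[trials])
  conn_ts(values = vals, time_axis = analytic$time_axis,
          band = analytic$band, subject_id = analytic$subject_id,
          condition = if (length(condition) == 1) condition else "all",
          region_labels = analytic$region_labels)
}

#' Connectivity timeseries container
#'
#' @param values array `[samples x N x N]`.
#' @param time_axis seconds.
#' @param band optional `band_definition`.
#' @param subject_id,condition provenance.
#' @param region_labels parcel names.
#' @param normalized whether values are baseline z-scores.
#' @param baseline_window ms pair used for normalization, when normalized.
#' @return a `conn_ts` object.
#' @export
conn_ts <- function(values, time_axis, band = NULL, subject_id = NA,
                    condition = NA, region_labels = NULL,
                    normalized = FALSE, baseline_window = NULL) {
  d <- dim(values)
  if (length(d) != 3 || d[2] != d[3])
    stop("values must be a samples x N x N array")
  if (length(time_axis) != d[1])
    stop("time axis length must equal the first dimension")
  structure(list(values = values, time_axis = time_axis, band = band,
                 subject_id = subject_id, condition = condition,
                 region_labels = region_labels, normalized = normalized,
                 baseline_window = baseline_window),
            class = "conn_ts")
}

#' @export
print.conn_ts <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<conn_ts> %s/%s: %d samples x %d x %d (%s, %s)\n", x$subject_id,
    x$condition, d[1], d[2], d[3],
    if (is.null(x$band)) "broadband" else x$band$name,
    if (x$normalized) "baseline z-scored" else "raw wPLI"))
  invisible(x)
}

#' Baseline z-score normalization of a connectivity timeseries
#'
#' Per edge, subtracts the mean and divides by the SD of that edge's own
#' baseline samples. The default SD uses the n - 1 (sample) convention;
#' `sd_method = "population"` divides by n.
#'
#' @param conn a raw `conn_ts`.
#' @param baseline ms pair, default the -500..0 ms pre-stimulus window.
#' @param sd_method "sample" (n - 1) or "population" (n).
#' @return normalized `conn_ts` (diagonal stays zero).
#' @export
zscore_to_baseline <- function(conn, baseline = c(-500, 0),
                               sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  if (isTRUE(conn$normalized)) stop("connectivity is already normalized")
  idx <- window_index(conn$time_axis, baseline)
  d <- dim(conn$values)
  n <- d[2]
  v <- matrix(conn$values, d[1], n * n)
  bm <- colMeans(v[idx, , drop = FALSE])
  bc <- sweep(v[idx, , drop = FALSE], 2, bm)
  bsd <- sqrt(colSums(bc^2) /
                (if (sd_method == "sample") length(idx) - 1 else length(idx)))
  off_diag <- as.vector(!diag(n))
  zero_sd <- off_diag & (bsd == 0 | !is.finite(bsd))
  if (any(zero_sd)) {
    bad <- sort(arrayInd(which(zero_sd)[1], c(n, n)))
    stop(sprintf("zero baseline SD on edge (%d, %d); cannot z-score",
                 bad[1], bad[2]))
  }
  z <- sweep(sweep(v, 2, bm), 2, pmax(bsd, .Machine$double.xmin), "/")
  z[, !off_diag] <- 0
  conn$values <- array(z, d)
  conn$normalized <- TRUE
  conn$baseline_window <- baseline
  conn
}

#' Mean whole-brain connectivity timeseries
#'
#' Per time sample, the mean over the `N (N - 1) / 2` unique region pairs.
#'
#' @param conn a `conn_ts` (raw or normalized).
#' @return a `wholebrain_ts`: numeric vector with time axis and provenance.
#' @export
mean_whole_brain <- function(conn) {
  d <- dim(conn$values)
  ut <- as.vector(upper.tri(matrix(0, d[2], d[2])))
  v <- matrix(conn$values, d[1], d[2] * d[2])
  structure(list(values = rowMeans(v[, ut, drop = FALSE]),
                 time_axis = conn$time_axis, band = conn$band,
                 subject_id = conn$subject_id, condition = conn$condition,
                 normalized = conn$normalized),
            class = "wholebrain_ts")
}

#' @export
print.wholebrain_ts <- function(x, ...) {
  cat(sprintf("<wholebrain_ts> %s/%s: %d samples (%s)\n", x$subject_id,
              x$condition, length(x$values),
              if (x$normalized) "z-scored" else "raw"))
  invisible(x)
}

#' Average over a time window
#'
#' Arithmetic mean over the samples whose time lies in the half-open window
#' `[start, end)` ms. For a `conn_ts` this yields an `N x N` edge matrix;
#' for a `wholebrain_ts`, a scalar.
#'
#' @param x a `conn_ts` or `wholebrain_ts`.
#' @param window ms pair.
#' @return matrix or scalar window mean.
#' @export
window_average <- function(x, window) UseMethod("window_average")

#' @export
window_average.conn_ts <- function(x, window) {
  idx <- window_index(x$time_axis, window)
  d <- dim(x$values)
  out <- matrix(colMeans(matrix(x$values, d[1], d[2] * d[2])[idx, ,
                                                             drop = FALSE]),
                d[2], d[2])
  dimnames(out) <- list(x$region_labels, x$region_labels)
  out
}

#' @export
window_average.wholebrain_ts <- function(x, window) {
  mean(x$values[window_index(x$time_axis, window)])
}

#' Per-subject connectivity pipeline
#'
#' Convenience wrapper running the standard chain for one subject: broadband
#' filter with notch, band filter, optional condition selection, analytic
#' signal, truncation to the analysis window, wPLI, and baseline z-scoring.
#'
#' @param epochs raw `source_epochs`.
#' @param band a [frequency_band()].
#' @param condition condition label to keep, or `NULL` for all trials.
#' @param analysis_window ms pair retained after filtering (edge-effect
#'   truncation).
#' @param zscore whether to z-score to baseline.
#' @param baseline baseline ms pair.
#' @param broadband whether to apply the broadband + notch stage first.
#' @param sd_method passed to [zscore_to_baseline()].
#' @return a `conn_ts`.
#' @export
subject_connectivity <- function(epochs, band, condition = NULL,
                                 analysis_window = c(-500, 1250),
                                 zscore = TRUE, baseline = c(-500, 0),
                                 broadband = TRUE,
                                 sd_method = "sample") {
  # condition selection first: filters act per trial, and this halves the
  # filtering work when only one condition is analysed
  if (!is.null(condition)) epochs <- select_condition_trials(epochs, condition)
  if (broadband) epochs <- broadband_filter(epochs)
  epochs <- band_filter(epochs, band)
  analytic <- analytic_signal(epochs)
  analytic <- crop_time(analytic, analysis_window)
  conn <- wpli_timeseries(analytic)
  if (zscore) conn <- zscore_to_baseline(conn, baseline,
                                         sd_method = sd_method)
  conn
}
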