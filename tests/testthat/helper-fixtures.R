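# Small in-code fixtures shared across test files.

# Analytic-epochs container straight from a complex array (bypasses the
# filtering/Hilbert chain so wPLI can be probed with exact inputs).
analytic_from_array <- function(z, time_axis = NULL, fs = 600,
                                labels = NULL) {
  analytic_epochs(z, time_axis = time_axis, sampling_rate = fs,
                  band = frequency_band("alpha", 8, 14),
                  region_labels = labels)
}

# conn_ts straight from a values array (samples x N x N).
conn_from_array <- function(values, time_axis, normalized = FALSE,
                            subject_id = "S01") {
  conn_ts(values = values, time_axis = time_axis,
          band = frequency_band("alpha", 8, 14), subject_id = subject_id,
          condition = "correct", normalized = normalized)
}

# Symmetric values array with given upper-triangle edge timeseries.
# edge_series: list mapping "i,j" to a numeric vector over samples.
values_from_edges <- function(n_regions, time_axis, edge_series) {
  Tn <- length(time_axis)
  v <- array(0, c(Tn, n_regions, n_regions))
  for (key in names(edge_series)) {
    ij <- as.integer(strsplit(key, ",")[[1]])
    v[, ij[1], ij[2]] <- edge_series[[key]]
    v[, ij[2], ij[1]] <- edge_series[[key]]
  }
  v
}

# One-trial source_epochs around a given single-region signal matrix
# (regions x samples replicated across trials).
epochs_from_signal <- function(x, fs = 600, time_axis = NULL,
                               n_trials = 1) {
  if (is.matrix(x)) nr <- nrow(x) else { x <- matrix(x, 1); nr <- 1 }
  ns <- ncol(x)
  if (is.null(time_axis)) time_axis <- (seq_len(ns) - 1) / fs
  dat <- array(0, c(n_trials, nr, ns))
  for (k in seq_len(n_trials)) dat[k, , ] <- x
  source_epochs(dat, time_axis, fs)
}

# Minimal simulator profile used by several tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_regions = 6, groups = list(FT = 2),
                   n_trials_per_condition = 4,
                   bands = default_bands()["alpha"], master_seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
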