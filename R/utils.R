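# Shared helpers: window arithmetic and small validators.
#
# Time axes are in seconds with 0 = stimulus onset; analysis windows are
# millisecond pairs interpreted half-open, [start, end).

# Indices of time-axis samples falling in a half-open ms window.
window_index <- function(time_s, window_ms) {
  if (length(window_ms) != 2L || window_ms[2] <= window_ms[1])
    stop("window must be an increasing ms pair")
  t_ms <- time_s * 1000
  eps <- 1e-9
  idx <- which(t_ms >= window_ms[1] - eps & t_ms < window_ms[2] - eps)
  if (length(idx) == 0L)
    stop(sprintf("window [%g, %g) ms contains no samples of the time axis",
                 window_ms[1], window_ms[2]))
  idx
}

# Window gating weight in [0, 1] with raised-cosine ramps at both edges,
# evaluated on the time axis. Avoids the broadband transients an abrupt
# phase-regime switch would create.
window_weight <- function(time_s, window_ms, ramp_ms = 50) {
  t_ms <- time_s * 1000
  w <- numeric(length(t_ms))
  lo <- window_ms[1]; hi <- window_ms[2]
  inside <- t_ms >= lo & t_ms < hi
  w[inside] <- 1
  if (ramp_ms > 0) {
    up <- inside & t_ms < lo + ramp_ms
    w[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - lo) / ramp_ms))
    dn <- inside & t_ms >= hi - ramp_ms
    w[dn] <- 0.5 * (1 - cos(pi * (hi - t_ms[dn]) / ramp_ms))
  }
  w
}

# Upper-triangle (i < j) edge index table for an N-node graph, in the fixed
# column-major order used throughout for subject-by-edge matrices.
edge_table <- function(n_regions) {
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, "j"], idx[, "i"]), , drop = FALSE]
}

# Deterministic child seed below 2^31 from a master seed and a counter.
child_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) %% 2147483647 + counter * 9973) %%
               2147483647)
}

# Maximal run length of TRUE values.
max_run_length <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# All runs of TRUE values as a (start, end, length) data frame.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what))
  invisible(x)
}
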