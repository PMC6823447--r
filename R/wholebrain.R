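# Supra-threshold cluster permutation test on whole-brain connectivity
# timeseries.
#
# The cluster statistic is the length of a maximal run of consecutive time
# samples whose t-statistic exceeds the threshold. Each permutation relabels
# the data (paired: independent per-subject condition swaps, equivalent to
# sign-flipping the per-subject difference; unpaired: group-label shuffle),
# recomputes the t-vector and records its largest supra-threshold run; an
# observed run is significant when strictly longer than the 95th percentile
# of the permutation null.

#' Stack whole-brain timeseries into a subjects-by-samples matrix
#'
#' @param ts_list list of `wholebrain_ts` sharing one time axis.
#' @return numeric matrix with the common time axis as attribute `"time"`.
#' @export
stack_wholebrain <- function(ts_list) {
  m <- do.call(rbind, lapply(ts_list, `[[`, "values"))
  rownames(m) <- vapply(ts_list, function(x) as.character(x$subject_id), "")
  attr(m, "time") <- ts_list[[1]]$time_axis
  m
}

#' Per-timepoint t-statistics between two timeseries sets
#'
#' Paired: one-sample t on the per-subject differences at each sample.
#' Unpaired: pooled-variance two-sample t. Samples with zero variance get
#' t = 0 by convention.
#'
#' @param series_a,series_b subjects-by-samples matrices (see
#'   [stack_wholebrain()]); for a paired test, same subjects in the same
#'   order.
#' @param paired logical.
#' @return numeric t-vector, one value per sample.
#' @export
timepoint_tstats <- function(series_a, series_b, paired = TRUE) {
  if (nrow(series_a) < 2 || nrow(series_b) < 2)
    stop("need at least 2 subjects per side")
  if (ncol(series_a) != ncol(series_b))
    stop("sample counts differ between the two sets")
  if (paired) {
    if (nrow(series_a) != nrow(series_b))
      stop("paired test requires equal subject counts")
    d <- series_a - series_b
    n <- nrow(d)
    m <- colMeans(d)
    v <- colSums(sweep(d, 2, m)^2) / (n - 1)
    t <- m / sqrt(v / n)
  } else {
    n1 <- nrow(series_a); n2 <- nrow(series_b)
    m1 <- colMeans(series_a); m2 <- colMeans(series_b)
    v1 <- colSums(sweep(series_a, 2, m1)^2) / (n1 - 1)
    v2 <- colSums(sweep(series_b, 2, m2)^2) / (n2 - 1)
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  }
  t[!is.finite(t)] <- 0
  t
}

# Largest supra-threshold run length for each row of a t matrix.
null_max_runs <- function(tmat, threshold, two_sided) {
  s <- if (two_sided) abs(tmat) > threshold else tmat > threshold
  apply(s, 1, max_run_length)
}

#' Cluster permutation test on whole-brain connectivity timeseries
#'
#' @param series_a,series_b subjects-by-samples matrices; for `paired =
#'   TRUE` rows must correspond to the same subjects.
#' @param n_perm number of permutations (>= 100).
#' @param t_threshold supra-threshold cut; observed and permuted t-vectors
#'   are thresholded at `t > t_threshold` (one-sided as is conventional for
#'   a directed contrast; set `two_sided = TRUE` for `|t|`).
#' @param alpha significance level for the max-run percentile.
#' @param paired logical.
#' @param two_sided threshold on `|t|` instead of `t`.
#' @param seed RNG seed; identical seeds give identical null distributions.
#' @return a `cluster_test` object: observed t-vector, cluster table with
#'   per-cluster corrected p-values (`p = (1 + #{null >= observed}) /
#'   (1 + n_perm)`), the null max-run distribution, the critical length
#'   (linear-interpolation percentile; ties are non-significant), and all
#'   parameters.
#' @export
cluster_permutation_test <- function(series_a, series_b, n_perm = 1000,
                                     t_threshold = 1.7, alpha = 0.05,
                                     paired = TRUE, two_sided = FALSE,
                                     seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  warnings <- character(0)
  if (1 / n_perm > alpha)
    warnings <- c(warnings, sprintf(
      "n_perm = %d cannot resolve alpha = %g", n_perm, alpha))
  if (!is.null(seed)) set.seed(seed)
  t_obs <- timepoint_tstats(series_a, series_b, paired = paired)
  supra <- if (two_sided) abs(t_obs) > t_threshold else t_obs > t_threshold
  clusters <- true_runs(supra)

  if (paired) {
    d <- series_a - series_b
    n <- nrow(d)
    ss <- colSums(d^2)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    m <- (signs %*% d) / n
    v <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
    tmat <- m / sqrt(v / n)
    tmat[!is.finite(tmat)] <- 0
    null <- null_max_runs(tmat, t_threshold, two_sided)
  } else {
    pooled <- rbind(series_a, series_b)
    n1 <- nrow(series_a)
    null <- vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(nrow(pooled))
      tp <- timepoint_tstats(pooled[idx[seq_len(n1)], , drop = FALSE],
                             pooled[idx[-seq_len(n1)], , drop = FALSE],
                             paired = FALSE)
      s <- if (two_sided) abs(tp) > t_threshold else tp > t_threshold
      max_run_length(s)
    }, numeric(1))
  }

  critical <- as.numeric(quantile(null, 1 - alpha, type = 7))
  time <- attr(series_a, "time")
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$length, function(len)
      (1 + sum(null >= len)) / (1 + n_perm), numeric(1))
    clusters$significant <- clusters$length > critical
    if (!is.null(time)) {
      clusters$start_ms <- time[clusters$start] * 1000
      clusters$end_ms <- time[clusters$end] * 1000
    }
    clusters <- clusters[order(clusters$p, -clusters$length), ]
  } else {
    clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(t_obs = t_obs, clusters = clusters,
                 null_distribution = null, critical_length = critical,
                 time_axis = time, warnings = warnings,
                 parameters = list(n_perm = n_perm, t_threshold = t_threshold,
                                   alpha = alpha, paired = paired,
                                   two_sided = two_sided, seed = seed)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<cluster_test> %s, t > %g, %d permutations, critical length %.1f\n",
    if (p$paired) "paired" else "unpaired", p$t_threshold, p$n_perm,
    x$critical_length))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("  no supra-threshold clusters\n")
  invisible(x)
}
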