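# Network-Based Statistic and masked network-sum group comparison.
#
# NBS controls the family-wise error rate of mass-univariate edge tests at
# the level of connected graph components: the observed retention-vs-
# baseline t-matrix is thresholded, its connected components are measured
# in edges, and each component's corrected p is the exceedance rate of its
# size in the permutation distribution of the maximal component size.

# Subjects-by-edges matrix of window-averaged connectivity.
edge_window_matrix <- function(conns, window) {
  n <- dim(conns[[1]]$values)[2]
  et <- edge_table(n)
  m <- t(vapply(conns, function(cn) {
    W <- window_average(cn, window)
    W[et]
  }, numeric(nrow(et))))
  rownames(m) <- vapply(conns, function(cn) as.character(cn$subject_id), "")
  attr(m, "edges") <- et
  attr(m, "n_regions") <- n
  m
}

# Subjects-by-edges matrix of the per-edge SD over a window's samples.
edge_window_sd <- function(conns, window) {
  n <- dim(conns[[1]]$values)[2]
  et <- edge_table(n)
  flat <- et[, 1] + (et[, 2] - 1) * n
  t(vapply(conns, function(cn) {
    idx <- window_index(cn$time_axis, window)
    v <- matrix(cn$values, dim(cn$values)[1], n * n)[idx, flat, drop = FALSE]
    apply(v, 2, sd)
  }, numeric(nrow(et))))
}

#' Edge-wise retention-vs-baseline contrast
#'
#' For every region pair, a paired t across subjects of the
#' baseline-referenced difference between the `window_a` and `window_b`
#' means of that edge's connectivity timeseries. Zero-variance edges get
#' t = 0 with a warning.
#'
#' Given *raw* wPLI timeseries, the per-subject statistic is
#' `(mean_a - mean_b) / sd_b` — identical to the `window_a` mean after
#' z-scoring to `window_b` — and the contrast also retains the
#' window-swapped counterpart `(mean_b - mean_a) / sd_a`, which [nbs()]
#' needs for an exactly exchangeable window-permutation null (the
#' normalization depends on the baseline window, so a plain sign flip of
#' the difference is not a true window swap). Given already-normalized
#' timeseries the swapped statistic is unavailable and downstream
#' permutation falls back to sign flips.
#'
#' @param conns list of `conn_ts` (raw preferred; normalized accepted), one
#'   per subject.
#' @param window_a,window_b ms pairs (defaults: retention 250-1250 vs
#'   baseline -500-0).
#' @return an `edge_contrast`: symmetric `t_matrix` with zero diagonal, the
#'   per-subject edge statistics (and swapped counterparts when available),
#'   and edge bookkeeping.
#' @export
edge_contrast <- function(conns, window_a = c(250, 1250),
                          window_b = c(-500, 0)) {
  if (length(conns) < 3) stop("need at least 3 subjects")
  A <- edge_window_matrix(conns, window_a)
  B <- edge_window_matrix(conns, window_b)
  D_swap <- NULL
  if (isTRUE(conns[[1]]$normalized)) {
    D <- A - B
  } else {
    sdA <- edge_window_sd(conns, window_a)
    sdB <- edge_window_sd(conns, window_b)
    tiny <- .Machine$double.xmin
    D <- (A - B) / pmax(sdB, tiny)
    D_swap <- (B - A) / pmax(sdA, tiny)
    D_swap[sdA == 0] <- 0
    D[sdB == 0] <- 0
  }
  n <- nrow(D)
  m <- colMeans(D)
  v <- colSums(sweep(D, 2, m)^2) / (n - 1)
  t <- m / sqrt(v / n)
  if (any(!is.finite(t))) {
    warning("zero-variance edge(s); their t set to 0")
    t[!is.finite(t)] <- 0
  }
  et <- attr(A, "edges")
  nr <- attr(A, "n_regions")
  tmat <- matrix(0, nr, nr)
  tmat[et] <- t
  tmat <- tmat + t(tmat)
  labels <- conns[[1]]$region_labels
  if (!is.null(labels)) dimnames(tmat) <- list(labels, labels)
  structure(list(t_matrix = tmat, diffs = D, diffs_swapped = D_swap,
                 edges = et, n_regions = nr,
                 window_a = window_a, window_b = window_b,
                 region_labels = labels),
            class = "edge_contrast")
}

# Maximal component size (edges or nodes) of the graph whose edges are the
# supra-threshold pairs, given edge indices into the edge table.
max_component_size <- function(edge_idx, et, size = "edges") {
  if (!length(edge_idx)) return(0L)
  g <- igraph::graph_from_edgelist(cbind(et[edge_idx, 1], et[edge_idx, 2]),
                                   directed = FALSE)
  comp <- igraph::components(g)
  if (size == "nodes") return(max(comp$csize))
  edge_comp <- comp$membership[et[edge_idx, 1]]
  max(tabulate(edge_comp))
}

#' Connected components of a supra-threshold adjacency
#'
#' @param adjacency symmetric logical/numeric matrix with zero diagonal;
#'   nonzero entries are the supra-threshold edges.
#' @param region_labels optional parcel names.
#' @return list of `network_component` objects (edges, nodes, counts, node
#'   degrees; `p_corrected` unset). Isolated nodes form no component.
#' @export
edge_components <- function(adjacency, region_labels = NULL) {
  adjacency <- adjacency != 0
  if (!isSymmetric(unname(adjacency)))
    stop("adjacency must be symmetric")
  diag(adjacency) <- FALSE
  n <- nrow(adjacency)
  et <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  if (!nrow(et)) return(list())
  g <- igraph::graph_from_edgelist(et, directed = FALSE)
  comp <- igraph::components(g)
  ids <- sort(unique(comp$membership[et[, 1]]))
  lapply(ids, function(id) {
    keep <- comp$membership[et[, 1]] == id
    edges <- et[keep, , drop = FALSE]
    nodes <- sort(unique(as.vector(edges)))
    deg <- tabulate(as.vector(edges), nbins = n)[nodes]
    names(deg) <- if (!is.null(region_labels)) region_labels[nodes]
                  else as.character(nodes)
    structure(list(edges = unname(edges), nodes = nodes,
                   n_edges = nrow(edges), n_nodes = length(nodes),
                   degree = deg, region_labels = region_labels,
                   p_corrected = NA_real_),
              class = "network_component")
  })
}

#' @export
print.network_component <- function(x, ...) {
  cat(sprintf("<network_component> %d edges, %d nodes%s\n", x$n_edges,
              x$n_nodes,
              if (is.na(x$p_corrected)) ""
              else sprintf(", p_corr = %.4g", x$p_corrected)))
  invisible(x)
}

#' Network-Based Statistic
#'
#' Thresholds the retention-vs-baseline edge contrast at `t > t_threshold`,
#' identifies connected components, and assigns each a corrected p-value
#' from the permutation distribution of the maximal component size.
#' Permutations swap each subject's window labels independently. With raw
#' input timeseries the swap is exact — the baseline normalization is
#' recomputed for the swapped labels, keeping the null exchangeable; with
#' pre-normalized input it degrades to sign-flipping the per-subject
#' difference, which is mildly anti-conservative because the statistic's
#' normalization depends on the baseline window.
#'
#' @param conns list of `conn_ts` (raw preferred), one per subject.
#' @param window_a,window_b contrast windows, ms.
#' @param t_threshold edge-forming threshold (one-sided `t >`).
#' @param n_perm permutations for the FWER null.
#' @param alpha component significance level.
#' @param seed RNG seed.
#' @param size component size measure, "edges" (default) or "nodes".
#' @return an `nbs_result`: components (with `p_corrected`, sorted by p),
#'   the null max-size distribution, the observed `edge_contrast`, and
#'   parameters.
#' @export
nbs <- function(conns, window_a = c(250, 1250), window_b = c(-500, 0),
                t_threshold = 2.0, n_perm = 5000, alpha = 0.05, seed = NULL,
                size = c("edges", "nodes")) {
  size <- match.arg(size)
  warnings <- character(0)
  if (n_perm < 1 / alpha)
    warnings <- c(warnings,
                  sprintf("n_perm = %d below 1/alpha = %g", n_perm, 1 / alpha))
  if (!is.null(seed)) set.seed(seed)
  ec <- edge_contrast(conns, window_a, window_b)
  et <- ec$edges
  t_obs <- ec$t_matrix[et]
  comps <- edge_components(ec$t_matrix * (ec$t_matrix > t_threshold),
                           ec$region_labels)

  D <- ec$diffs
  n <- nrow(D)
  null <- integer(n_perm)
  block <- 500L
  done <- 0L
  if (is.null(ec$diffs_swapped)) {
    # sign-flip fallback for pre-normalized input
    U <- matrix(0, n, ncol(D)); V <- D
  } else {
    # exact window swap: a permuted subject contributes the window-swapped,
    # re-normalized statistic, so rows are U + s * V with s = +-1
    U <- (D + ec$diffs_swapped) / 2
    V <- (D - ec$diffs_swapped) / 2
  }
  u_mean <- colMeans(U)
  uv_cross <- U * V
  ssq_base <- colSums(U^2) + colSums(V^2)
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    signs <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    m <- sweep((signs %*% V) / n, 2, u_mean, "+")
    ssq <- sweep(2 * (signs %*% uv_cross), 2, ssq_base, "+")
    v <- (ssq - n * m^2) / (n - 1)
    tmat <- m / sqrt(v / n)
    tmat[!is.finite(tmat)] <- 0
    for (p in seq_len(nb))
      null[done + p] <- max_component_size(which(tmat[p, ] > t_threshold),
                                           et, size)
    done <- done + nb
  }

  for (k in seq_along(comps)) {
    obs_size <- if (size == "edges") comps[[k]]$n_edges
                else comps[[k]]$n_nodes
    comps[[k]]$p_corrected <- (1 + sum(null >= obs_size)) / (1 + n_perm)
    comps[[k]]$significant <- comps[[k]]$p_corrected <= alpha
  }
  if (length(comps))
    comps <- comps[order(vapply(comps, `[[`, 0, "p_corrected"))]
  structure(list(components = comps, null_distribution = null,
                 contrast = ec, warnings = warnings,
                 parameters = list(window_a = window_a, window_b = window_b,
                                   t_threshold = t_threshold,
                                   n_perm = n_perm, alpha = alpha,
                                   seed = seed, size = size)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<nbs_result> t > %g, %d permutations, %d component(s)\n",
              p$t_threshold, p$n_perm, length(x$components)))
  for (cmp in x$components) print(cmp)
  invisible(x)
}

#' Node degrees of a network component, ranked
#'
#' Degree is the number of edges incident to a node; ties rank by node
#' index.
#'
#' @param component a `network_component`.
#' @return data frame (`node`, `label`, `degree`) in descending degree.
#' @export
node_degree <- function(component) {
  ord <- order(-component$degree, component$nodes)
  data.frame(node = component$nodes[ord],
             label = names(component$degree)[ord],
             degree = as.integer(component$degree[ord]),
             stringsAsFactors = FALSE)
}

#' Masked network-sum of connectivity
#'
#' Sums the window-averaged, baseline-z-scored connectivity over the edges
#' of one network mask, all other connections masked out: a single value
#' per subject quantifying how strongly that subject recruits the network.
#'
#' @param conn one subject's normalized `conn_ts`.
#' @param mask two-column matrix of edges (`i < j`), e.g.
#'   `component$edges`.
#' @param window ms pair, default the retention interval.
#' @return scalar network sum.
#' @export
network_sum <- function(conn, mask, window = c(250, 1250)) {
  mask <- matrix(as.integer(mask), ncol = 2)
  if (!nrow(mask)) stop("mask must contain at least one edge")
  n <- dim(conn$values)[2]
  if (any(mask < 1 | mask > n)) stop("mask references invalid regions")
  W <- window_average(conn, window)
  sum(W[mask])
}

#' Permutation test on per-subject network sums between groups
#'
#' Observed statistic: difference of group means. The null shuffles group
#' labels; the two-sided p is `(1 + #{|null| >= |obs|}) / (1 + n_perm)`.
#'
#' @param values_a,values_b per-subject network sums for the two groups.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return a `perm_test` with observed difference, p, null distribution and
#'   group sizes.
#' @export
group_permutation_test <- function(values_a, values_b, n_perm = 5000,
                                   seed = NULL) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("both groups need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(values_a) - mean(values_b)
  pooled <- c(values_a, values_b)
  n1 <- length(values_a)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled))
    mean(pooled[idx[seq_len(n1)]]) - mean(pooled[idx[-seq_len(n1)]])
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  structure(list(observed = obs, p = p, null_distribution = null,
                 n = c(length(values_a), length(values_b)),
                 values_a = values_a, values_b = values_b,
                 parameters = list(n_perm = n_perm, seed = seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> group mean difference %.4g, p = %.4g (n = %d vs %d)\n",
    x$observed, x$p, x$n[1], x$n[2]))
  invisible(x)
}
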