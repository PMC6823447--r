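# Edge contrasts, connected components, NBS, network sums.

# Build per-subject normalized conn_ts whose window means are prescribed:
# first two samples form window_b (0-2 ms), last two window_a (2-4 ms).
conns_with_diffs <- function(edge_diffs_per_subject, n_regions) {
  tv <- c(0, 1, 2, 3) / 1000
  lapply(seq_along(edge_diffs_per_subject), function(s) {
    series <- lapply(edge_diffs_per_subject[[s]], function(d)
      c(0, 0, d, d))
    v <- values_from_edges(n_regions, tv, series)
    conn_from_array(v, tv, normalized = TRUE,
                    subject_id = sprintf("S%02d", s))
  })
}

test_that("edge contrasts reproduce hand-computed paired t-values", {
  conns <- conns_with_diffs(list(list("1,2" = 1), list("1,2" = 2),
                                 list("1,2" = 3)), 3)
  # only edge (1, 2) varies; the untouched edges legitimately warn
  ec <- suppressWarnings(edge_contrast(conns, window_a = c(2, 4),
                                       window_b = c(0, 2)))
  expect_equal(ec$t_matrix[1, 2], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(ec$t_matrix[2, 1], ec$t_matrix[1, 2])
  expect_true(all(diag(ec$t_matrix) == 0))
  # same window twice -> all-zero t (zero variance path, with warning)
  expect_warning(ec0 <- edge_contrast(conns, window_a = c(0, 2),
                                      window_b = c(0, 2)),
                 "zero-variance")
  expect_true(all(ec0$t_matrix == 0))
  expect_error(edge_contrast(conns[1:2], c(2, 4), c(0, 2)), "3 subjects")
})

test_that("connected components split supra-threshold graphs correctly", {
  adj <- matrix(0, 7, 7)
  for (e in list(c(1, 2), c(2, 3), c(5, 6)))
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  comps <- edge_components(adj)
  expect_length(comps, 2)
  expect_equal(sort(vapply(comps, `[[`, 0L, "n_edges")), c(1L, 2L))
  # empty adjacency
  expect_length(edge_components(matrix(0, 4, 4)), 0)
  # complete graph on 4 nodes
  k4 <- 1 - diag(4)
  c4 <- edge_components(k4)
  expect_length(c4, 1)
  expect_equal(c4[[1]]$n_edges, 6L)
  expect_equal(c4[[1]]$n_nodes, 4L)
  expect_true(all(c4[[1]]$degree == 3))
  expect_error(edge_components(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("components agree with a union-find reference on random graphs", {
  set.seed(13)
  for (rep in 1:100) {
    n <- 20
    adj <- matrix(0, n, n)
    n_e <- sample(0:25, 1)
    if (n_e > 0) {
      picks <- sample(n * (n - 1) / 2, n_e)
      et <- which(upper.tri(adj), arr.ind = TRUE)[picks, , drop = FALSE]
      adj[et] <- 1
      adj <- adj + t(adj)
    }
    got <- edge_components(adj)
    ref <- uf_components(which(adj == 1 & upper.tri(adj), arr.ind = TRUE),
                         n)
    expect_equal(length(got), length(ref))
    got_sets <- lapply(got, function(cm) cm$nodes)
    ref_sets <- lapply(ref, function(cm) cm$nodes)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(ref_sets, paste, "", collapse = ","))
  }
})

test_that("component bookkeeping and relabelling invariance hold", {
  set.seed(29)
  n <- 12
  adj <- matrix(0, n, n)
  et <- which(upper.tri(adj), arr.ind = TRUE)[sample(66, 14), ]
  adj[et] <- 1; adj <- adj + t(adj)
  comps <- edge_components(adj)
  for (cm in comps) {
    expect_equal(sum(cm$degree), 2 * cm$n_edges)
    expect_true(all(cm$degree >= 1))
    expect_equal(cm$n_nodes, length(cm$nodes))
  }
  # relabelling regions permutes components consistently
  perm <- sample(n)
  adj_p <- adj[order(perm), order(perm)]  # node k -> position perm-inverse
  comps_p <- edge_components(adj_p)
  sets <- function(cs) sort(vapply(cs, function(cm)
    paste(sort(cm$nodes), collapse = ","), ""))
  remapped <- sort(vapply(comps, function(cm)
    paste(sort(match(cm$nodes, order(perm))), collapse = ","), ""))
  expect_equal(sets(comps_p), remapped)
})

test_that("node degree ranks hubs with deterministic tie-breaks", {
  adj <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3)))
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  cm <- edge_components(adj)[[1]]
  deg <- node_degree(cm)
  expect_equal(deg$node, c(2, 1, 3))
  expect_equal(deg$degree, c(2L, 1L, 1L))
  # star on 5 nodes: hub degree 4
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  dstar <- node_degree(edge_components(star)[[1]])
  expect_equal(dstar$degree[1], 4L)
  expect_equal(dstar$node[1], 1)
  # single edge: both endpoints degree 1
  single <- matrix(0, 3, 3); single[1, 2] <- single[2, 1] <- 1
  expect_equal(node_degree(edge_components(single)[[1]])$degree, c(1L, 1L))
})

test_that("NBS recovers a planted component and reports consistent p-values", {
  set.seed(37)
  n_sub <- 10
  planted <- c("1,2", "2,3", "3,4")
  all_pairs <- apply(which(upper.tri(diag(6)), arr.ind = TRUE), 1,
                     function(e) paste(sort(e), collapse = ","))
  conns <- conns_with_diffs(lapply(seq_len(n_sub), function(s) {
    d <- as.list(rnorm(length(all_pairs), 0, 0.5))  # background noise
    names(d) <- all_pairs
    for (key in planted) d[[key]] <- rnorm(1, mean = 2, sd = 0.5)
    d
  }), 6)
  res <- nbs(conns, window_a = c(2, 4), window_b = c(0, 2),
             t_threshold = 2, n_perm = 500, seed = 11)
  expect_gt(length(res$components), 0)
  top <- res$components[[1]]
  expect_true(all(c("1,2", "2,3", "3,4") %in%
                    paste(top$edges[, 1], top$edges[, 2], sep = ",")))
  expect_lte(top$p_corrected, 0.05)
  # p-values recompute from the stored null and are monotone in size
  sizes <- vapply(res$components, `[[`, 0L, "n_edges")
  ps <- vapply(res$components, `[[`, 0, "p_corrected")
  for (k in seq_along(sizes))
    expect_equal(ps[k],
                 (1 + sum(res$null_distribution >= sizes[k])) /
                   (1 + res$parameters$n_perm))
  expect_true(all(diff(ps[order(-sizes)]) >= 0))
  # determinism
  res2 <- nbs(conns, window_a = c(2, 4), window_b = c(0, 2),
              t_threshold = 2, n_perm = 500, seed = 11)
  expect_identical(res$null_distribution, res2$null_distribution)
})

test_that("network sums mask and aggregate edges as specified", {
  tv <- c(0, 1) / 1000
  v <- values_from_edges(4, tv, list("1,2" = c(1.5, 1.5),
                                     "3,4" = c(-0.5, -0.5),
                                     "1,3" = c(9, 9)))
  cn <- conn_from_array(v, tv, normalized = TRUE)
  expect_equal(network_sum(cn, rbind(c(1, 2), c(3, 4)), window = c(0, 2)),
               1.0)
  expect_error(network_sum(cn, matrix(numeric(0), ncol = 2), c(0, 2)),
               "at least one edge")
  # mask of all edges equals n_edges times the whole-brain window mean
  all_edges <- which(upper.tri(diag(4)), arr.ind = TRUE)
  wb <- window_average(mean_whole_brain(cn), c(0, 2))
  expect_equal(network_sum(cn, all_edges, c(0, 2)), nrow(all_edges) * wb,
               tolerance = 1e-12)
})

test_that("group permutation test behaves at its extremes and is seeded", {
  same <- rep(c(1, 2, 3, 4), 2)
  r_same <- group_permutation_test(same[1:4], same[5:8], n_perm = 500,
                                   seed = 1)
  expect_gt(r_same$p, 0.9)
  sep <- group_permutation_test(rep(10, 8), rep(0, 8), n_perm = 5000,
                                seed = 2)
  expect_lt(sep$p, 0.005)
  # the attainable floor is 1 / (n_perm + 1)
  expect_gte(sep$p, 1 / 5001)
  r1 <- group_permutation_test(rnorm(5), rnorm(5), n_perm = 200, seed = 9)
  set.seed(123)  # outside seed must not matter
  r2 <- group_permutation_test(r1$values_a, r1$values_b, n_perm = 200,
                               seed = 9)
  expect_identical(r1$p, r2$p)
  expect_error(group_permutation_test(1, 1:3), "at least 2")
})
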