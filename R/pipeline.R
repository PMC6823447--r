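# Configuration, serialization, and the end-to-end pipeline runner.
#
# One YAML (or JSON) document mirrors simulation_config field for field;
# arrays travel as RDS, tables as TSV, results and the run manifest as
# JSON, networks additionally as GraphML. Every randomized stage takes an
# explicit seed; a run manifest with content digests witnesses that reruns
# are bit-identical.

#' Read a simulation configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`, mirroring
#'   [simulation_config()] field for field (`planted_networks` entries give
#'   `edges` as a list of two-element pairs).
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$bands))
    raw$bands <- lapply(raw$bands, function(b)
      frequency_band(b$name, b$f_low, b$f_high))
  if (!is.null(raw$planted_networks))
    raw$planted_networks <- lapply(raw$planted_networks, function(net) {
      net$edges <- do.call(rbind, lapply(net$edges, as.integer))
      do.call(planted_network, net)
    })
  if (!is.null(raw$epoch_window)) raw$epoch_window <- unlist(raw$epoch_window)
  if (!is.null(raw$task_windows))
    raw$task_windows <- lapply(raw$task_windows, unlist)
  do.call(simulation_config, raw)
}

#' Write a simulation configuration to YAML
#'
#' @param config a `sim_config`.
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$bands <- lapply(config$bands, unclass)
  out$planted_networks <- lapply(config$planted_networks, function(net) {
    net <- unclass(net)
    net$edges <- lapply(seq_len(nrow(net$edges)), function(k)
      as.integer(net$edges[k, ]))
    net
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Save / load epoch containers
#'
#' Epochs are stored one file per subject (RDS). [save_epochs()] returns
#' the written paths.
#'
#' @param epochs_list named list of `source_epochs`.
#' @param dir output directory (created if needed).
#' @return `save_epochs`: character vector of paths; `load_epochs`: named
#'   list of `source_epochs`.
#' @export
save_epochs <- function(epochs_list, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(epochs_list, function(ep) {
    path <- file.path(dir, paste0(ep$subject_id, "_epochs.rds"))
    saveRDS(ep, path)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(dir) {
  files <- sort(list.files(dir, pattern = "_epochs\\.rds$",
                           full.names = TRUE))
  if (!length(files)) stop(sprintf("no epoch files found under %s", dir))
  eps <- lapply(files, readRDS)
  names(eps) <- vapply(eps, function(ep) as.character(ep$subject_id), "")
  eps
}

#' Export a network component as TSV edge list and GraphML
#'
#' @param component a `network_component`.
#' @param path_tsv edge-list TSV path (`region_i`, `region_j`, labels).
#' @param path_graphml optional GraphML path.
#' @param region_labels parcel names (defaults to those on the component).
#' @export
export_component <- function(component, path_tsv, path_graphml = NULL,
                             region_labels = component$region_labels) {
  lab <- function(k) if (is.null(region_labels)) as.character(k)
                     else region_labels[k]
  el <- data.frame(region_i = component$edges[, 1],
                   region_j = component$edges[, 2],
                   label_i = lab(component$edges[, 1]),
                   label_j = lab(component$edges[, 2]))
  write.table(el, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_edgelist(component$edges, directed = FALSE)
    g <- igraph::induced_subgraph(g, component$nodes)
    igraph::V(g)$label <- lab(component$nodes)
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(path_tsv)
}

# MD5 digests of a set of files, named by basename.
file_digests <- function(paths) {
  d <- tools::md5sum(paths)
  names(d) <- basename(paths)
  as.list(d)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, screens trials, computes per-subject normalized
#' connectivity in one band for correct and incorrect trials, runs the
#' whole-brain cluster permutation test (correct vs incorrect, per group),
#' the within-group NBS (retention vs baseline, correct trials), the masked
#' network-sum group comparison using each group's significant components,
#' and the brain-behaviour correlations. All outputs plus a digest manifest
#' are written under `out_dir`.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @param band_name analysis band name (must exist in `config$bands`).
#' @param n_perm_cluster,n_perm_nbs,n_perm_group permutation counts.
#' @param seed seed for all inference-stage permutations.
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, band_name = "alpha",
                         n_perm_cluster = 1000, n_perm_nbs = 1000,
                         n_perm_group = 1000, seed = config$master_seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  band <- config$bands[[band_name]]
  if (is.null(band)) stop(sprintf("band '%s' not in config", band_name))
  log_stage <- function(fmt, ...) message(sprintf(paste0("[wplinet] ", fmt),
                                                  ...))

  log_stage("simulate: %d regions, %s subjects, %d trials/condition",
            config$n_regions,
            paste(unlist(config$groups), collapse = "+"),
            config$n_trials_per_condition)
  cohort <- make_cohort(config)

  reports <- mapply(screen_trials, cohort$artifacts, cohort$epochs,
                    SIMPLIFY = FALSE)
  kept <- mapply(apply_screen, cohort$epochs, reports, SIMPLIFY = FALSE)
  log_stage("screening: %d/%d trials kept",
            sum(vapply(reports, attr, 0, "n_kept")),
            sum(vapply(reports, nrow, 0)))

  groups <- names(config$groups)
  subj_group <- cohort$truth$subjects$group
  names(subj_group) <- cohort$truth$subjects$subject_id

  log_stage("connectivity: band %s (%g-%g Hz)", band$name, band$f_low,
            band$f_high)
  # raw wPLI feeds the NBS (exact window-swap null); z-scored versions
  # feed the whole-brain, network-sum and behaviour stages
  conn_correct_raw <- lapply(kept, subject_connectivity, band = band,
                             condition = "correct", zscore = FALSE)
  conn_correct <- lapply(conn_correct_raw, zscore_to_baseline)
  conn_incorrect <- lapply(kept, subject_connectivity, band = band,
                           condition = "incorrect")

  cluster_results <- list()
  nbs_results <- list()
  for (g in groups) {
    ids <- names(kept)[subj_group[names(kept)] == g]
    wb_c <- stack_wholebrain(lapply(conn_correct[ids], mean_whole_brain))
    wb_i <- stack_wholebrain(lapply(conn_incorrect[ids], mean_whole_brain))
    cluster_results[[g]] <- cluster_permutation_test(
      wb_c, wb_i, n_perm = n_perm_cluster, paired = TRUE, seed = seed)
    nbs_results[[g]] <- nbs(conn_correct_raw[ids], n_perm = n_perm_nbs,
                            seed = seed)
    log_stage("group %s: %d cluster(s), %d NBS component(s)", g,
              nrow(cluster_results[[g]]$clusters),
              length(nbs_results[[g]]$components))
  }

  # masked network-sum group contrasts using each group's significant
  # components
  group_tests <- list()
  for (g in groups) {
    comps <- Filter(function(cm) isTRUE(cm$significant),
                    nbs_results[[g]]$components)
    if (!length(comps)) next
    mask <- comps[[1]]$edges
    sums <- vapply(conn_correct, network_sum, numeric(1), mask = mask)
    other <- setdiff(groups, g)[1]
    ga <- names(sums)[subj_group[names(sums)] == g]
    gb <- names(sums)[subj_group[names(sums)] == other]
    group_tests[[g]] <- group_permutation_test(sums[ga], sums[gb],
                                               n_perm = n_perm_group,
                                               seed = seed)
  }

  bb <- brain_behaviour(conn_correct, cohort$behaviour)

  # outputs
  write.table(cohort$behaviour, file.path(out_dir, "behaviour.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  screen_df <- do.call(rbind, lapply(names(reports), function(id)
    cbind(subject_id = id, as.data.frame(reports[[id]]))))
  write.table(screen_df, file.path(out_dir, "screen_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  comp_files <- character(0)
  for (g in groups) {
    for (k in seq_along(nbs_results[[g]]$components)) {
      stub <- file.path(out_dir, sprintf("component_%s_%02d", g, k))
      export_component(nbs_results[[g]]$components[[k]],
                       paste0(stub, ".tsv"), paste0(stub, ".graphml"),
                       region_labels = cohort$truth$region_labels)
      comp_files <- c(comp_files, paste0(stub, ".tsv"),
                      paste0(stub, ".graphml"))
    }
  }
  results <- list(
    band = band$name,
    clusters = lapply(cluster_results, function(x)
      list(clusters = x$clusters, critical_length = x$critical_length,
           parameters = x$parameters)),
    nbs = lapply(nbs_results, function(x)
      list(components = lapply(x$components, function(cm)
        list(n_edges = cm$n_edges, n_nodes = cm$n_nodes,
             p_corrected = cm$p_corrected)),
        parameters = x$parameters)),
    group_tests = lapply(group_tests, function(x)
      list(observed = x$observed, p = x$p, n = x$n)),
    brain_behaviour = bb)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(truth_to_list(cohort$truth),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- c(file.path(out_dir, c("behaviour.tsv", "screen_report.tsv",
                                  "results.json", "truth.json")),
             comp_files)
  manifest <- list(
    package_version = as.character(packageVersion("wplinet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seeds = list(master_seed = config$master_seed, inference_seed = seed),
    stages = c("simulate", "screen", "connectivity", "cluster_test", "nbs",
               "group_tests", "brain_behaviour"),
    parameters = list(band = band_name, n_perm_cluster = n_perm_cluster,
                      n_perm_nbs = n_perm_nbs, n_perm_group = n_perm_group),
    digests = file_digests(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, screen = reports,
                 clusters = cluster_results, nbs = nbs_results,
                 group_tests = group_tests, brain_behaviour = bb,
                 manifest = manifest))
}

# JSON-friendly view of a sim_truth.
truth_to_list <- function(truth) {
  list(master_seed = truth$master_seed,
       subjects = truth$subjects,
       networks = lapply(truth$networks, function(net)
         list(band = net$band,
              edges = lapply(seq_len(nrow(net$edges)), function(k)
                as.integer(net$edges[k, ])),
              kappa = net$kappa, window = net$window, group = net$group,
              condition = net$condition, lags = net$lags,
              kappa_s = as.list(net$kappa_s))),
       seeds = truth$seeds,
       behaviour_link = truth$behaviour_link,
       task_windows = truth$task_windows)
}
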