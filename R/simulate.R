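# Coupled-oscillator cohort simulator.
#
# Each region's trial signal is a sum over frequency bands of a narrowband
# unit-amplitude oscillation plus broadband white noise. Band phase follows
# a bounded-drift frequency random walk (mean-reverting deviation around the
# band centre) so that independent regions decorrelate while keeping their
# power inside the band. Coupling is implemented in phase: a planted edge
# (i, j) pulls both endpoint phases toward a shared per-edge phase process
# (offset by a fixed nonzero lag) with weight kappa * w(t), where w(t) gates
# the network's active window with raised-cosine ramps; the region signal is
# the cosine of the resulting mixture angle, so amplitude stays unity and
# coupling never leaks into the amplitude weighting of downstream
# estimators. Outside the window, and for unplanted pairs, phases are
# independent.

#' Frequency band definition
#'
#' @param name band label.
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high`.
#' @return a `band_definition` list.
#' @export
frequency_band <- function(name, f_low, f_high) {
  if (!(f_low > 0 && f_high > f_low))
    stop("band edges must satisfy 0 < f_low < f_high")
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_definition")
}

#' Canonical analysis bands
#'
#' Theta 4-7, alpha 8-14, beta 15-30 and low gamma 30-55 Hz.
#' @return named list of [frequency_band()] objects.
#' @export
default_bands <- function() {
  list(theta = frequency_band("theta", 4, 7),
       alpha = frequency_band("alpha", 8, 14),
       beta = frequency_band("beta", 15, 30),
       low_gamma = frequency_band("low_gamma", 30, 55))
}

#' Planted coupling network
#'
#' Declares a set of edges that share band-specific phase coupling inside an
#' active window, for one group and condition.
#'
#' @param band band name (must match a configured band).
#' @param edges two-column matrix of region indices, `i < j` per row.
#' @param kappa coupling strength in `[0, 1]`.
#' @param window active window, ms pair (default the retention interval).
#' @param group group label the coupling applies to, or `NULL` for all.
#' @param condition trial condition the coupling applies to, or `NULL` for
#'   all trials.
#' @param kappa_range optional length-2 range; when given, each subject's
#'   realized coupling strength is drawn uniformly from it (recorded in the
#'   simulation truth), otherwise all subjects use `kappa`.
#' @return a `planted_network` list.
#' @export
planted_network <- function(band, edges, kappa, window = c(250, 1250),
                            group = NULL, condition = "correct",
                            kappa_range = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges[, 1] >= edges[, 2]))
    stop("planted edges must have i < j")
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (!is.null(kappa_range) &&
      (length(kappa_range) != 2 || any(kappa_range < 0 | kappa_range > 1)))
    stop("kappa_range must lie in [0, 1]")
  structure(list(band = band, edges = edges, kappa = kappa, window = window,
                 group = group, condition = condition,
                 kappa_range = kappa_range),
            class = "planted_network")
}

#' Simulation configuration
#'
#' Complete description of a synthetic cohort: parcellation size, sampling,
#' epoch and task windows, group sizes, bands, planted coupling networks,
#' noise, the accuracy-generating link, and the master seed from which every
#' random draw is derived.
#'
#' @param n_regions number of parcellation regions (labels from
#'   [aal_labels()]).
#' @param sampling_rate sampling rate, Hz.
#' @param epoch_window epoch extent in seconds relative to stimulus onset.
#' @param task_windows named list of ms windows (baseline, encoding,
#'   retention).
#' @param groups named list/vector of subjects per group.
#' @param n_trials_per_condition trials per condition per subject.
#' @param bands list of [frequency_band()]s used to build the signal.
#' @param planted_networks list of [planted_network()]s.
#' @param noise_sd broadband white-noise SD (amplitude units; each band
#'   oscillation has unit amplitude).
#' @param behaviour_link list with `intercept`, `slope`, `noise_sd` for the
#'   accuracy model `accuracy = intercept + slope * kappa_s + eps`.
#' @param artifact list with `p_motion`, `p_spike`, `block_frac` governing
#'   contaminated head-position / sensor-amplitude traces.
#' @param conditions trial conditions to simulate (default both); cohorts
#'   restricted to `"correct"` generate identical correct-trial data to a
#'   two-condition cohort with the same seed, at half the cost.
#' @param master_seed integer master seed.
#' @return a validated `sim_config` object.
#' @export
simulation_config <- function(n_regions = 90,
                              sampling_rate = 600,
                              epoch_window = c(-1, 2),
                              task_windows = list(baseline = c(-500, 0),
                                                  encoding = c(0, 250),
                                                  retention = c(250, 1250)),
                              groups = list(FT = 20, VPT = 15),
                              n_trials_per_condition = 40,
                              bands = default_bands(),
                              planted_networks = list(),
                              noise_sd = 0.5,
                              behaviour_link = list(intercept = 80, slope = 0,
                                                    noise_sd = 5),
                              artifact = list(p_motion = 0, p_spike = 0,
                                              block_frac = 0.2),
                              conditions = c("correct", "incorrect"),
                              master_seed = 1L) {
  if (!length(conditions) ||
      !all(conditions %in% c("correct", "incorrect")))
    stop("conditions must be a subset of {correct, incorrect}")
  cfg <- structure(
    list(n_regions = n_regions, sampling_rate = sampling_rate,
         epoch_window = epoch_window, task_windows = task_windows,
         groups = groups, n_trials_per_condition = n_trials_per_condition,
         bands = bands, planted_networks = planted_networks,
         noise_sd = noise_sd, behaviour_link = behaviour_link,
         artifact = artifact, conditions = conditions,
         master_seed = as.integer(master_seed)),
    class = "sim_config")
  validate_config(cfg)
  cfg
}

#' Desk-scale configuration
#'
#' A reduced profile (30 regions, 8 + 8 subjects, 40 trials per condition)
#' sized for routine testing; the full 90-region, 20 + 15 subject profile is
#' the [simulation_config()] default.
#'
#' @param ... overrides passed to [simulation_config()].
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(n_regions = 30, groups = list(FT = 8, VPT = 8),
                   n_trials_per_condition = 40)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

validate_config <- function(cfg) {
  ew_ms <- cfg$epoch_window * 1000
  for (w in cfg$task_windows)
    if (w[1] < ew_ms[1] || w[2] > ew_ms[2])
      stop("task windows must lie within the epoch window")
  if (any(unlist(cfg$groups) < 2)) stop("group sizes must be >= 2")
  band_names <- vapply(cfg$bands, `[[`, "", "name")
  for (net in cfg$planted_networks) {
    if (!net$band %in% band_names)
      stop(sprintf("planted network references unknown band '%s'", net$band))
    if (any(net$edges < 1 | net$edges > cfg$n_regions))
      stop("planted edges reference invalid region indices")
    if (net$window[1] < ew_ms[1] || net$window[2] > ew_ms[2])
      stop("planted network window must lie within the epoch window")
    if (!is.null(net$group) && !net$group %in% names(cfg$groups))
      stop(sprintf("planted network references unknown group '%s'", net$group))
  }
  # reject contradictory plants: same edge/band with overlapping window,
  # overlapping group and overlapping condition scope
  nets <- cfg$planted_networks
  if (length(nets) > 1) {
    for (u in seq_len(length(nets) - 1)) for (v in (u + 1):length(nets)) {
      a <- nets[[u]]; b <- nets[[v]]
      if (a$band != b$band) next
      if (!is.null(a$group) && !is.null(b$group) && a$group != b$group) next
      if (!is.null(a$condition) && !is.null(b$condition) &&
          a$condition != b$condition) next
      if (a$window[2] <= b$window[1] || b$window[2] <= a$window[1]) next
      ea <- paste(a$edges[, 1], a$edges[, 2])
      eb <- paste(b$edges[, 1], b$edges[, 2])
      dup <- intersect(ea, eb)
      if (length(dup))
        stop(sprintf(paste0("conflicting planted specifications for edge(s) ",
                            "%s in band '%s' with overlapping windows"),
                     paste(dup, collapse = "; "), a$band))
    }
  }
  invisible(cfg)
}

epoch_time_axis <- function(cfg) {
  n <- round(diff(cfg$epoch_window) * cfg$sampling_rate) + 1
  cfg$epoch_window[1] + (seq_len(n) - 1) / cfg$sampling_rate
}

# Bounded-drift band phase processes for a block of oscillators:
# instantaneous frequency is the band centre plus a mean-reverting (AR(1),
# rho = 0.995) deviation with stationary SD 0.2 * bandwidth, clipped at
# 0.45 * bandwidth; phase is its integral plus a uniform initial phase.
# Returns phases, instantaneous frequencies and initial phases (compiled
# kernel).
phase_walk_matrix <- function(n, ncol, band, fs) {
  bw <- band$f_high - band$f_low
  fc <- (band$f_high + band$f_low) / 2
  rho <- 0.995
  sd_target <- 0.2 * bw
  step_sd <- sd_target * sqrt(1 - rho^2)
  phi0 <- runif(ncol, 0, 2 * pi)
  d0 <- rnorm(ncol, 0, sd_target)
  eps <- matrix(rnorm(n * ncol, 0, step_sd), n, ncol)
  walk <- cpp_phase_walk(eps, d0, phi0, rho, 0.45 * bw, fc, fs)
  walk$phi0 <- phi0
  walk
}

# Resolve which planted networks are active for a (group, condition) pair.
active_networks <- function(cfg, group, condition) {
  keep <- vapply(cfg$planted_networks, function(net) {
    (is.null(net$group) || net$group == group) &&
      (is.null(net$condition) || net$condition == condition)
  }, logical(1))
  cfg$planted_networks[keep]
}

# Per-band incidence structure of the active networks: for each band, an
# edge list with network index, endpoints and role, and per-region incident
# counts.
band_incidence <- function(cfg, nets) {
  lapply(cfg$bands, function(band) {
    rows <- list()
    for (ni in seq_along(nets)) {
      net <- nets[[ni]]
      if (net$band != band$name) next
      for (ei in seq_len(nrow(net$edges)))
        rows[[length(rows) + 1]] <- c(net = ni, edge = ei,
                                      i = net$edges[ei, 1],
                                      j = net$edges[ei, 2])
    }
    if (!length(rows)) return(NULL)
    tab <- do.call(rbind, rows)
    deg <- tabulate(c(tab[, "i"], tab[, "j"]), nbins = cfg$n_regions)
    list(edges = tab, degree = deg)
  })
}

# Simulate one trial: regions x samples matrix. All draws come from the
# current RNG state (seeded per trial by the caller) in a fixed order:
# shared edge processes first (band by band, edge by edge), then per-region
# own phases, then broadband noise.
simulate_trial <- function(cfg, incidence, net_info, time_s) {
  n <- length(time_s)
  R <- cfg$n_regions
  fs <- cfg$sampling_rate
  x <- matrix(0, n, R)   # samples x regions, transposed on return
  for (bi in seq_along(cfg$bands)) {
    band <- cfg$bands[[bi]]
    inc <- incidence[[bi]]
    shared <- if (!is.null(inc))
      phase_walk_matrix(n, nrow(inc$edges), band, fs)
    own <- phase_walk_matrix(n, R, band, fs)
    if (is.null(inc)) {
      x <- x + cos(own$phase)
    } else {
      # Kuramoto-style phase coupling for the planted regions: blend the
      # instantaneous frequency toward the shared process and add a
      # sinusoidal pull, so the emitted oscillation keeps unit amplitude
      # and locks exactly at full coupling weight
      E <- nrow(inc$edges)
      pr <- sort(unique(as.integer(c(inc$edges[, "i"], inc$edges[, "j"]))))
      wgt <- matrix(0, n, E)
      lags <- numeric(E)
      for (k in seq_len(E)) {
        info <- net_info[[inc$edges[k, "net"]]]
        wgt[, k] <- info$kappa_s * info$weight
        lags[k] <- info$lags[inc$edges[k, "edge"]]
      }
      edges_local <- cbind(match(inc$edges[, "i"], pr),
                           match(inc$edges[, "j"], pr))
      bw <- band$f_high - band$f_low
      phi <- own$phase
      phi[, pr] <- cpp_phase_couple(
        own$freq[, pr, drop = FALSE], own$phi0[pr], shared$phase,
        shared$freq, edges_local, lags, wgt,
        inc$degree[pr], gain = bw, fs = fs)
      x <- x + cos(phi)
    }
  }
  t(x + matrix(rnorm(n * R, 0, cfg$noise_sd), n, R))
}

#' Generate a synthetic cohort
#'
#' Simulates every subject of the configured cohort: epoched source-space
#' trials for both conditions, artifact-screening traces, a behaviour table,
#' and a `sim_truth` object recording every seed, realized coupling strength
#' and contamination label needed to verify downstream recovery.
#'
#' Identical configuration and master seed reproduce the cohort bit-exactly.
#'
#' @param config a [simulation_config()].
#' @return list with elements `epochs` (list of `source_epochs`),
#'   `artifacts` (list of `artifact_traces`), `behaviour` (data frame) and
#'   `truth` (`sim_truth`).
#' @export
make_cohort <- function(config) {
  validate_config(config)
  time_s <- epoch_time_axis(config)
  labels <- aal_labels(config$n_regions)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(sum(unlist(config$groups)))),
    group = rep(names(config$groups), unlist(config$groups)),
    stringsAsFactors = FALSE)
  n_sub <- nrow(subjects)

  # cohort-level draws under the master seed: per-edge lags and per-subject
  # realized coupling strengths
  set.seed(config$master_seed)
  networks <- lapply(config$planted_networks, function(net) {
    n_e <- nrow(net$edges)
    lags <- sample(c(-1, 1), n_e, replace = TRUE) * runif(n_e, 0.3, 1.2)
    kappa_s <- if (is.null(net$kappa_range)) rep(net$kappa, n_sub)
               else runif(n_sub, net$kappa_range[1], net$kappa_range[2])
    names(kappa_s) <- subjects$subject_id
    c(unclass(net), list(lags = lags, kappa_s = kappa_s))
  })

  # overall per-subject coupling strength used by the behaviour link: mean
  # realized kappa over the networks that apply to the subject's group
  subjects$kappa <- vapply(seq_len(n_sub), function(s) {
    ks <- vapply(networks, function(net) {
      if (is.null(net$group) || net$group == subjects$group[s])
        net$kappa_s[s] else NA_real_
    }, numeric(1))
    ks <- ks[!is.na(ks)]
    if (length(ks)) mean(ks) else 0
  }, numeric(1))

  conditions <- config$conditions
  n_tr <- config$n_trials_per_condition
  trial_labels <- rep(conditions, each = n_tr)
  seeds <- matrix(0L, n_sub, length(trial_labels))
  epochs <- vector("list", n_sub)
  artifacts <- vector("list", n_sub)
  artifact_truth <- vector("list", n_sub)

  # downstream lookups need the lag/kappa-augmented networks
  aug_config <- config
  aug_config$planted_networks <- networks

  for (s in seq_len(n_sub)) {
    grp <- subjects$group[s]
    dat <- array(0, c(length(trial_labels), config$n_regions,
                      length(time_s)))
    for (cond in conditions) {
      nets <- active_networks(aug_config, grp, cond)
      incidence <- band_incidence(config, nets)
      net_info <- lapply(nets, function(net)
        list(kappa_s = net$kappa_s[s],
             weight = window_weight(time_s, net$window),
             lags = net$lags))
      for (k in which(trial_labels == cond)) {
        seeds[s, k] <- child_seed(config$master_seed, (s - 1) * 1e5 + k)
        set.seed(seeds[s, k])
        dat[k, , ] <- simulate_trial(config, incidence, net_info, time_s)
      }
    }
    epochs[[s]] <- source_epochs(
      data = dat, time_axis = time_s, sampling_rate = config$sampling_rate,
      subject_id = subjects$subject_id[s], group = grp,
      trial_labels = trial_labels, region_labels = labels)
    tr <- make_artifact_traces(
      epochs[[s]], p_motion = config$artifact$p_motion,
      p_spike = config$artifact$p_spike,
      block_frac = config$artifact$block_frac,
      seed = child_seed(config$master_seed, 555e5 + s))
    artifacts[[s]] <- tr
    artifact_truth[[s]] <- attr(tr, "truth")
  }
  names(epochs) <- names(artifacts) <- subjects$subject_id

  truth <- structure(
    list(subjects = subjects, networks = networks, seeds = seeds,
         behaviour_link = config$behaviour_link,
         artifact_labels = artifact_truth,
         master_seed = config$master_seed,
         region_labels = labels, task_windows = config$task_windows),
    class = "sim_truth")
  behaviour <- make_behaviour_table(
    truth, seed = child_seed(config$master_seed, 777e5))
  list(epochs = epochs, artifacts = artifacts, behaviour = behaviour,
       truth = truth)
}

#' Behaviour table from simulation truth
#'
#' Accuracy follows `intercept + slope * kappa_s + eps`,
#' `eps ~ Normal(0, noise_sd^2)`, clamped to `[0, 100]`; demographic columns
#' (age, sex, maternal education, IQ-like and recall-like standard scores)
#' are filled with plausible values so the table exercises the behavioural
#' statistics end to end.
#'
#' @param truth a `sim_truth` from [make_cohort()].
#' @param link list with `intercept`, `slope`, `noise_sd`; defaults to the
#'   link recorded in `truth`.
#' @param seed RNG seed.
#' @return data frame, one row per subject.
#' @export
make_behaviour_table <- function(truth, link = truth$behaviour_link,
                                 seed = 1L) {
  set.seed(seed)
  n <- nrow(truth$subjects)
  eps <- if (link$noise_sd > 0) rnorm(n, 0, link$noise_sd) else numeric(n)
  accuracy <- pmin(pmax(link$intercept + link$slope * truth$subjects$kappa +
                          eps, 0), 100)
  data.frame(
    subject_id = truth$subjects$subject_id,
    group = truth$subjects$group,
    age = round(rnorm(n, 6.6, 0.35), 2),
    sex = rep_len(c("M", "F"), n),
    maternal_education = sample(c("post-secondary", "university",
                                  "post-graduate"), n, replace = TRUE,
                                prob = c(0.15, 0.65, 0.20)),
    iq = round(rnorm(n, 110, 13), 1),
    accuracy = accuracy,
    digit_recall = round(rnorm(n, 109, 11), 1),
    block_recall = round(rnorm(n, 104, 14), 1),
    stringsAsFactors = FALSE)
}

#' Artifact-screening traces for one subject
#'
#' Builds per-trial head-position distance traces (mm) and per-trial,
#' per-channel peak amplitudes (fT). With probability `p_motion` a trial's
#' position trace exceeds 5 mm over a contiguous block covering `block_frac`
#' of its samples; with probability `p_spike` one channel's peak exceeds
#' 2000 fT. Ground-truth contamination labels are attached as attribute
#' `"truth"`. Channels are the source regions here: simulated cohorts carry
#' no separate sensor array, so the amplitude rule is exercised on
#' region-level traces.
#'
#' @param epochs `source_epochs` the traces belong to.
#' @param p_motion,p_spike contamination probabilities in `[0, 1]`.
#' @param block_frac fraction of samples covered by a motion block.
#' @param seed RNG seed.
#' @return an `artifact_traces` object.
#' @export
make_artifact_traces <- function(epochs, p_motion = 0, p_spike = 0,
                                 block_frac = 0.2, seed = 1L) {
  if (any(c(p_motion, p_spike) < 0 | c(p_motion, p_spike) > 1))
    stop("probabilities must lie in [0, 1]")
  set.seed(seed)
  n_trials <- dim(epochs$data)[1]
  n_chan <- dim(epochs$data)[2]
  n_samp <- dim(epochs$data)[3]
  head_position <- matrix(abs(rnorm(n_trials * n_samp, 1.2, 0.5)),
                          n_trials, n_samp)
  peak_amplitude <- matrix(runif(n_trials * n_chan, 400, 1500),
                           n_trials, n_chan)
  motion <- runif(n_trials) < p_motion
  spike <- runif(n_trials) < p_spike
  block <- max(1L, round(block_frac * n_samp))
  for (k in which(motion)) {
    start <- sample.int(n_samp - block + 1L, 1L)
    head_position[k, start:(start + block - 1L)] <- runif(block, 6, 9)
  }
  for (k in which(spike))
    peak_amplitude[k, sample.int(n_chan, 1L)] <- runif(1, 2100, 4000)
  structure(list(head_position = head_position,
                 peak_amplitude = peak_amplitude,
                 subject_id = epochs$subject_id),
            class = "artifact_traces",
            truth = data.frame(trial = seq_len(n_trials),
                               motion = motion, spike = spike))
}
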