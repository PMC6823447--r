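---
title: "Time-resolved wPLI networks: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved wPLI networks: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wplinet)
```

## What this package computes

`wplinet` analyses event-related source-space MEG recordings of a
working-memory task: trials epoched around stimulus onset (−1 to 2 s at
600 Hz), parcellated into up to 90 AAL regions, with a pre-stimulus
baseline (−500–0 ms), an encoding window (0–250 ms) and a retention
(maintenance) window (250–1250 ms). The scientific question it serves is
whether, and in which frequency band, inter-regional phase synchrony during
retention differs between conditions (correct vs incorrect responses) and
between groups (e.g. full-term vs very-preterm-born children), and whether
that synchrony predicts behavioural accuracy.

The analysis chain is:

1. **Preprocess** — zero-phase 4th-order Butterworth band-pass 1–150 Hz
   with a 60 Hz notch, band filtering into theta (4–7), alpha (8–14), beta
   (15–30) and low gamma (30–55 Hz), and trial screening by head motion
   (>10% of samples beyond 5 mm) and sensor amplitude (>2000 fT).
2. **Connectivity** — instantaneous phase by the analytic signal; the
   weighted phase lag index (wPLI) between every region pair at every time
   sample, across trials:
   \[
   \mathrm{wPLI}_{ij}(t) \;=\;
   \frac{\bigl|\sum_k \mathrm{Im}\, z_{ik}(t)\,\overline{z_{jk}(t)}\bigr|}
        {\sum_k \bigl|\mathrm{Im}\, z_{ik}(t)\,\overline{z_{jk}(t)}\bigr|},
   \]
   0 when the denominator vanishes. Values run from 0 (random phase
   differences) to 1 (constant phase difference) and discount the real
   cross-spectrum, making the estimator insensitive to zero-lag
   (volume-conduction-like) coupling. Edge timeseries are z-scored to the
   baseline window and averaged into whole-brain timeseries.
3. **Inference** — a supra-threshold cluster permutation test over time for
   whole-brain condition contrasts; the Network-Based Statistic (NBS) for
   retention-vs-baseline edge contrasts with FWER control by the maximal
   connected component; node degree for hub identification; a masked
   network-sum permutation test for group contrasts; Pearson correlations
   between retention connectivity and accuracy.
4. **Simulation** — a coupled-oscillator cohort generator with planted,
   band- and window-specific coupling networks and complete ground truth,
   used to validate every stage.

## The synthetic cohort model

No public data accompany the study design this pipeline targets, so the
package ships a generator whose output has the statistical structure the
analysis assumes, with known truth.

Each region's trial signal is a sum over bands of a unit-amplitude
narrowband oscillation plus broadband Gaussian noise (SD 0.5 by default,
i.e. in-band SNR well above 1 after band filtering). Band phase is the
integral of an instantaneous frequency that wanders around the band centre
as a bounded-drift random walk: a mean-reverting AR(1) deviation
(autocorrelation 0.995 per sample, stationary SD 0.2 × bandwidth, clipped
at 0.45 × bandwidth). This keeps ≥90% of each oscillation's power inside
its band while making independent regions decorrelate — a pure sinusoid
cohort would make wPLI degenerate, since equal-frequency deterministic
signals hold a constant phase difference forever.

Coupling is implemented in phase, Kuramoto-style. Each planted edge has
its own shared phase process ψ_e; an endpoint region with coupling weight
λ(t) = κ·w(t) (split equally over the node's incident planted edges)
integrates the blended instantaneous frequency
(1 − λ)·f_own + λ·f_shared plus a sinusoidal pull
λ·G·sin(ψ_e + lag_e − φ), with gain G equal to one bandwidth. The emitted
signal is the cosine of that phase — unit amplitude at any κ. Keeping
amplitude flat matters: wPLI is amplitude-weighted, and a coupling scheme
that also modulated amplitude inside the active window would shift the
estimator's small-sample bias on every pair touching a planted region,
smearing the planted network into a halo of spurious edges. At λ = 1 the
frequency blend removes all detuning, so the pull drives the phase error
to zero within ~1/(2πG) s (≈27 ms in alpha) and the edge locks at its
lag; at intermediate λ entrainment is partial and measured wPLI rises
monotonically with κ. The per-edge lag is drawn uniformly from
±[0.3, 1.2] rad; the range excludes 0 and π because wPLI is blind to
zero-lag (and anti-phase) coupling, so such plants would be undetectable
by construction. The gate w(t) is 1 inside the network's active window
and 0 outside, with 50 ms raised-cosine ramps so the regime switch does
not inject broadband transients that band filters would smear into
neighbouring windows. Shared processes are per-edge, not per-component,
so two regions that are not themselves planted as an edge stay uncoupled
even when they share a neighbour.

Seed discipline: one master seed drives everything. Cohort-level draws
(per-edge lags, per-subject realized κ, behaviour noise, artifact labels)
happen once under the master seed; each (subject, trial) then gets a child
seed from a splittable counter (master + 9973 × counter mod 2³¹ − 1),
recorded in the `sim_truth`, so any single trial can be regenerated
bit-exactly.

Behaviour: accuracy = intercept + slope·κ_s + ε, ε ~ N(0, σ²), clamped to
[0, 100], where κ_s is the subject's mean realized coupling strength.
Artifact traces emulate the two screening rules: with probability
`p_motion` a contiguous block of `block_frac` of a trial's head-position
samples exceeds 5 mm; with probability `p_spike` one channel's peak
crosses 2000 fT. In simulated cohorts the "channels" are the source
regions — there is no separate sensor array — which is sufficient to
exercise the screening logic.

What the generator does *not* emulate: volume conduction and field spread
(no forward model), 1/f background spectra, amplitude dynamics coupled to
phase, inter-subject anatomical variability, or non-stationary artifacts.
Passing tests on this cohort therefore demonstrate that the estimators and
permutation procedures are correct and calibrated under the assumed signal
model, not that the pipeline is robust to every property of real MEG.

## Numerical choices

- **Filters.** Designs come from `signal::butter` (order 4, applied
  forward–backward, so effectively 8th-order magnitude response with zero
  phase); the notch is a 2nd-order IIR of quality factor 30 — the standard
  power-line notch — also two-pass. Application uses the conventional
  odd-reflection pad of 3 × order samples with steady-state initial
  conditions (the MATLAB `filtfilt` scheme), with extended-precision state
  so that filtering is linear to ~1e−13 relative. Narrowband designs still
  ring near epoch edges; the pipeline therefore filters the whole −1..2 s
  epoch and truncates to −500..1250 ms before any statistic, which is why
  the epochs are cut so much wider than the analysis window.
- **Analytic signal.** The Hilbert transform FFT runs at the next 5-smooth
  length (zero-padded, truncated back): the native epoch length 1801 is
  prime, where a mixed-radix FFT degenerates. Padding perturbs only the
  epoch ends, which the analysis window discards.
- **wPLI conventions.** The estimator is the standard amplitude-weighted
  one, not the debiased-square variant. 0/0 (all imaginary components
  vanish) is defined as 0 — no phase-lag evidence, the conservative
  choice. The cross-spectrum is estimated per time sample from
  single-sample analytic products across trials, preserving full temporal
  resolution.
- **Baseline z-scoring** divides by the n−1 (sample) SD by default;
  `sd_method = "population"` divides by n. The choice shifts every edge by
  a common factor and does not affect any permutation statistic.
- **Windows** are half-open ms intervals [start, end), time 0 = stimulus
  onset; the 1 s retention window at 600 Hz covers exactly 600 samples.
- **Cluster test.** One-sided t > 1.7 by default, as is conventional for a
  directed contrast (|t| available). Paired permutations are independent
  per-subject condition swaps — equivalent to sign-flipping the
  per-subject difference — which respects within-subject pairing; group
  contrasts use label shuffles. Zero-variance samples get t = 0. The
  critical length is the linear-interpolation 95th percentile of the null
  max-run distribution; ties are non-significant (strict >). Cluster
  p-values use the exceedance convention (1 + #{null ≥ obs})/(1 + n_perm),
  so the attainable floor with 1000 permutations is ≈ 0.001.
- **NBS.** Component size is edge count (node count by option); the
  edge statistic is the baseline-referenced retention mean
  (R̄ − B̄)/s_B — identical to the retention mean after z-scoring to
  baseline, so it matches the network-sum scale. The
  retention-vs-baseline permutation is a per-subject window swap. A
  subtlety matters here: swapping window labels is *not* equivalent to
  sign-flipping the statistic, because the normalization itself is
  computed from the baseline window. wPLI is floor-bounded and skewed, so
  realizations with a low baseline mean also have a small baseline SD and
  a positive retention difference; the statistic therefore has a positive
  null mean, and a sign-flip null is anti-conservative (measured
  family-wise error ≈ 0.14 at nominal 0.05 on null cohorts). Given raw
  wPLI input, `nbs()` performs the exact swap — a permuted subject
  contributes (B̄ − R̄)/s_R, the statistic renormalized to the swapped
  baseline — which restores exchangeability and calibrates the FWER;
  the sign-flip approximation remains only as a documented fallback for
  pre-normalized input. The one-sided t > 2.0 edge-forming threshold is
  the conventional conservative choice. The unequal window lengths
  (1000 ms retention vs 500 ms baseline) make the two window means
  differentially precise; the package keeps plain means and leaves this
  asymmetry to the permutation null, which sees exactly the same
  asymmetry.
- **Connected components** are delegated to igraph; an independent
  union-find reference in the test suite checks exact agreement on 1000
  random graphs.
- **Behavioural statistics.** Printed t-values with df = n₁ + n₂ − 2 imply
  pooled-variance tests, so `pooled_t_from_summary` uses the pooled
  convention; chi-squares are Pearson without continuity correction (the
  corrected version does not reproduce the published 2×2 statistic).
  One published value is *not* recoverable from printed summaries: the age
  comparison works out to t = 1.357 from the rounded means/SDs, which
  rounds to 1.36 rather than the printed 1.37 — the printed statistic was
  evidently computed on unrounded ages. The digit-recall and block-recall
  t-values are likewise not recoverable under either pooled or Welch
  assumptions (plausibly missing-data n differences) and are not asserted.

## Validation design and problem sizes

The test suite validates the pipeline at three levels, with problem sizes
chosen for statistical adequacy at desk scale:

- **Exactness**: wPLI endpoints (constant lag → 1, balanced imaginary
  parts → 0), hand-computed t and z values, filter defining properties,
  screening boundary cases (10.0% at the motion fraction is kept, 2000 fT
  exactly is kept — both rules are strict inequalities, motion takes
  precedence in the recorded reason).
- **Oracle equivalence**: compiled wPLI vs a naive triple-loop reference
  (≤1e−12); igraph components vs union-find (exact, 1000 random 20-node
  graphs).
- **Calibration and recovery** on simulated cohorts:
  - type-I error of the cluster test on 200 null cohorts (κ = 0,
    8 subjects, 10 regions, 20 trials/condition, alpha band, 500
    permutations) — expected fraction of cohorts with any significant
    cluster ≈ 0.05 (the strict-inequality rule makes it mildly
    conservative);
  - NBS family-wise error on 100 null cohorts at the same profile;
  - recovery of a planted connected 10-edge alpha retention network
    (a path on 11 nodes, κ = 0.8, 10 subjects, 15 regions, 40
    trials/condition): a significant NBS component with edge-Jaccard
    ≥ 0.5 against truth, and a significant whole-brain cluster
    overlapping the retention window. The path topology (maximal degree
    2) is deliberate: the generator splits a node's coupling budget over
    its incident planted edges, so only a low-degree network expresses
    the nominal per-edge coupling strength;
  - sign recovery of the brain–behaviour correlation at a true
    connectivity–accuracy correlation of 0.6 and n = 15. The experiment
    first calibrates how faithfully the subject-level measure tracks the
    planted coupling (per-subject κ_s ~ U(0.15, 0.65) on disjoint
    low-gamma edges; low gamma because its short autocorrelation gives
    the baseline normalization the most effective degrees of freedom),
    then sets the behaviour noise so the end-to-end true correlation is
    0.6. Notably, the subject-level z-scored measure is intrinsically
    noisy in a way trial counts cannot repair: each subject's z-scale
    divides by a baseline SD estimated from few effective samples
    (window length × bandwidth), which is why the calibration step is
    part of the design.

The region and trial counts above are deliberately smaller than the full
90-region, 35-subject profile: type-I error and FWER are properties of the
permutation machinery, not of the parcellation size, and the reduced
profiles keep the full suite tractable on a laptop while leaving the
effects they must detect comfortably powered. The full-scale profile
remains available through `simulation_config()` defaults.

## Known limitations

- Component-forming statistics localize imperfectly by construction: any
  null edge that crosses the t > 2.0 threshold and touches a detected
  component joins it. Because the baseline-referenced edge statistic has a
  positive null mean (the baseline SD in its denominator is estimated from
  few effective samples and co-varies with the numerator), null edges
  cross that fixed threshold more often than the nominal t-tail suggests
  — roughly 5–10% instead of 4% at ten subjects. Family-wise error is
  still controlled (the permutation null sees the same inflation; see the
  calibration tests), but detected components carry extra adjoining edges,
  so the edge-level overlap between a detected component and a planted
  network is routinely diluted even when detection itself is certain.

- The generator's phase-mixing coupling is monotone in κ but
  approximately quadratic for small κ, so weak couplings (κ ≤ 0.3) sit
  close to the wPLI noise floor at realistic trial counts.
- wPLI is amplitude-weighted by design: per-trial amplitude fluctuations
  reweight trials. Only a common gain across trials leaves the estimator
  exactly invariant.
- The screening module evaluates the published rejection rules; it does not
  attempt ICA-based artifact identification (a manual step) or continuous
  head-motion correction.
- Epoch containers are serialized as RDS plus TSV/JSON sidecars; vendor
  MEG formats and HDF5 are out of scope.
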