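---
title: "Methods: selectivity-filter gating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity-filter gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfgating)
```

sfgating quantifies selectivity-filter (SF) gating of K⁺ channels from two
complementary data sources: single-channel patch-clamp recordings, and time
series extracted from molecular-dynamics simulations (ion pore-axis
coordinates, inter-residue distances). This vignette explains the models and
numerical procedures, the defaults and why they were chosen, and what the
synthetic generators do and do not emulate.

## Single-channel analysis

### Dead time of a Gaussian filter

A recording low-pass filtered with a Gaussian filter of −3 dB cutoff $f_c$
attenuates brief events. The *dead time* $T_d$ is the shortest rectangular
event whose filtered peak still reaches 50% of the true amplitude — the
detection limit of 50%-threshold idealization. `dead_time()` finds it
numerically: a unit pulse is rasterized at the digitization rate (default
$50 f_c$) with fractional-sample area weighting, convolved with the discrete
Gaussian kernel (time-domain SD $0.1325/f_c$, the standard −3 dB relation,
truncated at ±5 SD), and the width at which the peak equals 0.5 is bisected.
At $f_c = 1$ kHz this gives 0.179 ms, and $T_d \propto 1/f_c$ exactly. The
continuous-time closed form $T_d = 2\sigma\,\Phi^{-1}(3/4)$ serves as an
independent oracle in the tests.

Brief events are attenuated along the numeric pulse-response curve
(`pulse_response()`): 50% at $1\,T_d$, ≈99% (at the peak) by $4\,T_d$. Note
that the per-event amplitude rule below measures a *trimmed mean*, which at
$4\,T_d$ still includes part of the Gaussian edge rise and sits near 97%;
the ≥99% figure refers to the filtered peak.

### Idealization, dwell times, NPo

`threshold_idealize()` places thresholds midway between adjacent
conductance levels ($\mathrm{closed} + (k - \tfrac12)\,i_{unit}$,
$k = 1..N$), assigns each sample the number of thresholds crossed, and
constrains the level path to move one level per sample, so stacked channels
always traverse intermediate levels. The baseline is an explicit input, not
auto-detected: at low open probability automatic baseline detection is the
dominant error source, so it is better supplied (a helper is the mode of the
all-points histogram).

`dwell_statistics()` excludes the first and last events (censored) and
aggregates all levels ≥ 1 into the open class. No missed-event correction is
applied to dwell means. Open probability follows
$NPo = \sum_i i P_i$ with $P_i$ the fraction of total time at level $i$, and
$Po = NPo/N$; $N$ defaults to the maximum simultaneous open level observed.

### Boltzmann voltage dependence

The voltage dependence of $Po$ is fitted with
$$Po(V) = \frac{Po_{max}}{1 + \exp[z\delta\,(V - V_{1/2})/k_BT]},$$
with effective gating valence $z\delta$ (e₀), half-maximal voltage
$V_{1/2}$ (mV), and maximal open probability $Po_{max}$. The sign convention
makes $Po$ fall with depolarization, as for SF (inactivation-type) gating.
Fitting (`fit_boltzmann()`) is Levenberg–Marquardt weighted least squares
(weights $1/\mathrm{SEM}^2$ when per-point SEMs exist; whether published
fits were weighted is generally unstated, so weighting is an option,
default on). Restarts come from a deterministic 8-point grid
($V_{1/2}$ at the 25/50/75/90% quantiles of the voltage range ×
$z\delta \in \{0.5, 2\}$); the lowest weighted RSS wins, ties broken by
lower $z\delta$. The e-fold slope $k_BT/(z\delta e)$ in mV is reported
alongside $z\delta$ because it is robust to the assumed temperature
(default 295 K; recording temperature is typically unstated).

### Unitary currents from all-points histograms

`all_points_histogram()` bins every digitized sample (default 0.1 pA bins —
a typical choice, configurable, with edges on the bin-width grid so 0 pA is
always an edge and histograms are comparable across recordings). For
records with clear open and closed peaks, `fit_two_gaussian()` fits
$$f(I) = A_O e^{-[(I-I_O)/\omega_O]^2} + A_C e^{-[(I-I_C)/\omega_C]^2}$$
by Poisson-weighted least squares (weight $1/\mathrm{count}$, occupied bins
only — empty bins carry no information here and, given unit weights, dilute
the residual-variance estimate and shrink the confidence intervals).
$\omega$ is the Gaussian width ($\sqrt2 \times$ SD). The unitary current is
$I_O - I_C$. Initialization takes the two largest well-separated local
maxima; a histogram without a resolvable second component is rejected with
a pointer to the tail method.

For low-$Po$ records with brief openings the open peak is buried under
open↔closed transition samples and the histogram is skewed. On
semi-logarithmic coordinates, however, the extreme falls of the histogram
are the pure tails of the level Gaussians — parabolas in log space.
`fit_log_tails()` fits $\log(\mathrm{counts})$ of each outer tail to a
parabola (count-weighted, since $\mathrm{var}[\log c] \approx 1/c$); the
vertex estimates the level mean. The tail window runs inward from the
histogram end and is truncated one bin beyond the outermost *interior*
count maximum (the level apex), growing the search window while counts are
still rising at its inner edge. A fixed outermost-fraction window (the
obvious alternative) reaches into the transition shoulder on low-$Po$ data
and biases the open level low by several tenths of a pA, defeating the
purpose of the method; `tail_fraction` (default 0.15 of occupied bins)
remains the initial search depth.

### Per-event amplitudes and the duration cutoff

`event_amplitudes()` implements the standard truncation rules: the
amplitude of an opening is the mean current from $T_d$ after the opening
threshold crossing to $T_d$ before the closing crossing, minus the flanking
closed baseline (flanks trimmed by $T_d$ on each side; global closed mean
when both flanks are shorter than $2 T_d$). Openings shorter than
$2 T_d$ (0.358 ms at 1 kHz) use the current at the event midpoint.
`amplitude_histogram()` restricts to openings longer than $6 T_d$
(1.074 ms at 1 kHz) by default, long enough to reach full amplitude with
several samples to average.

## Simulation-derived analyses

### Geometry, permeation counting, current

`sf_geometry()` orders the K⁺ binding sites along the pore axis — cavity,
Scav, S4…S0, extracellular — as contiguous half-open z intervals
([lo, hi)); the default spacing of 0.31 nm is the canonical carbonyl-plane
separation, since site coordinates are structure-specific the geometry is a
required, documented config. The filter entry plane is the lower boundary
of Scav and the exit plane the upper boundary of S0; their placement is a
config decision, and counted currents are insensitive to it as long as the
planes bracket all filter sites (a traversal must cross both).

`count_crossings()` runs a three-zone state machine per ion
(below/inside/above): an outward permeation event requires entering the
filter from below and exiting above; partial entries that retreat count
zero. A z jump larger than $L_z/2$ between frames is treated as a
periodic-boundary wrap and resets the ion's state to unknown, preventing
phantom crossings. Current follows $I = (n_{out} - n_{in})\,e_0/t$
(pA with $t$ in ns), and membrane voltage from an applied field is
$V = E L_z$.

`site_occupancy()` reports presence probability (fraction of frames with
≥1 ion in the site) as the primary statistic — matching how occupancies
near 1 are quoted — with the mean ion count alongside.

### Free-energy profiles

`free_energy_profile()` computes $G(z) = -\ln[\rho(z)/\rho_{max}]$ in kT
units from binned ion density, anchored so the minimum over occupied bins
is zero; minima mark binding sites, maxima the barriers. Empty bins are
masked, never assigned an artificial value, and a temperature argument
converts to kJ/mol on request. The profile is shift-invariant and
recoverable by construction: sampling from $\exp(-G)$ and inverting
recovers a planted double well within 0.2 kT RMS at the sample sizes used
in the tests (2–3 × 10⁵ points over 60 bins).

### Event detection in distance series

`detect_hbond_break()` scores a hydrogen-bond break (e.g., D64–Y51, the
precursor of the aspartate flip) as the first time the distance exceeds a
threshold continuously for at least a persistence time. The default
threshold is 0.7 nm — the main-text criterion; a 1 nm variant appears in
some figure annotations and both are exposed. Persistence defaults to
20 ns; re-arming (for multi-event inspection) requires a 0.1 nm
hysteresis drop.

`detect_inactivation()` watches the two diagonal cross-filter distance
pairs (G63 CA–CA of opposite monomers): the first time either pair leaves
the conducting band for at least the persistence time, with direction
dilation (above) or constriction (below). The transition is treated as
irreversible — at most one event per replica, at first passage — matching
the observed once-per-simulation behaviour. No numeric conducting band is
published, so `conducting_band()` estimates baseline mean ± 3 SD from each
replica's initial 250 ns; this is a package decision, not a literature
value. Series are resampled onto a common grid by previous-value hold —
distances are never interpolated across gaps.

`classify_rotamer()` calls the glutamate side chain *vertical* when its
carboxylate proton sits within 0.25 nm of the aspartate carboxylate (the
vertical-state hydrogen bond averages 0.167 nm; the cutoff brackets it
while excluding the swung-out horizontal state); the alternative
G61-amide-distance criterion (0.200 nm anchor) can be implemented with the
same function on that distance series.

`align_on_event()` aligns replicas at their (first) event time and averages
across replicas per lag, SEM across replicas (bootstrap SEMs would also be
defensible; across-replica SEM was chosen as the simpler, assumption-free
option). Per-monomer indicator columns are averaged first, so 1.0 means an
event in all four monomers simultaneously.

`delta_pka()` converts a deprotonation free energy to a pKa shift,
$\Delta pK_a = \Delta G / (2.303\,RT)$, and reports the absolute pKa
relative to the glutamate solution value of 4 (default 298 K, the
free-energy-calculation temperature).

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *recording and simulation conditions* with
exact ground truth:

- `simulate_gating_trace()`: continuous-time Markov gating (Gillespie
  dwells), rasterized by fractional-sample area weighting (sub-sample
  events attenuate realistically rather than rounding away), white
  Gaussian noise added before Gaussian filtering at the recording cutoff.
  The noise spectrum of real recordings is unpublished; white-before-filter
  is an assumption, not a claim. Defaults: 50 kHz sampling, 1 kHz filter,
  0.4 pA noise SD (the noise scale quoted for the recordings).
- `mthk_presets()` carries the printed study conditions: WT 200 mV dwells
  23.6 ms open / 58.2 ms closed and 14.78 pA amplitude; V55E 200 mV
  0.41 ms / 9.11 ms and 8.98 pA; Boltzmann parameters $V_{1/2}$ = 190 mV
  (200 mM K⁺) or 95 mV (5 mM K⁺) with a 14 mV e-fold slope at 295 K.
  $Po_{max}$ is not printed for the WT fit (the plateau is "> 0.9"); the
  preset uses 0.95, chosen once.
- `simulate_po_voltage()`: per-sweep binomial sampling around the Boltzmann
  curve (1000 events per voltage over 5 sweeps in the recovery runs).
- `simulate_ion_hops()`: a birth–death hop chain over the site ladder with
  per-boundary rates; per-frame z is the site center plus Gaussian jitter
  (default 0.03 nm, small against the 0.155 nm half-spacing so labels
  round-trip). Ground-truth crossing counts are defined at frame
  resolution — the site path sampled at frame times — because sub-frame
  excursions are invisible to any frame-based counter, making exact
  equality well-posed.
- `plant_flip_series()`: an AR(1)-discretized Ornstein–Uhlenbeck deviation
  about a mean path that steps irreversibly at the planted event time, so
  noiseless series are exactly piecewise-constant and the step is
  instantaneous.

Not emulated: open-channel noise in excess of baseline, slow baseline
drift, 1/f noise, multi-channel cross-talk, correlated ion motion
(knock-on), force-field-specific kinetics, and finite-sampling artifacts of
real trajectories. Green tests on synthetic data therefore demonstrate
correctness of the *analysis operations* under the stated conditions, not
that those conditions capture every property of real recordings or
simulations.

## Problem sizes and determinism

Every stochastic function takes an explicit seed; global RNG state is never
used or disturbed. The reproduction runs use desk-scale sizes chosen to
make the recovery targets statistically decisive: 30 s (high-$Po$
two-Gaussian recovery) and 120 s (dwell and tail-fit recovery) of 50 kHz
trace, 19 voltages × 5 sweeps × 1000 events (Boltzmann), 200-replica
detector and counter property checks, and 2–3 × 10⁵ samples for profile
inversion. `reproduce_targets()` reruns all of them from scratch and
reports a pass/fail table; `run_pipeline()` chains the full synthetic
analysis end to end with provenance (config hash, package version) in every
artifact.

## Known limitations

- Threshold idealization has no missed-event correction; dwell means at
  cutoffs near the dwell scale are biased (by design, matching the
  analysis being reproduced).
- The two-Gaussian amplitude model ignores filtered open-channel noise
  (no beta-distribution modeling) and subconductance levels.
- The log-tail open-level estimate is slightly conservative (a few
  hundredths of a pA low at the V55E conditions) because even long
  openings spend filtered samples below full amplitude.
- The permeation counter needs trajectories wrapped consistently; its
  wrap heuristic assumes displacements under $L_z/2$ per frame.
- `detect_inactivation()`'s default band is an estimate from the early
  trace; replicas that inactivate within the baseline window would bias
  it and should use a band from control replicas instead.
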