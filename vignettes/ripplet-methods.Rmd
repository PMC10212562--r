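---
title: "Methods: synthesizing and analyzing ultrafast cortical ripplet oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesizing and analyzing ultrafast cortical ripplet oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippletlab)
```

## The system being modeled

Brief optogenetic activation of thalamocortical axons in slices of mouse
barrel cortex evokes a transient (<25 ms) local field potential (LFP)
oscillation of 2–5 negative transients at roughly 400 Hz — a "ripplet".
Intracellularly, layer-4 fast-spiking (FS) interneurons fire a
stereotyped burst of ~4 spikes with trial-to-trial jitters of tens of
microseconds, phase-locked to the LFP troughs; regular-spiking (RS)
excitatory cells fire 1–2 spikes near the LFP negative peaks, in
antiphase to the FS cells, and receive regularly alternating
EPSC–IPSC sequences when voltage-clamped at an intermediate holding
potential (−50 to −55 mV, where EPSCs are negative and IPSCs positive
deflections).

`rippletlab` implements the full quantitative workflow around this
phenomenon: a hierarchical generator of synthetic sweep data with the
published cohort statistics, LFP decomposition and ripplet feature
extraction, spike-burst statistics and FS/RS classification, the
Jitter-Based Synchrony Index (JBSI), phase-locking analysis, EPSC/IPSC
onset detection, an event-driven simulator of the proposed
ripplet-generating circuit, and the nonparametric tests used to compare
conditions.

## The synthetic-data generator

All analyses in this package are validated on synthetic sweeps because
no raw recordings are deposited. The generator reproduces the cohort
structure of the experiments at three levels:

1. **Population level.** `population_params()` holds the published
   event-time means and SEMs: presynaptic volley peaks at 2.3/6.0/10.8 ms
   (SEMs 0.07/0.22/0.24, n = 8 slices), ripplet transients at
   4.4/6.5/8.9/11.9 ms (SEMs 0.11/0.26/0.30/0.38, n = 11), FS burst
   spikes at 3.1/5.5/7.7/10.3 ms (SEMs 0.06–0.14, n = 25 cells),
   per-trial FS jitters of 23/63/110/183 µs, and the FS/RS phase
   statistics (medians 26°, 161°, and 59° in the E–I cycle).
2. **Unit (slice/cell) level.** Per-unit mean event times are drawn so
   that the cohort SD equals SEM·√n. The correlation structure within a
   unit is not published; we decompose the scatter into a shared onset
   shift, a shared "tempo" factor that stretches all intervals, and a
   small (0.08 ms) independent per-order deviation. This keeps each
   unit's rhythm regular — as every recorded slice shows — while the
   first- and last-order marginal SDs match the published values
   exactly and intermediate orders approximately. Fully independent
   per-order draws would make ~25% of slices arrhythmic (adjacent peaks
   closer than any observed inter-peak interval).
3. **Trial level.** Events are placed in continuous time with Gaussian
   per-trial jitter and kernels evaluated at the 20 kHz sample grid, so
   jitters far below the 50 µs sampling period remain representable.

Kernel shapes are stylized, since the source data constrain timing, not
waveforms: presynaptic volleys and postsynaptic transients are negative
Gaussians (σ 0.25 and 0.35 ms) riding a slow positive half-cosine
envelope (12 ms), with explicit positive crests (σ 0.3 ms) at the cycle
troughs; EPSCs/IPSCs are differences of exponentials (rise 0.2/0.4 ms,
decay 1.0/2.5 ms); spikes are Gaussian depolarizations plus a brief
afterhyperpolarization — only the peak time matters downstream.
Amplitudes are free choices (the source constrains only the ≥0.5 mV
inclusion criterion); white-noise SDs default to 0.02 mV (LFP), 0.5 mV
(current clamp) and 5 pA (voltage clamp).

The cycle geometry ties the modalities together: troughs sit midway
between transients (plus a leading and a trailing trough half a mean
period outside); FS population volleys fire 26° of a cycle after each
trough; EPSC onsets coincide with troughs and IPSC onsets follow each FS
volley by the 0.8 ms monosynaptic delay. Pharmacological conditions are
additive by construction: TTX leaves only the square light artifact,
CNQX+APV leaves artifact plus presynaptic volleys, control adds the
postsynaptic component.

What the generator does **not** emulate: recording drift and seal
instability, non-Gaussian and correlated electrode noise, waveform
diversity across cells, unclamped spikes in voltage clamp, and true
network variability (packet-size fluctuations feeding back into timing).
Closure tests on this generator therefore demonstrate internal
consistency of the estimators at realistic noise levels, not performance
on raw laboratory records.

```{r generator-example}
slice <- draw_slices(population_params(), n_slices = 1, seed = 1)[[1]]
sweeps <- synth_lfp_sweeps(slice, n_sweeps = 10, seed = 2)
sweeps
```

## LFP decomposition and ripplet features

Averaged sweeps (`average_sweeps()`) are decomposed exactly as in the
experiments: the TTX average (pure artifact) is subtracted from every
condition (`subtract_artifact()`), and the CNQX+APV average is
subtracted from control to isolate the postsynaptic component
(`isolate_postsynaptic()`). `detect_ripplet_features()` pre-smooths with
a zero-phase Butterworth low-pass at 1.3 kHz (mirroring the acquisition
filter), finds transients as negative maxima exceeding 0.1 mV in a
3–20 ms post-onset window separated by ≥1.5 ms (below the smallest
observed inter-peak interval of 2.1 ms), and localizes all peaks by
three-point parabolic interpolation — necessary because the timing
precision of interest is below the sampling period. A slice whose
largest transient stays under 0.5 mV is flagged
`below_amplitude_criterion` rather than analyzed.

Troughs (positive maxima) are taken between consecutive transients plus
one leading and one trailing trough, so trough count = transient
count + 1 — the geometry in which one FS spike sits on every trough.
When a blocked average is available, transients and troughs are measured
on the postsynaptic difference, which matters for troughs that would
otherwise collide with a presynaptic volley; volleys themselves are then
read from the blocked trace over the full response window (on control
traces only the early 1–3.5 ms window is searched, because later volleys
are masked by the much larger transients).

Oscillation frequency is defined throughout as the reciprocal of the
mean inter-event interval, `(n−1)/(t_n − t_1)`; cohort summaries average
per-unit frequencies, not intervals, which is why the cohort values
(418 Hz FS bursts, 408 Hz transients, 239 Hz volleys) exceed the naive
frequency of the population-mean times.

```{r lfp-example}
f <- detect_ripplet_features(average_sweeps(sweeps), sweeps$protocol)
f
```

## Burst statistics and cell classification

`detect_spikes()` finds local maxima above 0 mV separated by ≥0.8 ms
(closer peaks merge, with a warning). `assign_spike_orders()` builds a
template from the trials with the modal spike count (per-order medians),
assigns every spike to the nearest template order within 0.8 ms, and
re-estimates once. Per-order jitter is the n−1 SD over the trials where
that order fired — failures are excluded, matching how low-reliability
spikes were treated. The CV identity (CV = jitter/mean·100) holds
exactly by construction.

The eight-parameter electrophysiological profile
(`extract_ephys_params()`) follows the standard definitions: threshold
at dV/dt = 5 V/s on the rheobase spike, spike height from threshold to
peak, width at half-height, AHP to the post-spike trough, input
resistance as the I–V slope over subthreshold steps within ±15 mV,
I<sub>max</sub> as the largest step before the first-spike height drops
more than 10% below its rheobase value (the published criterion is
qualitative; 10% is our operationalization), and F<sub>max</sub> as the
reciprocal of the mean of the last five ISIs at I<sub>max</sub>.
`classify_cell()` uses a threshold rule (FS: F<sub>max</sub> ≥ 150 Hz
and width ≤ 0.5 ms; RS: < 100 Hz and > 0.5 ms) in place of the source's
unspecified cluster analysis; on the generator archetypes the two
classes separate with zero confusion. `synth_step_family()` provides the
600-ms step families these functions are tested on; suprathreshold steps
charge with an accelerated (2.5 ms) time constant so that the first
spike rides a settled plateau.

## The Jitter-Based Synchrony Index

Synchrony S is the fraction of spikes in the less active train falling
within ±SW of a spike in the other train. Chance synchrony is computed
analytically: each jittered spike contributes the measure of the union
of the target ±SW windows intersected with its ±J jitter range, divided
by 2J. The jitter distribution is uniform on [−J, +J] — the unique
choice under which β = 2 bounds the index at 1 when J = 2·SW (a
synchronous spike's full target window then lies inside its jitter
range, so its chance contribution is at least ½). JBSI = β(S − ⟨S_J⟩).
Trials are pooled by counts and never matched across trial boundaries;
overlapping target windows are merged exactly, with no discretization.
`chance_synchrony_mc()` is retained purely as a Monte-Carlo oracle for
the analytic term.

`jbsi_matrix()` evaluates the index over SW 0.1–1.0 ms × virtual lags
−1…+1 ms in 0.1 ms steps. Pairwise *precision* is the smallest SW whose
best-lag JBSI exceeds 0.5; pairwise *lag* is the maximizing lag in that
row (ties resolve toward zero lag; positive lag shifts the jittered
train later). On pairs driven by shared volleys with 0.15 ms independent
jitter per cell, the index rises above 0.5 by SW = 0.3 ms and collapses
below it at 0.2 ms, reproducing the characteristic rise-then-collapse
profile and the 0.3 ms median pairwise precision.

```{r jbsi-example}
pair <- synth_pair_trains(c(3.1, 5.5, 7.7, 10.3), sigma_indep_ms = 0.15,
                          sigma_common_ms = 0.05, n_trials = 30, seed = 3)
m <- jbsi_matrix(pair$a, pair$b)
c(precision_ms = m$precision_ms, lag_ms = m$lag_at_precision_ms)
```

## Phase locking

Phase anchors alternate: LFP troughs at 0° (mod 360) and transients at
±180°, or EPSC onsets at 0° and IPSC onsets at 180°. A spike's phase is
linearly interpolated between its bracketing anchors on the unwrapped
scale, then re-expressed relative to the trough *nearest in time*. We
deliberately do not use the trough minimizing the phase difference: the
time-nearest rule lets phases run slightly beyond ±180° when the two
half-cycles differ in duration, which is exactly how the published
distributions behave (RS phases up to 187°). Summaries (median, 10th and
90th percentiles) are computed on the linear scale with interpolated
percentiles, not circular statistics, because the plotted scale is
linear. Spikes outside the anchor span are excluded and counted.
`phase_to_time()` converts angles to milliseconds via
`angle/360 × period`.

## EPSC–IPSC sequences

`detect_ei_onsets()` works on the baseline-subtracted, 2 kHz-smoothed
current. Candidate events are alternating local extrema surviving
*persistence pruning*: adjacent extrema whose relief is below
max(5 × baseline MAD, 10 pA) cancel iteratively, so a deflection is
detected by its relief relative to its neighbors rather than by absolute
level — essential when one component rides the other's decay. Extrema
stranded deep on the wrong side of baseline (more than two thresholds)
are recovery phases of the opposite component and are discarded. Onsets
are found by slope-threshold backtracking (stop below 10% of the event's
peak slope) with a foot guard, then refined by extrapolating the
maximal-slope tangent back to the local background line — robust to the
previous event's recovery slope. Alternation is enforced after the first
detected event by dropping the smaller of two same-sign neighbors, with
a warning.

Scope: the detector targets traces in which both components are visible,
as in the recordings it emulates (cells held at −50 to −55 mV with
moderate E–I balance). At extreme balance the minority component is
genuinely unresolvable by deflection analysis; closure tests therefore
use balances between roughly 0.35 and 0.65. Onsets of trailing IPSCs
(no following event to bound them) are the least accurate, occasionally
off by several hundred µs; EPSC onsets — the quantity regressed against
LFP troughs — close within 0.1 ms.

`net_charge()` is a trapezoidal integral of baseline-subtracted current
(negative = net excitatory); `trough_epsc_regression()` is ordinary
least squares of EPSC onsets on trough times with R².

## The circuit simulator

`simulate_ripplet()` implements the proposed generation mechanism as an
event-driven, volley-level cascade — deliberately not a conductance
model, which would add parameters the data do not constrain. The
thalamocortical volley triggers the first FS volley after 0.8 ms
(monosynaptic) and the first RS packet at 1.7 ms (FS cells lead by
0.9 ms). Each RS packet k is centered (k−1)·2.4 ms later — the cycle
period being the sum of the 0.9 ms RS→RS synaptic delay and the 1.5 ms
post-synaptic time-to-spike — and elicits an FS volley 1.5 ms after it.
Eligible (non-refractory) RS cells draw a threshold-crossing time
N(center, 0.3 ms) and participate with probability 0.9·0.6^(k−1)
(per-cycle synaptic depression). With inhibition on, cells crossing
after the IPSP-arrival cutoff are preempted; the cutoff is the previous
FS volley + 0.8 ms IPSP delay + a 0.2 ms IPSP rise-to-effect term. The
rise term is needed for internal consistency: without it the wavefront
would arrive 0.1 ms *before* the packet center and, in the noise-free
limit, silence every cell — whereas the mechanism it implements is
"too late to block the earliest spikes but in time to preempt the
laggards". The cascade stops at the first packet smaller than
`n_min = 10` cells; depression and n_min are calibrated so defaults give
the observed 2–7 cycles within 25 ms, with FS volleys always numbering
one more than RS volleys.

`deterministic = TRUE` switches every noise term off (crossings at the
centers, FS jitter zero, packet sizes equal to rounded expectations
instead of Bernoulli draws), giving the exact 2.4 ms schedule.

Disinhibited mode (`inhibition_on = FALSE`) emulates local GABA_A
blockade: no preemption and no fast per-cycle depression — the fast
depression is dropped because with it the discharge would still end
within tens of ms, contradicting the observed paroxysms of up to
~500 ms. Instead a slow adaptation factor exp(−t/150 ms) winds
participation down, terminating the discharge after several hundred ms.
The adaptation clock is an explicit modeling stand-in: how the real
paroxysm terminates is not established.

`sim_lfp()` renders a proxy LFP with negative transients 0.25 ms after
each RS packet center (so each transient lags the preceding FS volley by
~1.15 ms, about half a cycle — the observed antiphase relation), scaled
by the square root of relative packet size, with the thalamocortical
bump placed at its observed 2.3 ms latency from nominal light onset.
This trace feeds `detect_ripplet_features()` unchanged, closing the loop
between the simulator and the LFP pipeline.

```{r sim-example}
sim <- simulate_ripplet(circuit_params(seed = 4))
summarize_sim(sim)[c("fs_frequency_hz", "n_rs_volleys", "n_fs_volleys",
                     "duration_ms")]
```

## Statistics

`permutation_test()` is the two-tailed Monte-Carlo permutation test
(default 10,000 label permutations, two tails pooled via the absolute
statistic, the observed arrangement not counted); when no permutation is
as extreme the p-value is reported as the bound 1/n_perm with
`is_bound = TRUE`. `sign_test()` is the exact two-sided binomial sign
test. Both are validated against exhaustive enumeration at tiny n and a
type-I-error simulation.

## Reproduction runner and problem sizes

`run_reproduction(seed)` recomputes the package's headline quantities
from scratch: the four deterministic phase-time conversions; cohort
recoveries of the FS burst (≈418 Hz), ripplet transient (≈408 Hz) and
presynaptic volley (≈239 Hz) frequencies from 100 per-unit draws each;
the median pairwise JBSI precision over 6 synthetic FS–FS pairs of 30
trials; the deterministic RS inter-volley interval; and the maximum
discharge duration over 100 stochastic simulator runs. These problem
sizes mirror the published cohort sizes where stated (100-unit cohorts
for the frequency recoveries, 6 pairs, 100 seeds) and complete in a few
seconds. The full-pipeline closure used in the test suite runs 25 FS
cells and 11 + 8 slices through generation → detection → summary and
requires each recovered population mean to lie within three combined
standard errors of its target.

## Interfaces

The exported functions, `run_reproduction()`, and the
`scripts/acceptance.R` wrapper are the package's interface; sweep sets
interchange via a plain-text Sweep Table CSV (`read_sweepset()` /
`write_sweepset()`, metadata in `# key=value` headers, samples to six
decimals) and result objects serialize naturally to JSON via jsonlite.
No shell subcommand tool is shipped: the artifact is an analysis
library, and a thin CLI would add surface without adding capability.

## Known limitations

- Generator waveforms are stylized; detectors tuned here may need
  re-tuning for real electrode noise spectra and drift.
- E–I onset detection degrades at extreme excitation/inhibition balance
  and for trailing events (see above).
- The FS/RS classifier is a two-threshold rule with an explicit
  "unclassified" gap, not a clustering of all eight parameters.
- The simulator is volley-level: it reproduces timing and counts, not
  membrane potentials or synaptic conductances, and its disinhibited
  mode uses a phenomenological adaptation clock.
- Percentile phase summaries assume the linear plotting convention; no
  circular statistics are provided.
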