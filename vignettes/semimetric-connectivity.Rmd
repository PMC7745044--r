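---
title: "Semi-metric functional connectivity for fNIRS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-metric functional connectivity for fNIRS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semifc)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through dual-wavelength light attenuation. A common way to
summarize a multichannel recording is a functional-connectivity (FC)
network: channels are nodes, and the edge weight $x_{ij} \in [0,1]$ is the
coherence between channel time series in a task-relevant frequency band.
Conventional weighted graph analysis quantifies such networks through
shortest-path indices, but treats every direct edge at face value.

Semi-metric analysis asks a sharper question: for which channel pairs is
the *direct* connection weaker than an *indirect* route? After converting
weights to distances,

$$l_{ij} = \frac{1}{x_{ij}} - 1,$$

an edge is **semi-metric** when its direct distance exceeds the shortest
path $l'_{ij}$ through intermediate nodes — a violation of the triangle
inequality in the distance graph. The ratio $s_{ij} = l_{ij}/l'_{ij} \ge 1$
quantifies the violation, and the **semi-metric percentage**

$$\mathrm{SMP} = \frac{\#\{(i,j): s_{ij} > 1\}}{E}$$

(with $E$ the total number of edges) summarizes how much of the network's
information flow is redundant/indirect. Edges with $s_{ij} = 1$ form the
*metric backbone*, which alone reproduces every shortest-path length — a
property the test suite asserts on random networks.

This package implements the full chain — raw intensities to ΔHbO/ΔHbR,
wavelet-transform-coherence FC matrices, semi-metric and
weighted-graph-theory summaries, RMSSD heart-rate variability from PPG for
physiological validation, and the mixed-ANOVA/FDR statistical layer — plus
seed-deterministic generators that make every stage testable without any
real recording.

## Preprocessing model

The chain is fixed: optical density → wavelet motion correction →
modified Beer–Lambert → zero-phase low-pass → hemodynamic modality
separation.

* **Optical density.** $\mathrm{OD} = -\ln(I/\bar I)$ per channel and
  wavelength, with $\bar I$ the mean over a reference window (default: the
  whole recording — the raw-text wording of most acquisition chains leaves
  the reference unspecified, so it is configurable).
* **Motion correction.** Each series is decomposed with a maximal-overlap
  discrete wavelet transform (MODWT, Daubechies-5 by default, depth
  $\lfloor \log_2 n\rfloor - 4$). Within each detail level, coefficients
  deviating from the level median by more than 1.5 × IQR are zeroed and
  the signal is reconstructed. MODWT was chosen over the decimated DWT
  because it is defined for any signal length, aligns coefficients with
  time, and inverts exactly; the approximation level is never touched so
  slow hemodynamics pass through. Note that for heavy-tailed signals the
  1.5 × IQR rule zeroes a small fraction of coefficients even without
  artifacts (≈4% for Gaussian details); this mirrors the despiking
  behavior of the standard fNIRS correction this step models.
* **Beer–Lambert.** A 2×2 linear solve per sample using an editable
  extinction table (approximate literature values at 695/830 nm, units
  1/(mM·mm)), DPF 6.0 and 30 mm source–detector separation. These
  constants scale amplitudes only; they cancel exactly in round trips, and
  the package's tests rely on the exact inverse rather than on any
  particular constant.
* **Low-pass.** 3rd-order Butterworth at 1.0 Hz applied forward-backward
  (zero phase, unit DC gain).
* **Modality separation.** $\Delta HbO = \Delta HbO_f + \Delta HbO_s$ with
  $\Delta HbR = k_1 \Delta HbO_f + k_2 \Delta HbO_s$, $k_1 = -0.6 < 0$
  (anti-phase, neuronal) and $k_2 = +2.0 > 0$ (in-phase, systemic);
  closed-form inverse
  $\Delta HbO_f = (k_2\,\Delta HbO - \Delta HbR)/(k_2 - k_1)$. The
  constants are fixed documented defaults (estimating them per subject is
  out of scope); additivity of the two components is exact by
  construction.

## Coherence model

FC weights are squared wavelet transform coherence,

$$R^2 = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\,S(|W_y|^2/s)},$$

from analytic Morlet transforms ($\omega_0 = 6$, 12 voices per octave),
smoothed in time by a Gaussian of standard deviation equal to the scale
and across scales by a 0.6-octave boxcar. Self-coherence is identically 1
whatever the smoothing constants, which is why the tests anchor on
self-coherence, bounds, symmetry and planted-coupling ordering rather than
on bit-matching any particular toolbox. Values inside the cone of
influence are kept by default (a flag excludes them). The weight of an
edge is the mean coherence over scales with frequency in 0.01–0.2 Hz and
samples inside task blocks, each task block weighted equally; rest periods
are never used. Scales are restricted to the band of interest plus the
smoothing margin, which changes nothing numerically inside the band and
keeps the 496-pair build tractable.

## Graph-theory benchmark

The benchmark indices on the unthresholded weighted network are the mean
weighted clustering coefficient (geometric-mean triangle intensity on
weights normalized by the network maximum — the standard weighted
generalization whose binary special case is $2m/(k_i(k_i-1))$; the printed
binary formula is degenerate on complete weighted graphs), characteristic
path length $\lambda$, global efficiency, local efficiency (global
efficiency of each neighbor-induced subgraph, distances recomputed inside
the subgraph), and nodal efficiency (full-graph distances, averaged over
ROI members). Distances reuse the $1/x - 1$ conversion for consistency
with the semi-metric branch; an inverse-weight option ($l = 1/x$) exists
for parity with binary-graph conventions where a unit weight is a
unit-length edge. On complete uniform-coherence graphs the closed forms
$\lambda = 1/x - 1$ and $E_{global} = x/(1-x)$ hold exactly and are
asserted to $10^{-12}$. Regional clustering and $\lambda$ use ROI-induced
subgraphs; regional SMP counts intra-ROI edges only (the incident-edge
alternative is available as a flag). For hemispheric contrasts the two
midline channels (16 and 37 in the shipped 52-channel layout) are dropped,
leaving 15 channels per prefrontal hemisphere.

All-pairs shortest paths use Floyd–Warshall with strict-improvement
updates in ascending intermediate-node order, which fixes tie-breaks and
makes reconstructed paths — hence the shared-path histogram —
deterministic. Zero coherence maps to a clamped weight of $10^{-6}$
(a very long finite edge) rather than edge deletion, so $E$ stays the
complete-graph count. The semi-metric label uses a relative tolerance,
$s > 1 + 10^{-9}$; ties count as metric.

## HRV model

PPG traces are smoothed by a centered moving average whose window equals
one second of samples, beats are picked as local maxima, inter-beat
intervals outside 333–1000 ms (heart-rate bounds 60–180 bpm) or deviating
more than 20% from the median of a 5-interval context window are removed,
and RMSSD is

$$\mathrm{RMSSD} = \sqrt{\tfrac{1}{n-1}\sum_i (NN_{i+1} - NN_i)^2}.$$

Only genuinely successive pairs enter the sum: a difference across a
removed interval is not a beat-to-beat difference and is skipped.

Two design points deserve emphasis because they follow from the
smoothing stage's physics. A one-second moving average has spectral zeros
at 1, 2, 3, … Hz, so (i) a pulse train with intervals near 1000 ms is
*constant* after smoothing and its beats are undetectable, and (ii) at
typical heart rates only an attenuated, sign-flipped fundamental survives,
so local maxima of the smoothed trace lock to pulse-cycle midpoints
rather than systolic peaks. Midpoint intervals preserve slow (low-
frequency, Mayer-band) interval variability almost exactly but halve the
successive-difference signal of fast uncorrelated jitter. The beat
detector therefore thresholds the *baseline-removed* trace
(rolling-median subtracted) at the maximum of 0.3 × the rolling (1.5 s)
90th percentile of pulse amplitude and 5% of its global 90th percentile:
the local term adapts to amplitude modulation, the floor keeps noise
wiggles in near-flat stretches out, and the DC offset of the smoothed
trace cannot mask troughs.

## The synthetic-data generators

`gen_fnirs()` implements the minimal generative structure wavelet
coherence assumes: channels within a coupling block share a band-limited
(0.01–0.2 Hz) latent Gaussian oscillation whose amplitude doubles during
task blocks, plus independent band-limited noise; the coupling weight 0.5
splits variance between shared and private parts. ΔHbR follows the
modality-separation mixing exactly, a shared 0.1 Hz systemic wave is
added, and intensities come from the forward Beer–Lambert model around a
unit baseline. The default paradigm is 20 s of rest followed by five 60 s
task blocks with 30 s rests between (the between-task rest duration is a
declared choice). The defaults emulate a 10 Hz, 32-channel prefrontal
recording with two groups of 19 subjects; tests and the acceptance script
run deliberately scaled-down versions (8 channels, two short task blocks,
3–6 subjects per group, 6 voices per octave) so the whole suite completes
on one CPU, and the statistical behavior checked — oracle equality,
ordering of planted effects, type-I calibration — does not depend on the
problem size.

`gen_ppg()` draws NN intervals with mean heart rate 80 bpm whose
deviations are band-limited to 0.085–0.115 Hz, clipped to keep intervals
inside 600–930 ms (see the HRV section for why), and rescaled so the
ground-truth RMSSD equals the target exactly; each beat renders as an
asymmetric Gaussian pulse (rise 0.13 s, decay 0.22 s) at 200 Hz. The
mean rate of 80 bpm reflects a mildly loaded task state and keeps the
interval distribution clear of the smoothing filter's 1 Hz null; targets
whose amplitude cannot fit the heart-rate bounds are rejected as
infeasible. Across seeds the full pipeline recovers the generating RMSSD
with a median absolute error of about 3–4% (a small negative bias is
inherent to midpoint locking).

`gen_toy_network()` builds exact semi-metric fixtures: all non-planted
edges sit in a narrow strong band (0.5–0.6), where every direct edge beats
any two-hop detour, and planted edges are weakened (0.1–0.25) so that a
detour through any non-planted pair wins. The label set, and hence SMP,
is known by construction, and plantings that would leave an edge without
a metric two-hop detour are rejected.

What the generators do *not* emulate: balloon-model hemodynamics,
realistic motion artifacts beyond additive spikes, dicrotic PPG
morphology, respiratory-band (high-frequency) heart-rate variability, and
scalp/systemic confounds beyond a single shared slow wave. Passing tests
therefore demonstrate correctness of the computations and recoverability
of planted structure under the stated model, not performance on real
recordings.

## Statistics layer

Mixed ANOVAs use `aov()` error strata (`subject/state`, or
`subject/(state*region)` for the three-way design) on balanced complete
tables; partial eta squared is $SS_{effect}/(SS_{effect}+SS_{error})$
within the effect's stratum, and the suite checks the F statistics against
a closed-form sums-of-squares oracle. Pairwise follow-ups are paired and
pooled-SD independent t tests with Cohen's d (`mean(diff)/sd(diff)` for
paired contrasts — the printed values of the study this models do not pin
down a unique variant, so the choice is documented rather than asserted);
each comparison table is FDR-adjusted as one family by Benjamini–Hochberg
step-up. State-change correlations are Pearson correlations of
per-subject affective-minus-neutral differences, groups pooled.

## Numerical choices and degenerate inputs

* Coherence values are clipped to $[0,1]$ after smoothing; self-coherence
  is exact by cancellation.
* Weight 1 → distance 0: allowed; $1/d$ terms in efficiencies are capped
  at $10^{6}$ (the inverse of the clamp floor's distance), practically
  unreachable after clamping.
* Disconnected pairs (possible only with explicit zero weights under the
  inverse-weight option) contribute 0 to efficiencies and make $\lambda$
  fail loudly.
* Degenerate t tests (zero variance) and empty ROIs reject with
  messages; the ANOVA validates design completeness per subject and cell.
* All generators consume one `set.seed()` at entry; equal seeds give
  bit-identical outputs.

## Known limitations

Exact smoothing constants of wavelet-coherence implementations differ
between toolboxes; absolute coherence levels (and therefore absolute SMP
levels) are comparable only within one implementation. The semi-metric
labels themselves are scale-free (they depend only on ordering of path
sums), which is why oracle equality, closed forms and backbone
sufficiency are the load-bearing acceptance properties. The HRV chain
inherits the resolution limits of the one-second smoothing discussed
above. SNIRF/HDF5 container input is not provided; the package reads and
writes the delimited-text dialects documented in the I/O help pages.
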