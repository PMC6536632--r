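---
title: "Classifying striatal neuron types: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying striatal neuron types: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striocell)
```

`striocell` reproduces, as tested and reusable code, the analysis chain
used to separate striatal neuron types from whole-cell current-clamp
recordings and SWC reconstructions: per-cell feature extraction,
adaptation kinetics, global morphometry, and an unsupervised
classification stage (PCA, Ward clustering, silhouette model selection).
This vignette explains the models behind each stage, the conventions and
tunable parameters, what the synthetic generators do and do not emulate,
and the design decisions taken where the procedure was genuinely open.

## The measurement model

### Passive properties

Subthreshold behaviour is summarized by the steady-state current–voltage
relation of the non-depolarizing sweeps. The steady state of each sweep
is the mean over the final 100 ms of the 1-s step; a least-squares line
through the (I, V_ss) points gives the input resistance (slope, MΩ) and
the resting membrane potential (intercept, mV). Sweeps whose steady state
falls below −110 mV are excluded from the fit to stay in the linear range
(strong hyperpolarization engages inward rectification in real cells).

Sag is read on the hyperpolarizing sweep whose steady state is nearest
−100 mV, as the non-negative difference between the steady state and the
early trough (searched in the first 300 ms; the trace is smoothed with a
1-ms boxcar first so the minimum of the noise does not masquerade as
sag). The membrane time constant is fit on the hyperpolarizing sweep with
a deflection nearest −15 mV — large enough for good signal-to-noise,
small enough to stay linear. Because hyperpolarizing responses carry a
sag component, a plain exponential underestimates τ_m; the default fit
therefore includes an explicit sag term,
V(t) = V₀ + a[(1 − e^(−t/τ)) + s(e^(−t/τ_sag) − e^(−t/τ))],
falling back to the single exponential if it fails to converge.
Capacitance is derived as C_m = τ_m / R_in. Amplifier-reported
capacitance readings are not reproducible offline; the τ/R convention is
used instead and makes the synthetic ground truth checkable. The two
conventions agree for a single-compartment cell and differ for extended
ones — a point to keep in mind when comparing absolute C_m values across
studies.

### Spike detection and waveform metrics

The AP threshold is the inflection of the upstroke, operationalized as
the first sample at which dV/dt crosses a criterion (default 10 mV/ms).
Detection smooths the derivative with a 0.2-ms boxcar so that recording
noise cannot trigger it, then snaps the onset to the first raw-derivative
crossing; a candidate must also rise at least 15 mV within 1 ms, which
rejects slow depolarizing ramps whose noisy derivative grazes the
criterion, and onsets closer than 1 ms are refractory-suppressed. All
single-spike metrics are referenced to the detected threshold: amplitude
(threshold to peak), half-width (linear interpolation at half-maximal
amplitude on both flanks), AHP (post-peak trough minus threshold,
negative by convention, searched to the next AP or 50 ms), and the
extreme slopes of the rising and falling phases. The per-sweep rheobase
(current threshold) is the smallest depolarizing current with at least
one detected AP.

### Adaptation kinetics

Adaptation depends on drive, so it is measured on a standard criterion
sweep. Two conventions exist in practice and both are implemented: the
sweep nearest 50 pA above rheobase (default, `"plus50"`) and the smallest
sweep firing at least ten APs (`"ten_spikes"`). Instantaneous frequency
is the inverse interspike interval. Each IF value is timestamped at the
**midpoint** of its interval (measured from the first spike): an interval
average represents the underlying rate at the interval's centre, and with
this time base the exponential fits below recover generator time
constants to a fraction of a percent, whereas anchoring IF at the second
spike of each interval biases the fast time constant by several percent.

The frequency-adaptation ratio is 1 − mean(last 3 IF)/mean(first 2 IF),
so a non-adapting train scores 0; with single first/last values the
statistic is also available (`first_k`, `last_k`). Amplitude and duration
adaptation are plain last/first ratios. Decay time courses are fitted by
constrained nonlinear least squares,
y(t) = c + a_f e^(−t/τ_fast) + a_s e^(−t/τ_slow), with non-negative
amplitudes, time constants and offset (normalized IF plateaus above
zero). The fast component is weakly identified on noisy trains, so
several initializations (log-linear tail fit for the slow phase; a small
grid for the fast one) compete on residual sum of squares. Fits report an
R² flag (poor below 0.5) and a degeneracy flag when one amplitude
collapses below 1% — the signature of fitting two components to a
single-exponential course. AP broadening is classified by the sign of the
quadratic coefficient of a parabola in normalized width versus spike
index; only negative-curvature (saturating) trains enter
single-exponential broadening fits, mirroring how accelerating and
saturating broadening cannot be summarized by one τ. Responses with a
plateau potential — mean voltage in the 100 ms after stimulus offset more
than 20 mV above rest — are flagged and excluded from all τ summaries,
because a plateau interrupts and resets adaptation.

### Morphometry

The SWC reader enforces a single root, unique ids, resolvable parents and
acyclicity, and precomputes path and Euclidean distances per node. The 23
global features follow the usual L-Measure-style definitions: counts
(nodes, stems, bifurcations, branches = bifurcations + tips, tips),
95%-range extents per axis (2.5th to 97.5th percentile of node
coordinates), mean compartment diameter, total length, frustum total
volume, maximal path/Euclidean distance, branch order (soma = 0, +1 at
the stem and at every bifurcation), per-branch contraction
(Euclidean/path length) and fragmentation (compartments per branch),
daughter/parent diameter ratios at bifurcations, local (first
compartments) and remote (next endpoints) bifurcation amplitude angles,
Sholl crossings at 30 and 50 µm, and spine density. Sholl analysis is 2D
(XY projection, the classic convention) by default with a 3D option; a
compartment crosses radius r when its endpoint distances straddle r. The
surface-area profile assigns each compartment's frustum lateral area
π(r₁ + r₂)·slant to the bin of its midpoint path distance, so the bins
sum exactly to the total neurite lateral area — a synapse-weighted
alternative to crossing counts. Spines have no SWC standard; here they
are single-node leaves of type 8 attached to dendrite nodes, counted for
spine density but excluded from all other geometry. Axons (type 2) are
excluded from dendritic features by default and can be included via a
toggle.

### Classification

Features are z-scored (constant columns dropped with a warning — on
different scales, MΩ-sized features would otherwise dominate), reduced by
PCA computed via singular value decomposition, and truncated to the first
three components. Component signs follow a deterministic convention (the
largest-magnitude loading is positive) so scores and dendrograms are
bit-reproducible. Clustering is Ward's minimum-variance criterion on the
PC scores via the Lance–Williams update on squared distances
(`"ward.D2"`); the electrophysiology pipeline uses Euclidean distance and
the morphology pipeline the correlation distance 1 − r, applied with the
same update rule — formally non-Euclidean, but standard in heatmap-style
pipelines and retained here as the morphology convention. The number of
clusters is chosen by silhouette analysis with Euclidean distance on the
same scores, over k = 2…8 by default, ties toward the smaller k;
singleton clusters score 0 by convention. Cells with missing features are
dropped by default (or median-imputed); a cohort whose best mean
silhouette is below 0.45 triggers a warning, since single-population
cohorts plateau near 0.37 while genuinely structured ones sit well above
0.5. Radar-style summaries rescale each feature's cluster means to
[0, 1]; a feature constant across clusters maps to 0.5.

## The synthetic study conditions

Real recordings behind the published statistics are not available, so the
generators define the study conditions under which the pipeline is
exercised.

**Feature cohorts.** Each cell type is an archetype carrying the
published population mean ± SEM of its properties. Cohorts draw each
feature independently from a Gaussian; printed SEMs are converted to
population SDs as SD = SEM·√n with an assumed per-type n of 20 (per-type
sample sizes are not published; the assumption is exposed as
`n_assumed`). Three of the twelve properties (maximal rise and fall
slopes, rheobase) are not published for the three types; their means were
fixed once from physiology — narrow-spiking interneurons have steep
upstrokes (THIN 280 mV/ms) while broad-spiked FANS are shallow
(130 mV/ms), MSN sit hyperpolarized with low R_in and hence a high
rheobase (150 pA) — with fall slopes tied to amplitude, half-width and
rise rate through the AP template geometry below.

**Recordings.** The renderer composes, per sweep, a single-compartment RC
response (deflection I·R_in, time constant τ_m = C_m·R_in) with, for
hyperpolarizing steps, a slower sag conductance whose fraction is solved
so the rendered sag at a −100 mV steady state equals the type's target.
Above rheobase, spikes are emitted by integrating the rate model
IF(t) = f_end + (f₀ − f_end)(w_f e^(−t/τ_f) + (1 − w_f) e^(−t/τ_s)) with
f₀(I) = gain·(I − rheobase), one spike wherever the integrated rate
accrues one unit; optional multiplicative log-normal ISI jitter (default
CV 0.05) keeps trains ordered. Each AP is a threshold-anchored triangular
template — constant-slope rise at the target dV/dt, constant-slope fall
through the half-width target down to the AHP trough, a linear ramp back
to threshold before the next spike — whose amplitude decays and width
grows along the same bi-exponential kernel toward calibrated end ratios.
Spikes whose waveform cannot complete before stimulus offset are not
emitted, and the calibration (which solves f_end and the end ratios so
that the standard estimators on the deterministic criterion-sweep train
hit the published adaptation statistics exactly) applies the same rule,
so generator targets and extracted values agree to within discretization.
Cells draw a plateau flag with a per-type probability; plateau cells hold
−35 mV for 100 ms after offset. Per-cell recording metadata (series
resistance, RMP estimate, drift) is drawn so that typical cells pass QC.

**Morphologies.** Trees grow by stochastic recursion in 5-µm
compartments: per compartment, terminate at rate 1/mean_branch_len,
bifurcate at rate branch_prob_per_um (daughters taper and diverge by
35–43°), stop at the radial extent. The defaults order the three types as
observed — MSN densest (≈3.6 mm total length, ≈12 crossings at 30 µm,
spine density 0.57/µm), FANS intermediate (0.52/µm), THIN sparse and
aspiny — with z flattened to resemble slice-confined arbors.

**What the generators do not emulate.** Features are sampled
independently, so the within-type correlation structure of real neurons
(e.g. R_in with C_m) is absent; spike shapes are piecewise linear rather
than biophysical (no Hodgkin–Huxley dynamics, no depolarization block);
sag is a fixed-fraction relaxation, not an HCN model; noise is white
rather than 1/f with line pickup; morphologies have no varicosities,
no soma contours and no imaging artefacts. Passing tests therefore
demonstrate that the measurement and classification chain is correct and
self-consistent under realistic magnitudes — not that it is robust to
every artefact of real recordings.

## Numerical choices and degenerate inputs

Spike emission integrates the rate on a 0.1-ms grid with linear
interpolation of the crossing; detection and rendering work at the
protocol's sampling rate (default 20 kHz) and the renderer refuses rates
too low to resolve the AP upstroke. Exponential fits run bounded
Levenberg–Marquardt with multi-start initialization; non-convergent fits
return rss = ∞ and flags rather than errors. Cells without hyperpolarizing
sweeps get NA passive properties (the I-V fit needs two usable sweeps);
cells that never spike get NA for all AP-dependent features — NAs
propagate, they are never imputed silently. Ties in silhouette selection
break toward fewer clusters; duplicate items merge at height 0. All
stochastic stages derive per-cell/per-sweep seeds from one master seed,
so cohorts are reproducible end to end and byte-identical on re-run.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run cohort recovery at 30
cells/type over 10–20 seeds, feature round trips on full 41-sweep
renders, detection completeness on 100 seeds of two-sweep renders,
kinetics recovery on 50 jittered trains, and morphometry oracles on 100
random trees of a few hundred nodes — sizes at which every stochastic
check is stable across seeds while a full run completes in a few minutes
on one core.

## Known limitations

The FANS-subtype cohorts deserve a caveat: drawn as independent Gaussians
from the published subtype means ± SEM, the three subtypes overlap
heavily, and silhouette analysis on such cohorts typically prefers two
clusters. Recovering the finer split evidently depends on structure —
feature correlations, tighter effective spread, or properties beyond the
printed ones — that summary statistics do not carry. The package reports
what the procedure computes on the stated conditions rather than forcing
the published subtype count. Ward with correlation distance is a
convention, not a metric-space guarantee; and C_m values follow the τ/R
convention discussed above.
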