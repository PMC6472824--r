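---
title: "Moving-bump population dynamics and the geometry of rhythmic-timing trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-bump population dynamics and the geometry of rhythmic-timing trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bumptraj)
```

## The scientific problem

During rhythmic tapping to an isochronous metronome, medial premotor
populations show *moving bumps*: cells activate consecutively across each
produced interval, and the whole cascade repeats once per tapping cycle.
Projected into a low-dimensional state space, this population pattern traces
a closed loop per produced interval. Two competing readings of such data
exist. Under *temporal scaling*, the same loop is traversed more slowly for
slower tempos (speed falls, amplitude constant). Under *amplitude coding*,
slower tempos recruit more cells and trace larger loops at similar speed.
The package provides a simulation of the moving-bump account with
interval-dependent parameters, the full analysis chain (time normalization,
binning, shared-loading trajectories, loop geometry, demixed decomposition,
surprise-index activation periods, tempo and tap decoding), and an
end-to-end pipeline contrasting an *expanding* regime (neuron count and
single-cell activation duration grow with tempo) with a *static* control
(both fixed).

## The simulator and its stated world

`sim_config()` carries the published parameter set: target intervals 450,
550, 650, 850 and 1000 ms; 108, 120, 130, 170 and 182 neurons; activation
durations 197, 205, 213, 233 and 257 ms; 5 repetitions; 3 produced
intervals per trial. The static control fixes 130 neurons and 213 ms (the
mid-range values) at every interval.

**Single-cell waveforms.** Each cell's activation profile is the sum of 20
random gamma density functions: component modes uniform over the activation
window, shapes uniform in [2, 8], amplitudes uniform in (0, 1], the sum
peak-normalized to 1. Parameters are drawn relative to the window, so one
draw evaluated at two durations yields the same profile stretched in time —
this is how a cell's activation scales across tempos. A finite gamma sum is
not exactly zero at the right window edge, so a cosine taper over the outer
10% of the window (`edge_taper`, 0 disables it) enforces the contract that
the waveform vanishes outside its activation period.

**Recruitment.** Cells' peak times over a produced interval follow a
truncated Gaussian centred mid-interval. The recruitment *width is fixed in
absolute time* (`recruitment_sd_ms`, default 150 ms) rather than scaling
with the interval. This choice is deliberate: with the published neuron
counts and durations the instantaneous active mass `n * d / T` is nearly
constant by construction, and a recruitment width proportional to the
interval would make the population pattern in normalized phase essentially
identical across tempos — no amplitude modulation could then survive any
projection. A fixed absolute width concentrates recruitment mid-interval
relative to longer intervals, keeps the earliest activations before the
interval-start tap and the latest beyond the interval-end tap, and lets the
peak activation mass grow with `n * d`, which is the regime the expanding /
static contrast manipulates. A relative width remains available
(`recruitment_sd`).

Cells keep their recruitment *quantile rank* across intervals: base cells
sit at the quantiles of the recruitment distribution, and the extra cells a
longer interval recruits are inserted at random ranks strictly inside the
base span. Relative activation order is therefore preserved across tempos,
and added cells are intermediate, never at the bump's edges.

**Behaviour.** Produced intervals are Gaussian with mean
`target + constant_error` and SD `weber_fraction * target` (the scalar
property). Defaults: Weber fraction 0.05 and constant error −15 ms, values
typical of primate rhythmic tapping (the source data show a small
underestimation whose magnitude is not printed; −15 ms was chosen once and
not revisited). Metronome stimuli are exact; the continuation phase has
none. The reactive control draws interstimulus intervals from a pool,
places a stimulus-locked transient population response after every stimulus
(no periodic pre-stimulus build-up), and taps follow stimuli at a 381 ± 46
ms reaction latency.

**Noise.** Additive truncated-Gaussian rate noise, SD 0.05 of the peak rate
per 1-ms sample, clipped at zero. Oracle tests run noise-free.

**What a green test does and does not establish.** The generator emulates
cyclic sequential recruitment, nested populations and scalar behavioural
variability. It does not emulate: spiking irregularity beyond Poisson
draws, cell-to-cell rate heterogeneity (all waveforms are peak-normalized),
interval tuning of individual cells, motor transients at taps, or session
structure. Green tests therefore establish that the analysis chain measures
what it claims on data with known structure — not that the biological claim
is true.

## Normalization and binning

Event times are tap-normalized: the time of the interval-ending tap is
subtracted, the result divided by the produced interval, and the tap
sequence number added, so taps map to integers and a 7-tap trial spans
[0, 6]. Binning divides every inter-tap segment into half-open windows
(`[start, end)`; a spike exactly at a tap belongs to the following
segment): 50 windows per segment in UTND mode regardless of tempo, and
`round(target / 20 ms)` windows (half-up, so 23 at 450 ms and 50 at
1000 ms) in TIND mode. Rates are spike counts divided by the window's
real-time duration, in spikes/s; each neuron is then divided by its maximum
over all repetitions and intervals (silent cells flagged, left at zero).
Events before the first tap keep extrapolated negative normalized values
and are excluded from segment statistics.

## Trajectories and their geometry

The loading matrix is fitted once on the UTND matrix containing all trials
and intervals (per-neuron means subtracted and stored), and the same
transform projects every TIND trial, which makes trajectories comparable
across tempos and tasks. The first 8 components are retained by default
(the 1% variance cut is data-dependent, so the count is a parameter).
Lowess smoothing is applied per component along each trial with a span of
0.1 of one inter-tap segment (the source names the smoother but not its
span; the span is exposed).

Per segment: the radius is the mean distance from the segment centroid on
the plane of components 2–3 (a parameter — in clean simulations the
quarter-phase oscillatory pair often occupies components 1–2 instead);
variability pools the point-to-centroid distances across serial-order
segments and takes their SD (the alternative, SD of per-segment radii, is
`method = "radii_sd"`); linear speed is the mean bin-to-bin displacement on
components 1–3 divided by the bin duration, defined only for real-time
binning. Sinusoid fits use the model `a sin(2πt + c) + b t + d` on segments
resampled to 30 bins with time mapped to [0, 1] s; because the frequency is
fixed, the least-squares problem is linear and solved in closed form, with
the linear term playing the detrending role (fitting the line jointly
rather than sequentially keeps a pure sinusoid exactly recoverable).
Anchor analysis places a reference point at the centroid of all tap states
(or at the point minimizing the variance of anchor-to-tap distances,
`anchor_rule = "optimize"`) and regresses the anchor-to-tap and
anchor-to-half-interval distances on target interval. Distance profiles
resample segments to 30 bins by linear interpolation and compare bin by
bin.

## Demixed decomposition

The TIND data are resampled to 30 bins per segment, averaged per target
interval, and split exactly into a grand mean, a condition-independent
(time) marginalization, a target-interval marginalization and a per-trial
noise residual. Per marginalization, encoder/decoder pairs minimize the
reduced-rank regression loss; the solver is closed-form (ridge-regularized,
`lambda = 1e-6` times the mean diagonal of the data Gram matrix, raised
with a warning on rank deficiency). Components are ordered by explained
marginalized variance. A planted rank-1 interval effect is recoverable only
when its amplitude deviations have zero mean across conditions — a nonzero
mean belongs, by definition, to the time marginalization; the tests plant
effects accordingly.

## Activation periods

The surprise index of `n` spikes in a window of `T` seconds under baseline
rate `r` is `−log P(N ≥ n)` for a Poisson count, evaluated through the
incomplete-gamma identity in log space. Detection seeds a window at every
run of `min_spikes` spikes, grows the end while the surprise increases
(looking up to `lookahead = 3` spikes ahead so one lull does not truncate a
burst), trims the start likewise, and keeps non-overlapping windows by
descending surprise. Defaults — threshold 4.6 (≈ p < 0.01), 3 spikes,
20 ms — are explicit package choices; the source delegates them to cited
methods. The baseline is each cell's mean rate over the entire recording.
Calibration holds *per fixed window family* (the probability that a fixed
window's surprise exceeds `s` is at most `e^{−s}`); the greedy scan over
many windows is a maximum over a family and is not separately calibrated.

## Decoding

Tempo: each inter-tap segment of one first-layer component is resampled to
30 bins; a second-layer principal-component step turns each segment into a
3-coordinate point; a linear one-vs-one SVM (squared-hinge primal solved by
BFGS — written in-package, as no SVM library is available in the target
environment) is scored by 10 × 5-fold stratified cross-validation. The
component used is the one with the highest cross-validated accuracy.
Ablation removes the strongest-loading cells in 10% steps of the original
population down to 1%, flooring the smallest set at 15 cells (the published
endpoint of that step). Whether the first-layer loadings are re-fitted per
population size was genuinely open; measured on simulation, restricting the
original loadings decays to chance at the smallest sets while re-fitting
keeps every step far above chance — only the latter reproduces the
published robustness claim, so `refit = TRUE` is the default and the
restricted route stays available (`refit = FALSE`).

Tap times: a time-delay network (20 delays of the 20-ms-binned first
component, 10 sigmoid hidden units, sigmoid output) is trained toward 1 at
tap bins under a ridge-penalized squared error (the ridge stands in for
Bayesian-regularized backpropagation), by BFGS with restarts;
non-convergence reports the best restart with a warning. Output peaks above
0.12 are decoded taps; a decoded tap is correct within 60 ms of a produced
tap inside the decodable span (the first 19 bins of a trial cannot be
embedded and their taps are not scored). Trials are the cross-validation
unit.

## Numerical choices and degenerate inputs

Half-open bins make spike-count conservation exact; TIND bin counts round
half-up to match the printed 23-bin example; normalization is idempotent and
flags silent cells; zero-variance training matrices error; degenerate
segments (identical points) return radius 0 with a warning; single-bin
segments have no speed; identical produced intervals make the percentile
split return equal groups. Seeds: every generator is reproducible from its
config seed; the pipeline derives one deterministic substream per stage
from the master seed, all below 2^31.

## Known limitations

The central one is quantitative: with rates defined in spikes per second
and per-cell unit-peak normalization, a projected loop's amplitude is
bounded by the square root of the instantaneous active count, so with the
published parameter set (which holds `n * d / T` nearly constant) the
radius-versus-interval slope of the expanding simulation comes out slightly
negative rather than matching the published positive slope, and expanding
speed declines instead of staying flat. The variability contrast (expanding
increasing, static flat), the static temporal-scaling speed signature, the
activation-period trends and both decoders do reproduce. An alternative
unit convention — counts per normalized-time window, i.e. rate × produced
interval — recovers the published radius slope but eliminates the static
control's temporal-scaling signature and contradicts this package's binning
contract, so it was not adopted; the acceptance tests that depend on the
published radius slope are left failing rather than redefining the
contract. The simulator also omits the real-data features listed above, so
agreement on simulation is a check of the analysis chain, not evidence
about cortex.
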