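---
title: "Methods: simulating and analysing gonadotroph calcium recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing gonadotroph calcium recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadotrace)
```

## The experimental design being modelled

Pituitary gonadotrophs are identified functionally in perifusion calcium
imaging: a whole pituitary loaded with a calcium indicator is imaged at 5 Hz
(0.2 s/frame) while stimuli are washed over it. The default protocol is a
480 s recording — a 240 s (4-minute) pre-stimulus baseline used to score
spontaneous activity, a 30 s pulse of 10 nM GnRH, a washout, and a terminal
30 s high-potassium (KCl) depolarization. Any cell that responds to KCl is
alive and excitable; the KCl-responsive set is the 100% denominator for every
population fraction. Any KCl-viable cell whose calcium rises upon GnRH is
operationally a gonadotroph.

Three GnRH-evoked response shapes occur: **oscillatory** (repeated spikes
returning toward baseline), **biphasic** (an initial peak followed by a
sustained plateau), and **transitory** (a single small transient). After
cadmium exposure two further phenomena appear: the pattern mixture collapses
toward biphasic at 21 days, and at 35/56 days a subpopulation keeps
oscillating long past the pulse — **long-lasting** activity that continues
through washout and even the KCl window.

An alternative preset reflecting 1,000-frame (200 s) acquisitions is
available via `make_protocol(n_frames = 1000)`; the 4-minute baseline cannot
fit in such a recording, so the baseline is truncated with a warning and
spontaneous activity is scored on the available epoch. Whether basal activity
in the original design was scored from a separate recording is not
determinable from the published description; the 480 s default makes both
epochs coexist explicitly.

## Trace model

Each simulated cell renders as

$$F(t) = F_0\, e^{-\beta t}\,\bigl(1 + r(t)\bigr) + \varepsilon(t),$$

with resting fluorescence $F_0$ (log-normal around 100 a.u.),
photobleaching decay $\beta$ (default $5\times10^{-4}$/s, about 21% over
480 s), white Gaussian noise $\varepsilon$ with SD `noise_sd`·$F_0$
(default 0.3% — ROI-averaged traces from back-illuminated CCD imaging are
low-noise), and $r(t)$ a superposition of double-exponential transients
$k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$ normalized to unit peak:

* spontaneous events (baseline epoch only): Poisson count at
  `spont_rate` = 0.5/min in spontaneously active cells, rise 0.5 s /
  decay 3 s, amplitudes ≈ 0.18;
* the GnRH-evoked response (per pattern, below);
* a KCl kernel (rise 0.5 s, decay 5 s, amplitude ≈ 0.5) in every viable
  cell — except long-lasting cells, whose persisting spike train itself
  spans the KCl window, exactly as the class is defined.

**Amplitude calibration.** Every responder draws a peak response amplitude
$a$ from a lower-truncated normal whose *truncated* mean equals the group's
published mean MIF − 1 (the latent mean is solved numerically), and the
GnRH-evoked component is rescaled so its peak equals $a$ exactly. The
truncation floor (0.105; 0.13 for oscillatory cells) keeps every simulated
gonadotroph above the 10% detection criterion even after low-pass denoising;
using the truncated-mean inverse keeps the population mean on target despite
the floor.

**Spike trains.** Oscillatory cells draw a spike count from a negative
binomial matched to the published per-group mean/SD, truncated at ≥ 2 — a
single-spike trace is not identifiable as oscillatory by any peak-based
rule, and the published per-group minima (2–5 spikes) contain no
single-spike oscillatory cells. For the 21-day group the published SD² is
below the mean (NB undefined), so a rounded Gaussian clamped at ≥ 2 is used.
Spikes are spread quasi-regularly (jittered gaps, minimum 1.5 s) over the
response epoch — canonical cells within ~90 s of GnRH offset, long-lasting
cells through to a final spike inside the KCl window. Kernel decay narrows
with train density ($\tau_d = \min(2.05, 0.42\,\overline{\mathrm{ISI}})$ s,
floor 0.6 s), since fast-oscillating cells have correspondingly brief
transients; this also keeps inter-spike troughs resolvable at 5 Hz sampling.
The first spike of a train is rendered at full relative height because it
rides no predecessor tail.

**AUC calibration.** With amplitudes pinned to the MIF target, the area
under the response is set by waveform shape: the oscillatory kernel decay
(2.05 s) and the biphasic kernel (rise 0.5 s, decay 37.5 s, i.e. a sharp
rise followed by a slowly decaying plateau, ~40 s of area per unit
amplitude) were calibrated once against the control group's published mean
AUC given its pattern mixture and spike counts, then frozen. The recovered
control AUC is unbiased within sampling error; low-amplitude groups (21-day)
recover AUC with a small positive bias because the dF/F floor offset
(≈ Fmin noise bias × window length) is a larger share of a small area.

**Interventions.** `apply_intervention()` re-synthesizes a recording with
the same per-cell substreams and modifies event plans inside a window:
nifedipine scales evoked amplitudes and thins oscillation spikes
(configurable factors, weaker for long-lasting cells); the calcium-free/EGTA
paradigm abolishes spontaneous events and the KCl kernel in the window,
blunts long-lasting spikes to a configurable residual, and leaves events
after the window intact so activity recovers when calcium returns. The
response scale is fixed *before* interventions, so amplitude suppression
survives normalization. Unit factors reproduce the base recording
bit-for-bit.

**Seeding.** Each cell uses a private substream derived from (master seed,
cell index) by a linear congruential hash, so identical arguments are
bit-reproducible and growing `n_cells` never reshuffles earlier cells.

### What the generator does *not* emulate

Real recordings include motion, slowly wandering baselines that are not a
single exponential, correlated (shot + readout) noise, spontaneous activity
continuing through the response epoch, cross-cell covariance beyond shared
stimulus timing, and irregular/erratic oscillations of the kind seen at 35
days. Spontaneous events are confined to the baseline epoch by construction,
which keeps responder calls exact on synthetic data; on real data a
spontaneous transient inside the response window can masquerade as a GnRH
response. Passing recovery tests on this generator therefore demonstrates
that the analysis chain is unbiased under the stated waveform model — not
that it is robust to every pathology of real recordings.

## Preprocessing

`detrend_bleach()` fits one exponential to the 10th percentile of 20 s
blocks of the pre-stimulus baseline (a low percentile tracks the bleaching
envelope through sparse positive transients; the fit is a linear model on the
log scale, with a linear fallback) and divides it out. `preprocess()` then
applies a centred 3-frame (0.6 s) running mean — light denoising that
reduces the noise floor by √3 while attenuating the sharpest spike peaks by
under 3% — and normalizes each trace to dF/F = F/Fmin, whose per-column
minimum is exactly 1 by construction. Fmin is taken post-detrend over the
whole recording; positive transients do not move a minimum, and a noisy
minimum is the main source of the small (+1–2%) upward bias in dF/F levels,
which the design SE bands in the tests absorb. The KCl viability gate
retains ROIs exceeding dF/F 1.10 in the KCl window — the same 10% criterion
used for transients, since no separate depolarization threshold is
published — and can be disabled for calcium-free paradigms.

## Detection, metrics, classification

`detect_transients()` finds local maxima with (dF/F − 1) ≥ 0.10
(the published "10% of Fmin" criterion; since dF/F = F/Fmin, a transient
exceeding 10% of Fmin is exactly dF/F − 1 > 0.10), topographic prominence
≥ 0.05, and ≥ 1 s separation. Spontaneous activity is ≥ 1 such transient in
the first 240 s of baseline; responder status is dF/F − 1 ≥ 0.10 anywhere
from GnRH onset to 10 s before KCl onset. MIF is the windowed dF/F maximum;
AUC is the trapezoidal integral of max(dF/F − 1, 0) over the closed response
window, with the dF/F floor of 1 as baseline (a local pre-stimulus baseline
would disagree with the published normalization). The response window is
160 s from GnRH onset (capped 10 s before KCl): no window length is
published, so it is configuration, chosen so the printed AUC magnitudes are
achievable with the printed MIFs.

Classification is a fixed-order decision tree over the response window:
(1) ≥ 2 peaks whose median inter-peak trough falls below half the maximum
amplitude → oscillatory; (2) otherwise ≥ 30 contiguous seconds at ≥ 30% of
the maximum after the first peak → biphasic; (3) otherwise transitory. A
trace satisfying both rules is oscillatory — troughs returning toward
baseline are the class's defining feature. The published description gives
no numeric biphasic/transitory boundary, so these thresholds are exposed
configuration, not claims about the original visual scoring; the low
amplitude historically called "subumbral" and the "transitory" class are
treated as one single-transient class. Long-lasting means a detected
transient later than 120 s after GnRH offset (but before KCl onset) or ≥ 2
transients inside the KCl window — one KCl peak is the normal
depolarization response, repeated spiking there is the hallmark of the
long-lasting phenotype.

## Population and statistics

Synchrony is the zero-lag Pearson correlation of response-window segments
across responder pairs (the published figure is a static cell × cell
matrix; a ±lag maximum is available behind `max_lag_s`), with constant
traces assigned correlation 0 by convention. Aggregation follows the
published conventions strictly: responder and spontaneous fractions are
relative to KCl-viable cells, pattern proportions to responders, metric
means to responders, spike counts to oscillatory cells; group statistics are
mean ± sample SD over *per-animal means*, never pooled cells (pooling is
regression-tested against).

Inference uses the tie-corrected Kruskal–Wallis test (base R), Dunn's
pairwise mean-rank z tests with tie-corrected SE and Holm step-down
adjustment across all pairs of a metric (hand-implemented; no Dunn
implementation is available among the package's dependencies), and the
Wilcoxon signed-rank test for paired designs — exact by full enumeration of
sign patterns on midranks for n ≤ 12, normal approximation with continuity
correction and tie-corrected variance beyond. Zero paired differences are
dropped, the standard signed-rank convention. Dunn z is reported positive
when the second group of the pair has the higher mean rank. All three agree
with brute-force oracles in the test suite.

qPCR fold changes use the comparative 2^−ΔΔCt method: technical duplicates
averaged on the Ct scale, targets normalized to the housekeeping gene within
sample, ΔΔCt referenced to the mean ΔCt of the reference condition. With a
single housekeeping gene, "geometric mean expression" normalization reduces
exactly to its arithmetic mean Ct (log₂ space), and reference-condition fold
changes have geometric mean exactly 1.

## Test design and problem sizes

Recovery tests simulate the published cohort sizes — six animals per group
(five at 21 days) with tens to hundreds of cells per animal — and accept a
recovered statistic within three standard errors: the binomial design SE of
the pooled estimate for proportions (the exact SE of a mean of equal-sized
per-animal fractions, and more stable than an SD estimated from five
degrees of freedom), and the empirical across-animal SE for continuous
metrics. Exactness tests (label round-trips, spike counts, the 140-spike
fixture) run noise-free, where the pipeline is required to be perfect. The
null-calibration check runs 10⁴ Kruskal–Wallis replicates at n = 25 per
group, where the chi-square reference is accurate. These sizes keep the full
suite to a few minutes on one core while leaving every acceptance band
dominated by sampling error, not runtime compromise.

## Known limitations

* The AUC floor bias for low-amplitude groups noted above.
* The long-lasting fraction (default 0.25 of oscillatory/biphasic
  responders at 35/56 days) is a placeholder: no fraction is published.
* Correlation structure between cells arises only from shared stimulus
  timing; the generator cannot produce genuinely coupled oscillators, so
  synchrony comparisons across simulated groups are qualitative contrasts.
* Very dense spike trains (ISI at the 1.5 s floor) sit near the resolution
  limit of 5 Hz sampling plus 0.6 s smoothing; the generator's minimum gap
  and narrowed kernels are chosen so detection remains exact, but real data
  at such rates would demand a faster acquisition.
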