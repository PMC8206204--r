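---
title: "Estimating spontaneous-evoked correlation in M/EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous-evoked correlation in M/EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neural activity fluctuates spontaneously, and those fluctuations persist
through stimulation as trial-by-trial variation. Whether the pre-stimulus
state of a given electrophysiological variable shapes that variable's own
evoked response — and with which sign — cannot be read off a simple
correlation between pre- and post-stimulus values, because spontaneous
activity continues into the post-stimulus period: a trial selected for high
pre-stimulus amplitude remains high for a while for purely autocorrelational
reasons, and regresses to the mean thereafter. `sevcor` implements the two
estimators that avoid this circularity, together with the signal
decompositions (wavelet band power, oscillatory vs fractal components) and
the nonparametric cluster inference needed to apply them to sensor-time
data, and a generative simulation framework under which both estimators are
validated end to end.

## The two estimators

**TTV method.** For per-trial signal values, write the post-stimulus sample
as the sum of a spontaneous component $X$ and an evoked component $Y$. The
variance of a sum obeys

$$\sigma_{X+Y}^2 \;=\; \sigma_X^2 + \sigma_Y^2 + 2\,r_{XY}\,\sigma_X\sigma_Y .$$

All terms but the correlation $r_{XY}$ are non-negative, so a *decrease* of
across-trial variability after stimulus onset can only arise when
$r_{XY} < 0$. `ttv()` computes the across-trial standard deviation at every
channel and time point (sample SD, $n-1$ denominator), normalizes it to its
mean over the 100 ms pre-stimulus window, and expresses it as percent
change. `total_variance_oracle()` exposes the identity itself; the test
suite asserts it to $10^{-9}$ relative error. A TTV *increase* is not
informative about the sign of $r_{XY}$: it is compatible with independence
and with positive correlation alike.

**Pseudotrial method.** Trials are split at the median of their pre-stimulus
amplitude (mean over the 100 ms before onset, per channel) into high and low
groups. The same procedure is applied to *pseudotrials* — stimulus-free
segments of the same epochs, with their own "pre-stimulus" window — whose
group time courses estimate how spontaneous activity alone responds to the
selection, i.e. the regression to the mean. Subtracting pseudotrial from
real group means (high minus high, low minus low) and differencing the
corrected courses yields a signed estimate: a positive corrected
high-minus-low difference is evidence for positive spontaneous-evoked
correlation, a negative one for negative correlation.

Two conventions here were genuinely open and are fixed as follows:

* *Subtraction direction.* The source descriptions of the correction are
  ambiguous about which series is subtracted from which. `sevcor` computes
  `real − pseudo`, so that "high pre-stimulus leads to larger evoked
  response" always maps to a positive difference and positive cluster sign.
* *Normalization baseline.* Power-like signals are expressed as percent
  change before averaging, each trial kind normalized by the mean over its
  *own* pre-stimulus windows (real trials by the real pre-stimulus mean,
  pseudotrials by the pseudo-pre-stimulus mean). Time-domain signals are not
  normalized: their pre-stimulus mean is approximately zero, so percent
  change is undefined — `percent_change()` treats a non-positive baseline as
  an error to catch mis-routed signals.

**Windows.** All windows are half-open `[start, end)` with the onset sample
belonging to the post-stimulus period. Defaults: real pre-stimulus
`[-0.1, 0)` s, response `[0, 0.8)` s, pseudotrial response `[-0.9, -0.1)` s
with pre-stimulus `[-1.0, -0.9)` s. The pre-stimulus length control
(50/100/200 ms) rescales both pre-stimulus windows together and shifts the
pseudotrial onset so the pseudotrial block always ends exactly where the
real pre-stimulus window begins. An optional mode places the pseudotrial
uniformly at random in the eligible pre-onset span (seeded), for
anticipation controls in long inter-trial intervals.

## The synthetic-data generator

`gen_dataset()` emulates the statistical structure the estimators assume:

* **Background noise**: $1/f^\beta$ colored noise, $\beta$ drawn uniformly
  from $[0.5, 1.5]$ per trial, synthesized by shaping the spectrum of white
  Gaussian noise with $f^{-\beta/2}$ (DC zeroed) and standardized to unit
  sample variance. Spectral shaping gives the exact expected spectrum at
  $O(n \log n)$ cost.
* **Oscillation**: a 10 Hz sinusoid (random phase per trial) whose amplitude
  is itself a $1/f$ process low-pass filtered at 1 Hz (4th-order Butterworth
  applied forward and backward, i.e. zero phase), standardized and mapped to
  $1 + 0.5\,z$, floored at 0.05 so the amplitude stays physical.
* **Evoked responses**: one lobe of a sine (`response_duration`, default
  600 ms, starting at onset). `additive_coupled` adds the lobe with
  amplitude `gain ×` the pre-stimulus value (the mean raw signal over the
  100 ms before onset, matching the analysis definition); `additive_uncoupled`
  uses an independent standard-normal amplitude; `desync` multiplies the
  oscillation envelope by $(1 - d\cdot\mathrm{lobe})$, a pure oscillatory
  power reduction with no additive time-domain response.
* **SNR**: the noise is rescaled per trial so the oscillation-to-noise power
  ratio equals $\mathrm{SNR}_0 \exp(\mathcal N(0, s))$ — log-normal, keeping
  SNR positive. Grid sweeps map a variability level $v$ to
  $s = \sqrt{\log(1+v^2)}$, so the per-trial SNR multiplier has standard
  deviation $v$.

Defaults reproduce the reference cohort: 48 subjects, 128 trials of 4 s at
500 Hz (the rate the study's recordings were downsampled to), one channel.
Every trial's exponent, SNR, pre-stimulus value and realized response
amplitude are recorded as ground truth so coupling can be checked exactly
(`cor(prestim, amplitude)` is $\pm 1$ for coupled data and $\approx 0$ for
uncoupled).

**Calibration of the discrepancy experiment.** The magnitudes of the two
responses are not published quantities, so they are fixed once at values
that make both phenomena unambiguous at the 48-subject scale.
For the coupled simulation `run_discrepancy()` uses gain $-1$ — the evoked
amplitude is *minus* the pre-stimulus value, a unit-regression quench — over
a 300 ms lobe. The lobe must be fast: the correlation between the
pre-stimulus mean and the ongoing $1/f$ signal decays within roughly 300 ms,
and a 600 ms lobe peaks after the correlation is gone, where the added
component only inflates variance and no TTV decrease can form. (The slower
600 ms default is retained for the desynchronization arm and the SNR sweep,
matching the slower time course of oscillatory power changes.) The desync
depth is 0.8. With these values, both simulations produce a TTV decrease at
the permutation floor, and only the coupled one produces a pseudotrial
difference — the methodological discrepancy the experiment exists to show.

**What the generator does not emulate**: multichannel spatial covariance
(one simulated channel, as in the reference simulations), inter-trial
interval jitter and anticipation ramps, artifacts, non-sinusoidal
oscillations, and knee frequencies or multiple scaling regimes in the
aperiodic component. Passing tests therefore demonstrate estimator
correctness under the assumed generative structure, not robustness to every
property of recorded M/EEG.

## Spectral decompositions

**Wavelet band power.** `morlet_tfr()` convolves each trial with complex
Morlet wavelets (3 cycles by default; Gaussian SD $n_c / 2\pi f$, truncated
at $\pm 3$ SD) at 50 log-spaced frequencies over 2–200 Hz (2–50 Hz for
EEG-style data). Power is the squared magnitude; samples within one wavelet
half-length of the epoch edge are set to `NA` and excluded from all
downstream statistics. Whether "power" means amplitude or squared amplitude
does not affect the median split (a monotone transform); squared magnitude
is used throughout. `band_power()` averages over the frequencies inside a
closed band interval.

**Individualized bands.** `detect_alpha_band()` fits a robust (M-estimator)
line to log power vs log frequency over 4–18 Hz and looks for a residual
maximum in 7–14 Hz with prominence above 0.2 natural-log units; the band is
the peak ± its half-width at half prominence, floored at ±2 Hz. With a
detected peak, theta runs from 4 Hz to the alpha lower edge and beta from
the alpha upper edge to 30 Hz; without one, the standard 4–8/8–13/13–30
edges apply. Band edges always tile 2–30 Hz without gaps.

**IRASA.** `irasa()` separates a segment's spectrum into fractal
(scale-free) and oscillatory components by irregular resampling: for each
factor $h$ in 1.1–2.9 (step 0.05, excluding 2.0 — an integer factor would
map harmonics onto themselves), the segment is resampled by $h$ and by
$1/h$ (polyphase rational resampling) and both are *interpreted at the
original sampling rate*, which shifts spectral content by $1/h$ and $h$
respectively; a $1/f^\beta$ spectrum gains factors $h^{-\beta}$ and
$h^{+\beta}$ whose geometric mean restores it exactly, while an oscillatory
peak at $f_0$ lands at $f_0/h$ and $f_0 h$ and is rejected by the median
across the factor set. The oscillatory spectrum is the mixed spectrum minus
the fractal one; negative oscillatory values (possible because the fractal
estimate is a median) are propagated as missing data in all band summaries.

Estimator details that the generic description leaves open, fixed here and
validated in the test suite:

* Spectra are Hann-tapered periodograms of the (linearly detrended) segment,
  computed after first-difference *pre-whitening* and re-colored by the
  differencer's transfer function $4\sin^2(\pi f/f_s)$; without this, the
  steep $1/f^\beta$ spectrum leaks low-frequency power across the taper's
  main lobe and biases the lowest analyzed frequencies.
* The factor set is partitioned into six contiguous groups; within each
  group the up- and down-shifted spectra are averaged *before* the geometric
  mean. Averaging first removes the $\Gamma(3/2)^2 \approx \pi/4$ downward
  bias that the geometric mean of two independent $\chi^2_2$ periodogram
  estimates would carry; the median across groups still rejects oscillatory
  peaks, which any one $h$ shifts into a narrow factor run and hence into
  few groups.
* Down-shifted spectra are excluded below twice their own frequency
  resolution, where the shortened series cannot resolve the content.
* The fractal level is finally aligned to the mixed spectrum by the median
  of the per-frequency ratio, corrected by $\ln 2$ (the median of an
  exponential variable is $\ln 2$ times its mean). This robust scale
  matching centers the oscillatory residual on zero for scale-free input
  without disturbing slopes or localized peaks.

The analyzed range is 2–85 Hz: 85 Hz is the highest frequency whose
up-shifted content ($85 \times 2.9 \approx 247$ Hz) stays below the 250 Hz
Nyquist frequency, and 2 Hz is about the lowest frequency a 1.5 s window
resolves after down-shifting. `fit_fractal()` resamples the fractal
spectrum to points equally spaced in log frequency (so the dense
high-frequency end does not dominate), fits a least-squares line through
$(\ln f, \ln P)$, and reports the scaling exponent $\beta$ (negative slope)
and the broadband offset (exponentiated intercept, i.e. fitted power at
1 Hz; exponentiation uses the same natural-log base as the fit, asserted by
the exact case $P = 10 f^{-1.5} \Rightarrow$ offset $= 10$). The
time-resolved variant slides a 1.5 s window in 20 ms steps, centered on
each output time.

## Statistics

Point-wise inference uses Wilcoxon signed-rank tests at every channel and
time point, with zero differences dropped, mid-ranks for ties, and the
tie-corrected, continuity-corrected normal approximation (as in
`wilcox.test`); exhaustive sign-flip enumeration at $n = 6$ agrees with the
approximation to better than 0.05.

Cluster inference: points with two-tailed $p$ below the cluster-forming
threshold (0.05 by default; the choice is configurable because no canonical
value exists) are grouped by adjacency — consecutive time samples, and
channels within 1.3 × the median nearest-neighbor distance on the 2-D
layout at the same time point; single-channel data cluster over time only.
Cluster mass is the sum of member $z$ values, signs are kept separate, and
the null distribution is the maximum absolute cluster mass over random
within-subject condition swaps (sign flips of the paired differences, whose
absolute values — and hence ranks — are flip-invariant, so the ranks are
computed once). The observed statistic is included in the permutation
count: with $N$ permutations the one-tailed $p$ is at least $1/N$ and the
reported two-tailed $p$ at least $2/N$ — 0.002 at the 1000 permutations used
for simulations, 0.0002 at the 10 000 used for full analyses. Effect size
is Cohen's $d$ for dependent samples (mean difference over SD of the
differences) at every point; per-sensor summary indices are the signed area
under the effect curve across the time points of a significant cluster, and
the two methods' indices are compared across subjects by Spearman rank
correlation with spatially clustered permutation inference (subject
shuffles).

## Numerical conventions and degenerate inputs

* Median split: trials stably sorted by value with ties broken by trial
  index; top half high; with an odd count the middle trial goes low, so
  group sizes differ by at most one.
* Identical trials (zero across-trial SD) make the TTV baseline degenerate
  and raise a classed error rather than returning infinities.
* All randomness flows from explicit seeds; a master seed fans out through
  `child_seed()` (a multiplicative-congruential hash of the seed and an
  index path, always below $2^{31}$), so adding a downstream analysis stage
  never perturbs the random streams of earlier stages, and identical
  configurations reproduce bit-identical datasets and cluster masses.
* Epochs are exchanged losslessly in a documented Arrow/Feather layout
  (long-format table, schema metadata for the sampling rate, channels and
  layout version) readable from any Arrow implementation; EDF import/export
  is provided for interoperability with recording software, with the format's
  inherent 16-bit quantization.

## Problem sizes

The discrepancy experiment runs at its native scale (48 subjects × 128
four-second trials, 1000 permutations) in both the test suite and the
acceptance script. Supporting analyses choose sizes adequate to their
question: null calibration uses 40 cohorts of 12 subjects × 48 shorter
trials at 250 Hz (a false-positive rate is a property of the procedure, not
of the cohort size); the SNR sweep uses 8–10 subjects per cell with
detection rates as the outcome; IRASA property checks average 10–40
independent 4–8 s segments. These are the package's own choices of scale
for each question.

## Known limitations

* The aperiodic model is a single power law; knee frequencies and
  multifractal spectra are out of scope (the resampling in IRASA blurs the
  boundaries between scaling regimes).
* Band-edge oscillatory estimates at 2–4 Hz from 1.5 s windows carry the
  variance of a few periodogram bins; the sliding-window analyses are
  therefore most reliable as *contrasts* across conditions rather than as
  absolute band levels.
* The pseudotrial estimator assumes the inter-trial interval is long enough
  to carve a stimulus-free pseudotrial plus its pre-stimulus window from
  each epoch; epochs that do not cover the windows raise window errors
  rather than silently truncating.
* TTV decreases in broadband time-domain signals are not by themselves
  evidence of spontaneous-evoked correlation — demonstrating that confound
  is precisely the point of the two-simulation experiment.
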