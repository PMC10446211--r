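---
title: "Methods: population coding under axonal conduction delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population coding under axonal conduction delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`delaypop` analyzes stimulus encoding in converging sensory populations
when the presynaptic spikes do not arrive simultaneously.  The package was
developed around the active electrosensory system of wave-type electric
fish — p-type electroreceptor afferents (P-units) that phase-lock to the
electric organ discharge (EOD) and rate-code its amplitude modulations
(AM) — but the estimators and the integrate-and-fire population model are
generic.  This vignette documents the models, the estimators, the
calibration of the synthetic data generator, and the numerical choices.

## Signals and spike trains

Two containers carry all data: `sampled_signal` (a uniformly sampled
waveform with a rate in Hz) and `spike_train` (strictly increasing spike
times in seconds on `[0, duration]`).  Firing rates are estimated by
convolving binned spikes with a unit-mass Gaussian kernel
(`firing_rate()`); the kernel standard deviation defaults to 1 ms, the
rate grid to 20 kHz.  The convolution is zero-padded, so spikes within
about five kernel widths of an edge lose part of their mass; the rate
integral therefore equals the spike count only away from the edges, and
tests assert this with a 0.5% allowance.

All "standard deviations" of rates and intervals (`cv_isi()`,
`response_modulation()`, `response_variability()`) use the population
(divide-by-n) convention, because the defining expressions are plain
averages over time, trials or intervals.

Phase locking is quantified by the vector strength, the resultant length
of the unit phase vectors divided by the spike count, so that 1 means
perfect locking — the printed sum formulation only has a `[0, 1]` range
with this normalization.  Spike phases are measured from the preceding
rising zero-crossing of the carrier and normalized by that cycle's own
period; per-cycle normalization (rather than a mean-period normalization)
keeps the phase exact when carrier periods fluctuate.  For recorded
carriers with arbitrary waveforms any list of detected cycle-onset times
can be supplied instead.

Burstiness follows the interspike-interval convention: the fraction of
ISIs shorter than 1.5 EOD periods (not the fraction of spikes inside
bursts, a near-synonymous quantity that differs in edge cases).

The spike-triggered average (`sta()`) is the spike-count weighted mean of
stimulus segments around each spike; its peak lag is the response delay
(`sta_delay()`, positive when the stimulus precedes the spike).  Spikes
closer than the window half-width to the stimulus edges are excluded.

## Spectral estimation and information

`welch_spectra()` implements Welch averaging for auto- and cross-spectra
with trials and segments pooled into a single average: each trial is cut
into overlapping segments (50% by default), each segment is de-trended by
its mean and multiplied by a periodic Hann window, and periodograms are
averaged over all segments of all trials.  The default segment length is
the power of two nearest one second of samples, matching common practice
(2^15 samples at 40 kHz is 0.82 s).  The implementation is checked in the
test suite against frozen reference values computed with an independent
implementation (scipy.signal) on a deterministic tone fixture, to 6
significant digits.

The cross-spectrum convention is `Pxy = <conj(X) Y>`: the phase of `Pxy`
is the phase of the response relative to the stimulus, so a response
lagging by `d` seconds has phase slope `-2 pi d`.  The transfer function
is `H = Pxy / Pxx` with a relative power floor (`1e-10` of the peak
stimulus power) below which the quotient is masked.

Squared coherence is clipped into `[0, 1]`, and the lower-bound
information rate

\[ MI = -\int_{f_1}^{f_2} \log_2\!\big(1 - \gamma^2(f)\big)\, df \]

is computed by trapezoidal quadrature on the Welch grid with linearly
interpolated band edges; the coherence is clipped at `1 - 1e-12` before
the logarithm.  For band-limited stimuli the integration runs over the
stimulated band only; for the broadband AM stimulus it runs over
0-300 Hz.  The quadrature error is far below the estimator noise at the
default grid (about 1.2 Hz spacing).

Two estimator artifacts matter and are deliberately surfaced rather than
hidden.  First, with `n` averaged segments the coherence of independent
signals is biased to about `1/n`; information estimates from few segments
are therefore inflated.  The Gaussian-channel test (response = stimulus +
white noise at in-band SNR 1) requires at least 40 segments to recover
`300 log2(2) = 300` bit/s within 5%.  Second, when estimates with
different segment counts are compared (e.g. a single-neuron reference
versus population curves), the bias must be matched — all sizes in
`info_vs_size_sweep()` use identical Welch settings for exactly this
reason.

Cutoff frequencies scan outward from the spectral peak to the first
crossing of `max/sqrt(2)` (gain, -3 dB) or `max/2` (coherence) with
linear interpolation; a curve that never falls below threshold on a side
reports the range edge and a flag.  The half-maximum convention for
coherence cutoffs is a package choice isolated behind the `mode`
argument.

## Artificial populations

Homogeneous populations combine unique random combinations of distinct
trials of one cell (up to 10 per size); heterogeneous populations draw
one trial each from distinct cells (50 per size by default).
Heterogeneous members are aligned to the stimulus by subtracting their
cell's STA delay, which removes conduction-delay differences before any
controlled delay is injected.  Trials of a single cell share one delay,
so alignment is a no-op for homogeneous populations.

`inject_delays()` draws one zero-mean Gaussian delay per member and
shifts all of that member's spikes rigidly — mimicking a conduction
delay without adding spike-time jitter; within-member ISIs are preserved
exactly.  Draws are clipped at four standard deviations to bound spike
loss at the trace edges; dropped spikes are counted and attached to the
population response.  Grid analyses reuse one set of standard-normal
draws across all conditions (common random numbers), so differences
across a delay/kernel grid reflect the filtering rather than sampling
noise.

The population response is the average of the members' kernel rates
(1 ms kernel for recording-style data, 1.25 ms for the LIF model).  In
the delay-versus-synaptic-filter grid the Gaussian rate kernel itself is
widened to `sigma_kernel` (it proxies the synaptic low-pass); widening is
not stacked on top of the baseline kernel, which would obscure the
stated width.  A Gaussian kernel is an invertible linear filter, so in
exact arithmetic it cannot change coherence; the information loss along
the kernel axis arises where the attenuated response power falls to the
spectral leakage floor of the windowed estimator.  That loss is real for
any finite-precision pipeline, but it is much weaker than the loss along
the delay axis, which destroys phase alignment across members — the
package reproduces the characteristic asymmetry (delay hurts more than
an equal synaptic kernel).

## The LIF population model

`simulate_lif()` integrates
\[ \tau_m \dot V = -V + I_{off} + I_{stim}(t) + \sqrt{2D}\,\xi(t) \]
by Euler-Maruyama with per-step noise increment
`sqrt(2D dt)/tau`, spike emission and reset at threshold crossing.  Times
are in milliseconds inside the integrator (`tau_m` 0.25 ms, `dt` 0.01 ms,
`2D` = 5 by default; currents dimensionless); spike times are returned in
seconds.  Spikes are recorded at the crossing step without sub-step
interpolation — at `dt` = 0.01 ms the bias is far below the rate-kernel
width.  There is no refractory period in the population model.  Two
closed forms anchor the integrator: the deterministic ISI
`-tau ln(1 - theta/I)` (0.1277 ms at the default parameters, matched
within one `dt`) and the free-membrane Ornstein-Uhlenbeck variance
`2D/(2 tau)` (matched within 5%).

The population is a 1-D array at 2000 neurons/m; every neuron receives
the identical frozen stimulus plus independent noise, and each neuron's
spikes are shifted by its conduction delay before rate averaging.  Delays
are referenced to the population center; coherence magnitude is invariant
to the common offset, so only the spread matters (a property the test
suite checks directly).  `info_vs_size_sweep()` exploits exactly this:
neurons are simulated once for the largest size and reused across sizes
and velocities, with delays applied as post-hoc rigid shifts (rounded to
the 20 kHz rate grid, i.e. to 25 microseconds, which is negligible
against the 1.25 ms kernel).

For the crossover analysis (information falling back to the
single-neuron level at low conduction velocity and a high-frequency
band), the information-versus-size curve is intrinsically tangent to the
reference near the touching point, so the estimated curve may approach
without piercing it.  `crossover_size()` therefore interpolates the
crossing when the curve pierces the reference and otherwise reports the
closest approach beyond the peak (within a factor 1.5); averaging
replicate sweeps with fresh frozen stimuli, and optionally smoothing the
size axis with a short running mean, stabilizes the estimate.  The
delivered experiments use 24 trials per sweep, 0.2 s Welch segments
(72 segments per size — shorter segments trade frequency resolution for
a lower coherence-bias floor, which matters at single-neuron coherences
of order 0.01), and 3-4 replicate sweeps.

## The synthetic P-unit generator

Real P-units fire probabilistically but phase-locked to the EOD, skip
cycles, are bursty to very different degrees, and rate-code AM stimuli.
The surrogate encoder reuses the same LIF integrator with drive

\[ I(t) = I_{bias} + A \,\max(0, \sin 2\pi f_{EOD} t)\,
   \big(1 + g\, a(t)\big), \]

i.e. a half-wave rectified carrier-locked input modulated by the AM
waveform `a(t)`, plus an absolute refractory period of 1 ms (about one
EOD cycle) so at most one spike per cycle is fired, as observed.  Phase
locking, cycle skipping and rate coding then all emerge from one
mechanism.  The membrane constant is 0.5 ms and the integration step the
stimulus sampling interval (0.05 ms at 20 kHz).

The distributional form of P-unit heterogeneity is not empirically
constrained; the generator draws `bias_current` and `noise_intensity`
log-uniformly and `locking_strength`/`am_gain` uniformly from ranges in
`punit_heterogeneity()`.  These ranges were calibrated once against the
published summary statistics of recorded P-units — baseline rates of
roughly 60-530 Hz (mean about 250 Hz), CV_ISI about 0.5, vector strength
about 0.86, variable burstiness, response modulation of order 145 Hz and
single-cell information of order 100-300 bit/s at 10% AM contrast — and
are fixed; the test suite verifies that a generated population lands
inside the empirical mean +/- sd bands.  Carrier frequencies are drawn
from 611-875 Hz (the across-fish range), receptor positions uniformly
from a configurable span of a 0.15 m body, and every spike of a cell is
shifted by its ground-truth conduction delay
`position x body_length / velocity`.

What the generator does *not* emulate: receptor transduction dynamics, a
realistic EOD waveform (the carrier is a pure sinusoid, so cycle onsets
are exact zero-crossings), body-geometry changes of EOD amplitude and
waveform along the fish, serial ISI correlations, and any correlation
between cells beyond the shared stimulus.  Passing tests on synthetic
data therefore demonstrate estimator correctness and the qualitative
population phenomena (heterogeneity benefit, delay filtering), not
quantitative agreement with any particular recording.

## Localization and conduction velocity

Receptor positions are estimated from dipole scans: the power of the
firing rate at the AM frequency (Welch, ~1 s segments) versus dipole
position is fitted with a Gaussian plus additive baseline
(`b + a exp(-(x-c)^2 / 2w^2)`, Levenberg-Marquardt via minpack.lm,
center initialized at the argmax, width at a quarter of the scan span).
The baseline term absorbs the spontaneous-rate power floor; because only
the relative profile matters, the center estimate is invariant to
stimulus intensity.  Flat scans and non-convergent fits raise explicit
localization errors.

The preferred phase of baseline firing grows linearly with the
conduction delay and wraps at one EOD cycle.  `cluster_and_unwrap()`
standardizes (phase, position), runs k-means with k = 2 and 10 seeded
restarts (phase and position have incommensurate units, hence the
standardization; the feature pair, rather than phase alone, disambiguates
cells near the wrap), and adds `2 pi` to the caudal cluster when the
rostral cluster's mean phase exceeds the caudal's by at least `pi` — the
signature of a genuine wrap.  Data without such a gap (monotone within
one cycle, or already unwrapped) pass through unchanged, making the
operation idempotent.  Velocity is then `1/slope` of the ordinary
least-squares regression of absolute delay (`phase / (2 pi f_EOD)`)
on absolute position; a shared response latency is absorbed by the
intercept, and a non-positive slope raises an error rather than
returning a negative velocity.

One cycle is all this scheme can unwrap.  Whole wraps shared by every
cell cancel into the intercept and are harmless, but the *relative* delay
across the sampled positions must span less than about 1.5 cycles with a
single internal wrap boundary — comparable to the roughly 1.4-cycle
spread in the motivating dataset.  Across fish, carrier frequencies
differ, which makes the wrap boundary cell-specific once delays approach
the cycle period; phase-based velocity studies therefore use one carrier
frequency per study and choose the position span so the delay spread
stays near one cycle (`phase_study_position_range()` encodes this
geometry).  STA-based delays have no wrap ambiguity and provide the
complementary estimate for driven recordings.

Feature-position correlations use Pearson's r with two-sided p-values
multiplied by the number of tests (Bonferroni, capped at 1);
zero-variance features are flagged instead of correlated.

## Pipeline and reproducibility

`run_experiment()` drives the stages (`synth`, `characterize`,
`popinfo`, `lifsweep`) from a YAML/JSON or list config; unknown keys are
rejected by name, every run writes a manifest echoing the full config and
seed, and identical configs reproduce byte-identical result CSVs.
Studies are written as plain text (`stimulus.csv`, `cells.json`, one
spike-time file per trial) and round-trip through the package's readers
at full double precision.  All randomness flows through explicit integer
seeds; derived seeds are drawn below 2^30.

## Problem sizes in the delivered tests

The test suite runs desk-scale versions of each analysis: calibration on
40 cells with 2 s baselines; heterogeneity-benefit comparisons on a
12-cell study with ten 10 s trials per cell (10 homogeneous populations
per cell, 50 heterogeneous per size); delay filtering on a 22-cell study
(populations of 20, six delay levels; a 16-cell 4x4 delay/kernel grid);
LIF sweeps over sizes 1-70 with 24 trials and 3 replicates; velocity
recovery over ten studies of 40 cells spanning 10-60 m/s.  These sizes
were chosen to keep each experiment's estimator noise safely inside the
assertion tolerances while the whole suite completes in minutes.

## Known limitations

- The information estimate is a linear (coherence-based) lower bound;
  nonlinear encoding (e.g. envelope coding by saturating cells) is
  invisible to it.
- Coherence estimates carry the `1/n_segments` bias; comparisons are
  only made between estimates with matched segment counts, and absolute
  values from short recordings are inflated.
- Cells are treated as independent given the stimulus; correlated noise,
  weighted readouts and selective integration are out of scope.
- The phase-unwrapping velocity estimate resolves a single cycle
  ambiguity, as discussed above.
- The population readout is plain rate averaging; no integrator neuron
  with its own dynamics is modeled.
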