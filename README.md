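# delaypop

Population coding under axonal conduction delays.

Converging sensory populations pool many presynaptic spike trains into one
postsynaptic response.  Textbook treatments assume the spikes arrive
simultaneously, but axons have finite conduction velocity and a receptive
field has spatial extent: spikes from one end of the field lead, spikes
from the other end lag.  `delaypop` quantifies what that spread of arrival
times does to stimulus encoding, using the p-type electroreceptor
afferents (P-units) of the weakly electric fish *Apteronotus
leptorhynchus* as the model system: P-units encode amplitude modulations
(AM) of the fish's quasi-sinusoidal electric organ discharge (EOD), fire
phase-locked to the EOD cycle, and converge onto hindbrain pyramidal
cells with receptive fields spanning large parts of the body.

## What the package computes

**Single-train metrics.** Gaussian-kernel firing rates
y(t) = sum_j F(t - t_j) with F a unit-mass Gaussian; vector strength
rho = |sum_j exp(i phi_j)| / n of spike phases within the carrier cycle;
CV_ISI = sd(ISI)/mean(ISI); burst fraction (ISIs shorter than 1.5 EOD
periods); response modulation sigma_mod (temporal sd of the mean rate) and
across-trial variability sigma_psth; spike-triggered averages and the STA
response delay.

**Spectral estimates and information.** Welch-averaged auto- and
cross-spectra pooled over trials and ~1 s Hann-windowed segments, the
transfer function H(f) = P_rs(f)/P_ss(f) with -3 dB cutoffs, the squared
stimulus-response coherence gamma^2(f) = |P_sr|^2 / (P_rr P_ss), and the
linear lower bound on the mutual information rate

    MI = -Integral_band log2(1 - gamma^2(f)) df   [bit/s]

**Populations.** Homogeneous populations (repeated trials of one cell) and
heterogeneous populations (one trial each from distinct cells, aligned to
the stimulus by their STA delays); injection of Gaussian per-member
conduction delays (rigid shifts, sd sigma_delay); information versus
population size; matched-modulation comparison of homogeneous and
heterogeneous populations; the delay-versus-synaptic-kernel information
grid.

**LIF population simulator.** Leaky integrate-and-fire neurons,
tau dV/dt = -V + I_off + I_stim(t) + sqrt(2D) xi(t), arranged on a 1-D
sensory surface (2000 neurons/m) converging with finite conduction
velocity; coherence-based information of the population rate across sizes,
velocities and stimulus bands, including the population size at which
delays cancel the benefit of averaging.

**Synthetic P-unit generator.** A calibrated surrogate encoder (rectified
carrier-locked drive into the same LIF integrator, with an absolute
refractory period of one EOD cycle) reproduces the empirical heterogeneity
of P-unit baselines (rates ~60-530 Hz, CV_ISI ~0.5, vector strength ~0.86)
and rate-codes frozen band-limited Gaussian AM stimuli at 10% contrast,
with receptor positions, ground-truth conduction velocity and
receptive-field profiles known exactly — so every downstream estimator can
be tested by parameter recovery.

## Worked example

```r
library(delaypop)

study <- generate_study(n_cells = 8, velocity = 47.2, n_trials = 4,
                        duration = 10, seed = 7)

cell   <- study$cells[[1]]
onsets <- eod_cycle_onsets(cell$params$eod_frequency, cell$baseline$duration)
vs     <- vector_strength(cell$baseline, onsets)
rates  <- lapply(cell$trials, firing_rate)
coh    <- coherence(study$stimulus, rates)

pops <- assemble_heterogeneous(study, size = 8, n_populations = 5, seed = 1)
mi8  <- sapply(pops, function(a) population_mi(a, study)$mi)
del  <- sapply(pops, function(a)
  population_mi(inject_delays(a, 0.002, seed = 2), study)$mi)
```

printing, for this seed:

```
baseline rate : 369 Hz
CV_ISI        : 0.36
vector strength: 0.84
single-cell MI: 190 bit/s (0-300 Hz)
8-cell population MI: 659 +- 6 bit/s
with 2 ms delay spread: 271 bit/s
```

The single cell fires at 369 Hz, phase-locked to its carrier (vector
strength 0.84), and its response carries about 190 bit/s about the AM
stimulus.  Averaging eight distinct cells more than triples the
information; spreading their arrival times with a 2 ms conduction-delay
jitter destroys most of that gain — delays act as an information filter
that hits high-frequency stimulus components first.

## Layout

- `R/` — signals, spike-train metrics, spectral/information estimators,
  population assembly, localization/velocity regression, LIF simulator,
  synthetic generator, config-driven pipeline (`run_experiment()`)
- `src/` — Rcpp LIF integrator
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/` — methods vignette describing the models, calibration and
  numerical choices
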