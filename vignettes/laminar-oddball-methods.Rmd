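---
title: "Methods: laminar visual-oddball analysis with ground-truth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar visual-oddball analysis with ground-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During a visual oddball paradigm, the same grating orientation is seen in
three sensory contexts: equiprobable among seven others (the many-standards
*control*), highly likely (*redundant*), and rare among repetitions of the
orthogonal orientation (*deviant*). Comparing responses across contexts
separates *stimulus-specific adaptation* (SSA: redundant < control) from
*deviance detection* (DD: deviant > control), the cortical analogue of the
human mismatch negativity. With a 16-contact laminar probe spanning ~750 µm
of primary visual cortex, these contrasts can be resolved by depth
(layers 1, 2/3, 4, 5), by signal class (transmembrane currents, aggregate
spiking, oscillatory power), and by inter-laminar synchrony.

`laminarodd` implements the complete analysis chain for such recordings and,
critically, a forward simulator that injects *known* context effects so that
every stage of the chain can be validated by effect recovery rather than by
eyeballing.

# Signal chain

## LFP conditioning and CSD

The LFP path is a zero-phase (forward-backward) Butterworth low-pass with a
110 Hz passband edge. The filter is designed in second-order sections with
its -3 dB point placed 22% above the passband edge; the resulting zero-phase
response has < 0.1 dB ripple below 100 Hz and > 40 dB attenuation at 200 Hz.
After filtering, the LFP is decimated to 1 kHz (all analysed content lies
below 110 Hz).

The current source density (CSD) is the second spatial difference of the
voltage along depth, with the sinks-negative sign convention
(CSD = -d²V/dz²), divided by the squared 50 µm pitch. Boundary contacts use
Vaknin replication of the edge voltages by default so that the full
16-contact profile survives (the 12-contact layer window needs it); dropping
the undefined edge contacts is available as a configuration choice. Depth
smoothing convolves a normalised 5-point Hamming window across contacts
(edge-replicated); a 5-point Gaussian is the config alternative. The
description of this smoother in the field is ambiguous ("gaussian-smoothed
with a Hamming window"); we implement the concrete reading — a 5-point
Hamming kernel — and expose the Gaussian variant.

The per-layer *av-rec* waveform averages the CSD across trials per channel,
takes the absolute value, and averages the rectified currents within a
layer: a non-negative index of total transmembrane current that is immune to
sink/source cancellation across channels.

The simulator's LFP forward model is deliberately 1-D: the voltage profile
of an injected zero-sum current profile is its double cumulative sum along
depth (unit conductivity). This makes the CSD estimator an exact inverse at
interior contacts, so CSD recovery is checkable to machine precision — a
design choice that trades biophysical realism for testability.

## Layer-4 alignment

Recordings are aligned on a putative granular (layer 4) contact scored by
rank sum over three criteria: earliest multiunit peak, earliest current
sink, and the depth at which the power spectrum shifts from gamma (30–80 Hz)
to alpha/beta (8–30 Hz) dominance — the supragranular/infragranular
transition, taken to sit two contacts below the granular contact. The
crossover band edges are not standardised in the literature; both bands are
configuration fields. Latency criteria are discounted by relative amplitude
(15 ms over the full amplitude range) so that, among contacts whose
responses onset together, the strongest wins; contacts below 25% of the
maximum amplitude do not compete. Ties break superficially. When criteria
disagree by more than 3 contacts a warning is logged and the rank-sum winner
is still used. Whether the original protocol combined its criteria formally
or by inspection is unknown; the rank-sum rule is this package's choice.

The kept window is 12 contacts — 7 above and 5 below (inclusive) the
granular contact — partitioned from the top as 2 (L1), 5 (L2/3), 2 (L4,
alignment contact first) and 3 (L5).

## MUA envelope

Per contact: zero-phase 500–4000 Hz band-pass; common average reference
against the mean of the *other* 15 band-passed channels (removes common-mode
artifacts; the instantaneous mean of all referenced channels is identically
zero); full-wave rectification; Gaussian smoothing; decimation to 1 kHz.
"10 ms Gaussian windows" is ambiguous between FWHM and SD: the default reads
it as FWHM (sigma = 4.25 ms), with an SD interpretation available in the
config. The Gaussian is truncated at 3 sigma; its gain at 400 Hz is below
10^-24, so it is also the anti-alias filter for the 10-fold decimation.
Rectification precedes smoothing and down-sampling, in that order.

Envelopes are normalised by one scalar per recording — the SD of the
continuous envelope pooled over channels and timepoints — and the analysis
orientation is the one with the strongest normalised response in the first
100 ms, averaged over trials, kept contacts and contexts. A subject whose
best response stays below 0.5 normalised units is flagged "no clear
response" and excluded from MUA statistics only.

## Time-frequency analysis

Morlet wavelets: 100 frequencies (2–101 Hz, 1 Hz steps), cycles increasing
linearly 0.5 to 20, evaluated every 4 ms from -250 ms pre-onset to 250 ms
post-offset of the 500 ms stimulus. Kernels are amplitude-normalised so a
unit sinusoid at a grid frequency gives |W| = 1; absolute power is therefore
in relative units, which cancels in every context contrast. Output bins
whose 3-sigma wavelet support is not fully covered by the epoch are flagged.
LFP epochs are cut at -400 to +900 ms so no analysed bin is edge-flagged.

Induced power is the across-trial mean of |W|², averaged within layers. The
global baseline — one scalar per frequency and layer, pooled across *all*
contexts and trials over -200 to -50 ms pre-stimulus — is subtracted from
every context's map. Reading the baseline window as "-200 to -50" rather
than "-200 to +50" avoids smearing stimulus-onset energy into the baseline
through long low-frequency wavelets; the alternative reading is a config
switch. Because the shift is context-shared, context differences are
algebraically identical before and after correction.

Inter-electrode synchrony (IES): for each contact pair and frequency, the
phase-locking factor R is the resultant length of the phase-difference
phasors pooled over trials and the timepoints of the analysis window (early
50–250 ms, late 250–450 ms). Stimulus-locked phase alignment inflates R
without any electrode interaction, so a surrogate R is computed with one
contact's phases taken from the trial two positions ahead (wrap-around, so
every trial is used once) and subtracted. The resultant length was chosen as
the phase-consistency estimator (over, e.g., pairwise phase consistency)
because the phase-locking factor is the quantity the protocol reports;
"summing over trials" is read as the pooling over window timepoints inside
the resultant.

## Statistics

*Windowed contrasts.* Av-rec CSD (per layer) and normalised MUA (per kept
contact) are averaged in 30 ms bins from 50 to 260 ms and compared across
contexts by paired t-tests over subjects: MUA one-tailed in the hypothesised
direction (SSA reduction, DD increase), CSD two-tailed (either sign of
current change is compatible with either phenomenon).

*ROI ANOVA.* Six time-frequency regions of interest (delta/theta 2–7 Hz at
100–150 ms; low beta 12–22 Hz at 65–180 ms; high beta 26–35 Hz at 90–120 ms;
high gamma 68–77 Hz at 110–260 ms; alpha desynchronisation 6–12 Hz at
240–310 ms; late delta/theta 2–7 Hz at 350–560 ms) are each tested with a
layer (4) x context (3) repeated-measures ANOVA, Greenhouse–Geisser
corrected by default. Per-layer DD/SSA paired contrasts run when the
interaction is significant; the one a-priori planned test — supragranular
delta/theta DD, one-tailed — always runs. The high-beta and high-gamma
bands are printed inconsistently in the source literature (26–35 vs 26–36,
68–77 vs 67–76); the defaults follow the running-text values, with the
caption variant available via `default_rois(caption_variant = TRUE)`. No
correction is applied across the six ROIs by default (they are planned);
Holm across ROIs is a config extra.

*Cluster-mass permutation.* Deviant-minus-control seed-referenced synchrony
maps (12 kept contacts x 100 frequencies; superficial seed = kept contacts
1–2, granular seed = 8–9) are tested by sign-flip permutation: the observed
mean map is z-scored pointwise against the permutation distribution,
thresholded at |z| > 1.96, and contiguous supra-threshold bins
(4-neighbourhood in depth x frequency; 8 available) are summed into cluster
masses. The null is the per-permutation *maximum* absolute cluster mass
pooled over both signs; a cluster is significant when it exceeds 95% of the
null maxima (p < 0.025 per tail, 2500 permutations). The cluster-forming
threshold is not standardised; 1.96 is conventional, and the max-mass
correction keeps the family-wise error calibrated regardless (the test suite
verifies the family-wise rate at the nominal two-tailed 0.05 on null
cohorts). p-values use the add-one estimator, so the smallest attainable
p is 1/(n_perm + 1).

# The synthetic cohort

`simulate_recording()` builds, at 10 kHz on a 16 x 50 µm probe:

* spatially correlated 1/f background (exponent 1, per-contact SD 20 µV,
  Gaussian inter-contact correlation of length 2 contacts) plus
  depth-profiled narrowband backgrounds — gamma-band noise above, alpha/beta
  below the granular contact — that produce the spectral gradient the
  alignment uses;
* a stimulus-evoked laminar dipole (zero-sum current profile, granular sink
  at 45 ms, a weaker superficial sink at 85 ms) passed through the 1-D
  forward model, with log-normal trial-to-trial gain;
* induced oscillatory bursts: Hann-windowed sinusoids with random phase per
  trial (so they appear in induced power but largely cancel in evoked
  averages), with per-context *power* gains (amplitude scales with the
  square root of the gain, so doubling a gain doubles the induced-power
  difference);
* spiking transients: ~1 ms biphasic pulses with 500–4000 Hz energy at
  Poisson times — a 20 Hz background, an orientation-tuned evoked volley
  (strongest and earliest at the granular contact, latency increasing
   6 ms/contact away from it), and per-context rate effects;
* a phase-coupling effect: a 37.5 Hz burst whose phase is shared between the
  L1 contacts and two deep-L2/3 contacts on coupled trials and independent
  otherwise, with the per-context gain acting as the coupling probability.

The default catalogue (`default_ground_truth()`) injects the six effects the
analysis is designed to resolve: granular MUA adaptation (redundant rate
gain 0.4, 50–80 ms), supragranular MUA deviance detection (deviant gain 2.5,
140–230 ms), supragranular delta/theta (gain 4) and high-gamma (gain 2.5)
deviant power increases, a superficial high-beta deviant decrease
(gain 0.1), and deviant-specific decoupling (coupling probability 0.05) of
L1 from deep L2/3 at 34–41 Hz. Amplitudes are expressed in units of the
baseline noise SD and were chosen so that a 10-subject cohort recovers all
six effects reliably; the protocol itself prints no physical effect
amplitudes, so these are free parameters of the simulation, not estimates.

Short bursts cannot be arbitrarily narrowband: a 30 ms high-beta burst has a
mainlobe tens of Hz wide, so band-concentration properties are only
meaningful (and only asserted) for bursts whose duration-bandwidth product
permits them; the wavelet ROI averages are insensitive to this leakage
because they integrate the band.

What the generator does *not* emulate: biophysical neuron or conductance
models, retinotopy and stimulus drift dynamics, behavioural state
(locomotion, pupil), electrode drift, or line noise. Passing recovery tests
therefore demonstrates the correctness and statistical calibration of the
analysis chain, not its robustness to every artifact of real recordings.

# Problem sizes and reproducibility

Simulation studies use a many-standards run of 56 trials (7 per orientation)
and a 56-trial flip-flop oddball pair (7 deviants per run), giving 7 matched
trials per context — inside the 7–12 matched-trial range the protocol
reports — with 10 subjects per cohort and log-normal (SD 0.2) between-
subject amplitude variation. Full-session lengths (~250 control /
~150 oddball trials) are the `sequence_spec()` defaults and run identically,
with trial matching capped at 12 per context by default. Every stochastic
step (sequences, noise, trial matching, permutations) is seeded; per-subject
seeds derive deterministically from the master seed, outputs carry the
configuration hash and seed, and re-running any pipeline with the same
configuration and seed is bit-identical.

# Known limitations

* The 1-D forward model ignores lateral current spread and conductivity
  structure; CSD units are arbitrary (as in practice).
* The surrogate pairing makes IES slightly asymmetric in (a, b); a
  symmetrised variant is a config option.
* The repeated-measures ANOVA requires complete subject x layer x context
  tables; subjects missing cells must be dropped by the caller.
* Degrees of freedom are reported conventionally; no attempt is made to
  reproduce non-standard df notations.
* With small permutation counts the minimum attainable cluster p bounds how
  small reported p-values can be; the default 2500 permutations gives
  p >= 1/2501.
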