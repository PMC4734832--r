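---
title: "Water-maze LFP analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-maze LFP analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mazelfp)
```

This vignette documents the models behind `mazelfp`, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the design decisions taken where the methodology was
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## Session model and epoching

A session is one continuous two-channel recording (dCA1 and dlSTR): a
pre-maze baseline (60 s by default), then per trial a swim period ending
when the rat reaches the platform, and a 15 s platform period. Epochs are
half-open intervals `[t_start, t_end)` in seconds; sample conversion is
`floor(t * fs)`, 0-based, so reassembling adjacent epochs never duplicates
a sample. The maze epoch of a trial is the 4 s immediately before the
platform-reach event — the segment in which goal-directed swimming is
guaranteed. If the platform is reached in under 4 s, the epoch is
truncated to the trial bounds and flagged `short`; short epochs are kept
in the epoch table but excluded from spectral averaging, because a
shorter-than-window epoch would be estimated at a different spectral
resolution and bias the phase comparison.

Recordings are stored as raw little-endian float32 plus a JSON sidecar
(sampling rate, channel labels, sample count). 10 kHz acquisitions are
decimated before analysis (default target 1 kHz) with a zero-phase
windowed-sinc FIR low-pass cut at 80 % of the target Nyquist; the kernel
is convolved with its own reverse, so the passband response is the squared
(still flat) magnitude and the phase delay is exactly zero.

## Artifact scrubbing

Shake and knock artifacts appear as high-amplitude burst oscillations. The
detector emulates a manual 0.25 s sliding-window pass, automated for
reproducibility:

* window length 0.25 s, advanced by half a window so bursts straddling a
  boundary are still caught;
* a window is flagged when its RMS **or** its broadband (> 15 Hz
  high-passed) RMS exceeds `median + k_mad * MAD` of that statistic, with
  `k_mad = 6` by default; both thresholds are relative, so detection is
  invariant to rescaling the signal, and a constant trace (zero MAD)
  produces no flags;
* adjacent flagged windows merge, and merged-interval edges are refined at
  25 ms resolution against the same robust threshold. Without refinement
  the window grid over-flags each burst edge by up to a quarter second,
  which visibly biases the recovered-signal fraction at realistic burst
  rates;
* thresholds are computed over the pooled epochs of one task phase.
  Per-phase context matters in both directions: phases legitimately differ
  in amplitude (maze theta is elevated), so a session-wide threshold would
  read the whole maze phase as artifact, while a single 4 s maze epoch is
  too little context when one burst covers half of it.

Analysis windows that touch a flagged interval are excluded whole — no
splicing, which would manufacture spectral discontinuities. The
recovered-signal fraction is `clean / total` time per channel.

The human criterion for "a burst" is not formalisable from the available
description; `k_mad` is therefore an explicit free parameter, and no claim
is made that the default reproduces manual figures on real data.

## Multitaper spectra

PSD and coherence use DPSS (Slepian) tapers computed from the standard
symmetric tridiagonal eigenproblem, with `K = 3` tapers and `NW = 2` — the
smallest standard time-bandwidth product that admits three well-behaved
tapers (`K <= 2NW - 1`) — on 2 s windows with 1 s overlap. FFT length
equals window length, giving a 0.5 Hz grid. Per-window, per-taper
periodograms are averaged over tapers then windows, with one-sided density
scaling, so the raw PSD integrates to the signal variance (checked to 10 %
as a Parseval property). The PSD of an epoch is normalised by dividing by
the RMS of the epoch's clean samples; normalised power therefore scales
linearly with signal amplitude. Coherence,
`|<Sxy>|^2 / (<Sxx><Syy>)`, is left unnormalised — any per-channel scale
cancels — and is refused when only one window-taper estimate exists (it
would be identically 1). The theta summary statistic is the maximum of the
curve over the closed 5–12 Hz band, ties resolving to the lowest
frequency.

In the pipeline, per-epoch theta peaks are the observation unit for the
phase comparison; the pre-maze baseline is split into as many sub-epochs
as there are trials so each phase contributes several observations, and a
one-way fixed-effects ANOVA with Bonferroni follow-ups tests the phase
effect. Phase-level spectra pool the clean windows of all epochs of the
phase.

## Normalised-entropy modulation index

For a phase band and an amplitude band, both obtained by zero-phase FIR
filtering and the Hilbert (analytic-signal) transform, the instantaneous
amplitude is summed into `N = 18` phase bins of 20°, normalised to a
distribution `p`, and

```
MI = (ln N - H) / ln N,   H = -sum p_i ln p_i .
```

MI is 0 for a uniform distribution, 1 when all amplitude lies in one bin;
the log base cancels in the ratio (natural log is used). MI is invariant
to amplitude scaling and to circular rotation of the bin labels — both
pinned by tests, the latter being the property that makes time-shift
surrogates the right null (a shift that merely rotated a periodic
distribution would not change MI; see below).

Filter design: Hamming windowed-sinc, order the larger of three cycles of
the band's low cutoff and the length needed for a transition width of
20 % of the bandwidth, capped at a third of the segment; applied with
exactly zero phase via convolution with the kernel's own reverse. The
transition-width term is essential: with short (three-cycle) kernels the
modulation sidebands of a coupled gamma leak into neighbouring amplitude
bands, and because MI is scale-invariant the leaked — fully modulated —
residual can dominate the comodulogram even at −20 dB.

The comodulogram scans phase bands 2–12 Hz (1 Hz steps, ±1 Hz) against
amplitude bands 20–120 Hz (5 Hz steps, ±5 Hz) by default. These grids and
bandwidths are standard practice defaults, configurable because the
methodology leaves them open. Note that a ±5 Hz amplitude band does not
fully contain both modulation sidebands of a fast theta (±8 Hz), so the
comodulogram maximum can sit one amplitude step above the generative
carrier; parameter-recovery checks therefore accept the true cell ±1 grid
step. Artifact-masked samples are excluded from the histogram only —
filtering and the Hilbert transform always run on contiguous signal.

### Surrogate null

Each of 100 surrogates circularly shifts every amplitude envelope by a
random offset of at least 1 s, destroying the phase–amplitude pairing
while preserving both marginals; `z = (MI - mean_surr) / sd_surr` per
cell. Offsets come from a seeded RNG, so z-matrices are reproducible.
Circular shifting preserves sample count and amplitude distribution, which
is why it is preferred over non-circular shifts. In the pipeline,
surrogates are built per epoch (each epoch's envelope gets its own
offset), since task phases are analysed as collections of short epochs.

A subtlety drives one generator default: for a *strictly periodic* theta,
a circular shift only rotates the phase–amplitude distribution, and MI is
rotation-invariant — the surrogate null would sit on top of the observed
MI and z would hover near 0 at any coupling strength. Time-shift
surrogates are valid for real LFP precisely because theta phase drifts.
The generator therefore gives its oscillators Wiener phase drift
(`phase_jitter`, default 1 rad²/s, broadening the theta line by well under
the 2 Hz analysis bandwidth); `phase_jitter = 0` recovers the strictly
periodic textbook model.

## Synthetic generator: what it does and does not emulate

`generate_coupled_signal` implements the standard multiplicative coupling
model: theta `A_t sin(phi(t))` plus gamma
`A_g [(1-c) + c (1 + cos(phi(t) + phi_0)) / 2] sin(psi(t))` plus `1/f^1.5`
background noise, with `phi, psi` drifting as above. `c` is the fraction
of gamma amplitude modulated by theta phase; `phi_0 = 0` puts maximal
gamma at the envelope-cosine peak.

`generate_session` assembles per-phase segments for two channels. Theta is
amplitude-sustained: a constant-envelope oscillation whose stochastic
phase is the analytic angle of a narrowband (±1 Hz) Gaussian process
mixing a shared and a per-channel independent component. The mixing weight
is solved from the phase's coherence target using the analytic narrowband
and noise spectral densities (`coherence ~ w^4`, corrected for the noise
floor). Envelope normalisation reflects how sustained swim theta behaves —
a raw narrowband Gaussian would fluctuate ~35 % in RMS per 4 s epoch,
which is variance real maze theta does not show — and it keeps per-epoch
spectral estimates stable. Coherence targeting is approximate (the
band-peak statistic is upward-biased at low coherence); the target 1.0
case is exact and pinned by test, and contrasts between phases are
faithfully ordered, which is what the phase-comparison properties use.

Artifacts are damped oscillatory bursts (default 12 Hz) arriving as a
Poisson process, hitting both channels simultaneously (a head-shake moves
the whole headstage), with Gamma-distributed durations (shape 4, mean
1.5 s — fairly uniform, as shake bursts are) and an envelope decaying to
40 % of onset over the burst so the entire nominal interval remains
detectable. Onset amplitude is RMS-matched: burst RMS equals
`burst_amp_factor` × background RMS.

Not emulated: biophysical neural dynamics, volume conduction, spikes,
electrode drift, movement-speed covariates, or any vendor file format.
Absolute theta/gamma amplitudes and SNR are free parameters — nothing
calibrates them to in-vivo magnitudes — so passing tests certify the
analysis chain's correctness and sensitivity under the stated generative
model, not quantitative agreement with any specific animal's recordings.

## Group statistics and behaviour

ANOVAs are fixed-effects and computed from explicit sums of squares (the
one- and two-way decompositions), so every F in a report can be reproduced
by hand; agreement with `aov` to 1e-10 is pinned by tests, and p-values
come from `pf`. The two-way ANOVA requires a balanced complete design with
at least two replicates per cell, matching the session × group layout it
serves; repeated-measures structure across trials within a rat is
deliberately ignored, taking the row as the unit of observation. Pairwise
follow-ups are pooled-variance two-sample t tests with the Bonferroni
adjustment `min(m p, 1)`.

Double-H scoring takes a pre-extracted zone-visit sequence per trial (the
five error-zone identities are configuration, since they depend on the
trained path): an initial error is the first entry into an error zone, and
every further entry into an already-visited zone is a repetitive error, so
`initial <= 5` and `initial + repetitive` equals the total number of
error-zone entries. Consecutive duplicate labels collapse only when their
timestamps are identical (double-logged crossings); genuine re-entries
count. Latencies are start-relative; a missing platform event is flagged
not-reached rather than imputed, and a platform time before the goal-arm
time is rejected as physically impossible.

## Numerical choices and problem sizes

* DPSS tapers: dense symmetric eigendecomposition, cached per
  `(n, NW, K)`; ~2 s once for 2 s windows at 1 kHz.
* Analytic signal: FFT method (one-sided spectrum doubling).
* Surrogate offsets: uniform integers in `[fs, n - fs]` samples.
* Degenerate guards: all-zero amplitude rejects the histogram; zero
  surrogate SD yields z = 0 with a warning; zero within-group variance
  with unequal means yields p = 0.
* Validation problem sizes (chosen as comfortable single-CPU sizes):
  60 s single-condition traces at 1 kHz; sessions of 60 s baseline plus
  4 × 12 s trials with 15 s platforms; 10 seeds per Monte-Carlo property;
  100 surrogates per z-matrix; 2000 simulations for the ANOVA type-I
  check.

## Known limitations

* Coherence targets between 0 and 1 are met only approximately (upward
  bias of the band-peak estimator at low true coherence).
* The comodulogram's default ±5 Hz amplitude bands straddle, rather than
  contain, the sidebands of fast-theta modulation (see above).
* The scrubber's recall is defined for bursts well above background
  (≥ ~8× RMS); artifacts at 2–3× background are below the robust
  threshold by design.
* MI carries a positive finite-sample bias common to entropy estimators;
  comparisons should rely on the surrogate z, which shares the bias
  between observed and null.
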