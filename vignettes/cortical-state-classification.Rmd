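---
title: "Classifying cortical state from LFP and partitioning concurrent haemodynamics"
author: "cortstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cortical state from LFP and partitioning concurrent haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Anaesthetised (and sleeping) cortex alternates between a *synchronised*
state of large-amplitude, low-frequency field potentials and a
*desynchronised* state of low-amplitude, high-frequency activity. The two
states carry different baseline haemodynamics (desynchronisation elevates
oxy- and total haemoglobin and depresses deoxyhaemoglobin) and different
stimulus-evoked responses (robust when synchronised, attenuated and
late-peaking when desynchronised). Any neurovascular analysis that averages
across states therefore mixes two different regimes. `cortstate` assigns a
state to every analysis window of an LFP recording and conditions the
haemodynamic analysis on those labels.

## The classifier, step by step

1. **Feature extraction.** A sliding window (10 s, 1 s step for
   classification; 4 s, 0.4 s step during initialisation — the finer grid
   buys temporal detail where it matters most, at training) is transformed
   by FFT per channel, and the magnitude-squared power is summed into the
   five classical EEG bands: delta 0.5–3, theta 4–7, alpha 8–12, beta
   13–30, gamma 31–80 Hz. Band edges are inclusive; the published gaps
   between bands (e.g. 3–4 Hz) remain unassigned. Powers are computed per
   channel and then averaged over the deep channels (ids 13–16 when
   present), where low-frequency signal power is strongest.
2. **Relational coding.** The five band-power series are reduced to the ten
   absolute pairwise differences (every unordered band pair once, in a
   fixed canonical order). This captures how bands sit *relative to each
   other*, not absolute power.
3. **Bounds.** From the training state with the smaller pairwise-difference
   variance (the desynchronised state in practice, selectable
   automatically or explicitly), the upper bound is
   `UB = mean_k |mean_t Err_k|`, rounded to one decimal place by default;
   the lower bound is exactly `UB/2` and is not re-rounded. Bounds are set
   once per model: coded vectors are only mutually comparable under a
   single, frozen pair of bounds.
4. **Coding.** Each difference becomes one of three integer codes
   (defaults 2/3/4): below LB, between the bounds inclusive, above UB. Any
   integer-separated coding behaves identically under the L1 metric used
   below.
5. **Model vectors.** The `l = 5` most frequent distinct coded vectors per
   state become the model vectors (10 in total for two states). The
   fraction of a state's training windows matching one of its model
   vectors is reported as that state's *coverage* — coded vectors are
   categorical, so occurrence coverage is the operative reading of
   "variance explained". More vectors capture more coverage at linear cost
   in classification time.
6. **Classification.** A new window is coded under the frozen bounds and
   assigned the state of the L1-nearest model vector. Every window gets a
   label; there is no reject option.

### Assumptions

* Two states suffice (the machinery is k-state ready, but the default
  initialisation is two-state); the training recording contains clear
  episodes of both.
* The band-power *pattern*, not absolute power, separates the states —
  which is what makes the classifier robust to gain drift and electrode
  differences.
* Windows are long relative to the band structure (10 s gives 0.1 Hz bins,
  so even the delta band spans ~26 bins) and short relative to state
  dwell times (tens of seconds to minutes).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window / step (classification) | 10 / 1 | s | 0.1 Hz bins; 1 s label resolution |
| window / step (initialisation) | 4 / 0.4 | s | finer temporal detail for training |
| bands | δθαβγ, 0.5–80 | Hz | classical EEG decomposition |
| channels | 13–16 | — | deep sites carry the strongest low-frequency power |
| `l` (model vectors per state) | 5 | — | high coverage at modest comparison cost |
| codes (C1, C2, C3) | 2, 3, 4 | — | any integer-separated triple is equivalent |
| UB rounding | 1 | decimals | O(1) relative powers make 0.1 the natural quantum |
| power normalisation | relative | — | see below |
| RMS scheme (baseline) | 10 / 1 | s | matches the classifier's windowing |
| stable-period floor | 30 | s | excludes transition ramps and noise-dominated snippets |
| trial inclusion | ≥ 5 | trials/state | keeps noisy under-represented states out of grand averages |
| permutation repeats | 50 | — | box-plot outlier control |

**Power normalisation.** Whether band powers should enter the coding raw or
relative (divided by the window's total 0.5–80 Hz power) is genuinely open;
both modes are implemented and the choice is frozen into the trained model.
The default is *relative*, for two reasons: the upper bound is rounded to
one decimal place, which presumes O(1) feature values, and relative powers
make every coded vector — hence the whole classifier — exactly invariant to
multiplying the signal by a constant (a property the test suite asserts).
Raw mode is retained for spectra whose total power is itself informative.

**Channel averaging.** Powers are averaged across channels *after* the
per-channel FFT (and after per-channel normalisation in relative mode).
Averaging voltages before the FFT would let phase offsets between channels
cancel power; averaging powers is robust to them.

**Window time-stamping.** Windows are indexed by their *start* time
everywhere: segmentations, stable periods, stimulus exclusion and pre-trial
classification all key on that stamp. Consequently a window straddling a
transition is scored against the reference label at its start, and detected
state boundaries can sit up to about half a window early; the >30 s
stable-period floor absorbs this.

## Stimulation handling

During stimulation the evoked response contaminates the spectrum, so
windows whose start time falls in `[onset − 0.001 s, onset + 16.432 s]` are
excluded from classification use. Trials are then labelled by the majority
state of the classified windows starting in `[onset − prestim, onset)` with
`prestim` of 1, 5 or 10 s; a tied vote goes to the window nearest the
onset. Keying both rules to the window start time is deliberate: a 10 s
window beginning 1 s before onset extends into the stimulation period, and
excluding windows by *overlap* would leave no pre-stimulus windows at all.
The pre-stimulus stamp is what the prediction is about — the state the
cortex was in when the stimulus arrived.

## The synthetic generator

Each EEG band contributes band-limited Gaussian noise (synthesised in the
frequency domain, exactly zero outside the band), scaled per sample by the
hidden state's amplitude profile; per-state profiles and RMS scales are the
defaults' main levers (synchronised: delta-dominated, RMS 1.0;
desynchronised: beta/gamma-shifted, RMS 0.4). State dwells are shifted
exponentials (mean 120 s, floor 35 s — so >30 s stable periods exist by
construction). Channels share the band statistics but have independent
realisations, with a depth gain that gives deeper channels more delta/theta
power. A slow multiplicative gain drift (log-OU, sd 0.2, time constant
60 s) emulates fluctuating anaesthetic depth and electrode coupling; it is
what makes the amplitude-threshold baseline realistically fallible while
leaving the relative-power coding untouched. Haemodynamics follow the state
with a first-order lag (τ = 5 s — ramps are visible in real data but no
time constant is published, so this is a package convention) towards
per-state plateaus (+8.56 µM Hbo, −5.56 µM Hbr, +2.00 µM Hbt in
desynchronisation — the three species are generated independently, so Hbt
conservation is not enforced on simulated data), plus state-dependent
gamma-variate evoked responses (synchronised: large, peaking ~5 s;
desynchronised: small, maximal ~16 s) and white measurement noise.

What the generator does **not** emulate: biophysical neuron or vascular
dynamics, pixel-space optical imaging, blood-pressure or CO₂ fluctuation,
artefacts (movement, mains hum), non-stationary band profiles within a
state, and graded or mixed states — transitions are instantaneous in the
LFP. Passing tests therefore demonstrate that the pipeline recovers the
structure this model encodes, not that it will reach the same accuracy on
any particular real preparation.

## Numerical choices

* **FFT length.** At the default 1525.879 Hz rate a 10 s window is 15259
  samples — a prime length on which R's mixed-radix FFT degenerates. By
  default the transform is zero-padded to the next highly composite length
  (the `stats::spectrum(fast = TRUE)` convention); windowed energy is
  preserved exactly (Parseval), and the analytic bin spacing of the
  unpadded window (0.1 Hz at 10 s, 0.25 Hz at 4 s) is what
  `frequency_resolution()` reports. `fast = FALSE` forces the exact-length
  transform.
* **Taper.** Rectangular by default (a plain FFT); a Hann option exists for
  spectra with strong leakage concerns.
* **Tie-breaks.** Equal L1 distance to both states keeps the previous
  window's label (temporal continuity), defaulting to synchronised on the
  first window. An RMS exactly at the power threshold is synchronised
  (consistent with "higher → synchronised"); an all-constant RMS series
  triggers a warning. A tied pre-stimulus majority follows the window
  nearest the onset.
* **Quartiles.** The outlier rule uses linear-interpolation quartiles
  (R type 7) and fences at `Q1 − 1.5·IQR` / `Q3 + 1.5·IQR`. The minus sign
  on the lower fence is the only reading under which a lower fence exists
  at all.
* **Degenerate inputs.** Equal per-state generator profiles are allowed
  (they produce a valid labelled recording on which classifiers perform at
  chance); an all-zero difference series yields UB = LB = 0; training
  states with fewer than `l` distinct coded vectors raise an error rather
  than padding.

## The randomisation control, honestly

The control permutes state labels over analysis units (trials or stable
periods) within experiment, recomputes the desynchronised-minus-synchronised
difference 50 times, pools the true difference with the 50 null differences
and applies the 1.5 × IQR rule. Two properties behave differently and are
worth separating. *Detection* — the true difference being flagged — is
essentially certain under a configured effect of realistic size, and the
false-flag rate under a null configuration is small; both are asserted in
the test suite. *Uniqueness* — no permuted difference being flagged
alongside it — is a property of the rule, not of the effect: the
permutation null has bounded support whose extreme lattice points carry
mass of order 1% beyond the fences, so across 50 draws an occasional null
outlier is expected regardless of how strong the true effect is. A unique
outlier should be read as typical, not guaranteed.

## Problem sizes used by the tests

Unit tests run the generator at a reduced sampling rate (256 Hz) and
channel count so each case stays in the seconds range. The end-to-end
blocks use ten 600 s experiments at the full default rate and 16 channels
for state and offset recovery, two 600 s recordings at ~80/20 occupancy for
the comparison with the power threshold, and twenty 9-experiment cohorts of
the 30-trial stimulation protocol for the randomisation control — sizes
chosen to exercise the defaults fairly while keeping the suite fast enough
to run routinely.

## Known limitations

* Two-state initialisation only; k > 2 states would need labelled training
  episodes per state and have not been exercised.
* No streaming mode: classification is offline, though the model's frozen
  bounds and vectors would support it.
* Boundary placement inherits the ±half-window ambiguity of window-start
  stamping; downstream analyses should rely on the stable-period floor
  rather than exact transition times.
* The stimulation-exclusion endpoint (16.432 s) is adopted as a protocol
  constant; it is slightly longer than the 16 s pulse train and its exact
  provenance is undocumented.
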