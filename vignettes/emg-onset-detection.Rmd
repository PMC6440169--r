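---
title: "Adaptive GMM-based detection of EMG movement onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive GMM-based detection of EMG movement onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgonset)
```

## The problem

Surface EMG precedes observable motion: a muscle's electrical activity
rises tens to hundreds of milliseconds before the limb moves. A controller
for an assistive upper-limb exoskeleton that detects this rise can engage
its assistance *before* the kinematics change, which matters most for
users with little residual strength. The obstacles are well known: sEMG
amplitude statistics differ strongly across subjects and across muscles,
and they drift *within* a session (electrode impedance changes, posture
changes, fatigue, residual co-contraction). A fixed amplitude threshold
calibrated at the start of a session therefore degrades over time, and a
feature set chosen on one subject may not transfer to another.

This package addresses both problems with an unsupervised, per-feature
mixture model whose decision threshold adapts continuously, and an
information-theoretic procedure that selects features and muscles by how
much they actually tell us about the rest/movement state.

## The model

For each muscle and each time-domain feature, feature samples at the
window update rate are modelled as a two-component scalar Gaussian
mixture,

$$p(x, \lambda) = w_r \, \mathcal N(x;\mu_r,\sigma_r^2) +
                  w_m \, \mathcal N(x;\mu_m,\sigma_m^2),$$

with the low-mean component identified as *rest* and the high-mean
component as *movement*. The six parameters are estimated by EM on a
training session, unsupervised — no movement labels are needed, the burst
structure of the data itself separates the components. EM stops when the
largest absolute change over all six parameters falls below $10^{-6}$
(configurable; 500-iteration cap). Initialisation splits the sample at
its median; for the unimodal-looking but right-skewed amplitude features
this lands reliably in the basin of the dominant optimum, and a test
verifies the attained log-likelihood against an independent EM
implementation (mclust) to ~1e-11 when both are run to tight convergence.

The rest/movement boundary is the minimum-classification-error threshold
$\theta$ solving $w_r \mathcal N(\theta;\mu_r,\sigma_r^2) =
w_m \mathcal N(\theta;\mu_m,\sigma_m^2)$. In log form this is a quadratic
whenever $\sigma_r^2 \neq \sigma_m^2$; we take the root between the means
when one exists, otherwise the root nearest that interval, flagged. (With
unequal weights the equal-variance solution can legitimately fall outside
the inter-mean interval — e.g. $w=(0.7,0.3)$, unit variances, means 0 and
1 give $\theta = 0.5 + \ln(7/3) \approx 1.347$.) Samples at or above
$\theta$ are classified movement; the boundary itself goes to movement
because the rest criterion is strict inequality.

### Sequential adaptation

Refitting EM at every 10 ms step would be wasteful; freezing $\theta$
ignores drift. Instead each new observation updates the parameters with a
forgetting factor $\alpha = (L-1)/L$:

$$w_{i,l+1} = \alpha w_{i,l} + (1-\alpha)\, p(i \mid x_{l+1}, \lambda_l),$$

with the corresponding responsibility-weighted recursions for the means
and variances (the variance update uses the already-updated mean), and
$\theta$ recomputed in closed form after every update. A sample $t$ steps
in the past carries weight $\propto \alpha^t$, so $L$ is the effective
memory in update steps. The default $L = 1000$ (10 s at the 10 ms update
rate) is long enough to average over individual bursts and short enough to
track within-session drift; it is exposed everywhere. The weights are
renormalised so their sum is *exactly* 1 in floating point. Streaming
classification runs in compiled code; a pure-R single-step
`sequential_update()` defines the recursion and the two are tested for
agreement at 1e-12.

Classification of $x_l$ always uses the threshold derived *before* seeing
$x_l$, so the stream is causal, and adaptation starts at the first test
sample (no burn-in — the training-session parameters are the initial
state).

## Features and windows

Fourteen classical time-domain features are registered; the operating
subset is {IAV, SSI, WL, LOG}, the minimally redundant synergistic set
that the information analysis selects. Windows are 300 ms with a 10 ms
step, right-aligned (a window's timestamp is its end), so feature samples
never look into the future. The threshold features ZC/SSC/WAMP need an
amplitude deadband `eps`; it defaults to 1% of the channel RMS — the
protocol is rest-dominated, so whole-channel RMS approximates rest-phase
RMS without requiring segmentation — and is configurable. The LOG feature
clamps $|x|$ at $10^{-12}$ V (with a warning) to keep zero samples finite.

One deliberate reading of the literature's formulas: the trailing ramp
weight of MMAV2 is implemented as $4(N-i)/N$. The commonly printed
$4(i-N)/N$ is negative, which would make a nominally non-negative
amplitude feature sign-indefinite; the symmetric decaying ramp is the
evident intent (it is continuous at $i = 0.75N$).

The fast path computes all features from cumulative-sum rolling
statistics in $O(n)$; the scalar per-window implementation is the
reference, and tests assert agreement feature-by-feature.

## Information breakdown and selection

Feature values are discretised into equipopulated bins (rank-based, 4 per
channel by default; exactly equipopulated and invariant under monotone
transforms — the estimates depend only on ranks). The mutual information
between the binned response and the phase label is the plug-in estimate,
optionally debiased by a Panzeri–Treves-style first-order correction
(enabled by default below 10,000 samples; at the sample sizes used here
the correction is small either way). The joint information of a feature
set decomposes as

$$I(R;F) = I_{lin} + I_{sig\text{-}sim} + I_{cor\text{-}ind} +
           I_{cor\text{-}dep},$$

built constructively: $I_{lin}$ sums single-channel informations; a
conditionally-independent surrogate $P_{ind}(f|r)=\prod_c P(f_c|r)$ gives
$I_{ind}$ and the (non-positive) redundancy term
$I_{sig\text{-}sim} = I_{ind} - I_{lin}$; the phase-dependent correlation
term is the corresponding divergence between the observed and surrogate
conditionals, and $I_{cor\text{-}ind}$ closes the identity, which
therefore holds to machine precision by construction. Limiting cases pin
the terms down in tests: conditionally independent channels leave both
correlation terms near zero; a duplicated channel gains no information
and is flagged redundant ($I_{sig\text{-}sim} < 0$, and
$\to -I_{lin}/2$ in the near-deterministic-coding limit).

Selection proceeds in two steps. First, features must carry significantly
more information than white noise pushed through the identical pipeline
(Kruskal–Wallis across groups, then per-feature one-sided rank-sum tests
against the noise baseline at p < 0.001). Second, among the retained
features, pairs whose correlation term $I_{cor\text{-}ind} +
I_{cor\text{-}dep}$ is negative are linked as non-synergistic, and each
connected component keeps only its most informative member. On data with
the expected redundancy structure this yields {IAV, SSI, WL, LOG}.
Muscles are then ranked by the joint information of the selected set, and
the top P = 3 feed the info-based multi-muscle detector — three being the
smallest ensemble with a meaningful majority.

Window lengths are compared by a Friedman test on paired per-unit
information at 100/300/500 ms with paired Wilcoxon follow-ups. When every
paired difference is zero the Friedman statistic is 0/0; we report p = 1
(no evidence of a difference), which is the only sensible reading.

## Detectors and scoring

Each muscle's M = 4 feature classifiers vote; rest wins only with at
least $\lfloor M/2 \rfloor + 1$ rest votes, so ties go to movement — the
sensitive direction, appropriate for an assistive trigger. Type 2 applies
the same rule to the muscles' Type 1 outputs. Onsets are 0→1 transitions
of the final label stream surviving a debounce (default 1 step; raise it
to suppress flicker in noisy deployments).

A trial counts as detected (TP) if at least one onset falls within
$[t_0 - 0.5\,\mathrm{s},\ t_0 + 1.0\,\mathrm{s}]$ of the reference onset
$t_0$; latency is the first qualifying onset minus $t_0$ (negative =
anticipation). The acceptance window is a scoring choice, not part of the
method: observed latencies sit around $-0.2$ to $0$ s, well inside it,
and it is configurable. Specificity is counted sample-wise over
rest-phase steps only; the reaction gap between the cue and $t_0$ belongs
to neither phase and is excluded, so ambiguous steps cannot count against
(or for) the detector. $t_0$ itself comes from the measurements, not the
cue: for the reach, the earliest instant any of the four joint angles
reaches 10% of its own peak excursion from the rest baseline (joints
whose excursion stays below a 0.5° floor are ignored; all-flat trials are
flagged unscorable); for the return, the first crossing of the 2 N·m
elbow-torque threshold. Taking the *earliest* crossing across joints is a
choice — the alternative (e.g. the mean crossing) would shift all
latencies by a constant without reordering detectors.

Cross-validation is session-wise within a subject: each session trains
the mixtures, all remaining sessions are tested, and outcome measures are
averaged over rotations. A subject-wise holdout is the natural extension
but is out of scope here; the per-subject rotation is what the synthetic
benchmark exercises.

## The synthetic generator

No recordings ship with the package; the generator produces
protocol-faithful surrogates with full ground truth, which is what the
tests and the benchmark consume. Its defaults *are* the study conditions:
12 s trials (LED on 6 s — free reach in transparent mode for 2.5 s, then
position control; LED off 6 s — return after the torque crossing), 24
trials per session, 7 sessions per subject, 1 kHz, seven muscles.

The EMG model is amplitude-modulated Gaussian noise: channel $c$ is
$\sigma_c(t)\,\varepsilon(t)$ with
$\sigma_c(t) = \sigma_{rest}(1 + (g_c-1)\,e(t))$, where $e(t)$ is a
raised-cosine burst envelope (0.15 s edges) and $g_c$ the per-muscle,
per-event gain. This is the standard surrogate for interference-pattern
sEMG: it exercises every amplitude feature and the mixture model exactly
as real EMG does, while having a known rest RMS, known onsets and known
information structure. What it does *not* emulate: motor-unit
recruitment, spectral compression under fatigue, motion artefact, or
direction-specific kinematic differences — so passing tests demonstrate
the algorithmic contracts, not clinical performance. Defaults chosen once
as realistic values: rest noise 8 µV; reach-active gains AD 4.0, PD 3.2,
Biceps 2.6, Trapezius 1.8, Triceps 1.4; return-active gains ECU 3.6,
Biceps 2.8; a 10% residual of the reach excess while the target posture
is held (muscles never relax fully against a held posture); reaction time
0.30 ± 0.05 s truncated at 0.1 s; 80 ms electromechanical delay between
EMG and kinematic onset; 1.0 s minimum-jerk reach and return; joint
amplitudes (sAA, sFE, sIE, eFE) = (12, 40, 8, 35)° with 0.02° sensor
noise; a minimum-jerk torque ramp placed to cross 2 N·m exactly at the
ground-truth return instant (5 N·m peak, 0.4 s rise). Optional stressors:
a fractional within-session growth of $\sigma_{rest}$ (`drift`) and a
50 Hz mains component (`mains_amp`), both 0 by default.

The `drift` dial exists to demonstrate the point of the sequential
update: with the rest noise doubling over a session, a frozen-threshold
ablation's rest-phase false-positive rate climbs from ~0 to ~1 between
the first and last third of the session, while the adaptive detector's
stays flat. The acceptance script reports both numbers.

## Numerical choices and degenerate inputs

- **Zero-phase filtering.** Offline filtering is forward–backward
  (squared magnitude response, zero phase) so the filters add no group
  delay to latency estimates; a causal single-pass mode exists for online
  emulation. The implementation pads by odd reflection and initialises
  each pass at the step steady state; the padding length scales with the
  slowest filter pole (the Q = 30 notch rings for ~200 samples, far
  longer than the filter order suggests), so a pure 50 Hz tone is
  attenuated below 0.1% RMS and a constant input maps to ~1e-12 of its
  amplitude.
- **Segmentation windows.** The GoForward movement phase runs from the
  cue to position-control engagement; the GoBackward movement phase runs
  2 s from LED-off (capped at half the off period). The return completes
  in well under 2 s; letting the window run longer absorbs post-return
  quiescence into the movement label, which measurably dilutes the
  information estimates and can invert the backward muscle ranking.
- **Degenerate fits.** Zero-variance training data is an error; a
  collapsing component (variance below 1e-12 × sample variance) is
  floored and flagged, which also handles the exactly-separable two-point
  case. Underflowing responsibilities assign the sample to the
  nearer-mean component. Equal component means make the threshold
  degenerate (flagged, common mean returned).
- **Intervals** are 1-based half-open `[start, end)` sample-index pairs
  with parallel time bounds in seconds.

## Problem sizes

The test suite simulates short-trial sessions (8 s trials, 4 trials) for
most properties and one full-protocol subject (7 sessions × 24 × 12 s)
for the end-to-end benchmark; the acceptance script uses the
full-protocol subject throughout. These sizes give stable estimates
(e.g. ~29,000 feature steps per session) while keeping a complete run in
the minutes range on one CPU.

## Known limitations

Per-feature mixtures are univariate; no cross-feature covariance is
modelled (deliberately, matching the voting architecture). The white-noise
screening and the breakdown use binned estimators — continuous/binless
estimators are out of scope. Backward-event latency is positive relative
to the torque crossing (the torque reference already lags the EMG onset by
construction), so anticipation claims only make sense for the forward
event. And the generator's Gaussian surrogate cannot certify performance
on pathological EMG (spasticity, tremor), only the correctness of the
machinery.
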