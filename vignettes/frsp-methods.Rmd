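---
title: "Methods: fixation-related spectral perturbation analysis of sentence reading"
author: "frsp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixation-related spectral perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(frsp)
```

# The measurement problem

In self-paced sentence reading, the onset of word processing is marked not
by a stimulus trigger but by the reader's own first fixation on the word.
Co-registering eye tracking with EEG therefore allows event-locked analyses
of natural reading: the *fixation-related spectral perturbation* (FRSP) is
the change in oscillatory EEG power after a fixation (or the sentence-initial
fixation), relative to a pre-event baseline, expressed as a dB log ratio.
This package implements that analysis chain end to end —

1. word-level eye-movement measures with standard exclusion rules,
2. constant-cycle wavelet time-frequency decomposition,
3. dB baselining and cluster × band × time-window aggregation,
4. within-subject factorial ANOVA, planned contrasts and per-subject
   linear-trend (slope) tests —

together with a synthetic generator for the whole co-registered experiment
(stimulus corpus, fixation scanpaths, 64-channel EEG with injected
band-limited power effects), so that every stage is testable, with known
ground truth, without any recorded data.

The emulated experiment crosses word order (ORD: syntactically ordered;
RDM: pseudo-randomized) with target-word semantics (COR: congruent; SEM:
semantically unrelated), in 120 sentence quadruples read by 32 subjects in
two counterbalanced lists. Three ground-truth EEG effects are built into
the default synthetic sessions: a lower-beta (13–18 Hz) desynchronization
after fixations on semantically unrelated targets at the left
parieto-occipital cluster (0–300 ms), a theta (4–7 Hz) power elevation
300–900 ms after sentence onset for ordered sentences at both
parieto-occipital clusters, and a gamma (31–55 Hz) power ramp rising
linearly over the first 1800 ms of ordered sentences at right posterior
sites.

# Synthetic corpus and scanpaths

Word identities are never modelled: every downstream computation consults
only word positions and fixation timing, so a sentence is a vector of word
lengths (characters, drawn from a fixed distribution over 2–12 with mean
≈ 6.4). Sentence lengths are `round(Normal(9.56, 1.61))`, clipped at 4
words (round-half-to-even; clipping keeps the draw cheap and the clip is
rare). The target word is never the first or the last word.

The 1-based target position is drawn *conditionally on sentence length*,
`round(Normal(7.1 + 0.8 (L − 9.56), 0.55))`, resampled into `[2, L − 1]`.
The length–position coupling is essential: with an independent
`Normal(7.1, 1.37)` draw, truncation at `L − 1` pulls the realized mean
position down to ≈ 6.65, inconsistent with the joint statistics the
generator is meant to reproduce (mean length 9.56 *and* mean position 7.1
under the never-first/never-last constraint imply that position tracks
length). The slope 0.8 and residual SD were fixed once, from those joint
statistics alone, before any pipeline run.

Scanpaths are generated word by word, left to right. Each word is fixated
unless skipped (`skip_prob_other = 0.10`; the target `0.05`; the first
word never, since the gaze enters the sentence at its left edge). Fixation
durations are Gamma with shape 35 and condition-specific means; with
probability `refixation_prob` an immediate same-word refixation follows
(counting toward gaze duration), and after the first pass a single
second-pass fixation on the target is appended with probability
`regression_prob` (counting toward total viewing time only). Successive
fixations are separated by a fixed 30 ms saccade gap — only fixation
onsets and durations enter any downstream computation, so saccade
kinematics are deliberately out of scope. The per-condition parameters are
calibrated so the closed-form expectations

$$\mathrm{FFD}=m_1,\qquad \mathrm{GD}=m_1+p_{\text{refix}}\,m_{\text{refix}},
\qquad \mathrm{TVT}=\mathrm{GD}+p_{\text{reg}}\,m_{\text{2nd}}$$

equal 198/227/239 ms (ORD_COR), 203/237/270 (ORD_SEM), 211/248/273
(RDM_COR) and 217/260/290 (RDM_SEM). The shape of 35 keeps
P(duration < 80 ms) below 0.001 for every default mean, so the exclusion
rules (below) barely touch the calibration. Skipping and regression
probabilities are package choices — typical self-paced-reading rates —
because only the duration means are pinned down externally.

Two counterbalanced lists are built by randomly halving the quadruples:
list 1 sees one half as ORD_COR + RDM_SEM and the other half flipped;
list 2 swaps the halves. Every subject reads each quadruple exactly twice
(once ordered, once randomized, with opposite target semantics) and
contributes trials to all four conditions.

A note on sampling precision: with 32 subjects × 60 trials per condition,
the grand condition mean of GD/TVT has a Monte-Carlo standard error of
≈ 2–2.6 ms (the all-or-none refixation/regression mixture dominates the
trial variance). Realized means therefore scatter by a few ms around the
calibrated expectations at any fixed seed; the expectation-level
calibration itself is verified in the test suite by simulating ≥ 10⁴
target trials per condition.

# Synthetic EEG

Each subject's session is one continuous multi-channel recording at
500 Hz. The background is independent `1/f` noise per channel (spectral
exponent 1 by default, white noise at 0), scaled to 10 µV SD, plus a 10 Hz
idle rhythm at posterior channels. Trials are placed sequentially with
inter-trial intervals drawn from 750–1220 ms and enough spacing for the
sentence-locked analysis span. The event table holds every fixation (the
first first-pass fixation on the target is classed `target_fixation`) and
one `sentence_onset` event per trial.

Effects are *induced* power modulations, not additive evoked transients:
the band-limited component of each affected channel — extracted with a
zero-phase frequency-domain filter with 2 Hz raised-cosine transitions —
is multiplied by a gain envelope and recombined with the band-stop
remainder. Inside an event window the envelope reaches the amplitude gain
$10^{g/20}$ (power change $g$ dB) on a plateau with Hann ramps over the
tapered edges; ramp templates interpolate the gain linearly in dB across
the window. Overlapping windows compose multiplicatively. Channels outside
the six analysis clusters receive no effect. Effect sizes in dB are not
established for real data of this kind, so the default gains (−1 dB beta,
+1 dB theta, 0→+1 dB gamma ramp) are package choices sized for reliable
detection at 32 subjects.

One measurement caveat is physical, not a defect: a constant-cycle kernel
at frequency $f$ has a spectral mainlobe of roughly $\pm 2f/3$ (3 cycles),
so a narrow-band injection (e.g. 13–18 Hz read out at 15 Hz) is diluted by
the unamplified noise the kernel also integrates; the measured plateau for
a 3 dB injection is ≈ 1.7 dB. The test suite checks full ±0.3 dB recovery
with an injected band that covers the kernel mainlobe, and checks the
narrow-band case against a spectral-overlap oracle (kernel power spectrum
× background spectrum × gain profile). The default effect templates are
narrow-band, so the *measured* group effects are attenuated versions of
the nominal gains — which is also how real band-limited effects reach a
wavelet analysis.

# Eye-movement measures

First-pass segmentation assigns, per word, the maximal run of consecutive
fixations starting at its first fixation; later returns are second pass.
FFD is the duration of the first first-pass fixation, GD the sum of
first-pass durations, TVT the sum of all durations on the word; a word
with no surviving first-pass fixation counts as skipped, and
skipped-target trials are excluded from target analyses.

Exclusions: fixations shorter than 80 ms are removed, then fixations
longer than the subject's mean + 3 SD. The mean and SD are computed per
subject on raw (not log) durations pooled over all of that subject's
fixations, after the 80 ms cut, in one pass — the trimming rule speaks of
the *individual* mean, and pooling over measures and conditions is the
common reading; iterative re-trimming is deliberately not done. The upper
cut is strict (`>`), so ties at the boundary survive and an all-equal
duration set loses nothing.

Condition statistics follow standard practice for reading measures:
natural-log transform, subject × condition means, one-way
repeated-measures ANOVA over the four conditions, then paired t-tests of
the semantic contrast within each word-order level; raw (ms) means are
reported alongside for interpretability.

# Wavelet decomposition and FRSP

The analysis kernel at frequency $f$ is a Hann-tapered complex sinusoid of
nominal length `round(3 · fs / f)` samples (constant 3 cycles at every
frequency of the 3–70 Hz, 1 Hz grid; per-frequency cycle counts can be
supplied for the frequency-growing convention some toolboxes use). Kernels
are normalized so that a unit-amplitude sinusoid at the kernel frequency
yields unit power. Under this convention the expected wavelet power of
white noise with variance σ² is $2\sigma^2 f/f_s$ — the kernel's noise
bandwidth grows linearly with frequency — and the test suite asserts this
analytic law rather than a flat profile.

Epochs are sample-accurate half-open slices `[t0, t1)` with time 0 at the
event-onset sample (the onset sample belongs to the post-event side):
−1000…+1500 ms around target fixations, −1000…+2500 ms around sentence
onsets. Convolution is FFT-based; because the output time axis is
decimated (default: every 8th sample, 16 ms), the inverse transform is
taken at length `nfft/8` after aliasing the product spectrum — an exact
identity for decimated convolution, not an approximation — which makes
the whole-study transform tractable on one CPU. A validity mask marks,
per frequency, output samples within half a kernel of an epoch edge; at
3 Hz that trims 500 ms from each end, so a −1000…+1500 ms epoch is valid
over −500…+1000 ms. (Reported valid ranges in the EEG literature
sometimes differ slightly from this half-kernel arithmetic, reflecting
toolbox-internal output grids; the package documents the arithmetic and
does not chase such conventions.) A continuous mode — convolve the whole
recording once, then slice — is provided because fixation epochs overlap
in natural reading; epoched and continuous modes agree exactly on the
jointly valid region.

Baselining uses the 1000 ms before the locking event. The default
`trial_mean` scheme divides the trial-averaged power by the trial-averaged
baseline power and takes `10·log10`; it is exactly scale-invariant and
gives 0 dB in expectation for stationary input. The alternative
`single_trial` scheme (per-trial division, then averaging of per-trial dB)
is also implemented; note that averaging the log of noisy power estimates
carries a negative offset on stationary data (about −2 dB at low
frequencies, where the baseline holds few independent samples). The offset
is common to all conditions and cancels in contrasts, but `trial_mean` is
the default for its clean null behaviour.

# Aggregation and inference

FRSP maps are averaged — unweighted — over the channels of six fixed
five-electrode clusters (frontal/central/parieto-occipital × left/right),
the inclusive frequency bins of five bands (theta 4–7, alpha 8–12, lower
beta 13–18, upper beta 19–30, gamma 31–55 Hz), and the valid samples of
300 ms windows (two windows at the target level, six at the sentence
level). Any cell with no valid sample raises an error naming the cell.

The repeated-measures ANOVA treats subject as the random factor and tests
every within-subject effect against its interaction with subject. It is
implemented by projecting each subject's cell-mean vector onto orthonormal
effect contrasts (Kronecker products of normalized Helmert contrasts):
with balanced data this reproduces the textbook sums-of-squares
decomposition exactly (asserted against `stats::aov` error strata and
against hand-computed sums of squares at 10⁻¹⁰), while giving direct
access to per-effect error terms, to Greenhouse–Geisser ε (available, but
off by default — uncorrected dfs are the reference behaviour), and to
degenerate inputs (constant data yield F = 0 rather than 0/0). The
supported layouts include Time(2) × Hemisphere(2) × Cluster(3) ×
Condition(2) at the target level and Time(6) × Cluster(6) × Condition(2)
at the sentence level; for a single two-level factor, F equals the squared
paired t.

Planned contrasts are two-sided paired t-tests per cluster/band/window
cell, without multiple-comparison correction (the reference analysis
reports none; α = 0.05 throughout). A hierarchical follow-up driver
implements the gated sequence: overall ANOVA → per-hemisphere ANOVA when
the Time × Cluster × Condition interaction is significant → per-window
Cluster × Condition ANOVAs → per-cluster t-tests in windows with a
significant interaction.

The gamma trend test fits, per subject and condition, an OLS line to the
six sentence-level window means with the *window index* (1…6) as
regressor — slopes are then in dB per 300 ms step and comparable across
configurations — and tests the individual slopes against zero (one-sample,
one-sided) per condition, plus a two-sided paired t between conditions.
At the sentence level the two ordered and the two randomized conditions
are pooled (ORD vs RDM), and no hemisphere factor is used.

# Problem sizes, runtime and reproducibility

All randomness derives from one root seed via per-module child streams, so
any pipeline output is a pure function of (configuration, seed), and
regeneration is bit-identical. The test suite runs the full eye-movement
calibration at the default 32 subjects × 120 quadruples. For the
end-to-end spectral study the package's test configuration uses each
subject's first 30 quadruples (60 trials) and synthesizes the three
clusters the directional checks need (left/right parieto-occipital, right
central); at these sizes the whole study runs in a few minutes on one CPU
while leaving the group effects many standard errors from zero. The
vignette-level defaults (all 120 quadruples, all 30 cluster channels, or
the full 64-channel montage) scale the same code up linearly.

# What the synthetic data do and do not show

The generator emulates the *structure* the pipeline consumes: calibrated
fixation-duration distributions, condition-dependent refixation and
regression behaviour, 1/f EEG background with posterior alpha, and
event-locked induced band-power changes at specified clusters. It does not
emulate ocular or myogenic artifacts (sessions are generated artifact-free,
so no ICA stage exists here), volume conduction or reference-electrode
geometry (channels are independent), parafoveal preview or landing-position
effects, word-frequency/predictability modulation of durations, or
overlapping spectral signatures of successive fixations. Green tests
therefore certify the measurement and inference chain — that injected,
known effects of realistic size are recovered with correct direction,
location and timing, and that null data stay null at the nominal α — not
that any particular real dataset would show these effects.

# Known limitations

* Narrow-band effects are measured attenuated by the constant-cycle
  kernel bandwidth (see above); between-band leakage is likewise nonzero
  for neighbouring bands.
* The RM-ANOVA requires complete, balanced cell tables; unbalanced input
  is an error by design (aggregate first).
* `single_trial` baselining is offered for comparability but carries the
  documented stationary-data offset.
* BrainVision I/O covers the multiplexed float32/int16 dialects the
  package writes; vectorized orientation is not implemented.
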